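test_that("contribution rules reproduce the framework's weighting scheme", {
  # family-structure weighting, incl. the sole-parent equivalence premise
  expect_equal(contribution_parent_weighted(1, 2), 1)
  expect_equal(contribution_parent_weighted(2, 2), 2)
  expect_equal(contribution_parent_weighted(1, 1), 2)
  expect_equal(contribution_parent_weighted(0, 2), 0)
  expect_error(contribution_parent_weighted(2, 1), "exceeds")

  # persistence weighting is strictly ordered
  lc <- vapply(
    c("absent", "past", "current", "persistent"),
    contribution_longitudinal, numeric(1)
  )
  expect_equal(unname(lc), c(0, 1, 2, 3))
  expect_true(all(diff(lc) > 0))
  expect_error(contribution_longitudinal("sometimes"), "temporal")

  # occupational-status linear map: 1 at the lowest percentile, 0.25 at the
  # cut, nothing above it
  expect_equal(contribution_occupation(0), 1)
  expect_equal(contribution_occupation(0.25), 0.25)
  expect_equal(contribution_occupation(0.10), 0.70)
  expect_equal(contribution_occupation(0.30), 0)
  expect_equal(contribution_occupation(NA), 0)
  expect_error(contribution_occupation(1.2), "percentile")

  # prevalence saturation at 2
  expect_equal(vapply(0:3, contribution_event_prevalence, numeric(1)), c(0, 1, 2, 2))
  expect_error(contribution_event_prevalence(-1), "negative")
  expect_equal(vapply(0:3, contribution_sibling_weighted, numeric(1)), c(0, 1, 2, 2))

  expect_equal(contribution_remoteness("none"), 0)
  expect_equal(contribution_remoteness("outer_regional"), 1)
  expect_equal(contribution_remoteness("remote_or_very_remote"), 2)
})

test_that("hand-specified fixture families score as computed by hand", {
  co <- svf_fixture("tiny")
  expected <- attr(co, "expected")
  scores <- svf_score(co)
  expect_equal(scores$simple, expected$simple)
  expect_equal(scores$weighted, expected$weighted)
})

test_that("score_family agrees exactly with the brute-force oracle", {
  led <- svf_ledger()
  co <- random_cohort(300, led, seed = 42)
  scores <- svf_score(co, led)
  for (r in seq_len(nrow(co))) {
    orc <- oracle_score_row(as.list(co[r, ]), led)
    expect_equal(scores$simple[r], orc$simple)
    expect_equal(scores$weighted[r], orc$weighted)
  }
})

test_that("adding a presence signal never decreases either score", {
  led <- svf_ledger()
  co <- random_cohort(60, led, seed = 7)
  base <- svf_score(co, led)
  set.seed(99)
  for (iter in 1:120) {
    r <- sample(nrow(co), 1)
    co2 <- elevate_one(co, r, led)
    s2 <- svf_score(co2, led)
    expect_gte(s2$simple[r], base$simple[r])
    expect_gte(s2$weighted[r], base$weighted[r])
  }
})

test_that("a sole affected parent scores like a couple with both affected", {
  led <- svf_ledger()
  ind <- svf_indicators(led)
  pw <- ind$id[ind$method == "PARENT_WEIGHTED"]
  for (id in pw) {
    co <- svf_empty_cohort(2, led)
    co$n_parents <- c(1L, 2L)
    co[[paste0(id, "__parents")]] <- c(1, 2)
    s <- svf_score(co, led)
    expect_equal(s$weighted[1], s$weighted[2])
    expect_equal(s$weighted[1], 2)
  }
})

test_that("scores are bounded and missing observations score zero", {
  led <- svf_ledger()
  co <- random_cohort(200, led, seed = 3)
  s <- svf_score(co, led)
  expect_true(all(s$simple >= 0 & s$simple <= 32))
  expect_true(all(s$weighted >= 0 & s$weighted <= 63))

  empty <- svf_empty_cohort(4, led)
  s0 <- svf_score(empty, led, flag_missing = TRUE)
  expect_true(all(s0$simple == 0))
  expect_true(all(s0$weighted == 0))
  expect_true(all(s0$n_unobserved == 32))
})

test_that("score validation rejects inadmissible inputs", {
  led <- svf_ledger()
  co <- svf_empty_cohort(2, led)
  co$n_parents <- c(1L, 2L)
  co$mental_ill_health__parents <- c(2, 1) # two affected parents, sole family
  expect_error(svf_score(co, led), "exceeds n_parents")

  co2 <- svf_empty_cohort(1, led)
  co2$not_an_indicator__present <- 1
  expect_error(svf_score(co2, led), "unknown indicator")

  co3 <- svf_empty_cohort(1, led)
  co3$low_status_occupation__percentile <- 1.4
  expect_error(svf_score(co3, led), "percentile")

  expect_error(svf_score(svf_empty_cohort(1, led)[0, ], led), "no families")
})

test_that("binary matrix marks presence exactly where a contribution exists", {
  led <- svf_ledger()
  co <- random_cohort(150, led, seed = 11)
  bin <- svf_binary_matrix(co, led)
  s <- svf_score(co, led)
  expect_identical(dim(bin), c(150L, 32L))
  expect_true(all(bin %in% 0:1))
  expect_equal(unname(rowSums(bin)), as.numeric(s$simple))
  # occupation above the cut is absent even though a percentile is recorded
  co4 <- svf_empty_cohort(1, led)
  co4$low_status_occupation__percentile <- 0.30
  expect_equal(sum(svf_binary_matrix(co4, led)), 0)
})
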