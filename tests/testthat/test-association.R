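test_that("Hodges-Lehmann estimate matches exhaustive enumeration", {
  expect_equal(hodges_lehmann_shift(c(1, 2), c(3, 4))$estimate, 2)
  expect_equal(hodges_lehmann_shift(c(5, 1, 3), c(5, 1, 3))$estimate, 0)
  set.seed(31)
  for (rep in 1:20) {
    x <- round(rnorm(sample(2:30, 1), sd = 3), 2)
    y <- round(rnorm(sample(2:30, 1), mean = 1, sd = 3), 2)
    expect_equal(hodges_lehmann_shift(x, y)$estimate, oracle_hl(x, y))
  }
  expect_error(hodges_lehmann_shift(numeric(0), 1:3), "nonempty")
})

test_that("Hodges-Lehmann shift is equivariant and matches wilcox.test", {
  set.seed(12)
  x <- rnorm(25)
  y <- rnorm(30, 1)
  h0 <- hodges_lehmann_shift(x, y)
  h5 <- hodges_lehmann_shift(x, y + 5)
  expect_equal(h5$estimate, h0$estimate + 5)
  expect_equal(h5$ci_low, h0$ci_low + 5)
  expect_equal(h5$ci_high, h0$ci_high + 5)
  # independent cross-check: the rank-based interval in stats::wilcox.test
  wt <- suppressWarnings(stats::wilcox.test(y, x, conf.int = TRUE))
  expect_equal(h0$estimate, unname(wt$estimate))
  expect_equal(c(h0$ci_low, h0$ci_high), as.numeric(wt$conf.int),
    tolerance = 1e-8, ignore_attr = TRUE
  )
})

test_that("rank test matches exact enumeration on small untied samples", {
  expect_equal(svf_rank_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)), 0.10)
  set.seed(17)
  for (rep in 1:15) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    v <- sample(1000, n1 + n2) / 7
    g <- rep(c("a", "b"), c(n1, n2))
    expect_equal(
      svf_rank_test(v, g),
      oracle_wilcoxon_exact(v[g == "a"], v[g == "b"]),
      tolerance = 1e-12
    )
  }
})

test_that("rank test is label-invariant, needs two groups, handles k groups", {
  set.seed(5)
  v <- rnorm(40)
  g <- rep(c("x", "y"), 20)
  expect_equal(svf_rank_test(v, g), svf_rank_test(v, ifelse(g == "x", "y", "x")))
  expect_error(svf_rank_test(v, rep("x", 40)), "two nonempty groups")
  g3 <- rep(c("a", "b", "c"), length.out = 40)
  expect_equal(svf_rank_test(v, g3), stats::kruskal.test(v, factor(g3))$p.value)
})

test_that("rank test holds its size under the null", {
  set.seed(2024)
  reps <- 1000
  rejections <- 0
  for (r in seq_len(reps)) {
    v <- rnorm(60)
    g <- rep(c("a", "b"), 30)
    if (svf_rank_test(v, g) < 0.05) rejections <- rejections + 1
  }
  bounds <- stats::qbinom(c(0.025, 0.975), reps, 0.05)
  expect_gte(rejections, bounds[1])
  expect_lte(rejections, bounds[2])
})

test_that("cumulative risk regression recovers a planted slope", {
  set.seed(88)
  n <- 1000
  counts <- rpois(n, 3)
  b <- 1.17
  y <- 5 + b * counts + rnorm(n, sd = 4)
  fit <- svf_risk_regression(y, counts)
  expect_lt(abs(fit$beta - b), 2 * fit$se)
  expect_lt(fit$p, 0.001)
  expect_error(svf_risk_regression(y, rep(2, n)), "zero variance")
  # no planted relationship: slope indistinguishable from zero
  y0 <- rnorm(n)
  fit0 <- svf_risk_regression(y0, counts)
  expect_lt(abs(fit0$beta), 3 * fit0$se)
})

test_that("risk counts follow the documented modifiable panel", {
  co <- svf_fixture("null", seed = 1, n_families = 50)
  counts <- svf_risk_counts(co)
  expect_length(counts, 50)
  expect_true(all(counts >= 0 & counts <= length(svf_count_panel())))
  # hand check one family
  i <- 1
  by_hand <- sum(vapply(names(svf_count_panel()), function(cl) {
    !is.na(co[[cl]][i]) && co[[cl]][i] %in% svf_count_panel()[[cl]]
  }, logical(1)))
  expect_equal(counts[i], by_hand)
})

test_that("association suite recovers planted risk-factor directions", {
  co <- svf_fixture("reference", seed = 14, n_families = 800)
  scores <- svf_score(co)
  bin <- svf_binary_matrix(co)
  fit <- svf_efa(bin, k = 3)
  fs <- svf_factor_scores(fit, bin)
  assoc <- svf_associations(co, scores, fs)

  smoking <- assoc[assoc$risk_factor == "Smoking during pregnancy" &
    assoc$metric == "weighted" & !assoc$reference, ]
  expect_gt(smoking$estimate, 0)
  expect_lt(smoking$p, 0.05)
  solitary <- assoc[assoc$risk_factor == "Solitary sleep" &
    assoc$metric == "weighted" & !assoc$reference, ]
  expect_lt(solitary$estimate, 0)

  # structural exclusion: surface-sharing families never enter the
  # solitary-sleep contrast
  n_sharing <- sum(co$rf_surface_sharing == "yes", na.rm = TRUE)
  sol_rows <- assoc[assoc$risk_factor == "Solitary sleep" &
    assoc$metric == "weighted", ]
  expect_equal(unique(sol_rows$n_excluded), n_sharing)
  expect_lte(sum(sol_rows$n) + unique(sol_rows$n_excluded) +
    unique(sol_rows$n_missing), nrow(co))

  # reference rows carry no shift estimate; accounting adds up
  expect_true(all(is.na(assoc$estimate[assoc$reference])))
  ind_rows <- assoc[assoc$risk_factor == "Indigenous status" &
    assoc$metric == "weighted", ]
  expect_equal(sum(ind_rows$n) + unique(ind_rows$n_missing), nrow(co))

  # parametric sensitivity estimates agree in direction where nonparametric
  # shifts are significant
  sig <- assoc[!assoc$reference & !is.na(assoc$estimate) &
    !is.na(assoc$estimate_param) & assoc$p < 0.01 &
    abs(assoc$estimate) > 0.1, ]
  expect_true(all(sign(sig$estimate) == sign(sig$estimate_param)))

  # BH column present and never smaller than the raw P
  expect_true(all(assoc$p_bh >= assoc$p - 1e-12, na.rm = TRUE))

  # deterministic given the cohort
  assoc2 <- svf_associations(co, scores, fs)
  expect_identical(as.data.frame(assoc), as.data.frame(assoc2))

  p <- autoplot(assoc, metrics = "weighted")
  expect_s3_class(p, "ggplot")
})

test_that("shift intervals cover zero when no association is planted", {
  covered <- 0
  reps <- 40
  for (s in seq_len(reps)) {
    co <- svf_fixture("null", seed = 1000 + s, n_families = 150)
    sc <- svf_score(co)
    g <- co$rf_smoking
    ok <- !is.na(g)
    hl <- hodges_lehmann_shift(
      sc$weighted[ok & g == "no"],
      sc$weighted[ok & g == "yes"]
    )
    if (hl$ci_low <= 0 && hl$ci_high >= 0) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.9)
})
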