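test_that("the 0.40 inclusion rule reproduces the reference typing", {
  ref <- svf_reference_loadings()
  inc <- svf_included_indicators(ref, threshold = 0.40)
  expect_length(inc, 21)
  # the chaotic-lifestyle type
  expect_setequal(
    svf_included_indicators(ref, factor = "chaotic"),
    c(
      "alcohol_misuse", "substance_abuse", "criminal_offending",
      "long_term_criminal_offending", "domestic_violence",
      "child_abuse_neglect", "children_not_in_care", "multiple_partners",
      "stressful_life_events", "transience"
    )
  )
  # indicators printed exactly at the threshold are included
  expect_true("mental_ill_health" %in% inc)
  expect_true("limited_access_care" %in% inc)
  expect_length(svf_included_indicators(ref * 0), 0)
})

test_that("degenerate inputs are handled: constant columns, excessive k", {
  bin <- svf_binary_matrix(svf_fixture("null", seed = 5, n_families = 200))
  bin[, "risky_behaviours"] <- 0
  expect_warning(fit <- svf_efa(bin, k = 2, reference = NULL), "constant")
  expect_equal(nrow(fit$loadings), 31)
  expect_identical(fit$dropped, "risky_behaviours")

  small <- bin[, 1:4]
  suppressWarnings(
    expect_error(svf_efa(small, k = 3, reference = NULL), "at least")
  )
  suppressWarnings(expect_error(svf_efa(bin, k = 0), "at least 1"))
})

test_that("varimax rotation preserves the factor subspace", {
  bin <- svf_binary_matrix(svf_fixture("reference", seed = 2, n_families = 1000))
  R <- stats::cor(bin)
  L0 <- svfscore:::principal_axis(R, 3)
  fit <- svf_efa(bin, k = 3)
  # rotation is orthonormal, so L L' is invariant
  expect_equal(
    fit$loadings %*% t(fit$loadings),
    L0 %*% t(L0),
    tolerance = 1e-8, ignore_attr = TRUE
  )
})

test_that("in-sample factor scores are standardized and uncorrelated", {
  bin <- svf_binary_matrix(svf_fixture("reference", seed = 4, n_families = 2000))
  fit <- svf_efa(bin, k = 3)
  fs <- as.matrix(svf_factor_scores(fit, bin)[, fit$factor_names])
  expect_true(all(abs(colMeans(fs)) < 1e-8))
  expect_true(all(abs(apply(fs, 2, sd) - 1) < 1e-8))
  offdiag <- abs(cor(fs)[upper.tri(diag(3))])
  expect_true(all(offdiag < 0.05))
})

test_that("out-of-sample scoring applies the stored standardization", {
  train <- svf_binary_matrix(svf_fixture("reference", seed = 6, n_families = 1500))
  fit <- svf_efa(train, k = 3)
  new <- svf_binary_matrix(svf_fixture("reference", seed = 60, n_families = 5))
  fs <- svf_factor_scores(fit, new, restandardize = FALSE)
  expect_true(all(is.finite(as.matrix(fs[, fit$factor_names]))))
  # five arbitrary families are not forced to mean zero
  expect_gt(max(abs(colMeans(as.matrix(fs[, fit$factor_names])))), 1e-6)
  expect_error(svf_factor_scores(fit, new[, 1:10]), "lacks indicator")
})

test_that("recovered factors are labelled stably by reference congruence", {
  fits <- lapply(c(21, 22), function(s) {
    svf_efa(svf_binary_matrix(svf_fixture("reference", seed = s, n_families = 1500)), k = 3)
  })
  for (fit in fits) {
    expect_identical(
      fit$factor_names,
      c("chaotic", "socioeconomic", "psychosocial")
    )
  }
})

test_that("planted three-factor structure is recovered from one cohort", {
  bin <- svf_binary_matrix(svf_fixture("reference", seed = 1, n_families = 2000))
  fit <- svf_efa(bin, k = 3)
  expect_true(all(fit$congruence >= 0.90))
  # type scores carry most of the weighted-score signal
  co <- svf_fixture("reference", seed = 1, n_families = 2000)
  s <- svf_score(co)
  fs <- as.matrix(svf_factor_scores(fit, bin)[, fit$factor_names])
  r2 <- summary(stats::lm(s$weighted ~ fs))$r.squared
  expect_gt(r2, 0.5)
})

test_that("tetrachoric correlations recover a planted latent correlation", {
  set.seed(8)
  n <- 3000
  rho <- 0.5
  u <- matrix(rnorm(2 * n), n, 2)
  u[, 2] <- rho * u[, 1] + sqrt(1 - rho^2) * u[, 2]
  x <- as.integer(u[, 1] > qnorm(0.7))
  y <- as.integer(u[, 2] > qnorm(0.6))
  est <- svfscore:::tetrachoric_pair(x, y)
  expect_lt(abs(est - rho), 0.1)

  X <- cbind(a = x, b = y)
  R <- svfscore:::tetrachoric_matrix(X)
  expect_equal(diag(R), c(a = 1, b = 1))
  expect_equal(R[1, 2], R[2, 1])
})

test_that("tidy and glance summarise a fit", {
  bin <- svf_binary_matrix(svf_fixture("reference", seed = 9, n_families = 800))
  fit <- svf_efa(bin, k = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), 32 * 3)
  expect_identical(names(td), c("indicator", "factor", "loading", "included"))
  gl <- glance(fit)
  expect_equal(gl$k, 3)
  expect_equal(gl$n, 800)
  expect_true(gl$prop_variance > 0 && gl$prop_variance < 1)
  p1 <- autoplot(fit)
  expect_s3_class(p1, "ggplot")
})
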