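#' Hodges-Lehmann location-shift estimate with confidence interval
#'
#' Estimates the location shift between two samples as the median of all
#' pairwise differences `y - x`, with a distribution-free confidence interval
#' obtained from the Moses rank ordering of the pairwise differences (the
#' interval whose endpoints are the order statistics cut by the Mann-Whitney
#' critical value at the stated confidence).
#'
#' @param x Reference-group sample.
#' @param y Comparison-group sample.
#' @param conf Confidence level (default 0.95).
#' @return A named list: `estimate`, `ci_low`, `ci_high`, `conf`.
#' @examples
#' hodges_lehmann_shift(c(1, 2), c(3, 4))$estimate # 2
#' @export
hodges_lehmann_shift <- function(x, y, conf = 0.95) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  m <- length(x)
  n <- length(y)
  d <- sort(as.vector(outer(y, x, "-")))
  est <- stats::median(d)
  alpha <- 1 - conf
  mn <- m * n
  if (mn <= 2500) {
    k <- stats::qwilcox(alpha / 2, m, n)
    # largest k with P(U <= k) <= alpha/2
    if (stats::pwilcox(k, m, n) > alpha / 2) k <- k - 1
  } else {
    k <- floor(mn / 2 - stats::qnorm(1 - alpha / 2) *
      sqrt(mn * (m + n + 1) / 12))
  }
  k <- max(k, 0)
  if (k + 1 > mn - k) {
    ci <- c(min(d), max(d)) # too few pairs for the requested confidence
  } else {
    ci <- c(d[k + 1], d[mn - k])
  }
  list(estimate = est, ci_low = ci[1], ci_high = ci[2], conf = conf)
}

#' Nonparametric rank test of a score across groups
#'
#' Two groups are compared by the Wilcoxon rank-sum test (exact enumeration
#' when both groups have at most 10 untied observations, otherwise the normal
#' approximation with mid-rank tie correction); three or more groups by the
#' Kruskal-Wallis test.
#'
#' @param score Numeric score per family.
#' @param groups Group labels (coerced to factor; `NA` pairs dropped).
#' @return The two-sided P value.
#' @export
svf_rank_test <- function(score, groups) {
  keep <- !is.na(score) & !is.na(groups)
  score <- score[keep]
  groups <- droplevels(factor(groups[keep]))
  ng <- nlevels(groups)
  if (ng < 2) stop("rank test needs at least two nonempty groups", call. = FALSE)
  if (ng == 2) {
    sx <- score[groups == levels(groups)[1]]
    sy <- score[groups == levels(groups)[2]]
    ties <- anyDuplicated(score) > 0
    exact <- length(sx) <= 10 && length(sy) <= 10 && !ties
    suppressWarnings(
      stats::wilcox.test(sx, sy, exact = exact, correct = FALSE)$p.value
    )
  } else {
    stats::kruskal.test(score, groups)$p.value
  }
}

#' Cumulative risk-factor regression
#'
#' Ordinary least-squares regression of a vulnerability (or vulnerability
#' type) score on the per-family count of modifiable SUDI risk factors,
#' quantifying whether family vulnerability rises with the accumulation of
#' risk factors.
#'
#' @param scores Numeric score per family.
#' @param risk_counts Integer count of present risk factors per family.
#' @return A one-row tibble: `beta` (slope), `se`, `p`, `intercept`, `n`.
#' @export
svf_risk_regression <- function(scores, risk_counts) {
  keep <- !is.na(scores) & !is.na(risk_counts)
  scores <- scores[keep]
  risk_counts <- risk_counts[keep]
  if (length(scores) < 3) stop("too few complete observations", call. = FALSE)
  if (stats::var(risk_counts) == 0) {
    stop("risk-factor counts have zero variance", call. = FALSE)
  }
  fit <- stats::lm(scores ~ risk_counts)
  sm <- summary(fit)$coefficients
  tibble(
    beta = sm["risk_counts", "Estimate"],
    se = sm["risk_counts", "Std. Error"],
    p = sm["risk_counts", "Pr(>|t|)"],
    intercept = sm["(Intercept)", "Estimate"],
    n = length(scores)
  )
}

#' The SUDI risk-factor panel
#'
#' Metadata describing the risk-factor columns of a cohort table: level sets
#' with their reference level (the stratum against which location shifts are
#' estimated). Solitary sleep is defined only for infants not sharing a sleep
#' surface; surface-sharing families are excluded from that contrast.
#'
#' @return A tibble: `risk_factor`, `column`, `levels` (list-column, first
#'   element is the reference), `excludes`.
#' @export
svf_risk_panel <- function() {
  tibble(
    risk_factor = c(
      "Indigenous status", "Socioeconomic status of area", "Smoking during pregnancy",
      "Small for gestational age", "Pre-term birth", "Breastfeeding",
      "Sleep position", "Surface sharing", "Solitary sleep",
      "Sleep on soft surface", "Pillows in environment", "Excess bedding"
    ),
    column = c(
      "rf_indigenous", "rf_area_ses", "rf_smoking", "rf_sga", "rf_preterm",
      "rf_breastfeeding", "rf_sleep_position", "rf_surface_sharing",
      "rf_solitary_sleep", "rf_soft_surface", "rf_pillows", "rf_excess_bedding"
    ),
    levels = list(
      c("no", "yes"), c("high", "moderate", "low"), c("no", "yes"),
      c("gt25", "p11_25", "le10"), c("no", "yes"), c("yes", "no"),
      c("supine", "side", "prone"), c("no", "yes"), c("no", "yes"),
      c("no", "yes"), c("no", "yes"), c("no", "yes")
    ),
    excludes = c(
      NA, NA, NA, NA, NA, NA, NA, NA, "surface_sharing", NA, NA, NA
    )
  )
}

#' Default modifiable risk-factor count definition
#'
#' The items counted by [svf_risk_counts()]: a named list mapping risk-factor
#' columns to the level(s) counted as a present risk factor. Users may supply
#' an amended list to redefine the cumulative panel.
#'
#' @return Named list of character vectors.
#' @export
svf_count_panel <- function() {
  list(
    rf_smoking = "yes",
    rf_breastfeeding = "no",
    rf_sleep_position = c("side", "prone"),
    rf_surface_sharing = "yes",
    rf_solitary_sleep = "yes",
    rf_soft_surface = "yes",
    rf_pillows = "yes",
    rf_excess_bedding = "yes",
    rf_preterm = "yes",
    rf_sga = "le10"
  )
}

#' Per-family cumulative count of modifiable SUDI risk factors
#'
#' @param cohort Cohort tibble with `rf_*` columns.
#' @param panel Named list of column -> risky level(s); see
#'   [svf_count_panel()]. Missing items do not count.
#' @return Integer vector of counts, one per family.
#' @export
svf_risk_counts <- function(cohort, panel = svf_count_panel()) {
  cols <- intersect(names(panel), names(cohort))
  if (!length(cols)) stop("cohort has none of the panel's risk-factor columns",
    call. = FALSE
  )
  counts <- rep(0L, nrow(cohort))
  for (cl in cols) {
    counts <- counts + as.integer(!is.na(cohort[[cl]]) &
      cohort[[cl]] %in% panel[[cl]])
  }
  counts
}

#' Risk-factor association suite
#'
#' For every risk factor in the panel and every metric (family-weighted
#' composite score plus each vulnerability-type score), tests whether the
#' metric differs across risk-factor strata (Wilcoxon rank-sum for two
#' levels, Kruskal-Wallis for more) and estimates the shift of each stratum
#' against the reference level by the Hodges-Lehmann estimator with a
#' confidence interval. Parametric sensitivity estimates (Welch t-test /
#' linear-model contrasts) are reported alongside. Missing values are
#' excluded listwise per risk factor with counts logged; solitary sleep is
#' evaluated only among families not sharing a sleep surface. The reported P
#' values are unadjusted, matching the primary analysis; a Benjamini-Hochberg
#' adjusted column over the suite's tests is logged for transparency.
#'
#' @param cohort Cohort tibble with `rf_*` risk-factor columns.
#' @param scores Score tibble from [svf_score()] (its `weighted` column is
#'   analysed).
#' @param factor_scores Optional tibble of vulnerability-type scores from
#'   [svf_factor_scores()] (each column analysed as a metric).
#' @param panel Risk-factor panel metadata, see [svf_risk_panel()].
#' @param conf Confidence level for shift intervals.
#' @return A tibble of class `svf_associations`, one row per risk factor x
#'   metric x level: `risk_factor`, `metric`, `level`, `reference` (logical),
#'   `n`, `n_missing`, `n_excluded`, `estimate`, `ci_low`, `ci_high`
#'   (Hodges-Lehmann; `NA` on the reference row), `p` (group test, repeated
#'   across the factor's rows), `p_bh`, `estimate_param`, `ci_low_param`,
#'   `ci_high_param`, `p_param`, `note`.
#' @export
svf_associations <- function(cohort, scores, factor_scores = NULL,
                             panel = svf_risk_panel(), conf = 0.95) {
  stopifnot(nrow(cohort) == nrow(scores))
  metrics <- list(weighted = scores$weighted)
  if (!is.null(factor_scores)) {
    fs <- factor_scores[, setdiff(names(factor_scores), "family_id"), drop = FALSE]
    stopifnot(nrow(fs) == nrow(cohort))
    for (nm in names(fs)) metrics[[nm]] <- fs[[nm]]
  }
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    col <- panel$column[i]
    if (!col %in% names(cohort)) next
    g_raw <- as.character(cohort[[col]])
    excluded <- rep(FALSE, length(g_raw))
    if (!is.na(panel$excludes[i]) && panel$excludes[i] == "surface_sharing") {
      excluded <- !is.na(cohort$rf_surface_sharing) &
        cohort$rf_surface_sharing == "yes"
    }
    lev <- panel$levels[[i]]
    for (metric in names(metrics)) {
      sc <- metrics[[metric]]
      use <- !excluded & !is.na(g_raw) & !is.na(sc)
      g <- factor(g_raw[use], levels = lev)
      s <- sc[use]
      n_missing <- sum(!excluded & (is.na(g_raw) | is.na(sc)))
      n_excluded <- sum(excluded)
      present_levels <- lev[table(g)[lev] > 0]
      note <- NA_character_
      p <- NA_real_
      if (length(present_levels) >= 2) {
        p <- svf_rank_test(s, g)
      } else {
        note <- "fewer than two nonempty strata"
      }
      ref <- lev[1]
      x_ref <- s[g == ref]
      for (lv in lev) {
        is_ref <- lv == ref
        y <- s[g == lv]
        est <- list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
        par_est <- c(NA_real_, NA_real_, NA_real_)
        p_param <- NA_real_
        lv_note <- note
        if (!is_ref) {
          if (length(y) == 0 || length(x_ref) == 0) {
            lv_note <- "empty stratum"
          } else {
            est <- hodges_lehmann_shift(x_ref, y, conf = conf)
            if (length(y) >= 2 && length(x_ref) >= 2) {
              tt <- tryCatch(stats::t.test(y, x_ref, conf.level = conf),
                error = function(e) NULL
              )
              if (!is.null(tt)) {
                par_est <- c(
                  unname(diff(rev(tt$estimate))),
                  tt$conf.int[1], tt$conf.int[2]
                )
                p_param <- tt$p.value
              }
            }
          }
        }
        rows[[length(rows) + 1]] <- tibble(
          risk_factor = panel$risk_factor[i],
          metric = metric,
          level = lv,
          reference = is_ref,
          n = length(y),
          n_missing = n_missing,
          n_excluded = n_excluded,
          estimate = est$estimate,
          ci_low = est$ci_low,
          ci_high = est$ci_high,
          p = p,
          estimate_param = par_est[1],
          ci_low_param = par_est[2],
          ci_high_param = par_est[3],
          p_param = p_param,
          note = lv_note
        )
      }
    }
  }
  out <- bind_rows(rows)
  # BH adjustment across the suite's distinct group tests
  tests <- out |>
    distinct(.data$risk_factor, .data$metric, .data$p) |>
    mutate(p_bh = stats::p.adjust(.data$p, method = "BH"))
  out <- out |>
    left_join(tests, by = c("risk_factor", "metric", "p")) |>
    relocate("p_bh", .after = "p")
  attr(out, "conf") <- conf
  class(out) <- c("svf_associations", class(out))
  out
}
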