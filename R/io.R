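#' Read and write cohort and result tables
#'
#' Tables are plain UTF-8 CSV (comma separator, `.` decimal, mandatory header
#' row, empty cells for missing). Files written by the package begin with
#' comment lines (prefix `#`) recording the package version, the seed and the
#' ledger checksum; [svf_read_cohort()] skips such lines.
#'
#' @param path File path.
#' @param cohort Cohort tibble.
#' @param seed,ledger_checksum Provenance recorded in the header.
#' @return `svf_read_cohort()` returns a cohort tibble;
#'   `svf_write_table()` returns the path invisibly.
#' @name svf-io
NULL

#' @rdname svf-io
#' @export
svf_read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  if (nrow(df) == 0) stop("cohort file has no families: ", path, call. = FALSE)
  if (!all(c("family_id", "n_parents", "n_siblings") %in% names(df))) {
    stop("cohort file lacks family_id/n_parents/n_siblings columns",
      call. = FALSE
    )
  }
  df$family_id <- as.character(df$family_id)
  df
}

#' @rdname svf-io
#' @param x Data frame to write.
#' @export
svf_write_table <- function(x, path, seed = NA, ledger_checksum = NA) {
  header <- c(
    paste0("# svfscore version ", as.character(utils::packageVersion("svfscore"))),
    paste0("# seed ", seed),
    paste0("# ledger_checksum ", ledger_checksum),
    paste0("# written ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Run the full vulnerability-analysis pipeline
#'
#' Scores a cohort, fits the vulnerability-type factor analysis, computes
#' standardised type scores, runs the risk-factor association suite and the
#' cumulative risk-factor regressions, and (optionally) writes the result
#' tables and a run report to an output directory.
#'
#' @param cohort A cohort tibble or a path to a cohort CSV.
#' @param out_dir Output directory; `NULL` to skip writing files.
#' @param ledger Indicator ledger.
#' @param k Number of vulnerability-type factors (must be >= 1).
#' @param correlation Correlation matrix used by the factor analysis.
#' @param conf Confidence level of the shift intervals.
#' @param seed Seed recorded in output headers (the analysis itself is
#'   deterministic given the cohort).
#' @return A list with elements `scores`, `efa`, `factor_scores`,
#'   `associations`, `risk_regression` (one row per metric) and `report`
#'   (character vector of the rendered report lines).
#' @export
svf_pipeline <- function(cohort, out_dir = NULL, ledger = svf_ledger(), k = 3,
                         correlation = "pearson", conf = 0.95, seed = NA) {
  if (k < 1) stop("pipeline config invalid: k must be >= 1", call. = FALSE)
  if (is.character(cohort) && length(cohort) == 1) {
    cohort <- svf_read_cohort(cohort)
  }
  checksum <- attr(ledger, "checksum") %||% NA

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  scores <- stage("score", svf_score(cohort, ledger))
  bin <- stage("score", svf_binary_matrix(cohort, ledger))
  fit <- stage("efa", svf_efa(bin, k = k, correlation = correlation))
  fscores <- stage("efa", svf_factor_scores(fit, bin))
  assoc <- stage(
    "associate",
    svf_associations(cohort, scores, fscores, conf = conf)
  )
  counts <- stage("associate", svf_risk_counts(cohort))
  metrics <- c(list(weighted = scores$weighted),
    as.list(fscores[, fit$factor_names, drop = FALSE])
  )
  rreg <- stage("associate", bind_rows(lapply(names(metrics), function(nm) {
    mutate(svf_risk_regression(metrics[[nm]], counts), metric = nm, .before = 1)
  })))

  report <- c(
    paste0("svfscore pipeline report"),
    paste0("  version:          ", as.character(utils::packageVersion("svfscore"))),
    paste0("  seed:             ", seed),
    paste0("  ledger checksum:  ", checksum),
    paste0("  families:         ", nrow(cohort)),
    paste0("  indicators:       ", nrow(svf_indicators(ledger))),
    "",
    paste0(
      "  simple score:   median ", stats::median(scores$simple),
      " (range ", min(scores$simple), "-", max(scores$simple), ")"
    ),
    paste0(
      "  weighted score: median ", stats::median(scores$weighted),
      " (range ", min(scores$weighted), "-", max(scores$weighted), ")"
    ),
    paste0(
      "  Spearman cor(simple, weighted): ",
      sprintf("%.3f", stats::cor(scores$simple, scores$weighted, method = "spearman"))
    ),
    "",
    paste0(
      "  indicators at |loading| >= ", fit$threshold, ": ",
      length(svf_included_indicators(fit)), " of ", nrow(fit$loadings)
    ),
    paste0(
      "  cumulative risk-factor slopes: ",
      paste(sprintf("%s %.3f", rreg$metric, rreg$beta), collapse = ", ")
    )
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    w <- function(x, f) {
      svf_write_table(x, file.path(out_dir, f),
        seed = seed,
        ledger_checksum = checksum
      )
    }
    w(scores, "scores.csv")
    loadings_df <- bind_cols(
      tibble(id = rownames(fit$loadings)),
      as_tibble(as.data.frame(fit$loadings))
    )
    w(loadings_df, "loadings.csv")
    w(fscores, "factor_scores.csv")
    w(assoc, "associations.csv")
    w(rreg, "risk_regression.csv")
    writeLines(report, file.path(out_dir, "report.txt"))
  }

  list(
    scores = scores, efa = fit, factor_scores = fscores,
    associations = assoc, risk_regression = rreg, report = report
  )
}
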