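#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm sd cor median p.adjust rpois rbinom rnorm runif
#'   lm coef qwilcox wilcox.test kruskal.test t.test varimax complete.cases
NULL

# Scoring methods and their maximal per-indicator contribution. The composite
# saturates at 2 for within-family prevalence weighting and at 3 where a
# persistence (longitudinal) scale applies; the continuous occupational-status
# indicator contributes at most 1.
.svf_methods <- c(
  BINARY_1 = 1, BINARY_2 = 2,
  PARENT_WEIGHTED = 2, SIBLING_WEIGHTED = 2,
  EVENT_PREVALENCE = 2, REMOTENESS_WEIGHTED = 2,
  LONGITUDINAL = 3, PARENT_WEIGHTED_LONGITUDINAL = 3,
  CONTINUOUS_OCCUPATION = 1
)

.svf_dimensions <- c(
  "income_material", "employment", "housing", "health", "crime_safety",
  "transport_access", "family_social", "intergenerational", "education_skills"
)

#' Load the Social Vulnerability Framework indicator ledger
#'
#' The ledger is the machine-readable catalogue of social-vulnerability
#' indicators: the 32 operational indicators scored by the framework
#' (`in_queensland_svf = TRUE`) plus the normative-only indicators that are
#' catalogued for completeness but carry no scoring method (income, education,
#' public housing and car access have no operational data source and are
#' metadata only). Each operational indicator declares the scoring method used
#' for the family-weighted composite, from which its maximum attainable
#' contribution is derived.
#'
#' @param source Path to a ledger CSV with columns `id`, `name`, `dimension`,
#'   `method`, `in_queensland_svf`, or `NULL` (default) for the packaged
#'   ledger.
#' @return A tibble of class `svf_ledger`, one row per indicator, in the fixed
#'   order that drives the columns of every downstream matrix, with a
#'   `max_contribution` column derived from `method` and attributes `version`
#'   and `checksum` (MD5 of the source file).
#' @examples
#' ledger <- svf_ledger()
#' sum(ledger$in_queensland_svf)          # 32 operational indicators
#' sum(ledger$max_contribution, na.rm = TRUE)
#' @export
svf_ledger <- function(source = NULL) {
  path <- source %||% system.file("extdata", "svf_ledger.csv",
    package = "svfscore", mustWork = TRUE
  )
  if (!file.exists(path)) {
    stop("ledger file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  validate_ledger(raw)
  led <- as_tibble(raw) |>
    mutate(
      in_queensland_svf = as.logical(.data$in_queensland_svf),
      max_contribution = unname(.svf_methods[.data$method])
    )
  attr(led, "version") <- "1.0"
  attr(led, "checksum") <- unname(tools::md5sum(path))
  class(led) <- c("svf_ledger", class(led))
  led
}

validate_ledger <- function(raw) {
  needed <- c("id", "name", "dimension", "method", "in_queensland_svf")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("ledger is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(raw$id)) {
    stop("duplicate indicator id(s): ",
      paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  qld <- raw[as.logical(raw$in_queensland_svf), , drop = FALSE]
  bad_method <- qld$id[is.na(qld$method) | !(qld$method %in% names(.svf_methods))]
  if (length(bad_method)) {
    stop("indicator(s) with missing or unknown scoring method: ",
      paste(bad_method, collapse = ", "),
      call. = FALSE
    )
  }
  bad_dim <- raw$id[!(raw$dimension %in% .svf_dimensions)]
  if (length(bad_dim)) {
    stop("indicator(s) with unknown dimension: ",
      paste(bad_dim, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(raw)
}

#' Operational (scored) indicators of a ledger
#'
#' @param ledger A ledger tibble from [svf_ledger()].
#' @return The subset of rows with `in_queensland_svf = TRUE`, in ledger order.
#' @export
svf_indicators <- function(ledger) {
  stopifnot(inherits(ledger, "svf_ledger"))
  ledger[ledger$in_queensland_svf, , drop = FALSE]
}

#' Maximum attainable vulnerability scores
#'
#' Computes the ceiling of the simple summation score and of the
#' family-weighted composite score by exhaustive maximisation over admissible
#' observation states for every operational indicator (all family structures,
#' persistence states, event counts, occupational percentiles and remoteness
#' classes), rather than reading constants off the ledger. For the packaged
#' ledger this yields 32 and 63.
#'
#' @param ledger A ledger tibble from [svf_ledger()].
#' @return A named list with `simple_max` (integer) and `weighted_max`
#'   (numeric).
#' @examples
#' svf_max_scores(svf_ledger())
#' @export
svf_max_scores <- function(ledger) {
  ind <- svf_indicators(ledger)
  per_ind_max <- vapply(seq_len(nrow(ind)), function(i) {
    max(enumerate_contributions(ind$method[i]))
  }, numeric(1))
  list(
    simple_max = nrow(ind),
    weighted_max = sum(per_ind_max)
  )
}

# All contribution values an indicator of a given scoring method can attain,
# enumerated over a grid of admissible observation states (both family
# structures, every temporal state, event counts to saturation, a percentile
# grid including the endpoints and the cut, every remoteness class).
enumerate_contributions <- function(method) {
  switch(method,
    BINARY_1 = c(0, 1),
    BINARY_2 = c(0, 2),
    PARENT_WEIGHTED = {
      # n_parents x parents_affected grid
      grid <- expand.grid(n_parents = 1:2, affected = 0:2)
      grid <- grid[grid$affected <= grid$n_parents, ]
      mapply(contribution_parent_weighted, grid$affected, grid$n_parents)
    },
    SIBLING_WEIGHTED = vapply(0:4, contribution_sibling_weighted, numeric(1)),
    EVENT_PREVALENCE = vapply(0:4, contribution_event_prevalence, numeric(1)),
    REMOTENESS_WEIGHTED = vapply(
      c("none", "outer_regional", "remote_or_very_remote"),
      contribution_remoteness, numeric(1)
    ),
    LONGITUDINAL = vapply(
      c("absent", "past", "current", "persistent"),
      contribution_longitudinal, numeric(1)
    ),
    PARENT_WEIGHTED_LONGITUDINAL = {
      grid <- expand.grid(
        temporal = c("absent", "past", "current", "persistent"),
        affected = 0:2, stringsAsFactors = FALSE
      )
      mapply(
        function(t, a) if (a > 0) contribution_longitudinal(t) else 0,
        grid$temporal, grid$affected
      )
    },
    CONTINUOUS_OCCUPATION = vapply(
      c(0, 0.05, 0.1, 0.25, 0.26, 0.5, 1, NA_real_),
      contribution_occupation, numeric(1)
    ),
    stop("unknown scoring method: ", method, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
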