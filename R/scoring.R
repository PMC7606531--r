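#' Per-indicator contribution rules
#'
#' These scalar rules implement the family-weighted composite scoring of a
#' single indicator observation. Within-family prevalence weighting assigns 1
#' when one of two parents displays a characteristic and 2 when both parents
#' -- or a sole, unsupported parent -- display it (a sole parent is treated
#' as equivalent to a couple in which both parents are affected). Persistence
#' weighting assigns 1 for past-only, 2 for current, and 3 for persistent
#' vulnerability. Event-prevalence indicators saturate at 2; the continuous
#' occupational-status indicator maps the family's occupational percentile
#' (the higher-status parent's) linearly from 1 at the lowest status to 0.25
#' at the 25th percentile, contributing 0 above the cut.
#'
#' @param parents_affected Integer 0..2, number of parents displaying the
#'   characteristic.
#' @param n_parents Integer 1 or 2.
#' @param temporal One of `"absent"`, `"past"`, `"current"`, `"persistent"`.
#' @param siblings_affected Nonnegative integer.
#' @param event_count Nonnegative integer count of qualifying events.
#' @param percentile Occupational-status percentile in `[0, 1]` (0 = lowest
#'   status), or `NA` when unknown.
#' @param remoteness One of `"none"`, `"outer_regional"`,
#'   `"remote_or_very_remote"`.
#' @return The numeric contribution of the observation to the family-weighted
#'   composite score.
#' @name svf-contributions
NULL

#' @rdname svf-contributions
#' @export
contribution_parent_weighted <- function(parents_affected, n_parents) {
  if (is.na(parents_affected)) return(0)
  if (parents_affected > n_parents) {
    stop("parents_affected (", parents_affected, ") exceeds n_parents (",
      n_parents, ")",
      call. = FALSE
    )
  }
  if (parents_affected == 0) 0 else if (parents_affected == n_parents) 2 else 1
}

#' @rdname svf-contributions
#' @export
contribution_longitudinal <- function(temporal) {
  if (is.na(temporal)) return(0)
  states <- c(absent = 0, past = 1, current = 2, persistent = 3)
  if (!temporal %in% names(states)) {
    stop("unknown temporal state: ", temporal, call. = FALSE)
  }
  unname(states[temporal])
}

#' @rdname svf-contributions
#' @export
contribution_sibling_weighted <- function(siblings_affected) {
  if (is.na(siblings_affected)) return(0)
  if (siblings_affected < 0) stop("negative sibling count", call. = FALSE)
  min(siblings_affected, 2)
}

#' @rdname svf-contributions
#' @export
contribution_event_prevalence <- function(event_count) {
  if (is.na(event_count)) return(0)
  if (event_count < 0) stop("negative event count", call. = FALSE)
  min(event_count, 2)
}

#' @rdname svf-contributions
#' @export
contribution_occupation <- function(percentile) {
  if (is.na(percentile)) return(0)
  if (percentile < 0 || percentile > 1) {
    stop("occupation percentile outside [0, 1]: ", percentile, call. = FALSE)
  }
  if (percentile > 0.25) 0 else 1 - 3 * percentile
}

#' @rdname svf-contributions
#' @export
contribution_remoteness <- function(remoteness) {
  if (is.na(remoteness)) return(0)
  weights <- c(none = 0, outer_regional = 1, remote_or_very_remote = 2)
  if (!remoteness %in% names(weights)) {
    stop("unknown remoteness class: ", remoteness, call. = FALSE)
  }
  unname(weights[remoteness])
}

# Observation columns a scoring method reads from the cohort table.
cols_for_method <- function(id, method) {
  suffix <- switch(method,
    BINARY_1 = ,
    BINARY_2 = "present",
    PARENT_WEIGHTED = "parents",
    SIBLING_WEIGHTED = "siblings",
    LONGITUDINAL = "temporal",
    PARENT_WEIGHTED_LONGITUDINAL = c("parents", "temporal"),
    EVENT_PREVALENCE = "count",
    CONTINUOUS_OCCUPATION = "percentile",
    REMOTENESS_WEIGHTED = "remoteness"
  )
  paste0(id, "__", suffix)
}

# Vectorised contribution of one indicator over all families in a cohort.
# Missing cells follow the framework's convention: no information about an
# indicator is scored as the characteristic being absent.
indicator_contribution <- function(cohort, id, method) {
  n <- nrow(cohort)
  col <- function(suffix) {
    nm <- paste0(id, "__", suffix)
    if (!nm %in% names(cohort)) rep(NA, n) else cohort[[nm]]
  }
  out <- switch(method,
    BINARY_1 = {
      p <- col("present")
      ifelse(is.na(p) | p == 0, 0, 1)
    },
    BINARY_2 = {
      p <- col("present")
      ifelse(is.na(p) | p == 0, 0, 2)
    },
    PARENT_WEIGHTED = {
      a <- col("parents")
      np <- cohort$n_parents
      bad <- !is.na(a) & a > np
      if (any(bad)) {
        stop("parents_affected exceeds n_parents for indicator '", id,
          "' in family ", paste(cohort$family_id[bad], collapse = ", "),
          call. = FALSE
        )
      }
      ifelse(is.na(a) | a == 0, 0, ifelse(a == np, 2, 1))
    },
    SIBLING_WEIGHTED = {
      s <- col("siblings")
      if (any(!is.na(s) & s < 0)) stop("negative sibling count", call. = FALSE)
      pmin(ifelse(is.na(s), 0, s), 2)
    },
    LONGITUDINAL = longitudinal_vec(col("temporal"), id),
    PARENT_WEIGHTED_LONGITUDINAL = {
      a <- col("parents")
      lv <- longitudinal_vec(col("temporal"), id)
      ifelse(is.na(a) | a == 0, 0, lv)
    },
    EVENT_PREVALENCE = {
      k <- col("count")
      if (any(!is.na(k) & k < 0)) {
        stop("negative event count for indicator '", id, "'", call. = FALSE)
      }
      pmin(ifelse(is.na(k), 0, k), 2)
    },
    CONTINUOUS_OCCUPATION = {
      p <- col("percentile")
      if (any(!is.na(p) & (p < 0 | p > 1))) {
        stop("occupation percentile outside [0, 1] for indicator '", id, "'",
          call. = FALSE
        )
      }
      ifelse(is.na(p) | p > 0.25, 0, 1 - 3 * p)
    },
    REMOTENESS_WEIGHTED = {
      r <- col("remoteness")
      ok <- is.na(r) | r %in% c("none", "outer_regional", "remote_or_very_remote")
      if (!all(ok)) {
        stop("unknown remoteness class for indicator '", id, "'", call. = FALSE)
      }
      ifelse(is.na(r) | r == "none", 0,
        ifelse(r == "outer_regional", 1, 2)
      )
    },
    stop("unknown scoring method: ", method, call. = FALSE)
  )
  as.numeric(out)
}

longitudinal_vec <- function(temporal, id) {
  states <- c(absent = 0, past = 1, current = 2, persistent = 3)
  ok <- is.na(temporal) | temporal %in% names(states)
  if (!all(ok)) {
    stop("unknown temporal state for indicator '", id, "': ",
      paste(unique(temporal[!ok]), collapse = ", "),
      call. = FALSE
    )
  }
  ifelse(is.na(temporal), 0, unname(states[temporal]))
}

#' Score a cohort of families
#'
#' Computes, for every family, the per-indicator contributions, the simple
#' summation vulnerability score (count of indicators on which any member of
#' the immediate family displays the characteristic, range 0 to the number of
#' operational indicators) and the family-weighted composite score (sum of
#' prevalence-, structure- and persistence-weighted contributions, range 0-63
#' for the packaged ledger).
#'
#' @param cohort A cohort tibble, one row per family, with columns
#'   `family_id`, `n_parents`, `n_siblings` and per-indicator observation
#'   columns named `<id>__present`, `<id>__parents`, `<id>__siblings`,
#'   `<id>__temporal`, `<id>__count`, `<id>__percentile`, `<id>__remoteness`
#'   as the indicator's scoring method requires (see [svf_empty_cohort()] for
#'   a template). Missing cells are scored as the characteristic being absent.
#' @param ledger A ledger from [svf_ledger()].
#' @param flag_missing If `TRUE`, append an `n_unobserved` column counting,
#'   per family, the indicators for which every observation cell is missing
#'   (useful for sensitivity analyses of the absence-means-absent convention).
#' @return A tibble with columns `family_id`, `simple`, `weighted` and one
#'   `<id>__contribution` column per operational indicator, rows aligned with
#'   `cohort`.
#' @examples
#' ledger <- svf_ledger()
#' cohort <- svf_empty_cohort(3, ledger)
#' cohort$mental_ill_health__parents[1] <- 1
#' svf_score(cohort, ledger)
#' @export
svf_score <- function(cohort, ledger = svf_ledger(), flag_missing = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0) stop("cohort has no families", call. = FALSE)
  needed <- c("family_id", "n_parents", "n_siblings")
  if (!all(needed %in% names(cohort))) {
    stop("cohort must have columns: ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(cohort$n_parents)) || !all(cohort$n_parents %in% 1:2)) {
    stop("n_parents must be 1 or 2 for every family", call. = FALSE)
  }
  ind <- svf_indicators(ledger)
  # warn on observation columns that reference no ledger indicator
  obs_cols <- grep("__", names(cohort), value = TRUE)
  obs_ids <- unique(sub("__.*$", "", obs_cols))
  unknown <- setdiff(obs_ids, ledger$id)
  if (length(unknown)) {
    stop("observation column(s) reference unknown indicator(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  contrib <- lapply(seq_len(nrow(ind)), function(i) {
    indicator_contribution(cohort, ind$id[i], ind$method[i])
  })
  names(contrib) <- paste0(ind$id, "__contribution")
  cmat <- do.call(cbind, contrib)

  out <- tibble(
    family_id = cohort$family_id,
    simple = as.integer(rowSums(cmat > 0)),
    weighted = rowSums(cmat)
  )
  out <- bind_cols(out, as_tibble(cmat))
  if (flag_missing) {
    unobserved <- vapply(seq_len(nrow(ind)), function(i) {
      cols <- intersect(cols_for_method(ind$id[i], ind$method[i]), names(cohort))
      if (!length(cols)) {
        rep(TRUE, nrow(cohort))
      } else {
        rowSums(!is.na(as.data.frame(cohort[, cols]))) == 0
      }
    }, logical(nrow(cohort)))
    out$n_unobserved <- as.integer(rowSums(matrix(unobserved, nrow = nrow(cohort))))
  }
  out
}

#' Binary indicator matrix of a cohort
#'
#' Reduces each indicator observation to presence/absence: a family scores 1
#' on an indicator if any member of the immediate family displays the
#' characteristic in any state (any person affected, any non-absent temporal
#' state, any qualifying event, occupational status at or below the 25th
#' percentile, any non-metropolitan remoteness class). This is the input to
#' both the simple summation score and the factor analysis.
#'
#' @inheritParams svf_score
#' @return An integer matrix, families by indicators, with indicator ids as
#'   column names in ledger order and `family_id` as row names.
#' @export
svf_binary_matrix <- function(cohort, ledger = svf_ledger()) {
  ind <- svf_indicators(ledger)
  scores <- svf_score(cohort, ledger)
  cmat <- as.matrix(scores[, paste0(ind$id, "__contribution")])
  bin <- (cmat > 0) + 0L
  colnames(bin) <- ind$id
  rownames(bin) <- as.character(cohort$family_id)
  bin
}

#' All-absent cohort template
#'
#' Builds a cohort tibble of `n` couple-parented, no-sibling families with
#' every observation cell absent, carrying exactly the observation columns the
#' ledger's scoring methods read. Useful as a starting point for hand-built
#' fixtures.
#'
#' @param n Number of families.
#' @param ledger A ledger from [svf_ledger()].
#' @return A cohort tibble with `family_id` `"f1".."fn"`.
#' @export
svf_empty_cohort <- function(n, ledger = svf_ledger()) {
  ind <- svf_indicators(ledger)
  out <- tibble(
    family_id = paste0("f", seq_len(n)),
    n_parents = rep(2L, n),
    n_siblings = rep(0L, n)
  )
  for (i in seq_len(nrow(ind))) {
    for (cl in cols_for_method(ind$id[i], ind$method[i])) {
      out[[cl]] <- if (grepl("__(temporal|remoteness)$", cl)) {
        rep(NA_character_, n)
      } else {
        rep(NA_real_, n)
      }
    }
  }
  out
}
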