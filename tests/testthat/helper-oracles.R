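# Independent oracles used across the suite. These deliberately re-derive
# every scoring rule with naive scalar logic (no calls into the package's
# vectorised dispatch) so that agreement is a genuine cross-check.

# Brute-force score of one cohort row against a ledger.
oracle_score_row <- function(row, ledger) {
  ind <- ledger[ledger$in_queensland_svf, , drop = FALSE]
  contributions <- numeric(nrow(ind))
  names(contributions) <- ind$id
  g <- function(col) {
    v <- row[[col]]
    if (is.null(v) || length(v) == 0) NA else v
  }
  for (i in seq_len(nrow(ind))) {
    id <- ind$id[i]
    val <- 0
    method <- ind$method[i]
    if (method == "BINARY_1") {
      p <- g(paste0(id, "__present"))
      if (!is.na(p) && p != 0) val <- 1
    } else if (method == "BINARY_2") {
      p <- g(paste0(id, "__present"))
      if (!is.na(p) && p != 0) val <- 2
    } else if (method == "PARENT_WEIGHTED") {
      a <- g(paste0(id, "__parents"))
      np <- row$n_parents
      if (!is.na(a) && a > 0) {
        val <- if (a == np) 2 else 1
      }
    } else if (method == "SIBLING_WEIGHTED") {
      s <- g(paste0(id, "__siblings"))
      if (!is.na(s) && s > 0) val <- if (s >= 2) 2 else 1
    } else if (method == "LONGITUDINAL") {
      t <- g(paste0(id, "__temporal"))
      if (!is.na(t)) {
        val <- switch(t, absent = 0, past = 1, current = 2, persistent = 3)
      }
    } else if (method == "PARENT_WEIGHTED_LONGITUDINAL") {
      a <- g(paste0(id, "__parents"))
      t <- g(paste0(id, "__temporal"))
      if (!is.na(a) && a > 0 && !is.na(t)) {
        val <- switch(t, absent = 0, past = 1, current = 2, persistent = 3)
      }
    } else if (method == "EVENT_PREVALENCE") {
      k <- g(paste0(id, "__count"))
      if (!is.na(k) && k > 0) val <- if (k >= 2) 2 else 1
    } else if (method == "CONTINUOUS_OCCUPATION") {
      p <- g(paste0(id, "__percentile"))
      if (!is.na(p) && p <= 0.25) val <- 1 - 3 * p
    } else if (method == "REMOTENESS_WEIGHTED") {
      r <- g(paste0(id, "__remoteness"))
      if (!is.na(r)) {
        val <- switch(r, none = 0, outer_regional = 1, remote_or_very_remote = 2)
      }
    }
    contributions[id] <- val
  }
  list(
    simple = sum(contributions > 0),
    weighted = sum(contributions),
    contributions = contributions
  )
}

# Random admissible cohort over the full observation-state grid, independent
# of the package's generator.
random_cohort <- function(n, ledger, seed) {
  set.seed(seed)
  ind <- ledger[ledger$in_queensland_svf, , drop = FALSE]
  co <- svf_empty_cohort(n, ledger)
  co$n_parents <- sample(1:2, n, replace = TRUE)
  co$n_siblings <- sample(0:4, n, replace = TRUE)
  maybe_na <- function(v, p = 0.2) {
    v[runif(length(v)) < p] <- NA
    v
  }
  for (i in seq_len(nrow(ind))) {
    id <- ind$id[i]
    method <- ind$method[i]
    if (method %in% c("BINARY_1", "BINARY_2")) {
      co[[paste0(id, "__present")]] <- maybe_na(sample(0:1, n, replace = TRUE))
    }
    if (method %in% c("PARENT_WEIGHTED", "PARENT_WEIGHTED_LONGITUDINAL")) {
      co[[paste0(id, "__parents")]] <-
        maybe_na(vapply(co$n_parents, function(np) sample(0:np, 1), numeric(1)))
    }
    if (method == "SIBLING_WEIGHTED") {
      co[[paste0(id, "__siblings")]] <-
        maybe_na(vapply(co$n_siblings, function(ns) sample(0:max(ns, 0), 1), numeric(1)))
    }
    if (method %in% c("LONGITUDINAL", "PARENT_WEIGHTED_LONGITUDINAL")) {
      co[[paste0(id, "__temporal")]] <- maybe_na(
        sample(c("absent", "past", "current", "persistent"), n, replace = TRUE)
      )
    }
    if (method == "EVENT_PREVALENCE") {
      co[[paste0(id, "__count")]] <- maybe_na(sample(0:4, n, replace = TRUE))
    }
    if (method == "CONTINUOUS_OCCUPATION") {
      co[[paste0(id, "__percentile")]] <- maybe_na(round(runif(n), 3))
    }
    if (method == "REMOTENESS_WEIGHTED") {
      co[[paste0(id, "__remoteness")]] <- maybe_na(
        sample(c("none", "outer_regional", "remote_or_very_remote"), n, replace = TRUE)
      )
    }
  }
  co
}

# Hodges-Lehmann estimate by exhaustive enumeration of pairwise differences.
oracle_hl <- function(x, y) {
  d <- numeric(0)
  for (yi in y) for (xi in x) d <- c(d, yi - xi)
  sort(d)[ceiling(length(d) / 2):ceiling((length(d) + 1) / 2)] |> mean()
}

# Exact two-sided Wilcoxon rank-sum P by enumerating every assignment of the
# pooled ranks to the first group (no ties assumed).
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# One-step elevation of a random indicator observation; returns the modified
# cohort (used for monotonicity checks).
elevate_one <- function(co, row, ledger) {
  ind <- ledger[ledger$in_queensland_svf, , drop = FALSE]
  i <- sample(nrow(ind), 1)
  id <- ind$id[i]
  method <- ind$method[i]
  bump <- function(col, hi) {
    v <- co[[col]][row]
    if (is.na(v)) v <- 0
    co[[col]][row] <<- min(v + 1, hi)
  }
  if (method %in% c("BINARY_1", "BINARY_2")) bump(paste0(id, "__present"), 1)
  if (method %in% c("PARENT_WEIGHTED", "PARENT_WEIGHTED_LONGITUDINAL")) {
    bump(paste0(id, "__parents"), co$n_parents[row])
  }
  if (method == "SIBLING_WEIGHTED") bump(paste0(id, "__siblings"), max(co$n_siblings[row], 0))
  if (method %in% c("LONGITUDINAL", "PARENT_WEIGHTED_LONGITUDINAL")) {
    states <- c("absent", "past", "current", "persistent")
    cur <- co[[paste0(id, "__temporal")]][row]
    if (is.na(cur)) cur <- "absent"
    co[[paste0(id, "__temporal")]][row] <-
      states[min(match(cur, states) + 1, 4)]
  }
  if (method == "EVENT_PREVALENCE") bump(paste0(id, "__count"), 10)
  if (method == "CONTINUOUS_OCCUPATION") {
    v <- co[[paste0(id, "__percentile")]][row]
    if (is.na(v)) v <- 1
    co[[paste0(id, "__percentile")]][row] <- max(v - 0.1, 0)
  }
  if (method == "REMOTENESS_WEIGHTED") {
    states <- c("none", "outer_regional", "remote_or_very_remote")
    cur <- co[[paste0(id, "__remoteness")]][row]
    if (is.na(cur)) cur <- "none"
    co[[paste0(id, "__remoteness")]][row] <-
      states[min(match(cur, states) + 1, 3)]
  }
  co
}

# Ledger CSV writer for degenerate-ledger tests.
write_ledger_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}
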