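#' Reference loading pattern of the three vulnerability types
#'
#' The archetypal 32-indicator by 3-factor varimax loading pattern of the
#' chaotic-lifestyle, socioeconomic and psychosocial vulnerability types. It
#' is used (i) to label factors recovered from a fitted cohort by maximum
#' congruence, so type names are stable under factor permutation and sign
#' flips, and (ii) as the default planted loading matrix of the synthetic
#' cohort generator.
#'
#' @return A 32 x 3 numeric matrix with indicator ids as row names and
#'   columns `chaotic`, `socioeconomic`, `psychosocial`.
#' @export
svf_reference_loadings <- function() {
  path <- system.file("extdata", "svf_reference_loadings.csv",
    package = "svfscore", mustWork = TRUE
  )
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("chaotic", "socioeconomic", "psychosocial")])
  rownames(m) <- df$id
  m
}

#' Exploratory factor analysis of the binary vulnerability indicators
#'
#' Fits a k-factor solution to the presence/absence indicator matrix by
#' principal-axis factoring of the inter-indicator correlation matrix,
#' followed by an orthogonal varimax rotation so the resulting vulnerability
#' types are uncorrelated. Correlations are Pearson by default (phi
#' coefficients on binary data); tetrachoric correlations, which model the
#' binary indicators as thresholded bivariate normals, are available via
#' `correlation = "tetrachoric"`.
#'
#' Constant indicator columns carry no correlation information and are
#' dropped with a warning before fitting.
#'
#' @param binary_matrix Families-by-indicators matrix of 0/1, e.g. from
#'   [svf_binary_matrix()].
#' @param k Number of factors to extract (the scree eigenvalues in the result
#'   are advisory; k is never auto-selected).
#' @param correlation `"pearson"` or `"tetrachoric"`.
#' @param reference Loading matrix used to label recovered factors by maximum
#'   congruence (default [svf_reference_loadings()]); `NULL` for generic
#'   `factor1..k` labels.
#' @param max_iter,tol Principal-axis communality iteration controls.
#' @return An object of class `svf_efa`: list with `loadings` (indicators x k,
#'   rotated, sign- and label-aligned), `factor_names`, `eigenvalues` (of the
#'   full correlation matrix, for scree inspection), `correlation` (matrix
#'   used), `score_weights` (regression-method weights), `center`/`scale`
#'   (column statistics of the training matrix), `congruence` (per factor vs
#'   the reference, if given), `dropped` (constant columns removed), `n`.
#' @examples
#' \donttest{
#' cohort <- svf_simulate(svf_generator_config(n_families = 500, seed = 1))
#' fit <- svf_efa(svf_binary_matrix(cohort), k = 3)
#' fit$factor_names
#' }
#' @export
svf_efa <- function(binary_matrix, k = 3, correlation = c("pearson", "tetrachoric"),
                    reference = svf_reference_loadings(),
                    max_iter = 100, tol = 1e-6) {
  correlation <- match.arg(correlation)
  X <- as.matrix(binary_matrix)
  if (is.null(colnames(X))) {
    stop("binary_matrix must have indicator ids as column names", call. = FALSE)
  }
  vars <- apply(X, 2, stats::var)
  dropped <- colnames(X)[vars == 0]
  if (length(dropped)) {
    warning("dropping constant indicator column(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
    X <- X[, vars > 0, drop = FALSE]
  }
  p <- ncol(X)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (p < k + 2) {
    stop("k = ", k, " factors need at least ", k + 2,
      " indicators with nonzero variance (have ", p, ")",
      call. = FALSE
    )
  }
  R <- switch(correlation,
    pearson = stats::cor(X),
    tetrachoric = tetrachoric_matrix(X)
  )
  eig_full <- eigen(R, symmetric = TRUE, only.values = TRUE)$values

  L <- principal_axis(R, k, max_iter = max_iter, tol = tol)
  # raw varimax criterion: Kaiser row normalization is deliberately not used,
  # as it gives low-communality (mostly-noise) indicators the same rotational
  # weight as well-determined ones and destabilises the orientation
  rot <- stats::varimax(L, normalize = FALSE)
  Lr <- unclass(rot$loadings)[, , drop = FALSE]

  # sign convention: each factor points towards vulnerability (positive sum
  # of loadings)
  flip <- sign(colSums(Lr))
  flip[flip == 0] <- 1
  Lr <- sweep(Lr, 2, flip, `*`)

  factor_names <- paste0("factor", seq_len(k))
  congr <- NULL
  if (!is.null(reference)) {
    ref <- reference[intersect(rownames(reference), rownames(Lr)), , drop = FALSE]
    if (nrow(ref) >= 2 && ncol(ref) >= 1) {
      al <- align_to_reference(Lr[rownames(ref), , drop = FALSE], ref)
      Lr <- Lr[, al$order, drop = FALSE] |> sweep(2, al$sign, `*`)
      factor_names <- al$names
      congr <- al$congruence
    }
  }
  colnames(Lr) <- factor_names
  names(eig_full) <- NULL

  W <- solve(R, Lr) # regression-method score weights
  out <- list(
    loadings = Lr,
    factor_names = factor_names,
    k = k,
    threshold = 0.40,
    eigenvalues = eig_full,
    correlation_method = correlation,
    correlation = R,
    score_weights = W,
    center = colMeans(X),
    scale = apply(X, 2, stats::sd),
    congruence = congr,
    dropped = dropped,
    n = nrow(X)
  )
  class(out) <- "svf_efa"
  out
}

# Iterated principal-axis factoring: eigendecomposition of the reduced
# correlation matrix with communalities re-estimated until convergence.
# Initial communalities are squared multiple correlations.
principal_axis <- function(R, k, max_iter = 100, tol = 1e-6) {
  p <- ncol(R)
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(Rinv)) rep(0.5, p) else pmin(pmax(1 - 1 / diag(Rinv), 0.05), 0.995)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    ed <- eigen(Rr, symmetric = TRUE)
    vals <- pmax(ed$values[seq_len(k)], 0)
    L <- ed$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
    h2_new <- pmin(rowSums(L^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  rownames(L) <- rownames(R)
  L
}

#' Tucker's coefficient of factor congruence
#'
#' @param x,y Numeric loading vectors over the same indicators.
#' @return Congruence in `[-1, 1]`; 1 is proportional agreement.
#' @export
factor_congruence <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

# Match recovered factors to reference factors: over all column permutations
# and sign flips, maximise the summed absolute congruence; 1:1 assignment.
align_to_reference <- function(L, ref) {
  k <- ncol(L)
  kr <- ncol(ref)
  cg <- matrix(0, kr, k)
  for (i in seq_len(kr)) {
    for (j in seq_len(k)) cg[i, j] <- factor_congruence(ref[, i], L[, j])
  }
  # greedy 1:1 assignment on |congruence| (k is small)
  ord <- rep(NA_integer_, k)
  used_ref <- rep(FALSE, kr)
  used_col <- rep(FALSE, k)
  acg <- abs(cg)
  for (step in seq_len(min(k, kr))) {
    masked <- acg
    masked[used_ref, ] <- -Inf
    masked[, used_col] <- -Inf
    idx <- which(masked == max(masked), arr.ind = TRUE)[1, ]
    ord[idx[1]] <- idx[2]
    used_ref[idx[1]] <- TRUE
    used_col[idx[2]] <- TRUE
  }
  # unmatched recovered factors (k > kr) keep their position at the end
  leftover <- setdiff(seq_len(k), stats::na.omit(ord))
  ord_full <- c(stats::na.omit(ord), leftover)
  signs <- vapply(seq_along(ord_full), function(m) {
    if (m <= kr && !is.na(ord[m])) sign(cg[m, ord[m]]) else 1
  }, numeric(1))
  signs[signs == 0] <- 1
  nms <- c(
    colnames(ref)[seq_len(min(k, kr))],
    paste0("factor", setdiff(seq_len(k), seq_len(kr)))
  )[seq_len(k)]
  congruence <- vapply(seq_len(min(k, kr)), function(m) {
    abs(cg[m, ord[m]])
  }, numeric(1))
  names(congruence) <- colnames(ref)[seq_len(min(k, kr))]
  list(order = ord_full, sign = signs, names = nms, congruence = congruence)
}

#' Indicators substantially loading on the fitted factors
#'
#' An indicator is included in the vulnerability typing when its absolute
#' loading on some factor reaches the threshold (default 0.40; the comparison
#' is `>=` so indicators printed exactly at the threshold count as included).
#' With a `factor` argument, restricts to indicators reaching the threshold
#' on that factor.
#'
#' @param fit An `svf_efa` object, or a bare loading matrix with indicator
#'   row names.
#' @param threshold Absolute-loading inclusion threshold.
#' @param factor Optional factor name or index.
#' @return Character vector of indicator ids, in loading-matrix row order.
#' @export
svf_included_indicators <- function(fit, threshold = 0.40, factor = NULL) {
  L <- if (inherits(fit, "svf_efa")) fit$loadings else as.matrix(fit)
  if (!is.null(factor)) {
    keep <- abs(L[, factor]) >= threshold
  } else {
    keep <- apply(abs(L), 1, max) >= threshold
  }
  rownames(L)[keep]
}

#' Standardised factor scores (vulnerability-type scores)
#'
#' Scores families on the fitted vulnerability types by the regression
#' (Thomson) method, then -- for the fitted cohort -- explicitly
#' re-standardises the score columns to mean 0 and standard deviation 1, the
#' scale on which type scores are reported. The re-standardisation is a
#' symmetric (ZCA) whitening: the minimal linear transformation that also
#' makes the score columns exactly uncorrelated, matching the mutual
#' independence of the varimax-rotated types (raw regression scores of an
#' orthogonal solution retain small cross-correlations). Scoring new
#' families against a previously fitted model applies the stored
#' standardisation of the training cohort and does not re-standardise.
#'
#' @param fit An `svf_efa` object.
#' @param binary_matrix Binary indicator matrix to score (the training matrix
#'   is not stored in the fit, so pass it back in for in-sample scores).
#' @param restandardize Standardise columns to mean 0, sd 1 after scoring
#'   (default `TRUE`, the in-sample contract). Set `FALSE` for out-of-sample
#'   scoring.
#' @return A tibble of k factor-score columns named by `fit$factor_names`,
#'   one row per family, with a `family_id` column when the matrix has row
#'   names.
#' @export
svf_factor_scores <- function(fit, binary_matrix, restandardize = TRUE) {
  stopifnot(inherits(fit, "svf_efa"))
  X <- as.matrix(binary_matrix)
  need <- rownames(fit$loadings)
  if (!all(need %in% colnames(X))) {
    stop("binary_matrix lacks indicator column(s): ",
      paste(setdiff(need, colnames(X)), collapse = ", "),
      call. = FALSE
    )
  }
  X <- X[, need, drop = FALSE]
  sc <- fit$scale
  sc[sc == 0] <- 1
  Z <- sweep(sweep(X, 2, fit$center[need]), 2, sc[need], `/`)
  F <- Z %*% fit$score_weights
  if (restandardize) {
    # symmetric (ZCA) whitening of the centred regression scores: the minimal
    # linear transformation giving every column mean 0 and sd 1 *and* zero
    # cross-correlation, consistent with the orthogonal rotation
    F <- sweep(F, 2, colMeans(F))
    S <- stats::cov(F)
    ed <- eigen(S, symmetric = TRUE)
    if (min(ed$values) > 1e-12) {
      Sinv_half <- ed$vectors %*% diag(1 / sqrt(ed$values), ncol(F)) %*%
        t(ed$vectors)
      F <- F %*% Sinv_half
    } else {
      F <- apply(F, 2, function(col) {
        s <- stats::sd(col)
        if (s == 0) col else col / s
      })
    }
  }
  out <- as_tibble(as.data.frame(F))
  names(out) <- fit$factor_names
  if (!is.null(rownames(X))) {
    out <- bind_cols(tibble(family_id = rownames(X)), out)
  }
  out
}

# ---- tetrachoric correlations -----------------------------------------------

# Upper-quadrant probability P(X > a, Y > b) of a standard bivariate normal
# with correlation rho, by Gauss-Legendre quadrature over x.
bvn_upper <- function(a, b, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * 0.9999
  nodes <- .gl48$nodes
  weights <- .gl48$weights
  lo <- a
  hi <- max(a + 12, 12)
  x <- (hi - lo) / 2 * nodes + (hi + lo) / 2
  fx <- stats::dnorm(x) * stats::pnorm((rho * x - b) / sqrt(1 - rho^2))
  (hi - lo) / 2 * sum(weights * fx)
}

# ML tetrachoric correlation of one 0/1 pair with thresholds fixed at the
# margins.
tetrachoric_pair <- function(x, y) {
  n <- length(x)
  p1 <- mean(x)
  p2 <- mean(y)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    return(0)
  }
  a <- stats::qnorm(1 - p1)
  b <- stats::qnorm(1 - p2)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- n - n11 - n10 - n01
  negll <- function(rho) {
    p11 <- bvn_upper(a, b, rho)
    p10 <- (1 - stats::pnorm(a)) - p11
    p01 <- (1 - stats::pnorm(b)) - p11
    p00 <- 1 - p11 - p10 - p01
    probs <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(c(n11, n10, n01, n00) * log(probs))
  }
  stats::optimize(negll, c(-0.999, 0.999))$minimum
}

tetrachoric_matrix <- function(X) {
  p <- ncol(X)
  R <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      R[i, j] <- R[j, i] <- tetrachoric_pair(X[, i], X[, j])
    }
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  # nearest positive semi-definite repair if pairwise estimation broke psd
  ed <- eigen(R, symmetric = TRUE)
  if (min(ed$values) < 1e-8) {
    vals <- pmax(ed$values, 1e-8)
    R <- ed$vectors %*% diag(vals) %*% t(ed$vectors)
    D <- sqrt(diag(R))
    R <- R / outer(D, D)
    dimnames(R) <- list(colnames(X), colnames(X))
  }
  R
}

# 48-point Gauss-Legendre rule on [-1, 1]
.gl48 <- local({
  gl <- function(n) {
    # Golub-Welsch via symmetric tridiagonal eigenproblem
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    A <- diag(0, n)
    A[cbind(i, i + 1)] <- b
    A[cbind(i + 1, i)] <- b
    ed <- eigen(A, symmetric = TRUE)
    list(nodes = ed$values, weights = 2 * ed$vectors[1, ]^2)
  }
  gl(48)
})

#' @export
print.svf_efa <- function(x, ...) {
  cat("Vulnerability-type factor analysis (", x$correlation_method,
    " correlations, principal-axis + varimax)\n",
    sep = ""
  )
  cat("  families: ", x$n, ", factors: ", x$k, "\n", sep = "")
  if (!is.null(x$congruence)) {
    cat(
      "  congruence with reference pattern: ",
      paste(sprintf("%s %.2f", names(x$congruence), x$congruence),
        collapse = ", "
      ), "\n"
    )
  }
  inc <- svf_included_indicators(x)
  cat("  indicators at |loading| >= ", x$threshold, ": ", length(inc),
    " of ", nrow(x$loadings), "\n",
    sep = ""
  )
  invisible(x)
}
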