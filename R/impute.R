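#' Multivariate-normal imputation of traits and covariates
#'
#' EM fit of a single sample-wise i.i.d. Gaussian over the columns; missing
#' entries are replaced by their conditional expectations given the observed
#' entries in the same row. Binary columns (detected as two-valued 0/1 among
#' observed entries, or named in `binary_cols`) are thresholded at 0.5 back to
#' \{0,1\}. Observed entries are never altered.
#'
#' @param mat numeric matrix with NAs.
#' @param max_iter,tol EM controls (relative change in observed-data
#'   log-likelihood).
#' @param ridge diagonal regularizer applied when the covariance loses
#'   positive definiteness.
#' @param binary_cols optional column indices/names to threshold.
#' @return list of class `imputation_result`: `completed`, `mask` (TRUE where
#'   imputed), `mean`, `cov`, `method`, `iterations`.
#' @export
mvn_impute <- function(mat, max_iter = 200L, tol = 1e-6, ridge = 1e-6,
                       binary_cols = NULL) {
  X <- as.matrix(mat)
  storage.mode(X) <- "double"
  p <- ncol(X); n <- nrow(X)
  mask <- is.na(X)
  if (any(colSums(!mask) < 2)) stop("each column needs at least 2 observed values")
  bin <- detect_binary_cols(X, binary_cols)
  if (!any(mask)) {
    return(structure(list(completed = X, mask = mask, mean = colMeans(X),
                          cov = stats::cov(X), method = "mvn", iterations = 0L),
                     class = "imputation_result"))
  }
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- X
  for (j in seq_len(p)) Xc[mask[, j], j] <- mu[j]
  S <- stats::cov(Xc)
  ll_old <- -Inf; it <- 0L
  patterns <- apply(mask, 1L, function(r) paste(which(r), collapse = ","))
  for (it in seq_len(max_iter)) {
    S <- ensure_pd(S, ridge)
    Csum <- matrix(0, p, p)   # conditional covariance contributions
    ll <- 0
    for (pat in unique(patterns)) {
      rows <- which(patterns == pat)
      mi <- mask[rows[1], ]
      oi <- !mi
      if (!any(oi)) {  # fully missing row: marginal mean and covariance
        Xc[rows, ] <- matrix(mu, length(rows), p, byrow = TRUE)
        Csum <- Csum + length(rows) * S
        next
      }
      Xo <- X[rows, oi, drop = FALSE]
      d <- dmvnorm_log(Xo, mu[oi], S[oi, oi, drop = FALSE])
      ll <- ll + sum(d)
      if (!any(mi)) next
      Soo_inv <- chol2inv(chol(S[oi, oi, drop = FALSE]))
      B <- S[mi, oi, drop = FALSE] %*% Soo_inv
      cond_mean <- matrix(mu[mi], length(rows), sum(mi), byrow = TRUE) +
        sweep(Xo, 2L, mu[oi]) %*% t(B)
      Xc[rows, mi] <- cond_mean
      Cmm <- S[mi, mi, drop = FALSE] - B %*% S[oi, mi, drop = FALSE]
      Csum[mi, mi] <- Csum[mi, mi] + length(rows) * Cmm
    }
    mu <- colMeans(Xc)
    S_new <- crossprod(sweep(Xc, 2L, mu)) / n + Csum / n
    S <- S_new
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  completed <- X
  completed[mask] <- Xc[mask]
  for (j in bin) {
    imp <- mask[, j]
    completed[imp, j] <- as.numeric(completed[imp, j] > 0.5)
  }
  structure(list(completed = completed, mask = mask, mean = mu, cov = S,
                 method = "mvn", iterations = it),
            class = "imputation_result")
}

detect_binary_cols <- function(X, binary_cols) {
  if (!is.null(binary_cols)) {
    if (is.character(binary_cols)) return(match(binary_cols, colnames(X)))
    return(binary_cols)
  }
  which(apply(X, 2L, function(v) {
    obs <- v[!is.na(v)]
    length(unique(obs)) <= 2 && all(obs %in% c(0, 1))
  }))
}

ensure_pd <- function(S, ridge) {
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    warning("covariance not positive definite; ridge regularization applied")
    S <- S + diag(ridge * mean(diag(S)) + 1e-10, ncol(S))
  }
  S
}

#' Low-rank (soft-thresholded SVD) matrix completion
#'
#' Iterative SVD imputation for wide matrices: missing entries start at the
#' column means; at each iteration the current completion is factored, the
#' singular values are soft-thresholded (or truncated to `rank`), and missing
#' entries are refilled from the low-rank reconstruction. Observed entries
#' are restored exactly after convergence; binary columns are thresholded at
#' 0.5.
#'
#' @param mat numeric matrix with NAs.
#' @param rank target rank (used to derive the soft threshold; must be below
#'   `min(dim(mat))`).
#' @param lambda optional explicit soft threshold on singular values
#'   (overrides `rank`).
#' @param max_iter,tol iteration controls.
#' @param binary_cols as in [mvn_impute()].
#' @param seed unused randomness guard kept for interface stability.
#' @return an `imputation_result` with `method = "lowrank"` and the `rank`
#'   used.
#' @export
lowrank_impute <- function(mat, rank = 2L, lambda = NULL, max_iter = 500L,
                           tol = 1e-7, binary_cols = NULL, seed = 1L) {
  X <- as.matrix(mat)
  storage.mode(X) <- "double"
  if (rank >= min(dim(X))) stop("rank must be below min(dim(mat))")
  mask <- is.na(X)
  bin <- detect_binary_cols(X, binary_cols)
  if (!any(mask)) {
    return(structure(list(completed = X, mask = mask, rank = rank,
                          method = "lowrank", iterations = 0L),
                     class = "imputation_result"))
  }
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- X
  for (j in seq_len(ncol(X))) Xc[mask[, j], j] <- mu[j]
  old_miss <- Xc[mask]
  for (it in seq_len(max_iter)) {
    sv <- svd(Xc)
    d <- sv$d
    thr <- if (!is.null(lambda)) lambda else if (length(d) > rank) d[rank + 1L] else 0
    d_soft <- pmax(d - thr, 0)
    keep <- which(d_soft > 0)
    if (!length(keep)) keep <- 1L
    recon <- sv$u[, keep, drop = FALSE] %*% (d_soft[keep] * t(sv$v[, keep, drop = FALSE]))
    Xc[mask] <- recon[mask]
    delta <- sqrt(mean((Xc[mask] - old_miss)^2)) / (stats::sd(old_miss) + 1e-12)
    old_miss <- Xc[mask]
    if (delta < tol) break
  }
  completed <- X
  completed[mask] <- Xc[mask]
  for (j in bin) {
    imp <- mask[, j]
    completed[imp, j] <- as.numeric(completed[imp, j] > 0.5)
  }
  structure(list(completed = completed, mask = mask, rank = rank,
                 method = "lowrank", iterations = it),
            class = "imputation_result")
}
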