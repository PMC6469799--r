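#' Gaussian mixture model on quantitative traits
#'
#' Standard full-covariance EM, the covariate-unaware comparator for subtype
#' discovery. Binary traits are excluded by contract (mixtures over Bernoulli
#' blocks routinely fail to converge; callers should pass the quantitative
#' block only).
#'
#' @param quant_traits numeric matrix (or [trait_matrix()], whose quantitative
#'   block is used).
#' @param K number of components.
#' @param seed RNG seed.
#' @param n_restarts random-label restarts in addition to a k-means start.
#' @param max_iter,rel_tol EM controls.
#' @param ridge covariance regularizer added to each component's covariance.
#' @return list of class `subtype_estimate` with `z` (N x K
#'   responsibilities), `labels`, `means`, `weights`, `loglik`, `converged`.
#' @export
fit_gmm <- function(quant_traits, K, seed = 1L, n_restarts = 5L,
                    max_iter = 500L, rel_tol = 1e-8, ridge = 1e-6) {
  Y <- if (inherits(quant_traits, "trait_matrix")) quant_traits$quant else as.matrix(quant_traits)
  if (ncol(Y) == 0) stop("fit_gmm needs at least one quantitative trait")
  n <- nrow(Y); P <- ncol(Y)
  if (K == 1L) {
    mu <- colMeans(Y); S <- stats::cov(Y)
    ll <- sum(dmvnorm_log(Y, mu, S + diag(ridge, P)))
    return(structure(list(source = "gmm", z = matrix(1, n, 1),
                          labels = rep(1L, n), means = matrix(mu, 1),
                          weights = 1, loglik = ll, converged = TRUE),
                     class = "subtype_estimate"))
  }
  set.seed(derive_seed(seed, "gmm"))
  inits <- list(tryCatch(stats::kmeans(Y, K, nstart = 3)$cluster,
                         error = function(e) sample(seq_len(K), n, TRUE)))
  for (r in seq_len(n_restarts))
    inits[[length(inits) + 1L]] <- sample(seq_len(K), n, replace = TRUE)
  best <- NULL
  for (lab in inits) {
    Z <- matrix(0.05 / (K - 1), n, K); Z[cbind(seq_len(n), lab)] <- 0.95
    run <- gmm_em(Y, Z, max_iter, rel_tol, ridge)
    if (!is.null(run) && (is.null(best) || run$loglik > best$loglik)) best <- run
  }
  if (is.null(best)) stop("GMM failed to converge in every restart")
  ord <- order(best$weights, decreasing = TRUE)
  structure(list(source = "gmm", z = best$Z[, ord, drop = FALSE],
                 labels = max.col(best$Z[, ord, drop = FALSE], ties.method = "first"),
                 means = best$mu[ord, , drop = FALSE],
                 weights = best$weights[ord], loglik = best$loglik,
                 converged = best$converged),
            class = "subtype_estimate")
}

dmvnorm_log <- function(Y, mu, S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  cent <- sweep(Y, 2L, mu)
  q <- colSums(backsolve(ch, t(cent), transpose = TRUE)^2)
  -0.5 * (ncol(Y) * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

gmm_em <- function(Y, Z, max_iter, rel_tol, ridge) {
  n <- nrow(Y); P <- ncol(Y); K <- ncol(Z)
  ll_old <- -Inf; converged <- FALSE
  mu <- matrix(0, K, P); wts <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    nk <- colSums(Z)
    if (min(nk) < P + 2) return(NULL)  # collapsed component
    wts <- nk / n
    lw <- matrix(0, n, K)
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(Y * Z[, k]) / nk[k]
      cent <- sweep(Y, 2L, mu[k, ])
      S <- crossprod(cent * sqrt(Z[, k])) / nk[k] + diag(ridge, P)
      d <- dmvnorm_log(Y, mu[k, ], S)
      if (is.null(d)) return(NULL)
      lw[, k] <- log(wts[k]) + d
    }
    lse <- logsumexp_rows(lw)
    Z <- exp(lw - lse)
    ll <- sum(lse)
    if (anyNA(Z) || !is.finite(ll)) return(NULL)
    if (is.finite(ll_old) && abs(ll - ll_old) < rel_tol * (abs(ll_old) + 1)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  list(Z = Z, mu = mu, weights = wts, loglik = ll_old, converged = converged)
}

#' Canonical-correlation subtype score
#'
#' Applies CCA between the covariate matrix `G` and the joint (binary :
#' quantitative) phenotype matrix, both column-wise centered and scaled, and
#' returns the top phenotypic canonical variate as a continuous subtype score
#' with unit variance. The sign is canonicalized by positive correlation with
#' the first phenotype column.
#'
#' @param all_traits numeric matrix or [trait_matrix()] (blocks are joined).
#' @param G covariate matrix (non-empty).
#' @return `subtype_estimate` with continuous `z` and phenotype `loadings`.
#' @export
cca_subtype <- function(all_traits, G) {
  Y <- if (inherits(all_traits, "trait_matrix"))
    cbind(all_traits$binary, all_traits$quant) else as.matrix(all_traits)
  G <- as.matrix(G)
  if (ncol(G) == 0) stop("cca_subtype needs a non-empty covariate matrix G")
  Ys <- standardize_cols(Y); Gs <- standardize_cols(G)
  cc <- stats::cancor(Gs, Ys, xcenter = FALSE, ycenter = FALSE)
  z <- as.vector(Ys %*% cc$ycoef[, 1])
  z <- z / stats::sd(z)
  if (stats::cor(z, Ys[, 1]) < 0) z <- -z
  structure(list(source = "cca", z = z, loadings = cc$ycoef[, 1],
                 cor = cc$cor[1]), class = "subtype_estimate")
}

#' Principal-component subtype score
#'
#' Top principal component of a centered/scaled phenotype (or genotype)
#' matrix, optionally median-thresholded into a binary grouping. Sign is
#' canonicalized by positive correlation with the first column.
#'
#' @param mat numeric matrix.
#' @param source label, `"phenotype"` or `"genotype"`.
#' @param threshold if `TRUE`, return a 0/1 grouping split at the median.
#' @return `subtype_estimate` with `z` (continuous unit-variance score, or
#'   0/1 when thresholded) and `loadings`.
#' @export
pc_subtype <- function(mat, source = c("phenotype", "genotype"),
                       threshold = FALSE) {
  source <- match.arg(source)
  mat <- as.matrix(mat)
  sds <- apply(mat, 2L, stats::sd)
  if (all(sds < .Machine$double.eps)) stop("constant matrix has no principal component")
  ms <- standardize_cols(mat[, sds > 0, drop = FALSE])
  pc <- stats::prcomp(ms, center = FALSE, scale. = FALSE)
  z <- pc$x[, 1]
  z <- z / stats::sd(z)
  if (stats::cor(z, ms[, 1]) < 0) z <- -z
  if (threshold) z <- as.numeric(z > stats::median(z))
  structure(list(source = paste0(source, "_pc"), z = z,
                 loadings = pc$rotation[, 1]), class = "subtype_estimate")
}

#' Adjusted Rand index, exact or over a random subsample
#'
#' Chance-corrected agreement between two partitions: 0 for random guessing,
#' 1 for an exact match. For large cohorts the index is computed only over
#' pairs within a random subsample (default 300), which changes cost from
#' O(N^2) to O(subsample^2) with negligible bias.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param n_subsample subsample size; exact when `N <= n_subsample`.
#' @param seed RNG seed for the subsample.
#' @return scalar ARI estimate.
#' @export
adjusted_rand_subsampled <- function(labels_a, labels_b, n_subsample = 300L,
                                     seed = 1L) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  if (n > n_subsample) {
    set.seed(derive_seed(seed, "ari"))
    idx <- sample.int(n, n_subsample)
    labels_a <- labels_a[idx]; labels_b <- labels_b[idx]
  }
  adjusted_rand_index(labels_a, labels_b)
}

#' @rdname adjusted_rand_subsampled
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Co-clustering stability under cross-validated refitting
#'
#' The full-data fit defines a reference co-clustering. For each fold, the
#' model is refit on the training folds and held-out samples are assigned via
#' [predict_subtypes()]; the statistic is the fraction of originally
#' co-clustered held-out pairs (same likeliest subtype) that remain
#' co-clustered.
#'
#' @param traits,covariates data containers.
#' @param K number of subtypes.
#' @param n_folds folds (>= 2).
#' @param seed RNG seed.
#' @param max_pairs cap on evaluated pairs per fold (subsampled beyond this).
#' @param ... passed to [mfmr_opts()].
#' @return list with `fraction_preserved`, per-fold counts, and the reference
#'   fit.
#' @export
coclustering_stability <- function(traits, covariates, K, n_folds = 5L,
                                   seed = 1L, max_pairs = 2e6, ...) {
  stopifnot(n_folds >= 2)
  full <- fit_mfmr(traits, covariates,
                   opts = mfmr_opts(K = K, seed = derive_seed(seed, "ccfull"), ...))
  ref <- full$labels
  if (length(unique(ref)) < 2 && K > 1)
    warning("reference clustering is degenerate (single cluster)")
  n <- length(ref)
  set.seed(derive_seed(seed, "ccfolds"))
  fold <- sample(rep_len(seq_len(n_folds), n))
  kept <- 0; total <- 0
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- which(!tr)
    t_tr <- trait_matrix(traits$quant[tr, , drop = FALSE], traits$binary[tr, , drop = FALSE])
    c_tr <- covariate_set(covariates$homogeneous[tr, , drop = FALSE],
                          covariates$heterogeneous[tr, , drop = FALSE])
    fit_f <- fit_mfmr(t_tr, c_tr,
                      opts = mfmr_opts(K = K, seed = derive_seed(seed, paste0("cc", f)), ...))
    t_te <- trait_matrix(traits$quant[te, , drop = FALSE], traits$binary[te, , drop = FALSE])
    c_te <- covariate_set(covariates$homogeneous[te, , drop = FALSE],
                          covariates$heterogeneous[te, , drop = FALSE])
    new_lab <- predict_subtypes(fit_f, t_te, c_te)$labels
    m <- length(te)
    if (choose(m, 2) > max_pairs) {
      te_keep <- sample.int(m, floor(sqrt(2 * max_pairs)))
    } else te_keep <- seq_len(m)
    rl <- ref[te][te_keep]; nl <- new_lab[te_keep]
    co_ref <- outer(rl, rl, "==") & upper.tri(diag(length(rl)))
    co_new <- outer(nl, nl, "==")
    kept <- kept + sum(co_ref & co_new)
    total <- total + sum(co_ref)
  }
  list(fraction_preserved = if (total > 0) kept / total else NA_real_,
       pairs_preserved = kept, pairs_reference = total, reference_fit = full)
}
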