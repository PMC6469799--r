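#' Fitting options for the mixture of multi-trait regressions
#'
#' @param K number of subtypes (>= 1).
#' @param n_restarts random responsibility initializations; one additional
#'   GMM-derived initialization is always added when quantitative traits are
#'   present and `K > 1`.
#' @param max_iter ECM iteration cap per restart.
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param seed RNG seed controlling initializations.
#' @return list of class `mfmr_opts`.
#' @export
mfmr_opts <- function(K = 2L, n_restarts = 10L, max_iter = 1000L,
                      rel_tol = 1e-8, seed = 1L) {
  stopifnot(K >= 1, n_restarts >= 0, max_iter >= 1, rel_tol > 0)
  structure(list(K = as.integer(K), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 seed = as.integer(seed)),
            class = "mfmr_opts")
}

## ---- internal: standardized design bundle ---------------------------------

mfmr_prepare <- function(traits, covariates) {
  X <- covariates$homogeneous
  G <- covariates$heterogeneous
  if (ncol(G) < 1 || !all(G[, 1] == 1))
    stop("heterogeneous design must carry the intercept in column 1")
  Xs <- if (ncol(X)) standardize_cols(X) else X
  if (ncol(G) > 1) {
    Gtail <- standardize_cols(G[, -1, drop = FALSE])
    Gs <- cbind(1, Gtail)
    g_center <- c(0, attr(Gtail, "center")); g_scale <- c(1, attr(Gtail, "scale"))
  } else {
    Gs <- G; g_center <- 0; g_scale <- 1
  }
  D <- cbind(Xs, Gs)
  if (qr(D)$rank < ncol(D))
    stop("rank deficiency in the combined [X G] design")
  Ys <- if (ncol(traits$quant)) standardize_cols(traits$quant) else traits$quant
  list(Xs = Xs, Gs = Gs, Ys = Ys, Yb = traits$binary,
       x_center = if (ncol(X)) attr(Xs, "center") else numeric(0),
       x_scale = if (ncol(X)) attr(Xs, "scale") else numeric(0),
       g_center = g_center, g_scale = g_scale,
       y_center = if (ncol(traits$quant)) attr(Ys, "center") else numeric(0),
       y_scale = if (ncol(traits$quant)) attr(Ys, "scale") else numeric(0),
       N = nrow(G), Q = ncol(X), L = ncol(G),
       P = ncol(traits$quant), B = ncol(traits$binary))
}

## ---- E step ----------------------------------------------------------------

## Workhorse E-step on a prepared design with working-scale parameters.
e_step_core <- function(par, prep) {
  N <- prep$N; K <- length(par$p)
  lw <- matrix(rep(log(par$p), each = N), N, K)
  xa_q <- if (prep$Q && prep$P) prep$Xs %*% par$alpha_q else 0
  xa_b <- if (prep$Q && prep$B) prep$Xs %*% par$alpha_b else 0
  for (k in seq_len(K)) {
    if (prep$P) {
      mu <- xa_q + prep$Gs %*% matrix(par$beta_q[, k, ], nrow = prep$L)
      mu <- matrix(mu, N, prep$P)
      sd_k <- sqrt(par$sigma2[k, ])
      lw[, k] <- lw[, k] + rowSums(stats::dnorm(prep$Ys, mu,
                                                rep(sd_k, each = N), log = TRUE))
    }
    if (prep$B) {
      eta <- xa_b + prep$Gs %*% matrix(par$beta_b[, k, ], nrow = prep$L)
      eta <- matrix(eta, N, prep$B)
      pr <- clamp_prob(stats::pnorm(eta))
      lw[, k] <- lw[, k] + rowSums(prep$Yb * log(pr) + (1 - prep$Yb) * log(1 - pr))
    }
  }
  lse <- logsumexp_rows(lw)
  Z <- exp(lw - lse)
  list(Z = Z, loglik = sum(lse))
}

#' E-step: posterior subtype responsibilities under fixed parameters
#'
#' Computes `Z[i,k] proportional to p_k * f_k(traits_i)` in log space, with
#' quantitative traits contributing Gaussian densities and binary traits
#' probit probabilities, conditionally independent given the subtype.
#'
#' @param params a fitted `mfmr_fit` (or parameter list on the raw scale).
#' @param traits a [trait_matrix()].
#' @param covariates a [covariate_set()].
#' @return list with `Z` (N x K responsibilities, rows summing to 1), `p`,
#'   and the observed-data `loglik`.
#' @export
e_step <- function(params, traits, covariates) {
  prep <- raw_prep(traits, covariates)
  es <- e_step_core(raw_par(params), prep)
  list(Z = es$Z, p = params$p, loglik = es$loglik)
}

## raw-scale (unstandardized) versions used by exported e_step/log_likelihood
raw_prep <- function(traits, covariates) {
  list(Xs = covariates$homogeneous, Gs = covariates$heterogeneous,
       Ys = traits$quant, Yb = traits$binary,
       N = nrow(covariates$heterogeneous),
       Q = ncol(covariates$homogeneous), L = ncol(covariates$heterogeneous),
       P = ncol(traits$quant), B = ncol(traits$binary))
}

raw_par <- function(params) {
  list(p = params$p, alpha_q = params$alpha_q, alpha_b = params$alpha_b,
       beta_q = params$beta_q, beta_b = params$beta_b, sigma2 = params$sigma2)
}

#' Observed-data log-likelihood of an MFMR parameter set
#'
#' `sum_i log sum_k p_k f_k(row i)`, computed stably in log space.
#'
#' @inheritParams e_step
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, traits, covariates) {
  if (any(params$sigma2 <= 0)) stop("sigma2 must be positive")
  e_step(params, traits, covariates)$loglik
}

## ---- CM steps --------------------------------------------------------------

#' CM-step for quantitative traits
#'
#' Given responsibilities, jointly solves the responsibility-weighted
#' least-squares problem in the shared effects `alpha` and the per-subtype
#' effects `beta_k` for every quantitative trait, then updates the
#' per-subtype residual variances. Weights are `Z[,k] / sigma2[k,p]`, so the
#' update is exact conditional maximization given the current variances.
#'
#' @param Z N x K responsibility matrix.
#' @param traits,covariates data containers.
#' @param sigma2 current K x P residual variance matrix (defaults to 1s).
#' @param ridge fallback ridge added when the weighted normal equations are
#'   singular.
#' @return list with `alpha` (Q x P), `beta` (L x K x P), `sigma2` (K x P).
#' @export
cm_step_quantitative <- function(Z, traits, covariates, sigma2 = NULL,
                                 ridge = 1e-8) {
  prep <- raw_prep(traits, covariates)
  if (is.null(sigma2)) sigma2 <- matrix(1, ncol(Z), prep$P)
  up <- cm_quant_core(Z, prep, sigma2, ridge)
  list(alpha = up$alpha_q, beta = up$beta_q, sigma2 = up$sigma2)
}

cm_quant_core <- function(Z, prep, sigma2, ridge = 1e-8) {
  K <- ncol(Z); Q <- prep$Q; L <- prep$L; P <- prep$P
  D <- cbind(prep$Xs, prep$Gs)  # N x (Q+L)
  ## per-subtype cross products, shared across traits
  ctD <- vector("list", K); ctY <- vector("list", K); wsum <- colSums(Z)
  for (k in seq_len(K)) {
    wD <- D * Z[, k]
    ctD[[k]] <- crossprod(D, wD)          # (Q+L)^2
    ctY[[k]] <- crossprod(wD, prep$Ys)    # (Q+L) x P
  }
  alpha <- matrix(0, Q, P)
  beta <- array(0, dim = c(L, K, P))
  dim_full <- Q + K * L
  iq <- seq_len(Q)
  for (p in seq_len(P)) {
    A <- matrix(0, dim_full, dim_full); b <- numeric(dim_full)
    for (k in seq_len(K)) {
      w <- 1 / sigma2[k, p]
      ig <- Q + (k - 1L) * L + seq_len(L)
      Ck <- ctD[[k]] * w
      if (Q) {
        A[iq, iq] <- A[iq, iq] + Ck[iq, iq]
        A[iq, ig] <- Ck[iq, Q + seq_len(L)]
        A[ig, iq] <- Ck[Q + seq_len(L), iq]
      }
      A[ig, ig] <- Ck[Q + seq_len(L), Q + seq_len(L)]
      bk <- ctY[[k]][, p] * w
      if (Q) b[iq] <- b[iq] + bk[iq]
      b[ig] <- bk[Q + seq_len(L)]
    }
    coef <- tryCatch(solve(A, b), error = function(e) {
      warning("singular weighted normal equations; ridge fallback applied")
      solve(A + diag(ridge, dim_full), b)
    })
    if (Q) alpha[, p] <- coef[iq]
    beta[, , p] <- matrix(coef[Q + seq_len(K * L)], L, K)
  }
  ## residual variances given the new coefficients
  sig_new <- matrix(0, K, P)
  xa <- if (Q) prep$Xs %*% alpha else 0
  for (k in seq_len(K)) {
    mu <- xa + prep$Gs %*% matrix(beta[, k, ], nrow = L)
    r2 <- (prep$Ys - mu)^2
    sig_new[k, ] <- pmax(colSums(r2 * Z[, k]) / wsum[k], 1e-10)
  }
  list(alpha_q = alpha, beta_q = beta, sigma2 = sig_new)
}

## weighted probit log-likelihood for one binary trait
probit_wll <- function(theta, Dx, Gs, y, Z) {
  K <- ncol(Z); Q <- if (is.null(Dx)) 0L else ncol(Dx); L <- ncol(Gs)
  a <- if (Q) theta[seq_len(Q)] else numeric(0)
  xa <- if (Q) as.vector(Dx %*% a) else 0
  ll <- 0
  for (k in seq_len(K)) {
    bk <- theta[Q + (k - 1L) * L + seq_len(L)]
    pr <- clamp_prob(stats::pnorm(xa + as.vector(Gs %*% bk)))
    ll <- ll + sum(Z[, k] * (y * log(pr) + (1 - y) * log(1 - pr)))
  }
  ll
}

#' CM-step for binary traits
#'
#' Responsibility-weighted probit regression per binary trait on the expanded
#' design `[X, G (x) subtype]`, maximized by Fisher scoring with step halving
#' (each step is guaranteed not to decrease the weighted log-likelihood, which
#' preserves ECM monotonicity).
#'
#' @inheritParams cm_step_quantitative
#' @param init optional warm-start list with `alpha` (Q x B) and `beta`
#'   (L x K x B).
#' @param max_inner,tol inner Newton controls.
#' @return list with `alpha` (Q x B) and `beta` (L x K x B).
#' @export
cm_step_binary <- function(Z, traits, covariates, init = NULL,
                           max_inner = 50L, tol = 1e-9) {
  prep <- raw_prep(traits, covariates)
  up <- cm_binary_core(Z, prep, init, max_inner, tol)
  list(alpha = up$alpha_b, beta = up$beta_b)
}

cm_binary_core <- function(Z, prep, init = NULL, max_inner = 25L, tol = 1e-9) {
  K <- ncol(Z); Q <- prep$Q; L <- prep$L; B <- prep$B
  alpha <- init$alpha_b %||% matrix(0, Q, B)
  beta <- init$beta_b %||% array(0, dim = c(L, K, B))
  Dx <- if (Q) prep$Xs else NULL
  dim_full <- Q + K * L
  iq <- seq_len(Q)
  for (b in seq_len(B)) {
    y <- prep$Yb[, b]
    if (stats::var(y) == 0) {
      ## degenerate trait: intercept-only closed form, flagged
      warning(sprintf("binary trait %d is constant; fitting intercepts only", b))
      alpha[, b] <- 0
      beta[, , b] <- 0
      beta[1, , b] <- stats::qnorm(clamp_prob(mean(y)))
      next
    }
    theta <- c(if (Q) alpha[, b], as.vector(beta[, , b]))
    ll <- probit_wll(theta, Dx, prep$Gs, y, Z)
    for (it in seq_len(max_inner)) {
      grad <- numeric(dim_full); H <- matrix(0, dim_full, dim_full)
      xa <- if (Q) as.vector(Dx %*% theta[iq]) else 0
      for (k in seq_len(K)) {
        ig <- Q + (k - 1L) * L + seq_len(L)
        eta <- xa + as.vector(prep$Gs %*% theta[ig])
        pr <- clamp_prob(stats::pnorm(eta))
        phi <- stats::dnorm(eta)
        s <- Z[, k] * phi * (y - pr) / (pr * (1 - pr))
        w <- Z[, k] * phi^2 / (pr * (1 - pr))
        if (Q) {
          grad[iq] <- grad[iq] + crossprod(Dx, s)
          H[iq, iq] <- H[iq, iq] + crossprod(Dx, Dx * w)
          XtWG <- crossprod(Dx, prep$Gs * w)
          H[iq, ig] <- H[iq, ig] + XtWG
          H[ig, iq] <- H[ig, iq] + t(XtWG)
        }
        grad[ig] <- grad[ig] + crossprod(prep$Gs, s)
        H[ig, ig] <- H[ig, ig] + crossprod(prep$Gs, prep$Gs * w)
      }
      step <- tryCatch(solve(H + diag(1e-10, dim_full), grad),
                       error = function(e) grad / (max(diag(H)) + 1))
      ## step halving with a box constraint at +/-15 (separation guard);
      ## candidates are projected before evaluation so the weighted
      ## log-likelihood never decreases and ECM monotonicity is preserved
      sz <- 1; improved <- FALSE
      for (h in 1:30) {
        cand <- pmin(pmax(theta + sz * step, -15), 15)
        llc <- probit_wll(cand, Dx, prep$Gs, y, Z)
        if (is.finite(llc) && llc >= ll - 1e-12) { improved <- TRUE; break }
        sz <- sz / 2
      }
      if (!improved) break
      conv <- (llc - ll) < tol * (abs(ll) + 1)
      theta <- cand; ll <- llc
      if (conv) break
    }
    if (Q) alpha[, b] <- theta[iq]
    beta[, , b] <- matrix(theta[Q + seq_len(K * L)], L, K)
  }
  list(alpha_b = alpha, beta_b = beta)
}

## ---- full ECM fit ----------------------------------------------------------

ecm_run <- function(prep, Z0, opts) {
  K <- opts$K
  par <- list(p = pmax(colMeans(Z0), 1e-8))
  par$p <- par$p / sum(par$p)
  par$sigma2 <- matrix(1, K, max(prep$P, 1L))
  par$alpha_q <- matrix(0, prep$Q, prep$P)
  par$beta_q <- array(0, dim = c(prep$L, K, prep$P))
  par$alpha_b <- matrix(0, prep$Q, prep$B)
  par$beta_b <- array(0, dim = c(prep$L, K, prep$B))
  Z <- Z0
  trace <- numeric(0); ll_old <- -Inf
  converged <- FALSE; degenerate <- FALSE
  for (it in seq_len(opts$max_iter)) {
    if (anyNA(Z) || min(colSums(Z)) < max(K, 5)) { degenerate <- TRUE; break }
    if (prep$P) {
      up <- cm_quant_core(Z, prep, par$sigma2)
      par$alpha_q <- up$alpha_q; par$beta_q <- up$beta_q; par$sigma2 <- up$sigma2
    }
    if (prep$B) {
      up <- cm_binary_core(Z, prep, par, max_inner = if (it <= 2L) 25L else 4L)
      par$alpha_b <- up$alpha_b; par$beta_b <- up$beta_b
    }
    par$p <- pmax(colMeans(Z), 1e-10); par$p <- par$p / sum(par$p)
    es <- e_step_core(par, prep)
    if (anyNA(es$Z) || !is.finite(es$loglik)) { degenerate <- TRUE; break }
    Z <- es$Z
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) < opts$rel_tol * (abs(ll_old) + 1)) {
      converged <- TRUE; ll_old <- es$loglik; break
    }
    ll_old <- es$loglik
  }
  list(par = par, Z = Z, loglik = ll_old, trace = trace,
       converged = converged, degenerate = degenerate)
}

## convert working-scale parameters back to the raw data scale
unstandardize_par <- function(par, prep) {
  K <- length(par$p)
  out <- par
  xs <- prep$x_scale; xc <- prep$x_center
  gsc <- prep$g_scale; gc <- prep$g_center
  if (prep$P) {
    ys <- prep$y_scale; yc <- prep$y_center
    if (prep$Q) out$alpha_q <- par$alpha_q * outer(1 / xs, ys)
    for (k in seq_len(K)) {
      bk <- matrix(par$beta_q[, k, ], nrow = prep$L)
      bk <- bk * outer(1 / gsc, ys)
      shift <- if (prep$Q) colSums(par$alpha_q * (xc / xs)) else 0
      shift <- shift + if (prep$L > 1)
        colSums(matrix(par$beta_q[-1, k, ], nrow = prep$L - 1) * (gc[-1] / gsc[-1])) else 0
      bk[1, ] <- yc + ys * (par$beta_q[1, k, ] - shift)
      out$beta_q[, k, ] <- bk
    }
    out$sigma2 <- par$sigma2 * matrix(ys^2, K, prep$P, byrow = TRUE)
  }
  if (prep$B) {
    if (prep$Q) out$alpha_b <- par$alpha_b / xs
    for (k in seq_len(K)) {
      bk <- matrix(par$beta_b[, k, ], nrow = prep$L) / gsc
      shift <- if (prep$Q) colSums(par$alpha_b * (xc / xs)) else 0
      shift <- shift + if (prep$L > 1)
        colSums(matrix(par$beta_b[-1, k, ], nrow = prep$L - 1) * (gc[-1] / gsc[-1])) else 0
      bk[1, ] <- par$beta_b[1, k, ] - shift
      out$beta_b[, k, ] <- bk
    }
  }
  out
}

#' Fit the covariate-aware mixture of multi-trait regressions
#'
#' The generative model: each sample carries a latent subtype
#' `z_i ~ Categorical(p)`; quantitative trait `y_ip = X_i alpha_p +
#' G_i beta_kp + eps` with `eps ~ N(0, sigma2[k,p])`, and binary traits follow
#' probit models with the same design. Homogeneous covariates `X` have shared
#' effects; heterogeneous covariates `G` (whose first column is the intercept,
#' carrying the subtype main effects) have per-subtype effects. The model is
#' fit by Expectation Conditional-Maximization with multiple restarts;
#' quantitative traits and covariates are standardized internally and all
#' reported coefficients are on the original scale. Subtypes are relabeled so
#' the largest (by mixing proportion) comes first.
#'
#' @param traits a [trait_matrix()].
#' @param covariates a [covariate_set()].
#' @param opts an [mfmr_opts()] (or `K` may be given directly).
#' @param K convenience shortcut when `opts` is omitted.
#' @return An object of class `mfmr_fit`: raw-scale parameter matrices
#'   (`alpha_q`, `alpha_b`, `beta_q`, `beta_b`, `sigma2`, `p`), the final
#'   responsibilities `Z`, hard `labels`, the log-likelihood `trace`, and
#'   convergence/degeneracy flags.
#' @export
fit_mfmr <- function(traits, covariates, opts = NULL, K = 2L) {
  if (is.null(opts)) opts <- mfmr_opts(K = K)
  stopifnot(inherits(traits, "trait_matrix"), inherits(covariates, "covariate_set"))
  prep <- mfmr_prepare(traits, covariates)
  if (prep$N <= prep$Q + opts$K * prep$L)
    stop("not enough samples for the requested design")
  K <- opts$K
  set.seed(derive_seed(opts$seed, "mfmr_init"))
  inits <- list()
  if (K == 1L) {
    inits[[1]] <- matrix(1, prep$N, 1)
  } else {
    ## GMM-derived initialization on covariate-residualized quantitative traits
    if (prep$P > 0) {
      D <- cbind(prep$Xs, prep$Gs)
      R <- prep$Ys - D %*% qr.coef(qr(D), prep$Ys)
      g0 <- tryCatch(
        fit_gmm(R, K = K, seed = derive_seed(opts$seed, "gmm_init"),
                n_restarts = 1L, max_iter = 50L),
        error = function(e) NULL)
      if (!is.null(g0)) inits[[length(inits) + 1L]] <- g0$z
    }
    for (r in seq_len(opts$n_restarts)) {
      Zr <- matrix(stats::rgamma(prep$N * K, shape = 1), prep$N, K)
      inits[[length(inits) + 1L]] <- Zr / rowSums(Zr)
    }
    if (!length(inits)) {  # GMM init failed and no restarts requested
      Zr <- matrix(stats::rgamma(prep$N * K, shape = 1), prep$N, K)
      inits[[1L]] <- Zr / rowSums(Zr)
    }
  }
  best <- NULL
  for (Z0 in inits) {
    run <- ecm_run(prep, Z0, opts)
    if (run$degenerate && !is.null(best) && !best$degenerate) next
    if (is.null(best) || (best$degenerate && !run$degenerate) ||
        (run$degenerate == best$degenerate && run$loglik > best$loglik))
      best <- run
  }
  if (is.null(best)) stop("all ECM restarts failed")
  ## log-likelihood was computed on the standardized trait scale; adjust by
  ## the Jacobian so reported values refer to the raw data scale
  ll_adj <- if (prep$P) prep$N * sum(log(prep$y_scale)) else 0
  best$loglik <- best$loglik - ll_adj
  best$trace <- best$trace - ll_adj
  par <- unstandardize_par(best$par, prep)
  ## canonical subtype order: largest mixing proportion first (deterministic)
  ord <- order(par$p, -seq_along(par$p), decreasing = TRUE)
  par$p <- par$p[ord]
  par$beta_q <- par$beta_q[, ord, , drop = FALSE]
  par$beta_b <- par$beta_b[, ord, , drop = FALSE]
  par$sigma2 <- par$sigma2[ord, , drop = FALSE]
  Z <- best$Z[, ord, drop = FALSE]
  fit <- structure(list(
    K = K, p = par$p, alpha_q = par$alpha_q, alpha_b = par$alpha_b,
    beta_q = par$beta_q, beta_b = par$beta_b, sigma2 = par$sigma2,
    Z = Z, labels = max.col(Z, ties.method = "first"),
    loglik = best$loglik, trace = best$trace, converged = best$converged,
    degenerate = best$degenerate,
    schema = list(quant = colnames(traits$quant), binary = colnames(traits$binary),
                  homogeneous = colnames(covariates$homogeneous),
                  heterogeneous = colnames(covariates$heterogeneous))),
    class = "mfmr_fit")
  fit
}

#' @export
print.mfmr_fit <- function(x, ...) {
  cat(sprintf("mfmr_fit: K=%d, loglik=%.2f, %sconverged%s\n", x$K, x$loglik,
              if (x$converged) "" else "NOT ",
              if (x$degenerate) " (degenerate subtype)" else ""))
  cat("mixing proportions:", sprintf("%.3f", x$p), "\n")
  invisible(x)
}

#' Posterior subtype membership for new samples
#'
#' Runs the E-step under frozen parameters. The trait and covariate column
#' schema must match the training data.
#'
#' @param params an `mfmr_fit`.
#' @param traits,covariates new data with the training schema.
#' @return list with responsibilities `Z`, hard `labels`, and `loglik`.
#' @export
predict_subtypes <- function(params, traits, covariates) {
  sc <- params$schema
  if (!identical(colnames(traits$quant), sc$quant) ||
      !identical(colnames(traits$binary), sc$binary) ||
      !identical(colnames(covariates$homogeneous), sc$homogeneous) ||
      !identical(colnames(covariates$heterogeneous), sc$heterogeneous))
    stop("schema mismatch between training and prediction data")
  es <- e_step(params, traits, covariates)
  list(Z = es$Z, labels = max.col(es$Z, ties.method = "first"),
       loglik = es$loglik)
}

#' Cross-validated choice of the number of subtypes
#'
#' For each fold, fits the model on the training folds for every `K` in
#' `k_grid` and evaluates the observed-data log-likelihood on the held-out
#' fold, reported relative to the fold's `K = 1` baseline.
#'
#' @param traits,covariates data containers.
#' @param k_grid integer grid, must contain 1.
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed (fold assignment + fits).
#' @param ... passed to [mfmr_opts()].
#' @return data frame with columns `K`, `fold`, `rel_loglik`, plus a
#'   `summary` attribute of per-K means.
#' @export
cv_select_K <- function(traits, covariates, k_grid = 1:4, n_folds = 5L,
                        seed = 1L, ...) {
  stopifnot(n_folds >= 2, 1L %in% k_grid)
  n <- n_samples(traits)
  set.seed(derive_seed(seed, "cvfolds"))
  fold <- sample(rep_len(seq_len(n_folds), n))
  res <- list()
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    t_tr <- trait_matrix(traits$quant[tr, , drop = FALSE], traits$binary[tr, , drop = FALSE])
    t_te <- trait_matrix(traits$quant[te, , drop = FALSE], traits$binary[te, , drop = FALSE])
    c_tr <- covariate_set(covariates$homogeneous[tr, , drop = FALSE],
                          covariates$heterogeneous[tr, , drop = FALSE])
    c_te <- covariate_set(covariates$homogeneous[te, , drop = FALSE],
                          covariates$heterogeneous[te, , drop = FALSE])
    base_ll <- NULL
    for (K in sort(k_grid)) {
      fit <- fit_mfmr(t_tr, c_tr, opts = mfmr_opts(K = K, seed = derive_seed(seed, paste0("cv", f, "K", K)), ...))
      ll <- log_likelihood(fit, t_te, c_te)
      if (K == 1L) base_ll <- ll
      res[[length(res) + 1L]] <- data.frame(K = K, fold = f,
                                            rel_loglik = ll - base_ll)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "summary") <- stats::aggregate(rel_loglik ~ K, out, mean)
  out
}
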