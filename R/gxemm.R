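#' Genetic relationship matrix from genotype dosages
#'
#' Column-standardizes genotypes (dropping monomorphic SNPs with a warning,
#' mean-imputing missing calls per SNP) and returns `X X' / M`. The mean
#' diagonal is approximately 1 by construction.
#'
#' @param genotypes N x M dosage matrix.
#' @return list of class `grm` with `K` (N x N), `n_snps`, and `ids`.
#' @export
compute_grm <- function(genotypes) {
  g <- as.matrix(genotypes)
  if (anyNA(g)) {
    for (j in seq_len(ncol(g))) {
      miss <- is.na(g[, j])
      if (any(miss)) g[miss, j] <- mean(g[, j], na.rm = TRUE)
    }
  }
  v <- apply(g, 2L, stats::var)
  if (any(v < .Machine$double.eps)) {
    warning(sum(v < .Machine$double.eps), " monomorphic SNP(s) dropped from GRM")
    g <- g[, v >= .Machine$double.eps, drop = FALSE]
  }
  if (ncol(g) == 0) stop("no polymorphic SNPs left for the GRM")
  gs <- standardize_cols(g)
  K <- tcrossprod(gs) / ncol(gs)
  structure(list(K = K, n_snps = ncol(gs),
                 ids = rownames(genotypes) %||% as.character(seq_len(nrow(g)))),
            class = "grm")
}

#' Subtype-specific (heterogeneous) kernel
#'
#' Elementwise product `K o (Z Z')`: the covariance contributed by genetic
#' effects shared only within subtype, with soft memberships propagated. With
#' one subtype this is the GRM itself; with hard one-hot memberships it is
#' block diagonal across subtypes.
#'
#' @param grm a [compute_grm()] result or plain matrix.
#' @param Z N x K membership probabilities (rows on the simplex).
#' @return N x N kernel matrix.
#' @export
het_kernel <- function(grm, Z) {
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(K)) stop("dimension mismatch between GRM and Z")
  if (any(abs(rowSums(Z) - 1) > 1e-6)) stop("rows of Z must sum to 1")
  K * tcrossprod(Z)
}

## REML log-likelihood pieces for V = sum_i sigma[i] * KL[[i]]
reml_pieces <- function(sigma, KL, W, y) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(KL)) V <- V + sigma[i] * KL[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  ldV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViW <- Vi %*% W
  WtViW <- crossprod(W, ViW)
  chW <- tryCatch(chol(WtViW), error = function(e) NULL)
  if (is.null(chW)) return(NULL)
  ldW <- 2 * sum(log(diag(chW)))
  P <- Vi - ViW %*% chol2inv(chW) %*% t(ViW)
  Py <- P %*% y
  ll <- -0.5 * (ldV + ldW + sum(y * Py))
  list(ll = ll, P = P, Py = Py)
}

## Average-information REML over the kernels in KL (last one is identity).
ai_reml <- function(y, W, KL, max_iter = 60L, tol = 1e-6) {
  n <- length(y)
  vy <- stats::var(y)
  q <- length(KL)
  sigma <- rep(vy / q, q)
  lb <- 1e-6 * vy
  pc <- reml_pieces(sigma, KL, W, y)
  if (is.null(pc)) stop("initial REML evaluation failed")
  converged <- FALSE
  AI <- diag(q)
  for (it in seq_len(max_iter)) {
    KPy <- lapply(KL, function(Ki) Ki %*% pc$Py)
    trPK <- vapply(KL, function(Ki) sum(pc$P * Ki), numeric(1))
    yPKPy <- vapply(KPy, function(v) sum(pc$Py * v), numeric(1))
    grad <- -0.5 * (trPK - yPKPy)
    PKPy <- lapply(KPy, function(v) pc$P %*% v)
    AI <- matrix(0, q, q)
    for (i in seq_len(q)) for (j in i:q) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    }
    step <- tryCatch(solve(AI + diag(1e-10 * max(diag(AI)), q), grad),
                     error = function(e) sigma^2 * (yPKPy - trPK) / n)
    ## step halving with projection onto the nonnegative orthant
    ok <- FALSE; sz <- 1
    for (h in 1:30) {
      cand <- pmax(sigma + sz * step, lb)
      pc_new <- reml_pieces(cand, KL, W, y)
      if (!is.null(pc_new) && pc_new$ll >= pc$ll - 1e-10) { ok <- TRUE; break }
      sz <- sz / 2
    }
    if (!ok) { converged <- TRUE; break }  # no uphill step left
    delta <- pc_new$ll - pc$ll
    sigma <- cand; pc <- pc_new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, q))
  list(sigma = sigma, se = se, loglik = pc$ll, AI = AI, converged = converged,
       at_bound = sigma <= lb * 1.0001)
}

#' Fit the IID gene-by-subtype mixed model
#'
#' REML estimation of `V = sigma2_hom * K + sigma2_het * (K o ZZ') +
#' sigma2_e * I`, where `K` is the GRM and the heterogeneous kernel carries
#' genetic effects shared only within subtype (soft memberships propagated).
#' Also fits the constrained GREML model (`sigma2_het = 0`) and the
#' fixed-effects-only null, which downstream tests use. Heritability
#' fractions are computed on the fixed-effect-residualized variance scale,
#' weighting each component by its kernel's mean diagonal.
#'
#' @param y trait vector.
#' @param fixed fixed-effect design matrix (intercept added if absent);
#'   typically the step-1 covariates, subtype memberships and their
#'   interactions (see [gxemm_fixed_design()]).
#' @param grm a [compute_grm()] result or plain GRM matrix.
#' @param het_k heterogeneous kernel from [het_kernel()].
#' @param max_iter,tol AI-REML controls.
#' @return list of class `gxemm_fit` with components `sigma2` (hom, het, e),
#'   `se`, `h2_hom`, `h2_het`, `h2_iid`, `h2_greml`, standard errors,
#'   log-likelihoods of full/GREML/null fits and convergence flags.
#' @export
fit_iid_gxemm <- function(y, fixed, grm, het_k, max_iter = 60L, tol = 1e-6) {
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  n <- length(y)
  W <- as.matrix(fixed)
  if (!any(apply(W, 2, function(c) all(c == c[1]) && c[1] != 0)))
    W <- cbind(1, W)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) W <- W[, qrW$pivot[seq_len(qrW$rank)], drop = FALSE]
  I_n <- diag(n)
  full <- ai_reml(y, W, list(K, het_k, I_n), max_iter, tol)
  greml <- ai_reml(y, W, list(K, I_n), max_iter, tol)
  ## fixed-effects-only null: residual variance REML closed form
  r <- stats::lm.fit(W, y)$residuals
  s2_null <- sum(r^2) / (n - ncol(W))
  ll_null <- -0.5 * ((n - ncol(W)) * log(s2_null) + determinant(crossprod(W))$modulus +
                       (n - ncol(W)))
  dK <- mean(diag(K)); dH <- mean(diag(het_k))
  wts <- c(dK, dH, 1)
  tot <- sum(full$sigma * wts)
  h2_hom <- full$sigma[1] * dK / tot
  h2_het <- full$sigma[2] * dH / tot
  ## delta-method s.e. for the h2 fractions from the AI covariance
  Sg <- tryCatch(solve(full$AI), error = function(e) matrix(NA, 3, 3))
  hgrad <- function(i) {
    gv <- -full$sigma[i] * wts[i] * wts / tot^2
    gv[i] <- gv[i] + wts[i] / tot
    gv
  }
  se_hom <- sqrt(drop(t(hgrad(1)) %*% Sg %*% hgrad(1)))
  se_het <- sqrt(drop(t(hgrad(2)) %*% Sg %*% hgrad(2)))
  gsum <- hgrad(1) + hgrad(2)
  se_iid <- sqrt(drop(t(gsum) %*% Sg %*% gsum))
  tot_g <- greml$sigma[1] * dK + greml$sigma[2]
  h2_greml <- greml$sigma[1] * dK / tot_g
  Sg2 <- tryCatch(solve(greml$AI), error = function(e) matrix(NA, 2, 2))
  gg <- c(dK * greml$sigma[2], -greml$sigma[1] * dK) / tot_g^2
  se_greml <- sqrt(drop(t(gg) %*% Sg2 %*% gg))
  structure(list(sigma2 = stats::setNames(full$sigma, c("hom", "het", "e")),
                 se_sigma2 = full$se,
                 h2_hom = h2_hom, h2_het = h2_het, h2_iid = h2_hom + h2_het,
                 h2_greml = h2_greml,
                 sigma2_greml = stats::setNames(greml$sigma, c("g", "e")),
                 se_h2 = c(hom = se_hom, het = se_het, iid = se_iid,
                           greml = se_greml),
                 loglik_full = full$loglik, loglik_greml = greml$loglik,
                 loglik_null = ll_null,
                 converged = full$converged && greml$converged,
                 at_bound = full$at_bound, n = n),
            class = "gxemm_fit")
}

#' @export
print.gxemm_fit <- function(x, ...) {
  cat(sprintf("gxemm_fit (n=%d): h2_hom=%.3f (%.3f), h2_het=%.3f (%.3f), h2_iid=%.3f; h2_greml=%.3f\n",
              x$n, x$h2_hom, x$se_h2["hom"], x$h2_het, x$se_h2["het"],
              x$h2_iid, x$h2_greml))
  invisible(x)
}

#' Fixed-effect design for the mixed model
#'
#' Builds `[intercept, background, Z(-ref), background x Z(-ref)]`, the
#' covariates used in clustering plus their interactions with subtype
#' membership.
#'
#' @param Z membership probabilities.
#' @param background optional covariate matrix.
#' @return design matrix.
#' @export
gxemm_fixed_design <- function(Z, background = NULL) {
  Z <- as.matrix(Z)
  ref <- which.max(colSums(Z))
  W <- cbind(`(Intercept)` = rep(1, nrow(Z)))
  if (!is.null(background) && ncol(as.matrix(background)) > 0) {
    bg <- as.matrix(background)
    W <- cbind(W, bg)
    if (ncol(Z) > 1)
      for (j in seq_len(ncol(Z))[-ref]) W <- cbind(W, bg * Z[, j])
  }
  if (ncol(Z) > 1) W <- cbind(W, Z[, -ref, drop = FALSE])
  W
}

#' Tests on fitted variance components
#'
#' Wald test (one-sided) for total genetic variance `h2_g > 0` from the
#' GREML-constrained fit, and a likelihood-ratio test for `h2_het = 0` with
#' the boundary-aware 50:50 mixture of chi-squared 0 and 1 null.
#'
#' @param fit a `gxemm_fit`.
#' @return list with `wald_p_h2g`, `lrt_stat`, `lrt_p_h2het`.
#' @export
test_components <- function(fit) {
  if (is.null(fit$loglik_greml) || is.null(fit$loglik_full))
    stop("both full and constrained fits are required")
  wald_z <- fit$h2_greml / fit$se_h2["greml"]
  wald_p <- stats::pnorm(wald_z, lower.tail = FALSE)
  lrt <- 2 * (fit$loglik_full - fit$loglik_greml)
  lrt_p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  list(wald_p_h2g = unname(wald_p), lrt_stat = max(lrt, 0),
       lrt_p_h2het = unname(lrt_p))
}

## ---- GRM serialization -----------------------------------------------------

#' Read/write genetic relationship matrices
#'
#' `write_grm_tsv`/`read_grm_tsv` use a plain square TSV with sample IDs as
#' header. `write_grm_gcta`/`read_grm_gcta` use the binary GCTA triple
#' (`.grm.bin` single-precision lower triangle, `.grm.N.bin`, `.grm.id`).
#'
#' @param grm a `grm` object (or square matrix for TSV writing).
#' @param path file path (prefix without extension for the GCTA triple).
#' @return the `grm` (readers) or the path (writers), invisibly.
#' @export
write_grm_tsv <- function(grm, path) {
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  ids <- if (inherits(grm, "grm")) grm$ids else as.character(seq_len(nrow(K)))
  df <- data.table::as.data.table(K)
  data.table::setnames(df, ids)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE)
  K <- as.matrix(df)
  structure(list(K = unname(K), n_snps = NA_integer_, ids = colnames(df)),
            class = "grm")
}

#' @rdname write_grm_tsv
#' @export
write_grm_gcta <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$K)
  lower <- grm$K[upper.tri(grm$K, diag = TRUE)]  # column-major upper == row-major lower
  con <- file(paste0(path, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L)
  close(con)
  con <- file(paste0(path, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps), length(lower)), con, size = 4L)
  close(con)
  utils::write.table(data.frame(fid = grm$ids, iid = grm$ids),
                     paste0(path, ".grm.id"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_gcta <- function(path) {
  ids <- utils::read.table(paste0(path, ".grm.id"))
  n <- nrow(ids)
  m <- n * (n + 1) / 2
  con <- file(paste0(path, ".grm.bin"), "rb")
  vals <- readBin(con, numeric(), n = m, size = 4L)
  close(con)
  K <- matrix(0, n, n)
  K[upper.tri(K, diag = TRUE)] <- vals
  K <- K + t(K) - diag(diag(K))
  con <- file(paste0(path, ".grm.N.bin"), "rb")
  nsnp <- readBin(con, numeric(), n = 1, size = 4L)
  close(con)
  structure(list(K = K, n_snps = as.integer(round(nsnp)),
                 ids = as.character(ids[[2]])), class = "grm")
}
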