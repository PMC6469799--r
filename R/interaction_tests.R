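## least-squares helper returning coefficients and their covariance
fast_lm <- function(Xmat, y) {
  qrx <- qr(Xmat)
  if (qrx$rank < ncol(Xmat)) return(NULL)
  coef <- qr.coef(qrx, y)
  res <- y - Xmat %*% coef
  df_res <- length(y) - ncol(Xmat)
  s2 <- sum(res^2) / df_res
  Rinv <- backsolve(qr.R(qrx), diag(ncol(Xmat)))
  vcov <- tcrossprod(Rinv) * s2
  ## restore original column order (qr pivots)
  piv <- qrx$pivot
  vcov[piv, piv] <- vcov
  list(coef = coef, vcov = vcov, s2 = s2, df_res = df_res,
       loglik = -0.5 * length(y) * (log(2 * pi * mean(res^2)) + 1))
}

fast_glm_logit <- function(Xmat, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xmat, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  w <- fit$weights
  XtWX <- crossprod(Xmat, Xmat * w)
  vcov <- tryCatch(solve(XtWX), error = function(e) NULL)
  list(coef = fit$coefficients, vcov = vcov, deviance = fit$deviance)
}

## Z may be an N x K simplex matrix (discrete subtypes, soft memberships) or
## a single continuous score column (CCA/PC-style subtype estimates); the
## latter gives 1-df heterogeneity and 2-df global tests.
build_designs <- function(g, Z, background, background_interactions = FALSE) {
  Z <- as.matrix(Z)
  continuous <- ncol(Z) == 1 && stats::sd(Z[, 1]) > 1e-10
  if (continuous) {
    Zr <- Z
    colnames(Zr) <- "z"
    ref <- NA_integer_
    K <- 2L  # df bookkeeping: one interaction term
  } else {
    K <- ncol(Z)
    if (any(abs(rowSums(Z) - 1) > 1e-6))
      stop("rows of Z must sum to 1 (or pass a single continuous score column)")
    ref <- which.max(colSums(Z))
    Zr <- Z[, -ref, drop = FALSE]
    if (K > 1 && any(apply(Zr, 2, stats::sd) < 1e-10))
      stop("no subtype variation: responsibilities are constant")
  }
  base <- cbind(`(Intercept)` = rep(1, nrow(Z)))
  if (!is.null(background) && ncol(as.matrix(background)) > 0) {
    bg <- as.matrix(background)
    if (is.null(colnames(bg))) colnames(bg) <- paste0("bg", seq_len(ncol(bg)))
    base <- cbind(base, bg)
    if (background_interactions && K > 1) {
      for (j in seq_len(ncol(Zr)))
        base <- cbind(base, bg * Zr[, j])
    }
  }
  if (ncol(Zr) > 0) {
    if (!continuous) colnames(Zr) <- paste0("z", seq_len(K)[-ref])
    base <- cbind(base, Zr)
  }
  gz <- if (ncol(Zr) > 0) {
    m <- Zr * g; colnames(m) <- paste0("g:", colnames(Zr)); m
  } else NULL
  list(base = base, g = g, gz = gz, ref = ref, K = K,
       continuous = continuous)
}

#' Fixed-effect covariate-by-subtype interaction test
#'
#' Fits `y ~ background + z + g + g*z` using the subtype membership
#' probabilities `Z` directly as regressors (one column dropped for
#' identifiability; the largest subtype is the reference). Three modes:
#' `homogeneity` tests the shared effect `delta` with the interactions fixed
#' at zero (1 df); `heterogeneity` tests the K-1 interaction terms with
#' `delta` free (K-1 df); `global` jointly tests main plus interactions
#' (K df). Quantitative traits use linear regression with Wald chi-squared
#' statistics; binary traits use logistic regression with likelihood-ratio
#' statistics.
#'
#' @param y response vector.
#' @param g focal covariate (SNP dosage, treatment, ...).
#' @param Z N x K subtype membership probabilities (rows on the simplex).
#' @param background optional matrix of background covariates (genetic PCs
#'   etc.); an intercept is always added.
#' @param family `"quantitative"` or `"binary"`.
#' @param mode `"heterogeneity"`, `"homogeneity"` or `"global"`.
#' @param background_interactions also interact background columns with `z`
#'   (recommended under population structure).
#' @return object of class `test_result`: `statistic`, `df`, `p_value`,
#'   per-subtype `effects` (estimate, se for `delta + beta_k`), `family`,
#'   `mode`.
#' @export
interaction_test <- function(y, g, Z, background = NULL,
                             family = c("quantitative", "binary"),
                             mode = c("heterogeneity", "homogeneity", "global"),
                             background_interactions = FALSE) {
  family <- match.arg(family); mode <- match.arg(mode)
  Z <- as.matrix(Z)
  if (ncol(Z) == 1 && stats::sd(Z[, 1]) < 1e-10 && mode != "homogeneity")
    stop("no subtype variation: K = 1 supports only the homogeneity test")
  d <- build_designs(g, Z, background, background_interactions)
  X_hom <- cbind(d$base, g = g)
  X_full <- if (is.null(d$gz)) X_hom else cbind(X_hom, d$gz)
  n_int <- if (is.null(d$gz)) 0L else ncol(d$gz)
  ig <- ncol(d$base) + 1L                      # index of g in X_hom/X_full
  ii <- if (n_int) ig + seq_len(n_int) else integer(0)

  if (family == "quantitative") {
    f_full <- fast_lm(X_full, y)
    f_hom <- if (mode == "homogeneity") fast_lm(X_hom, y) else NULL
    if (is.null(f_full)) stop("collinear design in interaction test")
    res <- switch(mode,
      homogeneity = {
        stat <- f_hom$coef[ig]^2 / f_hom$vcov[ig, ig]
        list(stat = stat, df = 1L)
      },
      heterogeneity = {
        v <- f_full$vcov[ii, ii, drop = FALSE]
        b <- f_full$coef[ii]
        list(stat = drop(t(b) %*% solve(v, b)), df = n_int)
      },
      global = {
        idx <- c(ig, ii)
        v <- f_full$vcov[idx, idx, drop = FALSE]
        b <- f_full$coef[idx]
        list(stat = drop(t(b) %*% solve(v, b)), df = length(idx))
      })
    fit_for_effects <- f_full
  } else {
    f_base <- fast_glm_logit(d$base, y)
    f_hom <- fast_glm_logit(X_hom, y)
    f_full <- fast_glm_logit(X_full, y)
    if (is.null(f_full) || is.null(f_hom) || is.null(f_base))
      stop("logistic fit failed (possible separation)")
    res <- switch(mode,
      homogeneity = list(stat = f_base$deviance - f_hom$deviance, df = 1L),
      heterogeneity = list(stat = f_hom$deviance - f_full$deviance, df = n_int),
      global = list(stat = f_base$deviance - f_full$deviance,
                    df = 1L + n_int))
    fit_for_effects <- f_full
  }
  stat <- max(res$stat, 0)
  eff <- if (d$continuous) {
    ## slope of g at score 0 and score +1 (delta, delta + beta)
    data.frame(subtype = c("score=0", "score=1"),
               estimate = c(fit_for_effects$coef[ig],
                            fit_for_effects$coef[ig] + fit_for_effects$coef[ii]),
               se = c(sqrt(fit_for_effects$vcov[ig, ig]),
                      sqrt(fit_for_effects$vcov[ig, ig] +
                             fit_for_effects$vcov[ii, ii] +
                             2 * fit_for_effects$vcov[ig, ii])))
  } else subtype_effect_table(fit_for_effects, ig, ii, d$ref, d$K)
  structure(list(statistic = stat, df = res$df,
                 p_value = stats::pchisq(stat, res$df, lower.tail = FALSE),
                 effects = eff, family = family, mode = mode,
                 reference_subtype = d$ref),
            class = "test_result")
}

## per-subtype effect decomposition delta + beta_k with delta-method s.e.
subtype_effect_table <- function(fit, ig, ii, ref, K) {
  est <- se <- rep(NA_real_, K)
  dl <- fit$coef[ig]
  est[ref] <- dl
  if (!is.null(fit$vcov)) se[ref] <- sqrt(fit$vcov[ig, ig])
  others <- seq_len(K)[-ref]
  for (j in seq_along(ii)) {
    k <- others[j]
    est[k] <- dl + fit$coef[ii[j]]
    if (!is.null(fit$vcov))
      se[k] <- sqrt(fit$vcov[ig, ig] + fit$vcov[ii[j], ii[j]] +
                      2 * fit$vcov[ig, ii[j]])
  }
  data.frame(subtype = seq_len(K), estimate = est, se = se)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s %s test: stat=%.3f, df=%d, p=%.3g\n", x$family, x$mode,
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Vectorized interaction test across many quantitative traits
#'
#' Same model and Wald statistics as [interaction_test()] restricted to
#' quantitative traits, but sharing one QR decomposition across all trait
#' columns (the design depends only on the focal covariate). Used by genome
#' scans and large simulation studies where the per-trait loop dominates.
#'
#' @param Y N x P matrix of quantitative traits.
#' @param g focal covariate.
#' @param Z membership probabilities.
#' @param background optional covariate matrix.
#' @param mode as in [interaction_test()].
#' @param background_interactions as in [interaction_test()].
#' @return data frame with one row per trait: `trait`, `stat`, `df`, `p`.
#' @export
interaction_test_multi <- function(Y, g, Z, background = NULL,
                                   mode = c("heterogeneity", "homogeneity", "global"),
                                   background_interactions = FALSE) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  Z <- as.matrix(Z)
  if (ncol(Z) == 1 && stats::sd(Z[, 1]) < 1e-10 && mode != "homogeneity")
    stop("no subtype variation: K = 1 supports only the homogeneity test")
  d <- build_designs(g, Z, background, background_interactions)
  X_hom <- cbind(d$base, g = g)
  X_full <- if (is.null(d$gz)) X_hom else cbind(X_hom, d$gz)
  n_int <- if (is.null(d$gz)) 0L else ncol(d$gz)
  ig <- ncol(d$base) + 1L
  ii <- if (n_int) ig + seq_len(n_int) else integer(0)
  Xu <- if (mode == "homogeneity") X_hom else X_full
  qrx <- qr(Xu)
  if (qrx$rank < ncol(Xu)) stop("collinear design in interaction test")
  coefs <- qr.coef(qrx, Y)
  res <- Y - Xu %*% coefs
  df_res <- nrow(Y) - ncol(Xu)
  s2 <- colSums(res^2) / df_res
  Rinv <- backsolve(qr.R(qrx), diag(ncol(Xu)))
  XtXinv <- tcrossprod(Rinv)
  piv <- qrx$pivot
  XtXinv[piv, piv] <- XtXinv
  idx <- switch(mode, homogeneity = ig, heterogeneity = ii, global = c(ig, ii))
  Vsub_inv <- solve(XtXinv[idx, idx, drop = FALSE])
  B <- coefs[idx, , drop = FALSE]
  stat <- colSums(B * (Vsub_inv %*% B)) / s2
  df <- length(idx)
  data.frame(trait = colnames(Y) %||% paste0("q", seq_len(ncol(Y))),
             stat = stat, df = df,
             p = stats::pchisq(stat, df, lower.tail = FALSE),
             row.names = NULL)
}

#' Per-subtype effect estimates on a chosen scale
#'
#' Extracts the `delta + beta_k` decomposition from a fitted [test_result],
#' with plus/minus 2 s.e. intervals, optionally exponentiated to odds ratios
#' for logistic fits.
#'
#' @param result a `test_result`.
#' @param scale `"linear"` or `"odds_ratio"`.
#' @return data frame with estimate, se and 2-s.e. interval per subtype.
#' @export
subtype_specific_effects <- function(result, scale = c("linear", "odds_ratio")) {
  scale <- match.arg(scale)
  eff <- result$effects
  if (any(is.na(eff$se))) stop("missing coefficient covariance in test result")
  out <- data.frame(subtype = eff$subtype, estimate = eff$estimate,
                    se = eff$se,
                    lower = eff$estimate - 2 * eff$se,
                    upper = eff$estimate + 2 * eff$se)
  if (scale == "odds_ratio") {
    if (result$family != "binary")
      stop("odds ratios require a logistic (binary) fit")
    out$estimate <- exp(out$estimate)
    out$lower <- exp(out$lower); out$upper <- exp(out$upper)
  }
  out
}

#' Heterogeneity test for a large-effect covariate included in step 1
#'
#' When a focal covariate has large effects it should be included
#' homogeneously in `X` during clustering; this helper then runs the
#' interaction test on the resulting responsibilities, optionally with extra
#' conditioning covariates (e.g. disease status).
#'
#' @param traits a [trait_matrix()].
#' @param covariates the [covariate_set()] used for the step-1 fit.
#' @param focal column name (or index) of the focal covariate inside the
#'   homogeneous block.
#' @param fit the `mfmr_fit` obtained with `focal` in `X`.
#' @param trait trait column name (searched in both blocks).
#' @param extra_conditioning optional matrix of additional covariates.
#' @param mode test mode, as in [interaction_test()].
#' @return a `test_result`.
#' @export
droptest_large_covariate <- function(traits, covariates, focal, fit, trait,
                                     extra_conditioning = NULL,
                                     mode = "heterogeneity") {
  Xh <- covariates$homogeneous
  if (is.character(focal)) {
    if (!(focal %in% colnames(Xh)))
      stop("focal covariate was not included homogeneously in the step-1 fit; refit with it in X")
    fidx <- match(focal, colnames(Xh))
  } else fidx <- focal
  if (!(colnames(Xh)[fidx] %in% fit$schema$homogeneous))
    stop("focal covariate was not included homogeneously in the step-1 fit; refit with it in X")
  g <- Xh[, fidx]
  bg <- Xh[, -fidx, drop = FALSE]
  if (!is.null(extra_conditioning)) {
    ec <- as.matrix(extra_conditioning)
    for (j in seq_len(ncol(ec)))
      if (isTRUE(all.equal(as.vector(ec[, j]), as.vector(g))))
        stop("duplicated column: extra conditioning repeats the focal covariate")
    bg <- cbind(bg, ec)
  }
  if (trait %in% colnames(traits$quant)) {
    y <- traits$quant[, trait]; fam <- "quantitative"
  } else if (trait %in% colnames(traits$binary)) {
    y <- traits$binary[, trait]; fam <- "binary"
  } else stop("unknown trait: ", trait)
  interaction_test(y, g, fit$Z, background = bg, family = fam, mode = mode)
}

#' Genome scan with subtype-aware tests
#'
#' Runs one of three per-SNP tests with the responsibilities frozen:
#' `gwas` is the ordinary 1-df homogeneous test, `gxe_global` the K-df joint
#' main+interaction test, `het` the (K-1)-df heterogeneity test. Monomorphic
#' SNPs yield NA rows with a reason code. The genomic-control inflation
#' factor of the scan is attached and scans above `lambda_ceiling` flagged.
#'
#' @param genotypes N x M dosage matrix.
#' @param y trait vector.
#' @param Z subtype membership probabilities.
#' @param background optional background covariate matrix.
#' @param family trait family, as in [interaction_test()].
#' @param mode `"gwas"`, `"gxe_global"` or `"het"`.
#' @param background_interactions interact background with z (recommended
#'   with genetic PCs under structure).
#' @param snp_ids optional SNP names.
#' @param lambda_ceiling genomic-control QC threshold (default 1.5).
#' @return data frame (one row per SNP) with stat, df, p and per-subtype
#'   effects; attributes `lambda_gc` and `lambda_flag`.
#' @export
genome_scan <- function(genotypes, y, Z, background = NULL,
                        family = c("quantitative", "binary"),
                        mode = c("gwas", "gxe_global", "het"),
                        background_interactions = FALSE, snp_ids = NULL,
                        lambda_ceiling = 1.5) {
  family <- match.arg(family); mode <- match.arg(mode)
  genotypes <- as.matrix(genotypes)
  M <- ncol(genotypes)
  if (is.null(snp_ids))
    snp_ids <- colnames(genotypes) %||% paste0("snp", seq_len(M))
  tmode <- switch(mode, gwas = "homogeneity", gxe_global = "global",
                  het = "heterogeneity")
  K <- ncol(Z)
  rows <- vector("list", M)
  for (m in seq_len(M)) {
    gm <- genotypes[, m]
    if (stats::var(gm) < .Machine$double.eps) {
      rows[[m]] <- data.frame(snp_id = snp_ids[m], mode = mode,
                              stat = NA_real_, df = NA_integer_,
                              p = NA_real_, reason = "monomorphic")
      next
    }
    tr <- interaction_test(y, gm, Z, background = background, family = family,
                           mode = tmode,
                           background_interactions = background_interactions)
    row <- data.frame(snp_id = snp_ids[m], mode = mode, stat = tr$statistic,
                      df = tr$df, p = tr$p_value, reason = "")
    rows[[m]] <- row
  }
  out <- do.call(rbind, rows)
  lam <- lambda_gc(out$p[!is.na(out$p)])
  attr(out, "lambda_gc") <- lam
  attr(out, "lambda_flag") <- is.finite(lam) && lam > lambda_ceiling
  out
}

#' Genomic-control inflation factor
#'
#' Converts p-values to implied 1-df chi-squared statistics and divides their
#' median by the null median (0.4549...). Values near 1 indicate a calibrated
#' scan; values well above 1 indicate inflation.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return scalar inflation factor.
#' @export
lambda_gc <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0,1]")
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}
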