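test_that("K=1 fit reduces to OLS and probit maximum likelihood", {
  set.seed(2)
  n <- 400
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- as.vector(1 + X %*% c(0.5, -0.3) + rnorm(n))
  yb <- rbinom(n, 1, pnorm(0.3 + X[, 1] * 0.8))
  tm <- trait_matrix(quant = cbind(q1 = y), binary = cbind(b1 = yb))
  cs <- covariate_set(homogeneous = X, n = n)
  fit <- fit_mfmr(tm, cs, opts = mfmr_opts(K = 1))
  ols <- lm(y ~ X)
  expect_equal(unname(fit$alpha_q[, 1]), unname(coef(ols)[2:3]), tolerance = 1e-10)
  expect_equal(unname(fit$beta_q[1, 1, 1]), unname(coef(ols)[1]), tolerance = 1e-10)
  pr <- suppressWarnings(glm(yb ~ X, family = binomial(link = "probit")))
  expect_equal(unname(fit$alpha_b[, 1]), unname(coef(pr)[2:3]), tolerance = 1e-5)
  closed <- sum(dnorm(y, fitted(ols), sqrt(mean(resid(ols)^2)), log = TRUE)) +
    as.numeric(logLik(pr))
  expect_equal(fit$loglik, closed, tolerance = 1e-7)
  ## additivity: duplicating every row doubles the log-likelihood
  idx <- rep(seq_len(n), 2)
  tm2 <- trait_matrix(quant = tm$quant[idx, , drop = FALSE],
                      binary = tm$binary[idx, , drop = FALSE])
  cs2 <- covariate_set(homogeneous = X[idx, ], n = 2 * n)
  expect_equal(log_likelihood(fit, tm2, cs2), 2 * log_likelihood(fit, tm, cs),
               tolerance = 1e-10)
})

test_that("E-step matches hand-computed Bayes rule and its degenerate cases", {
  params <- list(p = c(0.4, 0.6),
                 alpha_q = matrix(0, 0, 1), alpha_b = matrix(0, 0, 0),
                 beta_q = array(c(-1, 2), dim = c(1, 2, 1)),
                 beta_b = array(0, dim = c(1, 2, 0)),
                 sigma2 = matrix(c(1, 4), 2, 1))
  y <- c(0.5, 3)
  tm <- trait_matrix(quant = cbind(q1 = y))
  cs <- covariate_set(n = 2)
  es <- e_step(params, tm, cs)
  manual <- t(vapply(y, function(yy) {
    w <- c(0.4 * dnorm(yy, -1, 1), 0.6 * dnorm(yy, 2, 2))
    w / sum(w)
  }, numeric(2)))
  expect_equal(es$Z, manual, tolerance = 1e-12, ignore_attr = TRUE)
  ## identical subtype blocks: every row equals p
  params2 <- params
  params2$beta_q <- array(c(1, 1), dim = c(1, 2, 1))
  params2$sigma2 <- matrix(1, 2, 1)
  es2 <- e_step(params2, tm, cs)
  expect_equal(es2$Z, matrix(c(0.4, 0.6), 2, 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## K = 1: all-ones column
  params1 <- list(p = 1, alpha_q = matrix(0, 0, 1), alpha_b = matrix(0, 0, 0),
                  beta_q = array(0, dim = c(1, 1, 1)),
                  beta_b = array(0, dim = c(1, 1, 0)), sigma2 = matrix(1, 1, 1))
  expect_equal(e_step(params1, tm, cs)$Z, matrix(1, 2, 1), ignore_attr = TRUE)
  expect_error(log_likelihood(within(params, sigma2 <- -sigma2), tm, cs),
               "sigma2")
})

test_that("quantitative CM step solves the weighted least-squares oracle", {
  set.seed(4)
  n <- 500
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x1"))
  z <- rbinom(n, 1, 0.4) + 1L
  y <- as.vector(0.7 * X + c(-1, 1.5)[z] + rnorm(n))
  tm <- trait_matrix(quant = cbind(q1 = y))
  cs <- covariate_set(homogeneous = X, n = n)
  ## hard truth responsibilities: equals OLS on the expanded design
  Z <- onehot(z)
  up <- cm_step_quantitative(Z, tm, cs)
  oracle <- lm(y ~ 0 + X + factor(z))
  expect_equal(unname(up$alpha[1, 1]), unname(coef(oracle)["X"]), tolerance = 1e-10)
  expect_equal(unname(up$beta[1, , 1]), unname(coef(oracle)[2:3]), tolerance = 1e-10)
  ## single subtype: plain OLS on [X G]
  up1 <- cm_step_quantitative(matrix(1, n, 1), tm, cs)
  o1 <- lm(y ~ X)
  expect_equal(unname(up1$beta[1, 1, 1]), unname(coef(o1)[1]), tolerance = 1e-10)
  ## no X, intercept-only G: responsibility-weighted means (GMM M-step)
  cs0 <- covariate_set(n = n)
  Zsoft <- cbind(runif(n)); Zsoft <- cbind(Zsoft, 1 - Zsoft)
  up0 <- cm_step_quantitative(Zsoft, tm, cs0)
  expect_equal(unname(up0$beta[1, 1, 1]), sum(Zsoft[, 1] * y) / sum(Zsoft[, 1]),
               tolerance = 1e-10)
})

test_that("binary CM step maximizes the weighted probit likelihood", {
  set.seed(5)
  n <- 600
  ## intercept-only, one subtype: closed-form probit intercept
  yb <- rbinom(n, 1, 0.3)
  tm <- trait_matrix(binary = cbind(b1 = yb))
  cs <- covariate_set(n = n)
  up <- cm_step_binary(matrix(1, n, 1), tm, cs)
  expect_equal(unname(up$beta[1, 1, 1]), qnorm(mean(yb)), tolerance = 1e-6)
  ## with truth memberships: matches glm on the expanded design
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x1"))
  z <- rbinom(n, 1, 0.5) + 1L
  eta <- 0.5 * X[, 1] + c(-0.8, 0.8)[z]
  yb2 <- rbinom(n, 1, pnorm(eta))
  tm2 <- trait_matrix(binary = cbind(b1 = yb2))
  cs2 <- covariate_set(homogeneous = X, n = n)
  up2 <- cm_step_binary(onehot(z), tm2, cs2)
  oracle <- suppressWarnings(
    glm(yb2 ~ 0 + X + factor(z), family = binomial(link = "probit")))
  expect_equal(unname(up2$alpha[1, 1]), unname(coef(oracle)["X"]), tolerance = 1e-5)
  expect_equal(unname(up2$beta[1, , 1]), unname(coef(oracle)[2:3]), tolerance = 1e-5)
  ## constant binary trait is flagged, not fatal
  tmc <- trait_matrix(binary = cbind(b1 = rep(1, n)))
  expect_warning(cm_step_binary(matrix(1, n, 1), tmc, cs), "constant")
})

test_that("ECM log-likelihood is non-decreasing on random datasets", {
  set.seed(6)
  for (rep in 1:6) {
    n <- 150
    ds <- small_k2(n = n, seed = 100 + rep, n_quant = 3, n_binary = 1)
    for (s in 1:2) {
      fit <- fit_mfmr(ds$traits, ds$covariates,
                      opts = mfmr_opts(K = 2, n_restarts = 1, max_iter = 60,
                                       seed = s))
      expect_true(all(diff(fit$trace) >= -1e-6 * (abs(fit$trace[-1]) + 1)),
                  info = sprintf("rep %d seed %d", rep, s))
    }
  }
})

test_that("subtype recovery is near-perfect at baseline and beats GMM when covariates bite", {
  ds <- small_k2(n = 2000, seed = 7)
  fit <- fit_mfmr(ds$traits, ds$covariates, opts = fast_opts(2, seed = 1))
  expect_gt(adjusted_rand_index(fit$labels, ds$z_true), 0.9)
  ## strong homogeneous covariate effects confound covariate-unaware GMM;
  ## compare mean accuracy over draws (GMM is bimodal: it locks on or fails)
  ari_m <- ari_g <- numeric(0)
  for (s in c(7, 8, 21, 22)) {
    dss <- small_k2(n = 1200, seed = s, h2_hom = 0.25, h2_z = 0.08)
    f <- fit_mfmr(dss$traits, dss$covariates,
                  opts = mfmr_opts(K = 2, n_restarts = 2, seed = 1))
    g <- fit_gmm(dss$traits$quant, K = 2, seed = 1)
    ari_m <- c(ari_m, adjusted_rand_index(f$labels, dss$z_true))
    ari_g <- c(ari_g, adjusted_rand_index(g$labels, dss$z_true))
  }
  expect_gt(mean(ari_m), mean(ari_g))
  expect_gt(mean(ari_m), 0.7)
  ## canonical label order is deterministic across identical fits
  fit2 <- fit_mfmr(ds$traits, ds$covariates, opts = fast_opts(2, seed = 1))
  expect_identical(fit$labels, fit2$labels)
  expect_true(all(diff(fit$p) <= 1e-12))  # largest subtype first
})

test_that("single-trait GMM reduction matches the mixture fit", {
  set.seed(8)
  n <- 1500
  z <- rbinom(n, 1, 0.45) + 1L
  y <- rnorm(n, c(-1.2, 1.2)[z], c(0.8, 1.1)[z])
  tm <- trait_matrix(quant = cbind(q1 = y))
  cs <- covariate_set(n = n)
  fit <- fit_mfmr(tm, cs, opts = mfmr_opts(K = 2, n_restarts = 3, seed = 2))
  g <- fit_gmm(cbind(q1 = y), K = 2, seed = 2, n_restarts = 3)
  expect_equal(sort(fit$beta_q[1, , 1]), sort(as.vector(g$means)), tolerance = 0.05)
  expect_gt(cor(fit$Z[, 1], g$z[, 1]) * sign(cor(fit$Z[, 1], g$z[, 1])), 0.98)
})

test_that("prediction reproduces training responsibilities and symmetry", {
  ds <- small_k2(n = 600, seed = 9)
  fit <- fit_mfmr(ds$traits, ds$covariates, opts = fast_opts(2, seed = 1))
  pr <- predict_subtypes(fit, ds$traits, ds$covariates)
  expect_equal(pr$Z, fit$Z, tolerance = 1e-8, ignore_attr = TRUE)
  ## symmetric parameters: posterior equals the prior for any sample
  sym <- fit
  sym$beta_q[, 2, ] <- sym$beta_q[, 1, ]
  sym$beta_b[, 2, ] <- sym$beta_b[, 1, ]
  sym$alpha_q <- fit$alpha_q
  sym$sigma2[2, ] <- sym$sigma2[1, ]
  pr2 <- predict_subtypes(sym, ds$traits, ds$covariates)
  expect_equal(pr2$Z[5, ], sym$p, tolerance = 1e-10, ignore_attr = TRUE)
  ## schema mismatch is an error
  tm_bad <- trait_matrix(quant = ds$traits$quant[, -1], binary = ds$traits$binary)
  expect_error(predict_subtypes(fit, tm_bad, ds$covariates), "schema")
})

test_that("cross-validated K selection behaves at both ends", {
  ds <- small_k2(n = 700, seed = 10)
  cv <- cv_select_K(ds$traits, ds$covariates, k_grid = 1:2, n_folds = 3,
                    seed = 1, n_restarts = 1)
  sm <- attr(cv, "summary")
  expect_equal(sm$rel_loglik[sm$K == 1], 0)
  expect_gt(sm$rel_loglik[sm$K == 2], 0)  # strong subtype effects
  ## pure noise: no out-of-sample reward for K > 1
  set.seed(11)
  tm0 <- trait_matrix(quant = matrix(rnorm(500 * 4), 500, 4))
  cs0 <- covariate_set(n = 500)
  cv0 <- cv_select_K(tm0, cs0, k_grid = 1:2, n_folds = 3, seed = 2,
                     n_restarts = 1)
  sm0 <- attr(cv0, "summary")
  expect_lt(sm0$rel_loglik[sm0$K == 2], 5)
})

test_that("rank-deficient designs and bad dimensions error clearly", {
  ds <- small_k2(n = 100, seed = 12, n_quant = 2, n_binary = 0)
  X <- cbind(ds$covariates$homogeneous[, 1:2], dup = ds$covariates$homogeneous[, 1])
  expect_error(fit_mfmr(ds$traits, covariate_set(homogeneous = X, n = 100)),
               "rank")
})
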