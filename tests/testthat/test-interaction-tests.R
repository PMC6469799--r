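test_that("degrees of freedom follow the homogeneity/heterogeneity/global contract", {
  set.seed(1)
  n <- 300
  g <- rnorm(n)
  y <- rnorm(n)
  for (K in 2:4) {
    Z <- matrix(rgamma(n * K, 1), n, K); Z <- Z / rowSums(Z)
    expect_equal(interaction_test(y, g, Z, mode = "homogeneity")$df, 1L)
    expect_equal(interaction_test(y, g, Z, mode = "heterogeneity")$df, K - 1L)
    expect_equal(interaction_test(y, g, Z, mode = "global")$df, K)
  }
})

test_that("hard memberships reproduce the brute-force grouped regression", {
  set.seed(2)
  n <- 400
  z <- rbinom(n, 1, 0.5)
  g <- rbinom(n, 2, 0.3)
  x <- rnorm(n)
  y <- 0.4 * x + 0.5 * z + 0.3 * g + 0.4 * g * z + rnorm(n)
  Z <- cbind(1 - z, z)
  it <- interaction_test(y, g, Z, background = cbind(x = x), mode = "heterogeneity")
  m <- lm(y ~ x + z + g + g:z)
  cn <- grep(":", names(coef(m)), value = TRUE)
  wald <- (coef(m)[cn] / sqrt(vcov(m)[cn, cn]))^2
  expect_equal(it$statistic, unname(wald), tolerance = 1e-10)
  ## homogeneity mode equals the classical main-effect test
  ith <- interaction_test(y, g, Z, background = cbind(x = x), mode = "homogeneity")
  mh <- lm(y ~ x + z + g)
  expect_equal(ith$statistic,
               unname((coef(mh)["g"] / sqrt(vcov(mh)["g", "g"]))^2),
               tolerance = 1e-10)
  ## batch path agrees with the scalar path
  Y <- cbind(q1 = y, q2 = rnorm(n))
  rb <- interaction_test_multi(Y, g, Z, background = cbind(x = x),
                               mode = "heterogeneity")
  expect_equal(rb$stat[1], it$statistic, tolerance = 1e-10)
})

test_that("per-subtype effects decompose as delta + beta_k", {
  set.seed(3)
  n <- 2000
  z <- rbinom(n, 1, 0.5)
  g <- rnorm(n)
  y <- 0.2 * g + 0.5 * g * z + rnorm(n)
  it <- interaction_test(y, g, cbind(1 - z, z), mode = "heterogeneity")
  eff <- subtype_specific_effects(it)
  expect_equal(nrow(eff), 2)
  ## subtype 2 is the z=1 group: slope delta + beta = 0.7; subtype 1: 0.2
  expect_lt(abs(eff$estimate[eff$subtype == 2] - 0.7), 0.1)
  expect_lt(abs(eff$estimate[eff$subtype == 1] - 0.2), 0.1)
  expect_true(all(is.finite(eff$se)))
  expect_error(subtype_specific_effects(it, scale = "odds_ratio"), "logistic")
  ## logistic odds ratio near 1 under no effect
  yb <- rbinom(n, 1, 0.4)
  itb <- interaction_test(yb, g, cbind(1 - z, z), family = "binary",
                          mode = "heterogeneity")
  orr <- subtype_specific_effects(itb, scale = "odds_ratio")
  expect_lt(max(abs(orr$estimate - 1)), 0.25)
})

test_that("heterogeneity p-values are calibrated with oracle memberships", {
  set.seed(4)
  ps <- replicate(300, {
    n <- 250
    z <- rbinom(n, 1, 0.5)
    g <- rbinom(n, 2, 0.3)
    y <- 0.5 * z + 0.3 * g + rnorm(n)  # homogeneous g effect only
    interaction_test(y, g, cbind(1 - z, z), mode = "heterogeneity")$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("invalid membership inputs are rejected", {
  y <- rnorm(50); g <- rnorm(50)
  Zc <- matrix(0.5, 50, 2)
  expect_error(interaction_test(y, g, Zc, mode = "heterogeneity"),
               "no subtype variation")
  expect_error(interaction_test(y, g, matrix(1, 50, 1), mode = "heterogeneity"),
               "no subtype variation")
  Zbad <- matrix(runif(100), 50, 2)
  expect_error(interaction_test(y, g, Zbad, mode = "heterogeneity"),
               "sum to 1")
})

test_that("droptest wires the step-1 fit into step-2 testing", {
  set.seed(5)
  n <- 1200
  z <- rbinom(n, 1, 0.5) + 1L
  focal <- rnorm(n)
  X <- cbind(focal = focal, pc1 = rnorm(n))
  ## focal covariate with opposite effects in the two subtypes
  q1 <- 1.5 * (z == 2) + ifelse(z == 1, 0.6, -0.6) * focal + rnorm(n)
  q2 <- -1.5 * (z == 2) + rnorm(n)
  tm <- trait_matrix(quant = cbind(q1 = q1, q2 = q2))
  cs <- covariate_set(homogeneous = X, n = n)
  fit <- fit_mfmr(tm, cs, opts = fast_opts(2, seed = 1))
  het <- droptest_large_covariate(tm, cs, "focal", fit, "q1")
  hom <- droptest_large_covariate(tm, cs, "focal", fit, "q1", mode = "homogeneity")
  expect_lt(het$p_value, 1e-6)
  expect_lt(het$p_value, hom$p_value)
  expect_error(droptest_large_covariate(tm, cs, "focal", fit, "q1",
                                        extra_conditioning = cbind(focal)),
               "duplicated")
  expect_error(droptest_large_covariate(tm, cs, "nope", fit, "q1"),
               "refit|unknown")
})

test_that("genome scans reduce to plain regression and handle monomorphic SNPs", {
  set.seed(6)
  n <- 500
  G <- cbind(snpA = rbinom(n, 2, 0.3), snpB = rep(0, n), snpC = rbinom(n, 2, 0.4))
  z <- rbinom(n, 1, 0.5)
  y <- 0.3 * G[, 1] + rnorm(n)
  Z <- cbind(1 - z, z)
  sc <- genome_scan(G, y, Z, mode = "gwas")
  expect_equal(sc$reason[2], "monomorphic")
  expect_true(is.na(sc$p[2]))
  m <- lm(y ~ z + G[, 1])
  expect_equal(sc$stat[1],
               unname((coef(m)[3] / sqrt(vcov(m)[3, 3]))^2), tolerance = 1e-10)
  expect_true(is.finite(attr(sc, "lambda_gc")))
  sc_het <- genome_scan(G[, c(1, 3)], y, Z, mode = "het")
  expect_true(all(sc_het$df == 1))
  sc_glob <- genome_scan(G[, c(1, 3)], y, Z, mode = "gxe_global")
  expect_true(all(sc_glob$df == 2))
})

test_that("lambda_gc matches its definition and scaling oracle", {
  set.seed(7)
  p <- runif(50000)
  expect_equal(lambda_gc(p), 1, tolerance = 0.03)
  expect_equal(lambda_gc(rep(0.5, 7)), 1, tolerance = 1e-12)
  chi <- rchisq(50000, 1)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(lambda_gc(p2), 2, tolerance = 0.06)
  expect_error(lambda_gc(numeric(0)), "empty")
  expect_error(lambda_gc(c(0.5, 0)), "0,1")
})

test_that("under population structure, MFMR+PCs stays calibrated while covariate-unaware GMM inflates", {
  ## regime where population structure is stronger than subtype structure;
  ## tested SNPs are drawn from the structured pool so they correlate with
  ## population. Directional property at reduced scale (8 reps, 2,000
  ## structure SNPs instead of 10,000).
  pm <- pg <- c()
  for (r in 1:8) {
    ds <- make_scenario("population_structure",
                        overrides = list(
                          n_samples = 1200, h2_z = 0.05,
                          structure = list(n_populations = 2L, fst = 0.1,
                                           n_structure_snps = 2000L,
                                           mixture = c(0.5, 0.5),
                                           pop_effect_var = 0.35)),
                        seed = 500 + r)
    grm <- suppressWarnings(compute_grm(ds$structure_snps))
    pcs <- eigen(grm$K, symmetric = TRUE)$vectors[, 1:3]
    colnames(pcs) <- paste0("pc", 1:3)
    cs <- covariate_set(homogeneous = cbind(ds$covariates$homogeneous, pcs),
                        n = 1200)
    fit <- fit_mfmr(ds$traits, cs,
                    opts = mfmr_opts(K = 2, n_restarts = 0L, rel_tol = 1e-6,
                                     seed = 1))
    g0 <- tryCatch(fit_gmm(ds$traits$quant, K = 2, seed = 1, n_restarts = 2L),
                   error = function(e) NULL)
    for (s in which(ds$snp_roles != "het")) {
      bg <- cbind(ds$covariates$homogeneous[, -s, drop = FALSE], pcs)
      rr <- interaction_test_multi(ds$traits$quant, ds$genotypes[, s], fit$Z,
                                   background = bg,
                                   background_interactions = TRUE,
                                   mode = "heterogeneity")
      pm <- c(pm, rr$p)
      if (!is.null(g0)) {
        rg <- interaction_test_multi(ds$traits$quant, ds$genotypes[, s],
                                     g0$z, mode = "heterogeneity")
        pg <- c(pg, rg$p)
      }
    }
  }
  expect_gt(mean(pg < 0.05), mean(pm < 0.05))
  expect_lt(mean(pm < 0.01), 0.02)
})

test_that("tuning subtypes to the tested SNP (step-1 inclusion in G) inflates FPR", {
  ## directional overfitting property: the same SNP tested after being given
  ## subtype-specific effects during clustering yields smaller null p-values
  set.seed(8)
  p_plus <- c(); p_std <- c()
  for (rep in 1:12) {
    ds <- small_k2(n = 500, seed = 300 + rep, n_quant = 6, n_binary = 0)
    snp <- ds$genotypes[, 1]  # null-role SNP
    Xother <- ds$covariates$homogeneous[, -1, drop = FALSE]
    cs_std <- covariate_set(homogeneous = ds$covariates$homogeneous, n = 500)
    cs_plus <- covariate_set(homogeneous = Xother,
                             heterogeneous = cbind(1, snp = snp))
    f_std <- fit_mfmr(ds$traits, cs_std, opts = fast_opts(2, seed = 1))
    f_plus <- fit_mfmr(ds$traits, cs_plus, opts = fast_opts(2, seed = 1))
    r_std <- interaction_test_multi(ds$traits$quant, snp, f_std$Z,
                                    background = Xother, mode = "heterogeneity")
    r_plus <- interaction_test_multi(ds$traits$quant, snp, f_plus$Z,
                                     background = Xother, mode = "heterogeneity")
    p_std <- c(p_std, r_std$p); p_plus <- c(p_plus, r_plus$p)
  }
  expect_gt(mean(p_plus < 0.05), mean(p_std < 0.05))
})
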