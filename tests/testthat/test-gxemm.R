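## shared small genotype world for kernel tests
make_geno <- function(n, m, seed) {
  set.seed(seed)
  matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(seq_len(m), each = n)]), n, m)
}

test_that("GRM construction: symmetry, PSD, unit mean diagonal", {
  g <- make_geno(150, 400, 1)
  grm <- compute_grm(g)
  expect_equal(grm$K, t(grm$K), tolerance = 1e-12)
  expect_gt(min(eigen(grm$K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(mean(diag(grm$K)), 1, tolerance = 0.05)
  ## identical rows are as related as a sample is to itself
  g2 <- rbind(g, g[1, ])
  K2 <- compute_grm(g2)$K
  expect_equal(K2[1, 151], K2[1, 1], tolerance = 1e-10)
  ## monomorphic SNPs dropped with warning
  expect_warning(compute_grm(cbind(g, 0)), "monomorphic")
  expect_error(compute_grm(matrix(1, 10, 2)), "polymorphic")
})

test_that("heterogeneous kernel identities", {
  g <- make_geno(80, 200, 2)
  grm <- compute_grm(g)
  expect_equal(het_kernel(grm, matrix(1, 80, 1)), grm$K, tolerance = 1e-12)
  expect_equal(het_kernel(grm, matrix(1 / 3, 80, 3)), grm$K / 3, tolerance = 1e-12)
  z <- rep(1:2, each = 40)
  hk <- het_kernel(grm, onehot(z))
  expect_true(all(hk[1:40, 41:80] == 0))
  expect_equal(hk[1:40, 1:40], grm$K[1:40, 1:40], tolerance = 1e-12)
  expect_error(het_kernel(grm, matrix(1, 10, 1)), "dimension")
  expect_error(het_kernel(grm, matrix(0.4, 80, 2)), "sum to 1")
})

test_that("leading GRM eigenvector separates simulated populations", {
  set.seed(3)
  gd <- draw_genotypes(300, 1500, structure = list(fst = 0.1, n_populations = 2,
                                                   mixture = c(0.5, 0.5)))
  grm <- compute_grm(gd$genotypes)
  ev <- eigen(grm$K, symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(cor(ev, as.numeric(gd$population == 1))), 0.9)
})

test_that("GREML-constrained fit matches a direct likelihood grid", {
  set.seed(4)
  n <- 250; m <- 500
  g <- make_geno(n, m, 5)
  grm <- compute_grm(g)
  gs <- scale(g)
  y <- as.vector(gs %*% rnorm(m, 0, sqrt(0.5 / m))) + rnorm(n, 0, sqrt(0.5))
  W <- cbind(rep(1, n))
  hk <- het_kernel(grm, matrix(1, n, 1))  # irrelevant here
  fit <- fit_iid_gxemm(y, W, grm, hk)
  ## independent oracle: dense grid over (sigma_g, sigma_e) REML likelihood
  reml_ll <- function(sg, se2) {
    V <- sg * grm$K + diag(se2, n)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    ViW <- Vi %*% W
    WtViW <- crossprod(W, ViW)
    P <- Vi - ViW %*% solve(WtViW) %*% t(ViW)
    -0.5 * (2 * sum(log(diag(ch))) + determinant(WtViW)$modulus + sum(y * (P %*% y)))
  }
  grid <- expand.grid(sg = seq(0.02, 1.2, length.out = 25),
                      se2 = seq(0.02, 1.2, length.out = 25))
  lls <- mapply(reml_ll, grid$sg, grid$se2)
  best <- grid[which.max(lls), ]
  expect_gte(fit$loglik_greml, max(lls) - 1e-4)
  expect_lt(abs(fit$sigma2_greml[1] - best$sg), 0.06)
  expect_lt(abs(fit$sigma2_greml[2] - best$se2), 0.06)
})

test_that("variance components recover and the opposite-effect scenario splits", {
  set.seed(6)
  n <- 800; m <- 1500
  g <- make_geno(n, m, 7)
  gs <- scale(g)
  z <- sample(1:2, n, TRUE)
  Z <- onehot(z)
  ## IID generative model: shared + independent per-subtype effects
  a <- rnorm(m) * sqrt(0.3 / m)
  cmat <- matrix(rnorm(m * 2), m, 2) * sqrt(0.2 / m)
  u <- as.vector(gs %*% a) + rowSums(gs * t(cmat[, z]))
  y <- u + rnorm(n, 0, sqrt(0.5))
  grm <- compute_grm(g)
  hk <- het_kernel(grm, Z)
  fit <- fit_iid_gxemm(y, gxemm_fixed_design(Z), grm, hk)
  expect_lt(abs(fit$h2_hom - 0.3), 2.5 * fit$se_h2["hom"] + 0.05)
  expect_lt(abs(fit$h2_het - 0.2), 2.5 * fit$se_h2["het"] + 0.05)
  expect_equal(fit$h2_iid, fit$h2_hom + fit$h2_het, tolerance = 1e-12)
  ## exactly opposite effects: no homogeneous signal, clear heterogeneous
  b <- rnorm(m) * sqrt(0.4 / m)
  y_opp <- rowSums(gs * t(cbind(b, -b)[, z])) + rnorm(n, 0, sqrt(0.6))
  fit_opp <- fit_iid_gxemm(y_opp, gxemm_fixed_design(Z), grm, het_kernel(grm, Z))
  expect_lt(fit_opp$h2_hom, 0.1)
  expect_gt(fit_opp$h2_het, 0.2)
  ## pure noise: everything near zero
  y0 <- rnorm(n)
  fit0 <- fit_iid_gxemm(y0, gxemm_fixed_design(Z), grm, hk)
  expect_lt(fit0$h2_iid, 2 * fit0$se_h2["iid"] + 0.1)
})

test_that("component tests: Wald, boundary-aware LRT, degenerate equality", {
  set.seed(8)
  n <- 800; m <- 1000
  g <- make_geno(n, m, 9)
  gs <- scale(g)
  z <- sample(1:2, n, TRUE); Z <- onehot(z)
  grm <- compute_grm(g); hk <- het_kernel(grm, Z)
  ## strong heterogeneity: LRT rejects (power grows with n; modest here)
  cmat <- matrix(rnorm(m * 2), m, 2) * sqrt(0.3 / m)
  y_het <- rowSums(gs * t(cmat[, z])) + rnorm(n, 0, sqrt(0.5))
  fit_het <- fit_iid_gxemm(y_het, gxemm_fixed_design(Z), grm, hk)
  tc <- test_components(fit_het)
  expect_lt(tc$lrt_p_h2het, 0.05)
  ## identical log-likelihoods give stat 0, p 1
  fake <- fit_het
  fake$loglik_full <- fake$loglik_greml
  tc0 <- test_components(fake)
  expect_equal(tc0$lrt_stat, 0)
  expect_equal(tc0$lrt_p_h2het, 1)
  expect_error(test_components(list(loglik_full = 1)), "constrained")
})

test_that("LRT for heterogeneity is conservative-to-uniform under the null", {
  set.seed(10)
  n <- 400; m <- 600
  reject <- replicate(10, {
    g <- matrix(rbinom(n * m, 2, 0.3), n, m)
    gs <- scale(g)
    z <- sample(1:2, n, TRUE); Z <- onehot(z)
    y <- as.vector(gs %*% rnorm(m, 0, sqrt(0.3 / m))) + rnorm(n, 0, sqrt(0.7))
    fit <- fit_iid_gxemm(y, gxemm_fixed_design(Z), compute_grm(g),
                         het_kernel(compute_grm(g), Z))
    test_components(fit)$lrt_p_h2het < 0.1
  })
  expect_lte(mean(reject), 0.3)
})

test_that("GRM serialization round-trips in TSV and GCTA binary formats", {
  g <- make_geno(40, 100, 11)
  grm <- compute_grm(g)
  tsv <- tempfile(fileext = ".tsv")
  write_grm_tsv(grm, tsv)
  back <- read_grm_tsv(tsv)
  expect_equal(back$K, grm$K, tolerance = 1e-6)
  pre <- tempfile()
  write_grm_gcta(grm, pre)
  back2 <- read_grm_gcta(pre)
  expect_equal(back2$K, grm$K, tolerance = 1e-6)
  expect_equal(back2$n_snps, grm$n_snps)
})
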