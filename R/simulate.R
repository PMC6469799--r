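#' Simulation configuration
#'
#' Describes one synthetic cohort: sample size, number of latent subtypes,
#' trait panel (27 quantitative + 3 binary by default), a small SNP panel
#' split among null / homogeneous-effect / heterogeneous-effect roles, and the
#' variance budget per component. Defaults reproduce the baseline simulated
#' world used throughout the package's calibration and power studies:
#' homogeneous SNPs jointly explain 4% of each trait's variance, heterogeneous
#' SNPs 0.4%, subtype main effects 20%, and the remainder is cross-trait
#' correlated Gaussian noise.
#'
#' @param n_samples number of individuals.
#' @param k_true number of latent subtypes (1 = no subtype structure).
#' @param n_quant,n_binary trait panel dimensions.
#' @param n_snps number of focal SNPs.
#' @param snp_roles character vector of length `n_snps` over
#'   `c("null","hom","het")`; default splits 4/4/4 (all "hom" when
#'   `k_true == 1`).
#' @param h2_hom,h2_het,h2_z variance fractions explained by homogeneous SNP
#'   effects, heterogeneous (subtype-specific) SNP effects, and subtype main
#'   effects. Must sum to < 1.
#' @param rho_ge SNP-subtype correlation in `[0,1]`; 0 gives non-heritable
#'   subtype labels, 1 makes labels a deterministic function of a genotype
#'   score.
#' @param noise_family `"gaussian"` or `"t5"` (Student t with 5 df, excess
#'   kurtosis 6).
#' @param noise_correlated draw a random cross-trait correlation matrix and
#'   mix noise columns through its square root.
#' @param snp_transform `"identity"`, `"square"` or `"exponentiate"`; the
#'   transform is applied to standardized genotypes before effect
#'   multiplication, so downstream analyses that use the raw additive coding
#'   are misspecified on purpose.
#' @param continuous_z replace discrete subtypes with a standard-normal score
#'   that scales the subtype main and heterogeneous effects.
#' @param ascertainment optional `list(trait_index=, population_prevalence=,
#'   sample_case_fraction=)` for case/control sampling.
#' @param structure optional `list(n_populations=2, fst=0.1,
#'   n_structure_snps=10000, mixture=c(.5,.5), pop_effect_var=0.05)` for
#'   Balding-Nichols population structure.
#' @param binary_prevalences per-binary-trait population prevalence.
#' @param maf_range ancestral minor-allele-frequency range for SNP draws.
#' @param mixing subtype mixing proportions (default uniform).
#' @param seed RNG seed for the dataset draw.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 3000, k_true = 2, n_quant = 27,
                       n_binary = 3, n_snps = 12, snp_roles = NULL,
                       h2_hom = 0.04, h2_het = 0.004, h2_z = 0.2,
                       rho_ge = 0, noise_family = c("gaussian", "t5"),
                       noise_correlated = TRUE,
                       snp_transform = c("identity", "square", "exponentiate"),
                       continuous_z = FALSE, ascertainment = NULL,
                       structure = NULL,
                       binary_prevalences = c(0.5, 0.3, 0.2),
                       maf_range = c(0.05, 0.5),
                       mixing = NULL, seed = 1L) {
  noise_family <- match.arg(noise_family)
  snp_transform <- match.arg(snp_transform)
  stopifnot(n_samples >= 2, k_true >= 1, n_quant >= 0, n_binary >= 0,
            n_snps >= 0)
  if (k_true == 1) { h2_z <- 0 }
  if (is.null(snp_roles)) {
    snp_roles <- if (k_true == 1 && !continuous_z) {
      rep("hom", n_snps)
    } else {
      rep(c("null", "hom", "het"), length.out = 3 * ceiling(n_snps / 3))[seq_len(n_snps)]
    }
  }
  stopifnot(length(snp_roles) == n_snps, all(snp_roles %in% c("null", "hom", "het")))
  if (!any(snp_roles == "het")) h2_het <- 0
  if (!any(snp_roles == "hom")) h2_hom <- 0
  if (h2_hom + h2_het + h2_z >= 1)
    stop("variance budget h2_hom + h2_het + h2_z must be < 1")
  if (rho_ge < 0 || rho_ge > 1) stop("rho_ge must lie in [0,1]")
  if (length(binary_prevalences) < n_binary)
    binary_prevalences <- rep_len(binary_prevalences, n_binary)
  if (any(binary_prevalences <= 0 | binary_prevalences >= 1))
    stop("binary prevalences must lie in (0,1)")
  if (is.null(mixing)) mixing <- rep(1 / k_true, k_true)
  stopifnot(length(mixing) == k_true, all(mixing > 0),
            abs(sum(mixing) - 1) < 1e-8)
  if (!is.null(structure)) {
    structure <- utils::modifyList(
      list(n_populations = 2L, fst = 0.1, n_structure_snps = 10000L,
           mixture = c(0.5, 0.5), pop_effect_var = 0.05), structure)
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be a sub-interval of (0, 0.5]")
  structure(list(n_samples = n_samples, k_true = k_true, n_quant = n_quant,
                 n_binary = n_binary, n_snps = n_snps, snp_roles = snp_roles,
                 h2_hom = h2_hom, h2_het = h2_het, h2_z = h2_z,
                 rho_ge = rho_ge, noise_family = noise_family,
                 noise_correlated = noise_correlated,
                 snp_transform = snp_transform, continuous_z = continuous_z,
                 ascertainment = ascertainment, structure = structure,
                 binary_prevalences = binary_prevalences[seq_len(n_binary)],
                 maf_range = maf_range, mixing = mixing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw genotype matrices, optionally with two-population structure
#'
#' Unstructured mode draws each SNP as Binomial(2, maf) with maf uniform on
#' `maf_range`. Structured mode uses the Balding-Nichols construction: an
#' ancestral frequency p drawn uniform on (0.05, 0.95), then per-population
#' frequencies Beta(p(1-F)/F, (1-p)(1-F)/F) with F the fixation index, then
#' binomial genotypes within population.
#'
#' @param n,m sample and SNP counts.
#' @param maf_range frequency interval for unstructured draws.
#' @param structure optional list with `fst`, `n_populations`, `mixture`.
#' @return list with `genotypes` (n x m integer matrix in 0/1/2), `maf`
#'   (ancestral frequencies) and `population` (labels, structured mode only).
#' @export
draw_genotypes <- function(n, m, maf_range = c(0.05, 0.5), structure = NULL) {
  if (n <= 0 || m <= 0) stop("n and m must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be a sub-interval of (0, 0.5]")
  if (is.null(structure)) {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    g <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    return(list(genotypes = g, maf = maf, population = NULL))
  }
  r <- structure$n_populations %||% 2L
  fst <- structure$fst %||% 0.1
  mixture <- structure$mixture %||% rep(1 / r, r)
  pop <- sample(seq_len(r), n, replace = TRUE, prob = mixture)
  p_anc <- stats::runif(m, 0.05, 0.95)
  sh1 <- p_anc * (1 - fst) / fst
  sh2 <- (1 - p_anc) * (1 - fst) / fst
  g <- matrix(0L, n, m)
  for (k in seq_len(r)) {
    idx <- which(pop == k)
    pk <- stats::rbeta(m, sh1, sh2)
    g[idx, ] <- matrix(stats::rbinom(length(idx) * m, 2L, rep(pk, each = length(idx))),
                       length(idx), m)
  }
  list(genotypes = g, maf = p_anc, population = pop)
}

#' Weir-Cockerham fixation index
#'
#' Variance-components estimator from genotypes and population labels, using
#' observed heterozygosity. By default returns the standard multi-locus
#' estimate, the ratio of summed components `sum(a) / sum(a + b + c)` (the
#' per-SNP ratio average is noticeably downward biased at these sample
#' sizes). Set `per_snp = TRUE` for per-SNP theta values (NA when
#' monomorphic).
#'
#' @param genotypes n x m matrix in 0/1/2.
#' @param population integer population labels.
#' @param per_snp return the per-SNP ratio vector instead.
#' @return scalar multi-locus estimate, or numeric vector when `per_snp`.
#' @export
fst_weir_cockerham <- function(genotypes, population, per_snp = FALSE) {
  pops <- sort(unique(population))
  r <- length(pops)
  if (r < 2) stop("need at least two populations")
  n_i <- vapply(pops, function(k) sum(population == k), numeric(1))
  p_i <- sapply(pops, function(k) colMeans(genotypes[population == k, , drop = FALSE]) / 2)
  h_i <- sapply(pops, function(k) colMeans(genotypes[population == k, , drop = FALSE] == 1L))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- as.vector(p_i %*% n_i) / (r * nbar)
  s2 <- as.vector(((p_i - pbar)^2) %*% n_i) / ((r - 1) * nbar)
  hbar <- as.vector(h_i %*% n_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  if (per_snp) {
    theta <- a / (a + b + cc)
    theta[!poly] <- NA_real_
    return(theta)
  }
  sum(a[poly]) / sum(a[poly] + b[poly] + cc[poly])
}

#' Draw subtype labels with optional genotype correlation
#'
#' With `rho_ge = 0` labels are i.i.d. Categorical(mixing). With
#' `rho_ge = 1` labels are a deterministic function of a per-sample genotype
#' score: the score is cut at the mixing-proportion quantiles. Intermediate
#' values copy the score-determined label with probability `rho_ge` and draw
#' i.i.d. otherwise, so label-score dependence increases monotonically.
#'
#' @param n sample count.
#' @param k subtype count.
#' @param mixing mixing proportions on the simplex.
#' @param rho_ge copying probability in `[0,1]`.
#' @param snp_score per-sample genetic score, required when `rho_ge > 0`.
#' @return integer labels in `1..k`.
#' @export
draw_subtypes <- function(n, k, mixing = rep(1 / k, k), rho_ge = 0,
                          snp_score = NULL) {
  if (abs(sum(mixing) - 1) > 1e-8 || any(mixing <= 0))
    stop("mixing must be strictly positive and sum to 1")
  if (rho_ge < 0 || rho_ge > 1) stop("rho_ge must lie in [0,1]")
  if (k == 1) return(rep(1L, n))
  iid <- sample(seq_len(k), n, replace = TRUE, prob = mixing)
  if (rho_ge == 0) return(iid)
  if (is.null(snp_score)) stop("snp_score required when rho_ge > 0")
  qs <- stats::quantile(snp_score, probs = cumsum(mixing)[-k], names = FALSE)
  det_lab <- findInterval(snp_score, qs, left.open = TRUE) + 1L
  copy <- stats::runif(n) < rho_ge
  ifelse(copy, det_lab, iid)
}

## Random cross-trait correlation matrix: scaled Wishart draw, df chosen so
## off-diagonal correlations are substantial but the matrix stays well
## conditioned.
random_correlation <- function(p) {
  w <- stats::rWishart(1L, df = p + 2L, Sigma = diag(p))[, , 1L]
  stats::cov2cor(w)
}

## Scale a vector/column set to exact empirical variance target (variance
## bookkeeping is exact in-sample by construction).
scale_to_var <- function(x, target) {
  v <- stats::var(as.vector(x))
  if (v < .Machine$double.eps || target <= 0) return(x * 0)
  x * sqrt(target / v)
}

#' Synthesize trait matrices from genotypes and subtype labels
#'
#' Builds each trait as the sum of a homogeneous SNP component, a
#' heterogeneous (subtype-specific) SNP component, a subtype main effect and
#' residual noise, with each component rescaled so its realized in-sample
#' variance fraction equals its configured target exactly. Binary traits are
#' produced by thresholding a unit-variance latent trait at the empirical
#' quantile matching the configured prevalence, matching the probit link used
#' by the mixture model.
#'
#' @param config a [sim_config()].
#' @param genotypes n x m matrix in 0/1/2.
#' @param z_true integer subtype labels (or real scores when
#'   `config$continuous_z`).
#' @param population optional population labels; when present a population
#'   main effect with variance `structure$pop_effect_var` is added.
#' @return list with `traits` ([trait_matrix()]), `covariates`
#'   ([covariate_set()] holding the SNPs as homogeneous covariates),
#'   `effect_sizes` (per-component coefficient arrays) and `realized_h2`.
#' @export
synthesize_traits <- function(config, genotypes, z_true, population = NULL) {
  n <- nrow(genotypes)
  if (length(z_true) != n) stop("z_true not conformable with genotypes")
  p_tot <- config$n_quant + config$n_binary
  k <- config$k_true
  roles <- config$snp_roles
  gs <- standardize_cols(genotypes)
  gt <- switch(config$snp_transform,
               identity = gs,
               square = standardize_cols(gs^2),
               exponentiate = standardize_cols(exp(gs)))
  hom_idx <- which(roles == "hom")
  het_idx <- which(roles == "het")

  budget_extra <- if (!is.null(population) && !is.null(config$structure))
    config$structure$pop_effect_var else 0
  h2_noise <- 1 - config$h2_hom - config$h2_het - config$h2_z - budget_extra
  if (h2_noise <= 0) stop("variance budget >= 1 after population effects")

  alpha_hom <- matrix(0, length(hom_idx), p_tot)
  beta_het <- array(0, dim = c(length(het_idx), max(k, 1L), p_tot))
  gamma <- matrix(0, max(k, 1L), p_tot)

  latent <- matrix(0, n, p_tot)
  comp_var <- matrix(0, p_tot, 4,
                     dimnames = list(NULL, c("hom", "het", "z", "noise")))

  ## noise block first: iid draws, optionally correlated across traits
  eps <- if (config$noise_family == "t5") {
    matrix(stats::rt(n * p_tot, df = 5), n, p_tot)
  } else {
    matrix(stats::rnorm(n * p_tot), n, p_tot)
  }
  if (config$noise_correlated && p_tot > 1) {
    sig <- random_correlation(p_tot)
    eps <- eps %*% chol(sig)
  }

  for (p in seq_len(p_tot)) {
    comp <- matrix(0, n, 4)
    if (length(hom_idx) && config$h2_hom > 0) {
      a <- stats::rnorm(length(hom_idx))
      u <- gt[, hom_idx, drop = FALSE] %*% a
      sc <- sqrt(config$h2_hom / max(stats::var(as.vector(u)), .Machine$double.eps))
      a <- a * sc
      alpha_hom[, p] <- a
      comp[, 1] <- gt[, hom_idx, drop = FALSE] %*% a
    }
    if (length(het_idx) && config$h2_het > 0) {
      if (config$continuous_z) {
        b <- stats::rnorm(length(het_idx))
        u <- (gt[, het_idx, drop = FALSE] %*% b) * z_true
        sc <- sqrt(config$h2_het / max(stats::var(as.vector(u)), .Machine$double.eps))
        b <- b * sc
        beta_het[, 1, p] <- b
        comp[, 2] <- (gt[, het_idx, drop = FALSE] %*% b) * z_true
      } else {
        b <- matrix(stats::rnorm(length(het_idx) * k), length(het_idx), k)
        b <- b - rowMeans(b)  # purely heterogeneous: zero net effect
        u <- rowSums(gt[, het_idx, drop = FALSE] * t(b[, z_true, drop = FALSE]))
        sc <- sqrt(config$h2_het / max(stats::var(u), .Machine$double.eps))
        b <- b * sc
        beta_het[, , p] <- b
        comp[, 2] <- rowSums(gt[, het_idx, drop = FALSE] * t(b[, z_true, drop = FALSE]))
      }
    }
    if (config$h2_z > 0) {
      if (config$continuous_z) {
        u <- z_true
        sc <- sqrt(config$h2_z / max(stats::var(u), .Machine$double.eps))
        gamma[1, p] <- sc
        comp[, 3] <- z_true * sc
      } else if (k > 1) {
        gm <- stats::rnorm(k)
        u <- gm[z_true]
        sc <- sqrt(config$h2_z / max(stats::var(u), .Machine$double.eps))
        gm <- (gm - mean(gm[z_true])) * sc
        gamma[, p] <- gm
        comp[, 3] <- gm[z_true]
      }
    }
    comp[, 4] <- scale_to_var(eps[, p] - mean(eps[, p]), h2_noise)
    latent[, p] <- rowSums(comp)
    comp_var[p, ] <- apply(comp, 2, stats::var)
  }

  if (budget_extra > 0) {
    pe <- scale_to_var(as.numeric(population == population[1]) -
                         mean(population == population[1]), budget_extra)
    latent <- latent + pe  # same population shift applied to every trait
  }

  qn <- config$n_quant
  quant <- latent[, seq_len(qn), drop = FALSE]
  colnames(quant) <- paste0("q", seq_len(qn))
  if (config$n_binary > 0) {
    bl <- latent[, qn + seq_len(config$n_binary), drop = FALSE]
    thr <- vapply(seq_len(config$n_binary), function(j)
      stats::quantile(bl[, j], 1 - config$binary_prevalences[j], names = FALSE),
      numeric(1))
    binary <- sweep(bl, 2, thr, ">") * 1
    colnames(binary) <- paste0("b", seq_len(config$n_binary))
  } else binary <- matrix(0, n, 0)

  snps <- genotypes
  colnames(snps) <- paste0("snp", seq_len(ncol(snps)))
  list(traits = trait_matrix(quant = quant, binary = binary),
       covariates = covariate_set(homogeneous = snps, n = n),
       effect_sizes = list(alpha_hom = alpha_hom, beta_het = beta_het,
                           gamma = gamma),
       realized_h2 = comp_var)
}

#' Draw a complete synthetic dataset
#'
#' Orchestrates [draw_genotypes()], [draw_subtypes()] and
#' [synthesize_traits()] under one seed, then applies case/control
#' ascertainment when configured.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_dataset`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  if (!is.null(config$ascertainment)) {
    asc <- config$ascertainment
    n <- ceiling(config$n_samples *
                   max(asc$sample_case_fraction / asc$population_prevalence,
                       (1 - asc$sample_case_fraction) / (1 - asc$population_prevalence)) * 1.2)
  }
  structure_snps <- NULL; population <- NULL
  if (!is.null(config$structure)) {
    gd <- draw_genotypes(n, config$structure$n_structure_snps,
                         config$maf_range, config$structure)
    structure_snps <- gd$genotypes
    population <- gd$population
    keep <- which(apply(structure_snps, 2, stats::var) > 0)
    snp_idx <- sample(keep, config$n_snps)
    genotypes <- structure_snps[, snp_idx, drop = FALSE]
    maf <- gd$maf[snp_idx]
  } else {
    gd <- draw_genotypes(n, config$n_snps, config$maf_range)
    genotypes <- gd$genotypes
    maf <- gd$maf
  }
  ## genotype score driving G-E correlation: standardized burden over the
  ## whole SNP panel, so at rho_ge = 1 subtype status is perfectly heritable
  ## and even null/homogeneous SNPs correlate with subtype
  snp_score <- rowSums(standardize_cols(genotypes))
  z_true <- if (config$continuous_z) {
    stats::rnorm(n)
  } else {
    draw_subtypes(n, config$k_true, config$mixing, config$rho_ge, snp_score)
  }
  syn <- synthesize_traits(config, genotypes, z_true, population)
  ds <- structure(list(genotypes = genotypes, structure_snps = structure_snps,
                       traits = syn$traits, covariates = syn$covariates,
                       z_true = z_true, snp_roles = config$snp_roles,
                       effect_sizes = syn$effect_sizes,
                       realized_h2 = syn$realized_h2, maf = maf,
                       population = population, config = config),
                  class = "sim_dataset")
  if (!is.null(config$ascertainment)) {
    asc <- config$ascertainment
    ds <- ascertain_case_control(ds, asc$trait_index %||% 1L,
                                 asc$sample_case_fraction,
                                 n_target = config$n_samples)
  }
  ds
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d samples, %d SNPs (%s), K_true=%s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(table(x$snp_roles), collapse = "/"),
              if (x$config$continuous_z) "continuous" else x$config$k_true))
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  ds$genotypes <- ds$genotypes[idx, , drop = FALSE]
  if (!is.null(ds$structure_snps))
    ds$structure_snps <- ds$structure_snps[idx, , drop = FALSE]
  ds$traits <- trait_matrix(quant = ds$traits$quant[idx, , drop = FALSE],
                            binary = ds$traits$binary[idx, , drop = FALSE])
  ds$covariates <- covariate_set(
    homogeneous = ds$covariates$homogeneous[idx, , drop = FALSE],
    heterogeneous = ds$covariates$heterogeneous[idx, , drop = FALSE])
  ds$z_true <- ds$z_true[idx]
  if (!is.null(ds$population)) ds$population <- ds$population[idx]
  ds
}

#' Ascertain a case/control sample on one binary trait
#'
#' Subsamples the dataset so the in-sample case fraction of the indexed
#' binary trait matches `case_fraction`. All aligned components (genotypes,
#' traits, covariates, true labels) are subset identically.
#'
#' @param dataset a `sim_dataset`.
#' @param trait_index index into the binary trait block.
#' @param case_fraction target in-sample case fraction.
#' @param n_target optional final sample size (default: as many samples as the
#'   available cases allow).
#' @return The subset `sim_dataset`.
#' @export
ascertain_case_control <- function(dataset, trait_index, case_fraction,
                                   n_target = NULL) {
  y <- dataset$traits$binary[, trait_index]
  cases <- which(y == 1); controls <- which(y == 0)
  pop_frac <- mean(y)
  if (abs(pop_frac - case_fraction) < 1e-12) {
    if (is.null(n_target) || n_target >= length(y)) return(dataset)
    return(subset_dataset(dataset, sort(sample(seq_along(y), n_target))))
  }
  if (is.null(n_target))
    n_target <- min(floor(length(cases) / case_fraction),
                    floor(length(controls) / (1 - case_fraction)))
  n_cases <- round(n_target * case_fraction)
  n_controls <- n_target - n_cases
  if (length(cases) < n_cases)
    stop(sprintf(
      "insufficient cases: need %d, have %d; oversample the population draw by >= %.1fx",
      n_cases, length(cases), n_cases / max(length(cases), 1)))
  if (length(controls) < n_controls)
    stop("insufficient controls for requested case fraction")
  idx <- sort(c(sample(cases, n_cases), sample(controls, n_controls)))
  subset_dataset(dataset, idx)
}

#' Named simulation scenarios
#'
#' Returns a fully drawn dataset under one of the canonical scenario settings
#' used in the package's calibration and power studies (baseline with and
#' without subtypes, heavy-tailed noise, non-linear SNP effects, continuous
#' subtype scores, case/control ascertainment, gene-environment correlation,
#' two-population structure, and trait/covariate mislabeling).
#'
#' @param name scenario id; one of `baseline_k1`, `baseline_k2`, `k_gt_2`,
#'   `t5_noise`, `nonlinear_square`, `nonlinear_exp`, `continuous_z`,
#'   `continuous_z_2x`, `case_control`, `ge_correlation`,
#'   `population_structure`, `swap_trait_covariate`.
#' @param overrides named list of [sim_config()] argument overrides.
#' @param seed RNG seed.
#' @return A `sim_dataset`.
#' @export
make_scenario <- function(name, overrides = list(), seed = 1L) {
  base <- list(seed = seed)
  args <- switch(
    name,
    baseline_k1 = list(k_true = 1),
    baseline_k2 = list(k_true = 2),
    k_gt_2 = list(k_true = 3),
    t5_noise = list(k_true = 1, noise_family = "t5"),
    nonlinear_square = list(k_true = 1, snp_transform = "square"),
    nonlinear_exp = list(k_true = 1, snp_transform = "exponentiate"),
    continuous_z = list(k_true = 2, continuous_z = TRUE),
    ## doubled heterogeneous SNP effect sizes => 4x the variance fraction
    continuous_z_2x = list(k_true = 2, continuous_z = TRUE, h2_het = 0.016),
    case_control = list(k_true = 2,
                        ascertainment = list(trait_index = 3L,
                                             population_prevalence = 0.2,
                                             sample_case_fraction = 0.5)),
    ge_correlation = list(k_true = 2, rho_ge = 0.5),
    population_structure = list(k_true = 2,
                                structure = list(n_populations = 2L, fst = 0.1,
                                                 n_structure_snps = 10000L,
                                                 mixture = c(0.5, 0.5))),
    swap_trait_covariate = list(k_true = 2),
    stop("unknown scenario name: ", name)
  )
  cfg <- do.call(sim_config, utils::modifyList(c(base, args), overrides))
  ds <- simulate_dataset(cfg)
  if (name == "swap_trait_covariate") {
    ## mislabel: first quantitative trait becomes a covariate, first SNP a trait
    q1 <- ds$traits$quant[, 1, drop = FALSE]
    snp1 <- ds$covariates$homogeneous[, 1, drop = FALSE]
    ds$traits <- trait_matrix(
      quant = cbind(ds$traits$quant[, -1, drop = FALSE],
                    swapped_snp = as.numeric(snp1)),
      binary = ds$traits$binary)
    ds$covariates <- covariate_set(
      homogeneous = cbind(ds$covariates$homogeneous[, -1, drop = FALSE],
                          swapped_trait = as.numeric(q1)),
      heterogeneous = ds$covariates$heterogeneous)
  }
  ds
}
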