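## ---- PLINK binary genotypes ------------------------------------------------

#' Read and write PLINK .bed/.bim/.fam genotype triples
#'
#' Minimal SNP-major readers/writers for additive dosages. Written files code
#' A1 as the counted allele so the decoded matrix round-trips exactly;
#' missing genotypes become NA on read.
#'
#' @param genotypes N x M matrix in 0/1/2 (NA allowed when writing).
#' @param prefix file prefix (without extension).
#' @param snp_ids,sample_ids,chr,pos optional metadata vectors.
#' @return `read_plink` returns a list with `genotypes`, `bim`, `fam`.
#' @export
write_plink <- function(genotypes, prefix, snp_ids = NULL, sample_ids = NULL,
                        chr = NULL, pos = NULL) {
  g <- as.matrix(genotypes)
  n <- nrow(g); m <- ncol(g)
  snp_ids <- snp_ids %||% colnames(g) %||% paste0("snp", seq_len(m))
  sample_ids <- sample_ids %||% rownames(g) %||% paste0("s", seq_len(n))
  chr <- chr %||% rep(1L, m)
  pos <- pos %||% seq_len(m)   # 1-based positions
  bim <- data.frame(chr = chr, id = snp_ids, cm = 0, pos = pos,
                    a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  fam <- data.frame(fid = sample_ids, iid = sample_ids, pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  ## 2-bit codes per genotype (A1 count): 0 -> 11, 1 -> 10, 2 -> 00, NA -> 01
  code <- matrix(3L, n, m)
  code[g == 1] <- 2L
  code[g == 2] <- 0L
  code[is.na(g)] <- 1L
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  npad <- ceiling(n / 4) * 4
  for (j in seq_len(m)) {
    cj <- c(code[, j], rep(0L, npad - n))
    byte <- cj[seq(1, npad, 4)] + cj[seq(2, npad, 4)] * 4L +
      cj[seq(3, npad, 4)] * 16L + cj[seq(4, npad, 4)] * 64L
    writeBin(as.raw(byte), con)
  }
  close(con)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat", "sex", "phe"))
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  bpr <- ceiling(n / 4)
  raw <- readBin(con, "raw", bpr * m)
  close(con)
  bits <- matrix(as.integer(raw), nrow = bpr)
  g <- matrix(NA_real_, n, m)
  lut <- c(2, NA, 1, 0)  # 2-bit code 0..3 -> dosage
  for (j in seq_len(m)) {
    b <- bits[, j]
    codes <- c(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
    codes <- matrix(codes, nrow = bpr)[, ] # bpr x 4
    codes <- as.vector(t(matrix(codes, bpr, 4)))[seq_len(n)]
    g[, j] <- lut[codes + 1L]
  }
  colnames(g) <- bim$id
  rownames(g) <- fam$iid
  list(genotypes = g, bim = bim, fam = fam)
}

## ---- dataset TSV round trip ------------------------------------------------

#' Write a simulated dataset to plain-text files
#'
#' Produces `phenotypes.tsv`, `covariates.tsv`, `genotypes.tsv` (each with a
#' leading `sample_id` column) and a `truth.json` sidecar holding the true
#' labels, SNP roles and effect sizes. Optionally also writes a PLINK triple.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created).
#' @param plink also write `genotypes.bed/.bim/.fam`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, plink = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_samples(dataset$traits)
  ids <- paste0("s", seq_len(n))
  ph <- data.frame(sample_id = ids, dataset$traits$quant, dataset$traits$binary,
                   check.names = FALSE)
  data.table::fwrite(ph, file.path(dir, "phenotypes.tsv"), sep = "\t")
  cv <- data.frame(sample_id = ids, dataset$covariates$homogeneous,
                   check.names = FALSE)
  data.table::fwrite(cv, file.path(dir, "covariates.tsv"), sep = "\t")
  gt <- data.frame(sample_id = ids, dataset$genotypes, check.names = FALSE)
  colnames(gt)[-1] <- paste0("snp", seq_len(ncol(dataset$genotypes)))
  data.table::fwrite(gt, file.path(dir, "genotypes.tsv"), sep = "\t")
  if (plink)
    write_plink(dataset$genotypes, file.path(dir, "genotypes"),
                sample_ids = ids)
  truth <- list(z_true = dataset$z_true, snp_roles = dataset$snp_roles,
                effect_sizes = dataset$effect_sizes,
                realized_h2 = dataset$realized_h2,
                config = dataset$config[setdiff(names(dataset$config),
                                                c("ascertainment", "structure"))])
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Run configuration
#'
#' Collects everything one end-to-end run needs: either file paths or a
#' simulation scenario, column role assignments, the number of subtypes (or a
#' grid for cross-validated selection), focal covariates with their step-1
#' handling, test modes and the multiple-testing / genomic-control settings.
#'
#' @param phenotypes,covariates,genotypes input file paths (TSV with header
#'   and `sample_id` first column; genotypes may be a PLINK prefix).
#' @param scenario simulation scenario name (alternative to file inputs).
#' @param scenario_overrides list of [sim_config()] overrides.
#' @param binary_traits column names to treat as binary traits.
#' @param K number of subtypes, or `NULL` with `k_grid` for CV selection.
#' @param k_grid integer grid for [cv_select_K()].
#' @param focal named character vector mapping focal covariate names to modes
#'   in `c("ignore","homogeneous","heterogeneous")` (MFMRX / MFMR / MFMR+).
#' @param scan_modes genome-scan modes to run.
#' @param scan_traits trait names to scan (default: first quantitative trait).
#' @param run_gxemm fit the polygenic variance-component model.
#' @param lambda_ceiling genomic-control QC threshold.
#' @param bonferroni_n divisor for the significance threshold.
#' @param seed master seed fanned out to all stages.
#' @param outdir output directory.
#' @return validated `run_config` list.
#' @export
run_config <- function(phenotypes = NULL, covariates = NULL, genotypes = NULL,
                       scenario = NULL, scenario_overrides = list(),
                       binary_traits = NULL, K = 2L, k_grid = NULL,
                       focal = character(0),
                       scan_modes = c("het"), scan_traits = NULL,
                       run_gxemm = FALSE, lambda_ceiling = 1.5,
                       bonferroni_n = 1L, seed = 1L, outdir = NULL) {
  if (is.null(scenario) && (is.null(phenotypes) || is.null(genotypes)))
    stop("provide either a scenario or phenotype+genotype paths")
  if (length(focal) && !all(focal %in% c("ignore", "homogeneous", "heterogeneous")))
    stop("focal modes must be ignore/homogeneous/heterogeneous")
  structure(list(phenotypes = phenotypes, covariates = covariates,
                 genotypes = genotypes, scenario = scenario,
                 scenario_overrides = scenario_overrides,
                 binary_traits = binary_traits, K = K, k_grid = k_grid,
                 focal = focal, scan_modes = scan_modes,
                 scan_traits = scan_traits, run_gxemm = run_gxemm,
                 lambda_ceiling = lambda_ceiling, bonferroni_n = bonferroni_n,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file holding the configuration fields.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$focal <- unlist(cfg$focal) %||% character(0)
  do.call(run_config, cfg)
}

#' Read a dataset from configured input files
#'
#' Accepts phenotype/covariate TSVs (header row, `sample_id` first column)
#' and genotypes as TSV or a PLINK prefix. Samples are aligned by ID across
#' files (inner join; dropped counts are reported), binary trait columns are
#' validated to be 0/1.
#'
#' @param config a [run_config()].
#' @return list with `traits`, `covariates`, `genotypes`, `ids`.
#' @export
read_dataset <- function(config) {
  ph <- as.data.frame(data.table::fread(config$phenotypes, sep = "\t"))
  if (!"sample_id" %in% colnames(ph)) stop("phenotypes need a sample_id column")
  cov <- if (!is.null(config$covariates)) {
    as.data.frame(data.table::fread(config$covariates, sep = "\t"))
  } else NULL
  gsrc <- config$genotypes
  if (!is.null(gsrc) && file.exists(paste0(gsrc, ".bed"))) {
    pl <- read_plink(gsrc)
    gt <- data.frame(sample_id = rownames(pl$genotypes), pl$genotypes,
                     check.names = FALSE)
  } else if (!is.null(gsrc)) {
    gt <- as.data.frame(data.table::fread(gsrc, sep = "\t"))
  } else gt <- NULL
  ids <- ph$sample_id
  for (other in list(cov, gt)) if (!is.null(other)) ids <- intersect(ids, other$sample_id)
  dropped <- length(ph$sample_id) - length(ids)
  if (dropped > 0) message(dropped, " sample(s) dropped during ID alignment")
  if (length(ids) == 0) stop("no overlapping sample IDs across input files")
  align <- function(df) df[match(ids, df$sample_id), setdiff(colnames(df), "sample_id"), drop = FALSE]
  ph_m <- align(ph)
  bin_cols <- config$binary_traits %||%
    colnames(ph_m)[vapply(ph_m, function(v) all(stats::na.omit(v) %in% c(0, 1)), logical(1))]
  for (b in bin_cols) {
    vals <- stats::na.omit(ph_m[[b]])
    if (!all(vals %in% c(0, 1)))
      stop("binary trait column contains values outside {0,1}: ", b)
  }
  quant_cols <- setdiff(colnames(ph_m), bin_cols)
  traits <- trait_matrix(quant = ph_m[, quant_cols, drop = FALSE],
                         binary = ph_m[, bin_cols, drop = FALSE])
  covariates <- covariate_set(
    homogeneous = if (!is.null(cov)) as.matrix(align(cov)) else NULL,
    n = length(ids))
  genotypes <- if (!is.null(gt)) as.matrix(align(gt)) else NULL
  list(traits = traits, covariates = covariates, genotypes = genotypes,
       ids = ids)
}

#' Run the full two-step pipeline
#'
#' simulate/read -> impute (if missing) -> fit the mixture (with optional
#' cross-validated K selection) -> step-2 tests (per-SNP heterogeneity scan
#' and, optionally, the polygenic variance-component fit). All stage seeds
#' derive deterministically from the master seed.
#'
#' @param config a [run_config()].
#' @return results bundle (list) with the fit, Z table, test tables,
#'   genomic-control factors and a manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (!is.null(config$scenario)) {
    ds <- make_scenario(config$scenario, config$scenario_overrides,
                        seed = derive_seed(seed, "simulate"))
    traits <- ds$traits; genotypes <- ds$genotypes
    base_cov <- ds$covariates
  } else {
    rd <- read_dataset(config)
    traits <- rd$traits; genotypes <- rd$genotypes
    base_cov <- rd$covariates
  }
  ## role assignment for focal covariates
  Xh <- base_cov$homogeneous
  Gh <- NULL
  if (length(config$focal)) {
    for (nm in names(config$focal)) {
      if (!nm %in% colnames(Xh)) stop("unknown focal covariate: ", nm)
      mode <- config$focal[[nm]]
      if (mode == "ignore") {
        Xh <- Xh[, setdiff(colnames(Xh), nm), drop = FALSE]
      } else if (mode == "heterogeneous") {
        Gh <- cbind(Gh, Xh[, nm, drop = FALSE])
        Xh <- Xh[, setdiff(colnames(Xh), nm), drop = FALSE]
      }
    }
  }
  covariates <- covariate_set(homogeneous = Xh,
                              heterogeneous = if (is.null(Gh)) NULL else
                                cbind(1, Gh))
  ## impute missing phenotype entries if any
  if (anyNA(traits$quant) || anyNA(traits$binary)) {
    joint <- cbind(traits$quant, traits$binary)
    imp <- mvn_impute(joint)
    pq <- ncol(traits$quant)
    traits <- trait_matrix(quant = imp$completed[, seq_len(pq), drop = FALSE],
                           binary = imp$completed[, -seq_len(pq), drop = FALSE])
  }
  ## step 1
  if (!is.null(config$k_grid)) {
    cv <- cv_select_K(traits, covariates, k_grid = config$k_grid,
                      seed = derive_seed(seed, "cvk"))
    sm <- attr(cv, "summary")
    K <- sm$K[which.max(sm$rel_loglik)]
  } else {
    cv <- NULL
    K <- config$K
  }
  fit <- fit_mfmr(traits, covariates,
                  opts = mfmr_opts(K = K, seed = derive_seed(seed, "mfmr")))
  bundle <- list(fit = fit, K = K, cv = cv, config = config,
                 Z = data.frame(sample_id = seq_len(nrow(fit$Z)), fit$Z))
  if (K == 1L) {
    bundle$step2 <- NULL
    bundle$note <- "no subtype variation: step-2 heterogeneity tests refused at K=1"
    return(bundle)
  }
  ## step 2: genome scans on requested traits
  scan_traits <- config$scan_traits %||% colnames(traits$quant)[1]
  scans <- list(); lambdas <- list()
  for (tr in scan_traits) {
    fam <- if (tr %in% colnames(traits$binary)) "binary" else "quantitative"
    y <- if (fam == "binary") traits$binary[, tr] else traits$quant[, tr]
    for (md in config$scan_modes) {
      sc <- genome_scan(genotypes, y, fit$Z, background = NULL, family = fam,
                        mode = md, lambda_ceiling = config$lambda_ceiling)
      key <- paste(tr, md, sep = ".")
      sc$trait <- tr
      scans[[key]] <- sc
      lambdas[[key]] <- attr(sc, "lambda_gc")
    }
  }
  bundle$scans <- scans
  bundle$lambda_gc <- unlist(lambdas)
  if (isTRUE(config$run_gxemm) && !is.null(genotypes)) {
    grm <- compute_grm(genotypes)
    hk <- het_kernel(grm, fit$Z)
    W <- gxemm_fixed_design(fit$Z, covariates$homogeneous)
    y <- traits$quant[, scan_traits[1]]
    gx <- fit_iid_gxemm(y, W, grm, hk)
    bundle$gxemm <- gx
    bundle$gxemm_tests <- test_components(gx)
  }
  bundle$manifest <- list(seed = seed, K = K,
                          package_version = as.character(utils::packageVersion("mixwas")),
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  bundle
}

#' Write a results bundle to disk
#'
#' Emits TSV tables (scan results, Z, variance components), the serialized
#' model (JSON) and a run manifest with stable column order. Refuses to
#' overwrite an existing output directory unless `force = TRUE`.
#'
#' @param bundle result of [run_pipeline()].
#' @param outdir output directory.
#' @param force overwrite existing results.
#' @return `outdir`, invisibly.
#' @export
write_results <- function(bundle, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force)
    stop("output directory not empty; rerun with force = TRUE")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$scans)) {
    all_sc <- do.call(rbind, lapply(bundle$scans, function(s) {
      s$lambda_gc <- attr(s, "lambda_gc"); s
    }))
    data.table::fwrite(all_sc, file.path(outdir, "scan_results.tsv"), sep = "\t")
  } else {
    data.table::fwrite(data.frame(snp_id = character(), mode = character(),
                                  stat = numeric(), df = integer(), p = numeric()),
                       file.path(outdir, "scan_results.tsv"), sep = "\t")
  }
  data.table::fwrite(bundle$Z, file.path(outdir, "subtype_probabilities.tsv"),
                     sep = "\t")
  if (!is.null(bundle$gxemm)) {
    gx <- bundle$gxemm
    data.table::fwrite(data.frame(component = c("hom", "het", "e"),
                                  sigma2 = unname(gx$sigma2),
                                  h2 = c(gx$h2_hom, gx$h2_het, NA)),
                       file.path(outdir, "variance_components.tsv"), sep = "\t")
  }
  write_mfmr_model(bundle$fit, file.path(outdir, "model.json"))
  jsonlite::write_json(bundle$manifest %||% list(),
                       file.path(outdir, "manifest.json"), auto_unbox = TRUE)
  invisible(outdir)
}

## ---- model serialization ---------------------------------------------------

#' Serialize / restore a fitted mixture model
#'
#' Versioned JSON round-trip of the parameter matrices and training schema,
#' sufficient for [predict_subtypes()] on new data.
#'
#' @param fit an `mfmr_fit`.
#' @param path JSON file path.
#' @return the restored `mfmr_fit` (reader) or `path` (writer), invisibly.
#' @export
write_mfmr_model <- function(fit, path) {
  obj <- list(format = "mixwas_mfmr", version = 1L, K = fit$K, p = fit$p,
              alpha_q = fit$alpha_q, alpha_b = fit$alpha_b,
              beta_q = list(dim = dim(fit$beta_q), data = as.vector(fit$beta_q)),
              beta_b = list(dim = dim(fit$beta_b), data = as.vector(fit$beta_b)),
              sigma2 = fit$sigma2, loglik = fit$loglik, schema = fit$schema)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mfmr_model
#' @export
read_mfmr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mixwas_mfmr")) stop("not a serialized mixwas model")
  restore_mat <- function(m, nr) {
    m <- as.matrix(m); if (length(m) == 0) matrix(0, 0, 0) else m
  }
  fit <- list(K = obj$K, p = obj$p,
              alpha_q = restore_mat(obj$alpha_q),
              alpha_b = restore_mat(obj$alpha_b),
              beta_q = array(obj$beta_q$data, dim = obj$beta_q$dim),
              beta_b = array(obj$beta_b$data, dim = obj$beta_b$dim),
              sigma2 = as.matrix(obj$sigma2), loglik = obj$loglik,
              schema = lapply(obj$schema, function(s) if (length(s)) s else NULL))
  class(fit) <- "mfmr_fit"
  fit
}
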