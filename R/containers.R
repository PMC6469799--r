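#' Trait matrix container
#'
#' Bundles the quantitative trait block `Y` (N x P, real) and the binary trait
#' block `Yb` (N x B, entries in \{0,1\}) that are jointly modeled by
#' [fit_mfmr()]. Blocks may be empty (0 columns) but must share the row count.
#' Missing values are not allowed; impute first (see [mvn_impute()]).
#'
#' @param quant numeric matrix or data frame of quantitative traits (may have
#'   0 columns).
#' @param binary numeric matrix or data frame of binary traits coded 0/1 (may
#'   have 0 columns).
#' @return An object of class `trait_matrix` with elements `quant` and
#'   `binary`.
#' @export
trait_matrix <- function(quant = NULL, binary = NULL) {
  n <- NULL
  mk <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (is.null(colnames(x)) && ncol(x) > 0)
      colnames(x) <- paste0(nm, seq_len(ncol(x)))
    x
  }
  quant <- mk(quant, "q")
  binary <- mk(binary, "b")
  if (is.null(quant) && is.null(binary))
    stop("trait_matrix needs at least one trait block")
  n <- nrow(quant %||% binary)
  if (is.null(quant)) quant <- matrix(0, n, 0)
  if (is.null(binary)) binary <- matrix(0, n, 0)
  if (nrow(quant) != nrow(binary))
    stop("quantitative and binary blocks must have the same number of rows")
  if (anyNA(quant) || anyNA(binary))
    stop("trait_matrix does not accept missing values; impute first")
  if (ncol(binary) > 0) {
    bad <- which(!apply(binary, 2L, function(v) all(v %in% c(0, 1))))
    if (length(bad))
      stop("binary trait column(s) not coded 0/1: ",
           paste(colnames(binary)[bad], collapse = ", "))
  }
  structure(list(quant = quant, binary = binary), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d samples, %d quantitative + %d binary traits\n",
              nrow(x$quant), ncol(x$quant), ncol(x$binary)))
  invisible(x)
}

#' Covariate set container
#'
#' Splits covariates by how their effects are modeled inside the mixture:
#' `homogeneous` covariates `X` carry one shared effect per trait (alpha),
#' while `heterogeneous` covariates `G` carry one effect per subtype per
#' trait (beta). The first column of `G` must be an intercept column of ones;
#' its per-subtype coefficients are the subtype main effects (gamma).
#'
#' @param homogeneous numeric matrix `X` (N x Q), no intercept column.
#' @param heterogeneous numeric matrix `G` (N x L); if `NULL`, an
#'   intercept-only `G` is created. If supplied without a leading column of
#'   ones, one is prepended.
#' @param n sample count, required only when both blocks are `NULL`-ish.
#' @return An object of class `covariate_set` with elements `homogeneous` and
#'   `heterogeneous`.
#' @export
covariate_set <- function(homogeneous = NULL, heterogeneous = NULL, n = NULL) {
  if (!is.null(homogeneous)) {
    homogeneous <- as.matrix(homogeneous)
    storage.mode(homogeneous) <- "double"
    if (is.null(colnames(homogeneous)) && ncol(homogeneous) > 0)
      colnames(homogeneous) <- paste0("x", seq_len(ncol(homogeneous)))
    n <- nrow(homogeneous)
  }
  if (!is.null(heterogeneous)) {
    heterogeneous <- as.matrix(heterogeneous)
    storage.mode(heterogeneous) <- "double"
    n <- nrow(heterogeneous)
  }
  if (is.null(n)) stop("covariate_set needs n when no covariates are given")
  if (is.null(homogeneous)) homogeneous <- matrix(0, n, 0)
  if (is.null(heterogeneous)) {
    heterogeneous <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else if (!all(heterogeneous[, 1] == 1)) {
    heterogeneous <- cbind("(Intercept)" = 1, heterogeneous)
  } else {
    colnames(heterogeneous)[1] <- "(Intercept)"
  }
  if (is.null(colnames(heterogeneous)))
    colnames(heterogeneous) <- c("(Intercept)",
                                 paste0("g", seq_len(ncol(heterogeneous) - 1L)))
  if (anyNA(homogeneous) || anyNA(heterogeneous))
    stop("covariate_set does not accept missing values; impute first")
  if (nrow(homogeneous) != nrow(heterogeneous))
    stop("covariate blocks must have the same number of rows")
  structure(list(homogeneous = homogeneous, heterogeneous = heterogeneous),
            class = "covariate_set")
}

#' @export
print.covariate_set <- function(x, ...) {
  cat(sprintf("covariate_set: %d samples, Q=%d homogeneous, L=%d heterogeneous (incl. intercept)\n",
              nrow(x$heterogeneous), ncol(x$homogeneous), ncol(x$heterogeneous)))
  invisible(x)
}

n_samples <- function(x) {
  if (inherits(x, "trait_matrix")) nrow(x$quant)
  else if (inherits(x, "covariate_set")) nrow(x$heterogeneous)
  else nrow(x)
}
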