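#' @keywords internal
"_PACKAGE"

## Numerically stable log(sum(exp(x))) by row for a matrix of log weights.
logsumexp_rows <- function(lw) {
  m <- apply(lw, 1L, max)
  m + log(rowSums(exp(lw - m)))
}

## Deterministic fan-out of one master seed into per-stage sub-seeds.
## Keeps derived seeds in the 32-bit signed range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483399L) + 1L
}

## Column standardization that tolerates constant columns (left at 0).
standardize_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[sd < .Machine$double.eps] <- 1
  sc <- sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
  attr(sc, "center") <- mu
  attr(sc, "scale") <- sd
  sc
}

## Clamp probabilities away from {0,1} for stable log-likelihoods.
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a
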