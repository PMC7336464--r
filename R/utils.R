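#' Round half away from zero
#'
#' Percentage reporting uses conventional half-up rounding (26.65 -> 26.7),
#' not the round-half-even rule of base `round()`.
#'
#' @param x numeric
#' @param digits decimal places
#' @return numeric
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Genomic inflation factor
#'
#' Median-based lambda: the median of the chi-square quantiles implied by
#' the observed p-values over the null median `qchisq(0.5, 1)`. Values near
#' 1 indicate a calibrated test; inflation above ~1.1 indicates residual
#' confounding (e.g. uncorrected population structure).
#'
#' @param p vector of p-values
#' @return scalar lambda
#' @export
genomic_lambda <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  if (!length(p)) stop("no usable p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

# Fix eigen/PC sign: make the largest-magnitude element of each loading
# vector positive so decompositions are reproducible across platforms.
fix_signs <- function(rotation, scores) {
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(rotation = rotation, scores = scores)
}
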