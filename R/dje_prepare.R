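#' Filter junctions on mean raw count
#'
#' Keeps junctions whose mean raw count across all samples is at least
#' `min_mean` (default 10, inclusive). Low-count junctions carry little
#' information and destabilize the mean-variance trend.
#'
#' @param m A `JunctionCountMatrix`.
#' @param min_mean Minimum mean raw count (inclusive).
#' @return The filtered `JunctionCountMatrix`, row order preserved.
#' @export
filter_junctions <- function(m, min_mean = 10) {
  stopifnot(inherits(m, "JunctionCountMatrix"), min_mean >= 0)
  keep <- rowMeans(m$counts) >= min_mean
  if (!any(keep))
    stop("no junctions pass the expression filter; ",
         "adjust the threshold based on the mean-variance trend")
  m$counts <- m$counts[keep, , drop = FALSE]
  m$meta <- m$meta[keep, , drop = FALSE]
  m
}

#' Log2 counts per million
#'
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`, where the library size of a
#' sample is the column sum over all junctions in the matrix. The half-count
#' and unit-library offsets stabilize zeros.
#'
#' @param m A `JunctionCountMatrix`.
#' @return Numeric matrix of logCPM values with the dimnames of the counts.
#' @export
logcpm <- function(m) {
  counts <- if (inherits(m, "JunctionCountMatrix")) m$counts else as.matrix(m)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size for sample(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
}

#' Observation-level mean-variance weights
#'
#' Count data are heteroscedastic on the logCPM scale: low counts are noisier.
#' Following the precision-weighting idea for RNA-seq linear models, an
#' unweighted fit per junction yields residual standard deviations whose
#' square roots are smoothed (LOWESS, span 0.5) against average log2 count.
#' Each observation's fitted log-count is then mapped through the trend
#' (linear interpolation, constant beyond the edges) and its weight is the
#' predicted fourth power of the inverse square-root standard deviation,
#' i.e. `predicted^(-4)` — the inverse of the predicted variance.
#'
#' @param y logCPM matrix (junctions x samples).
#' @param m The `JunctionCountMatrix` the logCPM came from (for library sizes).
#' @param design Design matrix (samples x p), full column rank.
#' @param span LOWESS span for the trend.
#' @return Positive weight matrix with the dimensions of `y`.
#' @export
mean_variance_weights <- function(y, m, design, span = 0.5) {
  counts <- if (inherits(m, "JunctionCountMatrix")) m$counts else as.matrix(m)
  if (nrow(y) < 10L)
    stop("too few junctions to estimate the mean-variance trend; ",
         "consider an unweighted analysis")
  n <- ncol(y); p <- ncol(design)
  if (qr(design)$rank < p) stop("design matrix is not of full column rank")
  if (n <= p) stop("more coefficients than samples")
  lib <- colSums(counts)
  fit <- stats::lm.fit(design, t(y))
  res <- as.matrix(fit$residuals)               # samples x junctions
  sigma <- sqrt(colSums(res^2) / (n - p))
  sq_sd <- sqrt(sigma)
  abar <- rowMeans(y) + mean(log2(lib)) - log2(1e6)
  lo <- stats::lowess(abar, sq_sd, f = span)
  fitted_cpm <- design %*% as.matrix(fit$coefficients)   # samples x junctions
  fitted_count <- t(fitted_cpm) +
    matrix(log2(lib) - log2(1e6), nrow = nrow(y), ncol = n, byrow = TRUE)
  pred <- stats::approx(lo$x, lo$y, xout = fitted_count, rule = 2,
                        ties = mean)$y
  pred <- pmax(matrix(pred, nrow = nrow(y)), 1e-4)  # guard a degenerate trend
  w <- pred^(-4)
  dimnames(w) <- dimnames(y)
  w
}
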