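#' Per-junction weighted least squares
#'
#' Fits the experimental design to every junction's logCPM profile by weighted
#' least squares. The coefficient of interest (e.g. a test-vs-control group
#' indicator; orientation is test minus control when the design is built with
#' the control level as baseline) becomes the absolute log fold change.
#'
#' @param y logCPM matrix (junctions x samples).
#' @param design Design matrix (samples x p) including an intercept.
#' @param weights Strictly positive observation weight matrix, same shape as
#'   `y`, or `NULL` for unweighted fits.
#' @param coef Column name or index of the coefficient of interest.
#' @return Object of class `JunctionFit`: list with per-junction vectors
#'   `beta` (coefficient of interest, log2 scale), `u` (unscaled standard
#'   error), `s2` (residual variance), `df` (residual degrees of freedom),
#'   plus `design`, `weights` and `coef`.
#' @export
fit_linear_model <- function(y, design, weights = NULL, coef = 2L) {
  y <- as.matrix(y)
  n <- ncol(y); p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match samples")
  if (qr(design)$rank < p) stop("design matrix is rank deficient")
  if (n - p <= 0L) stop("no residual degrees of freedom (n <= p)")
  if (is.null(weights)) weights <- matrix(1, nrow(y), n, dimnames = dimnames(y))
  if (any(weights <= 0)) stop("weights must be strictly positive")
  if (is.character(coef)) {
    coef <- match(coef, colnames(design))
    if (is.na(coef)) stop("coefficient of interest not found in design")
  }
  J <- nrow(y)
  beta <- u <- s2 <- numeric(J)
  for (j in seq_len(J)) {
    w <- weights[j, ]
    sw <- sqrt(w)
    qr_j <- qr(design * sw)
    cf <- qr.coef(qr_j, y[j, ] * sw)
    resid <- y[j, ] - drop(design %*% cf)
    R <- qr.R(qr_j)
    cov_unscaled <- chol2inv(R)
    piv <- qr_j$pivot
    unpiv <- order(piv)
    beta[j] <- cf[coef]
    u[j] <- sqrt(cov_unscaled[unpiv, unpiv, drop = FALSE][coef, coef])
    s2[j] <- sum(w * resid^2) / (n - p)
  }
  structure(list(beta = beta, u = u, s2 = s2, df = rep(n - p, J),
                 junction_id = rownames(y), design = design,
                 weights = weights, coef = coef),
            class = "JunctionFit")
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; converges in a handful of steps.
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Residual variances are shrunk toward a pooled prior estimated by the
#' method of moments on `z = log(s2)`: the prior degrees of freedom `d0`
#' solve `trigamma(d0/2) = var(e) - mean(trigamma(df/2))` with
#' `e = z - digamma(df/2) + log(df/2)`, and the prior variance `s0_2` comes
#' from the corresponding mean equation. When the between-junction spread of
#' `z` does not exceed its sampling expectation, `d0` is infinite and every
#' posterior variance equals the pooled (geometric-mean) variance. Moderated
#' t-statistics use `d0 + df` degrees of freedom, two-sided p-values, and
#' Benjamini-Hochberg FDR.
#'
#' @param fit A `JunctionFit`.
#' @return Object of class `ModeratedStats`: list with `d0`, `s0_2`,
#'   per-junction `s2_post`, `t`, `p`, `fdr`, `df_total`.
#' @export
ebayes_moderate <- function(fit) {
  s2 <- fit$s2; df <- fit$df
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok)) stop("all residual variances are zero; degenerate data")
  if (sum(ok) < 2L) stop("need at least 2 junctions with positive variance")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(z))          # pooled value; identity when all s2 equal
    s2_post <- rep(s0_2, length(s2))
  }
  t_mod <- fit$beta / (fit$u * sqrt(s2_post))
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  structure(list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, t = t_mod, p = p,
                 fdr = stats::p.adjust(p, method = "BH"),
                 df_total = df_total),
            class = "ModeratedStats")
}
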