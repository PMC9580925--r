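#' Biweight midcorrelation
#'
#' Robust correlation that down-weights observations far from the median.
#' With `u_i = (x_i - median(x)) / (9 * MAD(x))` (raw MAD, no consistency
#' constant) and weights `a_i = (1 - u_i^2)^2` for `|u_i| < 1` (0 otherwise),
#' the transformed values `x~_i = (x_i - median(x)) * a_i` give
#' `bicor = sum(x~ y~) / (||x~|| ||y~||)`. When a vector has zero MAD the
#' biweight is undefined and the function falls back to Pearson correlation
#' with a warning.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
bicor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("bicor needs at least 3 complete pairs")
  tx <- .biweight_transform(x)
  ty <- .biweight_transform(y)
  if (is.null(tx) || is.null(ty)) {
    warning("zero median absolute deviation; falling back to Pearson")
    return(stats::cor(x, y))
  }
  den <- sqrt(sum(tx^2)) * sqrt(sum(ty^2))
  if (den == 0) return(NA_real_)
  min(1, max(-1, sum(tx * ty) / den))
}

.biweight_transform <- function(v) {
  med <- stats::median(v)
  mad0 <- stats::median(abs(v - med))
  if (mad0 == 0) return(NULL)
  u <- (v - med) / (9 * mad0)
  a <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  (v - med) * a
}

# correlation of each row of a matrix with a vector, by method
.row_cor <- function(expr, trait, method) {
  switch(method,
         pearson = drop(stats::cor(t(expr), trait)),
         spearman = drop(stats::cor(t(expr), trait, method = "spearman")),
         bicor = {
           ty <- .biweight_transform(trait)
           if (is.null(ty)) return(drop(stats::cor(t(expr), trait)))
           apply(expr, 1L, function(x) {
             tx <- .biweight_transform(x)
             if (is.null(tx)) return(stats::cor(x, trait))
             den <- sqrt(sum(tx^2)) * sqrt(sum(ty^2))
             if (den == 0) NA_real_ else min(1, max(-1, sum(tx * ty) / den))
           })
         })
}

#' Correlate junction expression with numeric traits
#'
#' Pairwise-complete correlation of every junction with every numeric trait,
#' with Student-t p-values on `n_used - 2` degrees of freedom and
#' Benjamini-Hochberg FDR computed per trait across junctions (the screening
#' family of interest). Zero-variance junctions or traits yield `NA`
#' coefficients with a warning and are excluded from the FDR adjustment.
#'
#' @param expr Expression matrix (junctions x samples), e.g. logCPM.
#' @param traits Data frame or matrix of numeric traits (samples x q),
#'   missing values allowed.
#' @param method `"bicor"` (default), `"pearson"` or `"spearman"`.
#' @return Long data frame with one row per (junction, trait): `junction_id`,
#'   `trait`, `method`, `coefficient`, `p`, `fdr`, `n_used`.
#' @export
correlate <- function(expr, traits, method = c("bicor", "pearson",
                                               "spearman")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  traits <- as.data.frame(traits)
  if (nrow(traits) != ncol(expr))
    stop("traits rows must align with expression samples")
  out <- vector("list", ncol(traits))
  for (q in seq_along(traits)) {
    tr <- as.numeric(traits[[q]])
    use <- is.finite(tr)
    if (sum(use) < 3L)
      stop("trait '", names(traits)[q], "': fewer than 3 complete samples")
    ex <- expr[, use, drop = FALSE]
    tr_u <- tr[use]
    n_used <- rowSums(is.finite(ex))
    sd0 <- apply(ex, 1L, stats::sd) == 0 | stats::sd(tr_u) == 0
    r <- rep(NA_real_, nrow(ex))
    if (!all(sd0))
      r[!sd0] <- .row_cor(ex[!sd0, , drop = FALSE], tr_u, method)
    if (any(sd0))
      warning("zero-variance junction or trait; coefficients set to NA for ",
              sum(sd0), " pair(s) of trait '", names(traits)[q], "'")
    r <- pmin(1, pmax(-1, r))
    tstat <- r * sqrt((n_used - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n_used - 2)
    fdr <- rep(NA_real_, length(p))
    okp <- !is.na(p)
    fdr[okp] <- stats::p.adjust(p[okp], method = "BH")
    out[[q]] <- data.frame(junction_id = rownames(expr), trait = names(traits)[q],
                           method = method, coefficient = r, p = p, fdr = fdr,
                           n_used = n_used, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way ANOVA association with a categorical trait
#'
#' Per-junction one-way ANOVA of expression on a categorical trait, computed
#' by matrix operations across all junctions at once. Levels with fewer than
#' 2 samples are dropped with a warning; at least two remaining levels are
#' required. FDR is Benjamini-Hochberg across junctions.
#'
#' @param expr Expression matrix (junctions x samples).
#' @param trait Per-sample categorical labels (factor or character).
#' @return Data frame with `junction_id`, `trait` (`"anova"` method), `F`,
#'   `p`, `fdr`, `n_used`, `df1`, `df2`.
#' @export
anova_assoc <- function(expr, trait) {
  expr <- as.matrix(expr)
  trait <- factor(trait)
  if (length(trait) != ncol(expr))
    stop("trait labels must align with expression samples")
  use <- !is.na(trait)
  tr <- droplevels(trait[use])
  tab <- table(tr)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("dropping level(s) with fewer than 2 samples: ",
            paste(small, collapse = ", "))
    use[trait %in% small] <- FALSE
    tr <- droplevels(trait[use])
  }
  if (nlevels(tr) < 2L) stop("need at least 2 levels with >= 2 samples")
  ex <- expr[, use, drop = FALSE]
  n <- ncol(ex); k <- nlevels(tr)
  G <- stats::model.matrix(~ tr - 1)                  # n x k indicator
  nk <- colSums(G)
  group_means <- ex %*% G %*% diag(1 / nk, k)
  grand <- rowMeans(ex)
  ssb <- colSums(t((group_means - grand)^2) * nk)
  sst <- rowSums((ex - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  data.frame(junction_id = rownames(expr), method = "anova",
             F = Fstat, p = p, fdr = stats::p.adjust(p, method = "BH"),
             n_used = n, df1 = k - 1, df2 = n - k,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Covariate-adjusted linear association
#'
#' Residualizes both the expression of every junction and the numeric trait
#' on an intercept plus the covariates, then correlates the residuals; the
#' test statistic is `t = r * sqrt((n - c - 2) / (1 - r^2))` on `n - c - 2`
#' degrees of freedom — the large-matrix formulation used by expression-QTL
#' engines. With no covariates this reduces exactly to the Pearson
#' correlation test.
#'
#' @param expr Expression matrix (junctions x samples).
#' @param trait Numeric trait vector.
#' @param covariates Optional numeric matrix/data frame (samples x c).
#' @return Long data frame as in [correlate()], method `"linear"`.
#' @export
linear_assoc <- function(expr, trait, covariates = NULL) {
  expr <- as.matrix(expr)
  trait <- as.numeric(trait)
  if (length(trait) != ncol(expr))
    stop("trait must align with expression samples")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != ncol(expr))
      stop("covariates must align with expression samples")
  }
  use <- is.finite(trait)
  if (!is.null(covariates)) use <- use & rowSums(!is.finite(covariates)) == 0
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (sum(use) <= ncov + 2L) stop("too few samples for the covariate model")
  X <- cbind(`(Intercept)` = rep(1, sum(use)),
             if (!is.null(covariates)) covariates[use, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  rt <- qr.resid(qx, trait[use])
  if (stats::sd(rt) < 1e-10 * (stats::sd(trait[use]) + 1e-300)) {
    warning("trait is (numerically) a linear function of the covariates; ",
            "associations undefined")
    return(data.frame(junction_id = rownames(expr), trait = "trait",
                      method = "linear", coefficient = NA_real_,
                      p = NA_real_, fdr = NA_real_, n_used = sum(use),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  re <- t(qr.resid(qx, t(expr[, use, drop = FALSE])))
  n <- sum(use)
  r <- drop(stats::cor(t(re), rt))
  r <- pmin(1, pmax(-1, r))
  df <- n - ncov - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  data.frame(junction_id = rownames(expr), trait = "trait", method = "linear",
             coefficient = r, p = p, fdr = stats::p.adjust(p, method = "BH"),
             n_used = n, stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank top trait associations for radar display
#'
#' Selects the traits that pass `fdr < fdr_max` and `|coefficient| > rho_min`
#' for at least one of the chosen junctions, ranks them by their maximum
#' absolute coefficient, truncates to `top_k`, and returns one signed
#' coefficient per (trait, junction) — the data behind a radar chart where
#' positive coefficients sit in the outer region and negative ones in the
#' inner region.
#'
#' @param assoc Long association table from [correlate()] or
#'   [linear_assoc()].
#' @param junctions Junction IDs to display.
#' @param fdr_max,rho_min,top_k Selection thresholds (defaults 0.05, 0.2, 20).
#' @return List with `traits` (ranked character vector) and `data` (long data
#'   frame `trait`, `junction_id`, `coefficient`, `rank`).
#' @export
spliceradar_data <- function(assoc, junctions, fdr_max = 0.05, rho_min = 0.2,
                             top_k = 20L) {
  missing <- setdiff(junctions, assoc$junction_id)
  if (length(missing))
    stop("junction(s) not present in the association table: ",
         paste(missing, collapse = ", "))
  sub <- assoc[assoc$junction_id %in% junctions, , drop = FALSE]
  pass <- !is.na(sub$fdr) & sub$fdr < fdr_max &
    !is.na(sub$coefficient) & abs(sub$coefficient) > rho_min
  traits_pass <- unique(sub$trait[pass])
  if (!length(traits_pass)) {
    message("no trait passes fdr < ", fdr_max, " and |coefficient| > ",
            rho_min, " for the selected junctions")
    return(list(traits = character(),
                data = data.frame(trait = character(),
                                  junction_id = character(),
                                  coefficient = numeric(), rank = integer())))
  }
  strength <- vapply(traits_pass, function(tr)
    max(abs(sub$coefficient[sub$trait == tr & pass])), numeric(1))
  ranked <- traits_pass[order(-strength)]
  ranked <- utils::head(ranked, top_k)
  dat <- sub[sub$trait %in% ranked, c("trait", "junction_id", "coefficient")]
  dat$rank <- match(dat$trait, ranked)
  dat <- dat[order(dat$rank, dat$junction_id), , drop = FALSE]
  rownames(dat) <- NULL
  list(traits = ranked, data = dat)
}
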