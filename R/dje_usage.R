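#' Within-gene relative junction usage
#'
#' For every junction of a gene with at least two fitted junctions, the
#' relative log fold change contrasts the junction's coefficient against the
#' precision-weighted leave-one-out mean of the other junctions of the same
#' gene: `rel_j = beta_j - sum(v_k beta_k, k != j) / sum(v_k, k != j)` with
#' precisions `v_k = 1/u_k^2`. Leaving the target junction out avoids
#' self-dilution in genes with few junctions. The standard error combines the
#' junction's own uncertainty with that of the leave-one-out mean, and the
#' moderated posterior variance scales the t-statistic as in the absolute
#' test. Junctions in single-junction genes are not testable (`NA`).
#'
#' @param fit A `JunctionFit`.
#' @param mod A `ModeratedStats` for the same fit.
#' @param gene Character vector of host gene IDs aligned with the junctions
#'   (NA for unassigned junctions, which are never tested).
#' @return Data frame with per-junction `rel_logFC`, `rel_t`, `rel_p`,
#'   `rel_fdr` (NA where untested).
#' @export
relative_usage <- function(fit, mod, gene) {
  J <- length(fit$beta)
  stopifnot(length(gene) == J)
  rel_logFC <- rel_t <- rel_p <- rep(NA_real_, J)
  usable <- !is.na(gene) & is.finite(fit$u) & fit$u > 0
  v <- 1 / fit$u^2
  for (g in unique(gene[usable])) {
    idx <- which(usable & gene == g)
    if (length(idx) < 2L) next
    sv <- sum(v[idx]); svb <- sum(v[idx] * fit$beta[idx])
    denom <- sv - v[idx]
    loo_mean <- (svb - v[idx] * fit$beta[idx]) / denom
    rel <- fit$beta[idx] - loo_mean
    se <- sqrt(fit$u[idx]^2 + 1 / denom)
    tstat <- rel / (se * sqrt(mod$s2_post[idx]))
    rel_logFC[idx] <- rel
    rel_t[idx] <- tstat
    rel_p[idx] <- 2 * stats::pt(-abs(tstat), df = mod$df_total[idx])
  }
  rel_fdr <- rep(NA_real_, J)
  tested <- !is.na(rel_p)
  rel_fdr[tested] <- stats::p.adjust(rel_p[tested], method = "BH")
  data.frame(rel_logFC = rel_logFC, rel_t = rel_t, rel_p = rel_p,
             rel_fdr = rel_fdr)
}

#' Gene-level differential-usage p-values
#'
#' Aggregates the relative-usage p-values of each gene's junctions with the
#' Simes combination `min_i( m * p_(i) / i )`, then adjusts across genes with
#' Benjamini-Hochberg.
#'
#' @param rel_p Numeric vector of per-junction relative-usage p-values.
#' @param gene Host gene per junction, aligned with `rel_p`.
#' @return Data frame with `gene_id`, `n_junctions`, `p`, `fdr`.
#' @export
gene_level_p <- function(rel_p, gene) {
  ok <- !is.na(rel_p) & !is.na(gene)
  if (!any(ok))
    return(data.frame(gene_id = character(), n_junctions = integer(),
                      p = numeric(), fdr = numeric()))
  sp <- split(rel_p[ok], gene[ok])
  simes <- vapply(sp, function(p) {
    p <- sort(p)
    min(length(p) * p / seq_along(p))
  }, numeric(1))
  out <- data.frame(gene_id = names(sp),
                    n_junctions = lengths(sp),
                    p = unname(simes),
                    fdr = stats::p.adjust(unname(simes), method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify junctions into expression/usage groups
#'
#' Junctions are classified from the significance pattern of their absolute
#' (between-condition) and relative (within-gene) log fold changes:
#' * Group 0 — neither test significant: no differential expression or usage.
#' * Group 2 — exactly one test significant: change explained by overall gene
#'   expression (or usage alone).
#' * Groups 1 and 3 — both tests significant. The discriminator
#'   `D = rel_logFC - abs_logFC` is compared with the spread of `D` over all
#'   doubly significant junctions (population standard deviation
#'   `sigma_D`): junctions inside the distribution (`|D| < sd_k * sigma_D`)
#'   show equal levels of differential expression and usage (Group 1), while
#'   junctions outside it show divergent levels, indicating concomitant gene
#'   expression and splicing changes (Group 3).
#'
#' Significance means `fdr < fdr_thresh` and `|logFC| > lfc_thresh`. With
#' fewer than 3 doubly significant junctions (or zero spread) the distribution
#' of `D` is undefined and all doubly significant junctions fall in Group 1,
#' with a warning.
#'
#' @param abs_logFC,abs_fdr Absolute log fold changes and FDR.
#' @param rel_logFC,rel_fdr Relative log fold changes and FDR (NA = untested).
#' @param lfc_thresh,fdr_thresh,sd_k Thresholds (defaults 1.0, 0.05, 2.0).
#' @return Integer vector of groups in `{0, 1, 2, 3}`.
#' @export
classify_junctions <- function(abs_logFC, abs_fdr, rel_logFC, rel_fdr,
                               lfc_thresh = 1.0, fdr_thresh = 0.05,
                               sd_k = 2.0) {
  sig_abs <- !is.na(abs_fdr) & abs_fdr < fdr_thresh &
    abs(abs_logFC) > lfc_thresh
  sig_rel <- !is.na(rel_fdr) & rel_fdr < fdr_thresh &
    !is.na(rel_logFC) & abs(rel_logFC) > lfc_thresh
  group <- integer(length(abs_logFC))
  group[xor(sig_abs, sig_rel)] <- 2L
  both <- which(sig_abs & sig_rel)
  if (length(both)) {
    D <- rel_logFC[both] - abs_logFC[both]
    if (length(both) < 3L) {
      warning("fewer than 3 doubly significant junctions; ",
              "spread of rel-abs differences undefined, assigning Group 1")
      group[both] <- 1L
    } else {
      sigma_d <- sqrt(mean((D - mean(D))^2))   # population SD
      if (sigma_d == 0) {
        group[both] <- 1L
      } else {
        group[both] <- ifelse(abs(D) >= sd_k * sigma_d, 3L, 1L)
      }
    }
  }
  group
}

#' Detect neojunctions
#'
#' A neojunction is expressed in the test condition but absent from every
#' control sample: raw count 0 in all control samples and count > 0 in at
#' least `ceiling(min_frac * n_test)` test samples (so isolated single-sample
#' artifacts are not called when `min_frac` demands more support).
#'
#' @param m A `JunctionCountMatrix`.
#' @param condition Factor/character of per-sample condition labels.
#' @param test,control The labels of the test and control conditions.
#' @param min_frac Minimum fraction of test samples expressing the junction.
#' @return Logical vector, one flag per junction.
#' @export
detect_neojunctions <- function(m, condition, test = "test",
                                control = "control", min_frac = 0.25) {
  condition <- as.character(condition)
  if (length(condition) != ncol(m$counts))
    stop("condition labels must match samples")
  if (!test %in% condition || !control %in% condition)
    stop("condition labels must contain both '", test, "' and '",
         control, "'")
  ctl <- m$counts[, condition == control, drop = FALSE]
  tst <- m$counts[, condition == test, drop = FALSE]
  need <- ceiling(min_frac * ncol(tst))
  rowSums(ctl > 0) == 0L & rowSums(tst > 0) >= max(need, 1L)
}
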