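#' Build a two-condition design matrix
#'
#' Intercept plus a test-condition indicator, so the coefficient of interest
#' is test minus control on the log2 scale.
#'
#' @param condition Per-sample condition labels.
#' @param test,control Labels of the two conditions.
#' @return Design matrix with columns `(Intercept)`, `test`.
#' @export
make_design <- function(condition, test = "test", control = "control") {
  condition <- as.character(condition)
  if (!all(condition %in% c(test, control)))
    stop("condition labels must be '", test, "' or '", control, "'")
  design <- cbind(`(Intercept)` = 1, test = as.numeric(condition == test))
  rownames(design) <- names(condition)
  design
}

#' Differential junction expression and usage analysis
#'
#' Runs the full per-junction pipeline on a filtered, gene-annotated count
#' matrix: logCPM transform, mean-variance observation weights, per-junction
#' weighted linear fit, empirical-Bayes moderation, within-gene relative
#' usage, gene-level p-values, Group 0-3 classification, neojunction
#' detection, and per-condition expression summaries. Deterministic given its
#' inputs.
#'
#' @param m A `JunctionCountMatrix` with gene assignments in `meta`
#'   (see [annotate_junctions()] or [apply_gene_map()]).
#' @param condition Per-sample condition labels (`test` / `control`).
#' @param design Optional design matrix; defaults to [make_design()]. Extra
#'   covariate columns are allowed; `coef` selects the contrast of interest.
#' @param coef Coefficient of interest in `design` (default `"test"`).
#' @param test,control Condition labels.
#' @param min_mean Expression filter threshold (mean raw count).
#' @param lfc_thresh,fdr_thresh,sd_k Classification thresholds.
#' @param min_frac Neojunction prevalence threshold in the test condition.
#' @param use_weights Compute mean-variance observation weights (default) or
#'   fit unweighted.
#' @return Object of class `DJEResult`: list with `table` (the per-junction
#'   results data frame), `gene_table`, `fit`, `moderated`, `condition`,
#'   and `params`.
#' @export
dje_analyze <- function(m, condition, design = NULL, coef = "test",
                        test = "test", control = "control",
                        min_mean = 10, lfc_thresh = 1.0, fdr_thresh = 0.05,
                        sd_k = 2.0, min_frac = 0.25, use_weights = TRUE) {
  stopifnot(inherits(m, "JunctionCountMatrix"))
  condition <- as.character(condition)
  if (length(condition) != ncol(m$counts))
    stop("condition labels must match the samples of the count matrix")
  m <- filter_junctions(m, min_mean = min_mean)
  if (is.null(design)) design <- make_design(condition, test, control)
  y <- logcpm(m)
  w <- if (use_weights) mean_variance_weights(y, m, design) else NULL
  fit <- fit_linear_model(y, design, weights = w, coef = coef)
  mod <- ebayes_moderate(fit)
  gene <- m$meta$gene_id
  rel <- relative_usage(fit, mod, gene)
  gene_tab <- gene_level_p(rel$rel_p, gene)
  group <- classify_junctions(fit$beta, mod$fdr, rel$rel_logFC, rel$rel_fdr,
                              lfc_thresh = lfc_thresh,
                              fdr_thresh = fdr_thresh, sd_k = sd_k)
  neo <- detect_neojunctions(m, condition, test = test, control = control,
                             min_frac = min_frac)
  is_test <- condition == test
  counts <- m$counts
  tab <- data.frame(
    junction_id = m$meta$junction_id,
    chrom = m$meta$chrom, start = m$meta$start, end = m$meta$end,
    strand = m$meta$strand,
    gene_id = m$meta$gene_id,
    annotated = m$meta$annotated,
    novel = !m$meta$annotated,
    shares_splice_site = m$meta$shares_splice_site,
    abs_logFC = fit$beta, abs_t = mod$t, abs_p = mod$p, abs_fdr = mod$fdr,
    rel_logFC = rel$rel_logFC, rel_t = rel$rel_t, rel_p = rel$rel_p,
    rel_fdr = rel$rel_fdr,
    group = group,
    neojunction = neo,
    mean_test = rowMeans(counts[, is_test, drop = FALSE]),
    mean_control = rowMeans(counts[, !is_test, drop = FALSE]),
    median_test = apply(counts[, is_test, drop = FALSE], 1, stats::median),
    median_control = apply(counts[, !is_test, drop = FALSE], 1,
                           stats::median),
    n_expressed_test = rowSums(counts[, is_test, drop = FALSE] > 0),
    n_expressed_control = rowSums(counts[, !is_test, drop = FALSE] > 0),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, gene_table = gene_tab, fit = fit,
                 moderated = mod, matrix = m, condition = condition,
                 params = list(min_mean = min_mean, lfc_thresh = lfc_thresh,
                               fdr_thresh = fdr_thresh, sd_k = sd_k,
                               min_frac = min_frac, coef = coef,
                               test = test, control = control,
                               use_weights = use_weights)),
            class = "DJEResult")
}

#' @export
print.DJEResult <- function(x, ...) {
  tab <- x$table
  de <- sum(tab$abs_fdr < x$params$fdr_thresh &
              abs(tab$abs_logFC) > x$params$lfc_thresh, na.rm = TRUE)
  cat(sprintf("DJEResult: %d junctions, %d genes tested\n",
              nrow(tab), nrow(x$gene_table)))
  cat(sprintf("  DE junctions (FDR < %g, |logFC| > %g): %d\n",
              x$params$fdr_thresh, x$params$lfc_thresh, de))
  cat(sprintf("  groups 1/2/3: %d/%d/%d; neojunctions: %d; novel: %d\n",
              sum(tab$group == 1L), sum(tab$group == 2L),
              sum(tab$group == 3L), sum(tab$neojunction), sum(tab$novel)))
  invisible(x)
}

# full-precision TSV writer so numeric columns survive a round trip exactly
.write_tsv_full <- function(df, path) {
  out <- df
  for (i in seq_along(out)) {
    if (is.double(out[[i]])) out[[i]] <- sprintf("%.17g", out[[i]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write / read the per-junction results table
#'
#' Tab-separated, one row per junction, numeric columns at full precision so
#' that reading the file back reproduces the table losslessly.
#'
#' @param res A `DJEResult` (or its `table` data frame).
#' @param path Output path.
#' @export
write_dje_table <- function(res, path) {
  tab <- if (inherits(res, "DJEResult")) res$table else res
  .write_tsv_full(tab, path)
}

#' @rdname write_dje_table
#' @export
read_dje_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Per-gene splice-plot data
#'
#' Returns the junctions of one gene ordered by genomic coordinate, with the
#' fields needed to draw a gene-wise splice plot: relative logFC, a
#' significance color class (`up` / `down` for significant junctions above
#' the logFC threshold, `suprathreshold-nonsignificant` for junctions beyond
#' the threshold without FDR support, `ns` otherwise), neojunction and novel
#' flags, and the junction's genomic arc endpoints. The `lfc_thresh`
#' attribute gives the grey significance band (+/- threshold).
#'
#' @param res A `DJEResult`.
#' @param gene_id Gene to extract.
#' @param lfc_thresh,fdr_thresh Thresholds; default to those of the analysis.
#' @return Data frame of plot records ordered by (start, end), with
#'   attribute `lfc_thresh`.
#' @export
splice_plot_data <- function(res, gene_id, lfc_thresh = NULL,
                             fdr_thresh = NULL) {
  stopifnot(inherits(res, "DJEResult"))
  if (is.null(lfc_thresh)) lfc_thresh <- res$params$lfc_thresh
  if (is.null(fdr_thresh)) fdr_thresh <- res$params$fdr_thresh
  tab <- res$table
  sel <- !is.na(tab$gene_id) & tab$gene_id == gene_id
  if (!any(sel)) {
    genes <- unique(stats::na.omit(tab$gene_id))
    near <- genes[order(utils::adist(gene_id, genes))]
    stop("gene '", gene_id, "' not found; nearest gene IDs: ",
         paste(utils::head(near, 3L), collapse = ", "))
  }
  g <- tab[sel, , drop = FALSE]
  g <- g[order(g$start, g$end), , drop = FALSE]
  sig <- !is.na(g$rel_fdr) & g$rel_fdr < fdr_thresh &
    !is.na(g$rel_logFC) & abs(g$rel_logFC) > lfc_thresh
  supra <- !sig & !is.na(g$rel_logFC) & abs(g$rel_logFC) > lfc_thresh
  color_class <- ifelse(sig & g$rel_logFC > 0, "up",
                        ifelse(sig, "down",
                               ifelse(supra, "suprathreshold-nonsignificant",
                                      "ns")))
  out <- data.frame(junction_id = g$junction_id, start = g$start,
                    end = g$end, strand = g$strand,
                    rel_logFC = g$rel_logFC, rel_fdr = g$rel_fdr,
                    color_class = color_class,
                    neojunction = g$neojunction, novel = g$novel,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lfc_thresh") <- lfc_thresh
  out
}
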