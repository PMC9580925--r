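MODULE_COLORS <- c("grey", "turquoise", "blue", "brown", "yellow", "green",
                   "red", "black", "pink", "magenta", "purple",
                   "greenyellow", "tan", "salmon", "cyan", "midnightblue",
                   "lightcyan", "grey60", "lightgreen", "lightyellow",
                   "royalblue", "darkred", "darkgreen", "darkturquoise",
                   "darkgrey", "orange", "darkorange", "white", "skyblue",
                   "saddlebrown")

.module_color <- function(label) {
  MODULE_COLORS[(label %% length(MODULE_COLORS)) + 1L]
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity (typically
#' `1 - TOM`), followed by a static branch cut whose height is indexed by the
#' `deep_split` sensitivity (0.99, 0.97, 0.95, 0.93, 0.91 for deep_split
#' 0..4: deeper splits cut lower and produce more modules). Clusters smaller
#' than `min_module_size` are left unassigned (label 0, grey). When the
#' expression matrix is supplied, modules whose eigengenes correlate at least
#' `1 - merge_cut_height` are merged iteratively. Final labels are ordered by
#' decreasing module size.
#'
#' @param dissim Symmetric dissimilarity matrix (e.g. `1 - tom_similarity()`).
#' @param cfg A [network_config()].
#' @param expr Optional expression matrix (junctions x samples) enabling the
#'   eigengene merge step.
#' @return List of class `ModuleAssignment`: `labels` (named integer vector,
#'   0 = unassigned), `colors`, `sizes`, `hclust`.
#' @export
detect_modules <- function(dissim, cfg = network_config(), expr = NULL) {
  dissim <- as.matrix(dissim)
  n <- nrow(dissim)
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- paste0("J", seq_len(n))
  if (n < cfg$min_module_size) {
    warning("fewer junctions than min_module_size; no modules assigned")
    labels <- stats::setNames(integer(n), ids)
    return(structure(list(labels = labels,
                          colors = .module_color(labels),
                          sizes = integer(), hclust = NULL),
                     class = "ModuleAssignment"))
  }
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  h_cut <- c(0.99, 0.97, 0.95, 0.93, 0.91)[cfg$deep_split + 1L]
  h_cut <- min(h_cut, max(hc$height))   # cutree needs a reachable height
  cl <- stats::cutree(hc, h = h_cut)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < cfg$min_module_size])
  cl[cl %in% small] <- 0L
  if (!is.null(expr) && length(unique(cl[cl != 0L])) >= 2L) {
    cl <- .merge_close_modules(expr, cl, cfg$merge_cut_height)
  }
  # relabel by decreasing size, 0 stays unassigned
  nz <- cl[cl != 0L]
  if (length(nz)) {
    ord <- names(sort(table(nz), decreasing = TRUE))
    map <- stats::setNames(seq_along(ord), ord)
    cl[cl != 0L] <- map[as.character(nz)]
  }
  labels <- stats::setNames(as.integer(cl), ids)
  structure(list(labels = labels, colors = .module_color(labels),
                 sizes = table(labels[labels != 0L]), hclust = hc),
            class = "ModuleAssignment")
}

.merge_close_modules <- function(expr, cl, merge_cut_height) {
  repeat {
    mods <- sort(unique(cl[cl != 0L]))
    if (length(mods) < 2L) break
    me <- vapply(mods, function(k) {
      .first_pc(expr[cl == k, , drop = FALSE])$me
    }, numeric(ncol(expr)))
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (max(cc) < 1 - merge_cut_height) break
    cl[cl == mods[best[2L]]] <- mods[best[1L]]
  }
  cl
}

# first principal component of row-standardized expression:
# ME is the leading right singular vector (unit norm), sign-oriented so that
# it correlates non-negatively with the mean member profile
.first_pc <- function(expr_members) {
  sc <- t(scale(t(as.matrix(expr_members))))
  sc[!is.finite(sc)] <- 0
  sv <- svd(sc)
  me <- sv$v[, 1L]
  mean_prof <- colMeans(sc)
  if (sum(me * mean_prof) < 0) me <- -me
  list(me = me, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Module eigengenes and membership
#'
#' The eigengene (ME) of a module is the first principal component of its
#' members' standardized expression (samples-long, unit norm), oriented to
#' correlate non-negatively with the mean member profile. `var_explained` is
#' the fraction of standardized variance captured by the ME. Module
#' membership (MM) of a junction is the correlation between its expression
#' and its own module's eigengene.
#'
#' @param expr Expression matrix (junctions x samples).
#' @param modules A `ModuleAssignment` (or named integer label vector).
#' @return List of class `Eigengenes`: `eigengenes` (samples x modules matrix
#'   with columns `ME1`, ...), `var_explained`, `membership` (named vector,
#'   NA for unassigned junctions).
#' @export
module_eigengenes <- function(expr, modules) {
  labels <- if (inherits(modules, "ModuleAssignment")) modules$labels else
    modules
  expr <- as.matrix(expr)
  labels <- labels[rownames(expr)]
  mods <- sort(unique(labels[labels != 0L]))
  if (!length(mods)) stop("no assigned modules")
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    pc <- .first_pc(expr[labels == mods[i], , drop = FALSE])
    me[, i] <- pc$me
    ve[i] <- pc$var_explained
  }
  mm <- rep(NA_real_, nrow(expr))
  names(mm) <- rownames(expr)
  for (i in seq_along(mods)) {
    members <- which(labels == mods[i])
    mm[members] <- drop(stats::cor(t(expr[members, , drop = FALSE]),
                                   me[, i]))
  }
  structure(list(eigengenes = me, var_explained = ve, membership = mm),
            class = "Eigengenes")
}

#' Module-trait correlation matrix
#'
#' Correlates every module eigengene with every numeric trait
#' (pairwise-complete), with Student-t p-values and Benjamini-Hochberg FDR
#' across the whole matrix. Summarizing members through eigengenes keeps the
#' multiple-testing burden at the module count rather than the junction
#' count.
#'
#' @param eg An `Eigengenes` object (or the eigengene matrix itself).
#' @param traits Numeric trait data frame/matrix (samples x q).
#' @return List with matrices `cor`, `p`, `fdr` (modules x traits).
#' @export
module_trait_correlation <- function(eg, traits) {
  me <- if (inherits(eg, "Eigengenes")) eg$eigengenes else as.matrix(eg)
  traits <- as.matrix(as.data.frame(traits))
  if (nrow(traits) != nrow(me))
    stop("traits rows must align with eigengene samples")
  cc <- stats::cor(me, traits, use = "pairwise.complete.obs")
  nmat <- crossprod(!is.na(me), !is.na(traits))
  tstat <- cc * sqrt((nmat - 2) / pmax(1 - cc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = nmat - 2)
  fdr <- matrix(stats::p.adjust(p, method = "BH"), nrow(p),
                dimnames = dimnames(p))
  list(cor = cc, p = p, fdr = fdr)
}

#' Two-pass filter: remove gene-expression-driven junction-trait signal
#'
#' Junction significance (GS) for a trait is the absolute correlation between
#' junction expression and the trait; gene significance is the same for the
#' junction's host-gene expression. Junctions whose trait association merely
#' reflects their gene's expression fall on the regression line of junction
#' GS on gene GS; junctions at least 2 standardized residuals outside that
#' distribution carry gene-independent (splicing-driven) trait signal and are
#' kept for network re-construction.
#'
#' @param junc_expr Junction expression matrix (junctions x samples).
#' @param gene_expr Gene expression matrix (genes x samples).
#' @param host Character vector: host gene per junction (must exist in
#'   `gene_expr`).
#' @param trait Numeric trait vector (samples).
#' @param z_cut Keep junctions with `|standardized residual| >= z_cut`.
#' @return Data frame of class `TwoPassStats` with `junction_id`, `gene_id`,
#'   `gs_junction`, `gs_gene`, `residual_z`, `kept`.
#' @export
two_pass_filter <- function(junc_expr, gene_expr, host, trait, z_cut = 2) {
  junc_expr <- as.matrix(junc_expr)
  gene_expr <- as.matrix(gene_expr)
  if (length(host) != nrow(junc_expr))
    stop("host genes must align with junctions")
  missing <- setdiff(unique(host), rownames(gene_expr))
  if (length(missing))
    stop("host gene(s) absent from gene expression: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  gs_j <- abs(drop(stats::cor(t(junc_expr), trait)))
  gs_g_all <- abs(drop(stats::cor(t(gene_expr), trait)))
  gs_g <- gs_g_all[match(host, rownames(gene_expr))]
  fit <- stats::lm(gs_j ~ gs_g)
  r <- stats::resid(fit)
  s <- stats::sd(r)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate two-pass distribution; ",
         "all junction-trait signal is gene-driven")
  z <- r / s
  out <- data.frame(junction_id = rownames(junc_expr), gene_id = host,
                    gs_junction = gs_j, gs_gene = gs_g, residual_z = z,
                    kept = abs(z) >= z_cut, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("TwoPassStats", class(out))
  out
}

#' Host-gene expression from junction counts
#'
#' Gene expression proxy for the 2-pass filter: raw junction counts are
#' summed per host gene, then transformed to logCPM with gene-level library
#' sizes.
#'
#' @param m A `JunctionCountMatrix` with gene assignments.
#' @return logCPM matrix (genes x samples).
#' @export
gene_expression <- function(m) {
  stopifnot(inherits(m, "JunctionCountMatrix"))
  ok <- !is.na(m$meta$gene_id)
  g <- rowsum(m$counts[ok, , drop = FALSE], m$meta$gene_id[ok])
  lib <- colSums(g)
  if (any(lib <= 0)) stop("zero gene-level library size")
  t(log2(t(g + 0.5) / (lib + 1) * 1e6))
}

#' Export a network to graph-tool edge lists
#'
#' Cytoscape dialect: TSV `source target weight source_module target_module`
#' with each undirected edge emitted once (source before target in
#' lexicographic order) and `weight >= weight_min`. VisANT dialect:
#' `source target 0 weight`, no header. A node attribute table
#' (junction, gene, module) is written alongside.
#'
#' @param mat TOM or adjacency matrix.
#' @param modules A `ModuleAssignment` (or named label vector).
#' @param dir Output directory (created if needed).
#' @param weight_min Minimum edge weight in `[0, 1]`.
#' @param gene Optional named vector of host genes for the node table.
#' @param prefix File name prefix.
#' @return Invisible list with the edge/node data frames and file paths.
#' @export
export_network <- function(mat, modules, dir, weight_min = 0, gene = NULL,
                           prefix = "network") {
  stopifnot(weight_min >= 0, weight_min <= 1)
  mat <- as.matrix(mat)
  labels <- if (inherits(modules, "ModuleAssignment")) modules$labels else
    modules
  ids <- rownames(mat)
  if (is.null(ids)) stop("matrix must carry junction rownames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  w <- mat[ut]
  keep <- w >= weight_min
  i <- ut[keep, 1L]; j <- ut[keep, 2L]; w <- w[keep]
  a <- ids[i]; b <- ids[j]
  swap <- a > b
  src <- ifelse(swap, b, a)
  tgt <- ifelse(swap, a, b)
  edges <- data.frame(source = src, target = tgt, weight = w,
                      source_module = unname(labels[src]),
                      target_module = unname(labels[tgt]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(junction_id = ids,
                      gene_id = if (is.null(gene)) NA_character_ else
                        unname(gene[ids]),
                      module = unname(labels[ids]),
                      stringsAsFactors = FALSE)
  cyto <- file.path(dir, paste0(prefix, "_cytoscape.tsv"))
  .write_tsv_full(edges, cyto)
  visant <- file.path(dir, paste0(prefix, "_visant.tsv"))
  vis <- data.frame(source = edges$source, target = edges$target,
                    flag = rep(0L, nrow(edges)), weight = edges$weight)
  for (k in seq_along(vis))
    if (is.double(vis[[k]])) vis[[k]] <- sprintf("%.17g", vis[[k]])
  utils::write.table(vis, visant, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  nodefile <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  utils::write.table(nodes, nodefile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(edges = edges, nodes = nodes,
                 files = c(cytoscape = cyto, visant = visant,
                           nodes = nodefile)))
}

#' Junction co-expression network analysis
#'
#' One-pass pipeline: feature and sample quality control, soft-threshold
#' selection, adjacency and topological overlap, module detection, module
#' eigengenes, and (optionally) module-trait correlation. When `two_pass`
#' is requested together with a `trait` and gene expression, the
#' gene-expression-driven junction-trait signal is removed with
#' [two_pass_filter()] and the network is re-constructed on the kept
#' junctions only.
#'
#' @param expr Junction expression matrix (junctions x samples), e.g. logCPM.
#' @param cfg A [network_config()].
#' @param traits Optional numeric trait table (samples x q).
#' @param power Optional fixed soft power (skips automatic selection).
#' @param two_pass Run the 2-pass gene-expression subtraction.
#' @param gene_expr Gene expression matrix (genes x samples), required for
#'   `two_pass`.
#' @param host Host gene per junction (named or aligned with `expr` rows),
#'   required for `two_pass`.
#' @param trait_name Column of `traits` used for the 2-pass filter.
#' @return List of class `JCNAResult`: `soft_threshold`, `modules`,
#'   `eigengenes`, `module_trait`, `kept_samples`, `kept_junctions`,
#'   `two_pass` (stats or NULL), `tom`, `config`.
#' @export
run_jcna <- function(expr, cfg = network_config(), traits = NULL,
                     power = NULL, two_pass = FALSE, gene_expr = NULL,
                     host = NULL, trait_name = NULL) {
  expr <- as.matrix(expr)
  all_samples <- colnames(expr)
  if (!is.null(host) && is.null(names(host))) {
    if (length(host) != nrow(expr))
      stop("host must be named or aligned with the rows of expr")
    names(host) <- rownames(expr)
  }
  keep_j <- good_features(expr)
  expr <- expr[keep_j, , drop = FALSE]
  keep_s <- remove_outlier_samples(expr, min_samples = cfg$min_samples)
  expr <- expr[, keep_s, drop = FALSE]
  if (ncol(expr) < cfg$min_samples)
    warning("fewer than ", cfg$min_samples, " samples; network unstable")
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)[match(keep_s, all_samples), ,
                                    drop = FALSE]
  }
  tp <- NULL
  if (two_pass) {
    if (is.null(gene_expr) || is.null(host) || is.null(trait_name) ||
        is.null(traits))
      stop("two_pass requires gene_expr, host and trait_name")
    tr <- as.numeric(traits[[trait_name]])
    tp <- two_pass_filter(expr, gene_expr[, keep_s, drop = FALSE],
                          host[rownames(expr)], tr)
    expr <- expr[tp$kept, , drop = FALSE]
    if (nrow(expr) < cfg$min_module_size)
      warning("fewer kept junctions than min_module_size after 2-pass")
  }
  sft <- pick_soft_threshold(expr, cfg)
  if (is.null(power)) power <- sft$chosen_power
  a <- adjacency_matrix(expr, power = power, type = cfg$type,
                        method = cfg$correlation)
  tom <- tom_similarity(a)
  mods <- detect_modules(1 - tom, cfg, expr = expr)
  eg <- if (any(mods$labels != 0L)) module_eigengenes(expr, mods) else NULL
  mt <- if (!is.null(eg) && !is.null(traits))
    module_trait_correlation(eg, traits) else NULL
  structure(list(soft_threshold = sft, power = power, modules = mods,
                 eigengenes = eg, module_trait = mt,
                 kept_samples = keep_s, kept_junctions = rownames(expr),
                 two_pass = tp, tom = tom, config = cfg),
            class = "JCNAResult")
}
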