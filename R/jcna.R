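#' Network analysis configuration
#'
#' Defaults: biweight midcorrelation, unsigned network, candidate soft powers
#' 1..20, scale-free fit target 0.8, minimum module size 20 junctions,
#' medium tree-cut sensitivity (`deep_split = 2`), eigengene merge cut height
#' 0.25, and a recommended minimum of 15 samples per condition.
#'
#' @param correlation `"bicor"`, `"pearson"` or `"spearman"`.
#' @param type `"unsigned"` or `"signed"`.
#' @param powers Candidate soft-threshold powers.
#' @param scale_free_target Signed R^2 required for scale-free topology.
#' @param min_module_size Smallest allowed module.
#' @param deep_split Cluster-splitting sensitivity, 0 (coarse) .. 4 (fine).
#' @param merge_cut_height Modules with eigengene correlation at least
#'   `1 - merge_cut_height` are merged.
#' @param min_samples Minimum recommended sample count.
#' @return A list of class `NetworkConfig`.
#' @export
network_config <- function(correlation = c("bicor", "pearson", "spearman"),
                           type = c("unsigned", "signed"), powers = 1:20,
                           scale_free_target = 0.8, min_module_size = 20L,
                           deep_split = 2L, merge_cut_height = 0.25,
                           min_samples = 15L) {
  correlation <- match.arg(correlation)
  type <- match.arg(type)
  stopifnot(all(powers >= 1), scale_free_target > 0, scale_free_target <= 1,
            deep_split %in% 0:4, merge_cut_height > 0, merge_cut_height <= 1)
  structure(list(correlation = correlation, type = type,
                 powers = as.integer(powers),
                 scale_free_target = scale_free_target,
                 min_module_size = as.integer(min_module_size),
                 deep_split = as.integer(deep_split),
                 merge_cut_height = merge_cut_height,
                 min_samples = as.integer(min_samples)),
            class = "NetworkConfig")
}

# pairwise correlation between rows of expr by method; bicor via the
# biweight transform so the whole matrix is one crossproduct
.cor_matrix <- function(expr, method = "bicor") {
  expr <- as.matrix(expr)
  cc <- switch(method,
    pearson = stats::cor(t(expr)),
    spearman = stats::cor(t(expr), method = "spearman"),
    bicor = {
      tf <- t(apply(expr, 1L, function(x) {
        tx <- .biweight_transform(x)
        if (is.null(tx)) x - mean(x) else tx   # Pearson fallback per row
      }))
      nrm <- sqrt(rowSums(tf^2))
      if (any(nrm == 0)) stop("zero-variance junction in correlation input; ",
                              "run good_features() first")
      tcrossprod(tf / nrm)
    })
  pmin(pmax(cc, -1), 1)
}

#' Remove outlier samples before network construction
#'
#' Samples are clustered by average-linkage hierarchical clustering on the
#' Euclidean distance between expression profiles; cutting the dendrogram at
#' `cut_height` (automatic default: mean + 2.5 SD of the merge heights) and
#' keeping the largest cluster removes samples that join the tree unusually
#' late.
#'
#' @param expr Expression matrix (junctions x samples).
#' @param cut_height Numeric height or `"auto"`.
#' @param min_samples Warn when fewer samples remain.
#' @return Character vector of kept sample IDs.
#' @export
remove_outlier_samples <- function(expr, cut_height = "auto",
                                   min_samples = 15L) {
  expr <- as.matrix(expr)
  d <- stats::dist(t(expr))
  if (all(d == 0)) return(colnames(expr))
  hc <- stats::hclust(d, method = "average")
  h <- hc$height
  if (identical(cut_height, "auto")) {
    cut_height <- mean(h) + 2.5 * stats::sd(h)
    if (!is.finite(cut_height)) return(colnames(expr))
  }
  if (cut_height >= max(h)) return(colnames(expr))
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(cl)[cl == as.integer(names(sizes)[which.max(sizes)])]
  if (length(keep) < min_samples)
    warning("only ", length(keep), " samples remain after outlier removal")
  keep
}

#' Drop junctions unusable for network construction
#'
#' Removes junctions with more than `max_missing_frac` missing values or with
#' variance not exceeding `min_variance`.
#'
#' @param expr Expression matrix (junctions x samples).
#' @param max_missing_frac Maximum tolerated fraction of missing values.
#' @param min_variance Variance must exceed this (default 0: drop constants).
#' @return Character vector of kept junction IDs.
#' @export
good_features <- function(expr, max_missing_frac = 0.5, min_variance = 0) {
  expr <- as.matrix(expr)
  miss <- rowMeans(!is.finite(expr))
  v <- apply(expr, 1L, function(x) stats::var(x[is.finite(x)]))
  keep <- miss <= max_missing_frac & !is.na(v) & v > min_variance
  rownames(expr)[keep]
}

#' Weighted adjacency matrix
#'
#' `|cor|^power` for unsigned networks, `((1 + cor)/2)^power` for signed
#' networks; diagonal fixed at 1.
#'
#' @param expr Expression matrix (junctions x samples); ignored when
#'   `cor_mat` is supplied.
#' @param power Soft-threshold power (>= 1).
#' @param type `"unsigned"` or `"signed"`.
#' @param method Correlation method.
#' @param cor_mat Optional precomputed correlation matrix.
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(expr = NULL, power = 6, type = "unsigned",
                             method = "bicor", cor_mat = NULL) {
  stopifnot(power >= 1)
  if (is.null(cor_mat)) cor_mat <- .cor_matrix(expr, method)
  a <- switch(type,
              unsigned = abs(cor_mat)^power,
              signed = ((1 + cor_mat) / 2)^power,
              stop("type must be 'unsigned' or 'signed'"))
  diag(a) <- 1
  a
}

# scale-free topology fit: histogram of connectivities in equal-width bins,
# signed R^2 of log10 p(k) on log10 k (positive when the slope is negative)
.scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 2L) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- as.numeric(table(bin)) / length(k)
  ok <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2L]) * r2
}

#' Soft-threshold diagnostics and power selection
#'
#' For every candidate power, computes the adjacency, the connectivity
#' distribution, and the signed scale-free fit index (R^2 of the log-log
#' regression of the connectivity histogram, positive when high-connectivity
#' nodes are rare). The chosen power is the smallest one whose fit index
#' reaches `scale_free_target`; when no power reaches it (e.g. pure noise
#' input has no scale-free structure) the maximizing power is returned with
#' `target_reached = FALSE`.
#'
#' @param expr Expression matrix (junctions x samples).
#' @param cfg A [network_config()].
#' @return List of class `SoftThresholdTable`: `table` (per-power data frame
#'   with `power`, `sft_r2`, `mean_k`, `median_k`, `max_k`), `chosen_power`,
#'   `target_reached`.
#' @export
pick_soft_threshold <- function(expr, cfg = network_config()) {
  expr <- as.matrix(expr)
  v <- apply(expr, 1L, stats::var)
  if (any(!is.finite(v) | v == 0))
    stop("zero-variance junctions present; run good_features() first")
  if (nrow(expr) < 50L)
    warning("fewer than 50 junctions; soft-threshold diagnostics unstable")
  cc <- .cor_matrix(expr, cfg$correlation)
  rows <- lapply(cfg$powers, function(b) {
    a <- adjacency_matrix(cor_mat = cc, power = b, type = cfg$type)
    k <- rowSums(a) - 1
    data.frame(power = b, sft_r2 = .scale_free_fit(k), mean_k = mean(k),
               median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # a fit only counts when the network is non-vacuous: at very high powers
  # any input (noise included) produces a spuriously good fit on a network
  # whose mean connectivity is essentially zero
  eligible <- !is.na(tab$sft_r2) & tab$mean_k >= 1
  reach <- which(eligible & tab$sft_r2 >= cfg$scale_free_target)
  if (length(reach)) {
    chosen <- tab$power[reach[1L]]
    reached <- TRUE
  } else {
    pool <- if (any(eligible)) which(eligible) else seq_len(nrow(tab))
    chosen <- tab$power[pool[which.max(tab$sft_r2[pool])]]
    reached <- FALSE
  }
  structure(list(table = tab, chosen_power = chosen,
                 target_reached = reached),
            class = "SoftThresholdTable")
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where the
#' sum runs over shared neighbors `u != i, j` and `k_i` is the connectivity
#' of node i; `TOM_ii = 1`. The dissimilarity used for clustering is
#' `1 - TOM`.
#'
#' @param a Symmetric adjacency matrix, entries in `[0, 1]`, unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (any(abs(diag(a) - 1) > 1e-12)) stop("adjacency diagonal must be 1")
  k <- rowSums(a) - 1
  S <- a %*% a                   # includes u = i and u = j terms (2 * a_ij)
  num <- S - a                   # shared-neighbor sum + a_ij
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}
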