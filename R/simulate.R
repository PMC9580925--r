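#' Simulation configuration
#'
#' Describes a two-condition junction-count experiment: genes with a known
#' junction structure, per-gene baseline expression (log-normal, CPM scale),
#' per-gene junction usage proportions (Dirichlet), negative-binomial counts,
#' and spiked events of each classification class. Junction read counts are
#' drawn as `NB(mean = libsize * gene_cpm * usage / 1e6, dispersion)`.
#'
#' Spiked events (each names a distinct gene; the first junction of the gene
#' is the target):
#' * usage shift — the target junction's usage moves by `delta` on the
#'   natural-logit scale between conditions at constant gene total
#'   (expected classification: Group 1; `delta = 2*log(2)` gives a true
#'   relative logFC of 2).
#' * gene DE — all junctions of the gene scale by `2^logfc`
#'   (expected: Group 2).
#' * combined — both at once with unequal magnitudes (expected: Group 3).
#' * neojunction — the target junction has zero usage in the control
#'   condition and `spike_usage_base` usage in the test condition.
#'
#' Spiked genes use a controlled baseline (`spike_gene_cpm` CPM; target
#' junction usage `spike_usage_base`) so that the true effect sizes recorded
#' in the truth table are exact and events are expressed well above the
#' default filter.
#'
#' @param n_genes Number of genes.
#' @param junctions_per_gene Range (min, max) of junctions per gene.
#' @param n_test,n_control Samples per condition (default 15 each, the
#'   recommended minimum for network analysis).
#' @param gene_cpm_meanlog,gene_cpm_sdlog Log-normal baseline gene expression
#'   (CPM scale).
#' @param usage_concentration Dirichlet concentration of junction usage.
#' @param dispersion Negative-binomial dispersion (0 = Poisson).
#' @param libsize_range Library size range (uniform).
#' @param n_usage,n_gene_de,n_combined,n_neojunction Number of spiked events
#'   of each class (assigned to distinct genes in order).
#' @param usage_delta Logit-scale usage shift (natural log odds).
#' @param gene_de_logfc log2 fold change(s) of gene-DE events, recycled
#'   across events; the default `c(2, -2)` alternates up- and down-regulated
#'   genes so that spiked events leave the library composition balanced.
#' @param combined_delta,combined_gene_logfc Effects of combined events; the
#'   default gene logFC of -4 puts the rel-minus-abs discriminator of these
#'   junctions on the same side of zero as the usage-shift cluster, as the
#'   distribution-based Group rule expects.
#' @param spike_usage_base Baseline usage of spiked target junctions.
#' @param spike_gene_cpm Baseline CPM of spiked genes.
#' @param seed Integer seed; fully determines the simulated data.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 60L, junctions_per_gene = c(4L, 6L),
                       n_test = 15L, n_control = 15L,
                       gene_cpm_meanlog = log(100), gene_cpm_sdlog = 0.7,
                       usage_concentration = 5, dispersion = 0.1,
                       libsize_range = c(1.5e6, 2.5e6),
                       n_usage = 0L, n_gene_de = 0L, n_combined = 0L,
                       n_neojunction = 0L,
                       usage_delta = 2 * log(2), gene_de_logfc = c(2, -2),
                       combined_delta = 2 * log(2), combined_gene_logfc = -4,
                       spike_usage_base = 0.15, spike_gene_cpm = 100,
                       seed = 1L) {
  n_spiked <- n_usage + n_gene_de + n_combined + n_neojunction
  if (n_spiked > n_genes)
    stop("more spiked events than genes")
  if (n_spiked > 0L && junctions_per_gene[1L] < 2L)
    stop("spiked genes need at least 2 junctions per gene")
  if (spike_usage_base <= 0 || spike_usage_base >= 1)
    stop("spike_usage_base must lie strictly in (0, 1)")
  p2 <- stats::plogis(stats::qlogis(spike_usage_base) + usage_delta)
  if (p2 <= 0 || p2 >= 1)
    stop("infeasible usage shift: shifted proportion leaves (0, 1)")
  structure(as.list(environment()), class = "SimConfig")
}

.rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  g / sum(g)
}

#' Simulate a junction count experiment
#'
#' Generates a two-condition junction count matrix with known gene structure,
#' a junction-to-gene map, and a ground-truth table of spiked events.
#' Junctions never observed in any sample are dropped (as in real junction
#' quantification files). Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List of class `SimData`: `matrix` (a `JunctionCountMatrix` with
#'   gene assignments), `condition` (per-sample labels, control first),
#'   `gene_map`, `truth` (one row per spiked event: `class`, `gene_id`,
#'   `junction_id`, `true_rel_logfc`, `true_abs_logfc`), `config`.
#' @export
simulate_junction_counts <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n_genes <- cfg$n_genes
  jpg <- sample(seq(cfg$junctions_per_gene[1L], cfg$junctions_per_gene[2L]),
                n_genes, replace = TRUE)
  classes <- rep("background", n_genes)
  n_spiked <- cfg$n_usage + cfg$n_gene_de + cfg$n_combined + cfg$n_neojunction
  if (n_spiked > 0L)
    classes[seq_len(n_spiked)] <- rep(c("group1", "group2", "group3",
                                        "neojunction"),
                                      c(cfg$n_usage, cfg$n_gene_de,
                                        cfg$n_combined, cfg$n_neojunction))
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  gene_cpm <- exp(stats::rnorm(n_genes, cfg$gene_cpm_meanlog,
                               cfg$gene_cpm_sdlog))
  gene_cpm[classes != "background"] <- cfg$spike_gene_cpm

  n_s <- cfg$n_control + cfg$n_test
  condition <- rep(c("control", "test"), c(cfg$n_control, cfg$n_test))
  samples <- sprintf("%s_%02d", condition,
                     c(seq_len(cfg$n_control), seq_len(cfg$n_test)))
  lib <- round(stats::runif(n_s, cfg$libsize_range[1L], cfg$libsize_range[2L]))

  rows <- list(); truth <- list()
  pos <- 0L
  de_counter <- 0L
  for (g in seq_len(n_genes)) {
    J <- jpg[g]
    cls <- classes[g]
    # junction coordinates: consecutive introns along one chromosome
    start <- pos + seq_len(J) * 2000L
    end <- start + 700L
    pos <- max(end) + 5000L
    if (cls %in% c("group1", "group3", "neojunction")) {
      base <- c(cfg$spike_usage_base,
                (1 - cfg$spike_usage_base) * .rdirichlet1(J - 1L,
                                                          cfg$usage_concentration))
    } else {
      base <- .rdirichlet1(J, cfg$usage_concentration)
    }
    usage_control <- usage_test <- base
    cpm_control <- cpm_test <- gene_cpm[g]
    true_rel <- true_abs <- NA_real_
    if (cls %in% c("group1", "group3")) {
      delta <- if (cls == "group1") cfg$usage_delta else cfg$combined_delta
      p1 <- base[1L]
      p2 <- stats::plogis(stats::qlogis(p1) + delta)
      usage_test <- c(p2, base[-1L] * (1 - p2) / (1 - p1))
      true_rel <- (stats::qlogis(p2) - stats::qlogis(p1)) / log(2)
      true_abs <- log2(p2 / p1)
      if (cls == "group3") {
        cpm_test <- cpm_test * 2^cfg$combined_gene_logfc
        true_abs <- true_abs + cfg$combined_gene_logfc
      }
    } else if (cls == "group2") {
      de_i <- de_counter <- de_counter + 1L
      lfc <- rep_len(cfg$gene_de_logfc, cfg$n_gene_de)[de_i]
      cpm_test <- cpm_test * 2^lfc
      true_rel <- 0
      true_abs <- lfc
    } else if (cls == "neojunction") {
      p1 <- base[1L]
      usage_control <- c(0, base[-1L] / (1 - p1))
      true_rel <- NA_real_   # infinite by construction
      true_abs <- NA_real_
    }
    mu <- matrix(0, J, n_s)
    is_test <- condition == "test"
    mu[, !is_test] <- outer(usage_control * cpm_control, lib[!is_test]) / 1e6
    mu[, is_test] <- outer(usage_test * cpm_test, lib[is_test]) / 1e6
    cnt <- if (cfg$dispersion > 0) {
      matrix(stats::rnbinom(J * n_s, mu = mu, size = 1 / cfg$dispersion),
             J, n_s)
    } else {
      matrix(stats::rpois(J * n_s, lambda = mu), J, n_s)
    }
    jid <- format_junction_id("chr1", start, end, 1L)
    rownames(cnt) <- jid
    rows[[g]] <- cnt
    if (cls != "background")
      truth[[g]] <- data.frame(class = cls, gene_id = gene_ids[g],
                               junction_id = jid[1L],
                               true_rel_logfc = true_rel,
                               true_abs_logfc = true_abs,
                               stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  storage.mode(counts) <- "integer"
  colnames(counts) <- samples
  gene_map <- data.frame(
    junction_id = rownames(counts),
    gene_id = rep(gene_ids, jpg),
    annotated = TRUE, stringsAsFactors = FALSE)
  if (any(classes == "neojunction")) {
    neo_j <- vapply(which(classes == "neojunction"),
                    function(g) rownames(rows[[g]])[1L], character(1))
    gene_map$annotated[gene_map$junction_id %in% neo_j] <- FALSE
  }
  observed <- rowSums(counts) > 0
  counts <- counts[observed, , drop = FALSE]
  gene_map <- gene_map[observed, , drop = FALSE]
  m <- junction_count_matrix(counts)
  m <- apply_gene_map(m, gene_map)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(class = character(), gene_id = character(),
               junction_id = character(), true_rel_logfc = numeric(),
               true_abs_logfc = numeric())
  rownames(truth) <- NULL
  structure(list(matrix = m, condition = condition, gene_map = gene_map,
                 truth = truth, config = cfg),
            class = "SimData")
}

#' Simulate sample traits linked to expression
#'
#' Each numeric trait is `effect * standardized target expression +
#' N(0, noise_sd)`; the theoretical correlation with the target is
#' `effect / sqrt(effect^2 + noise_sd^2)`. Categorical traits threshold the
#' latent numeric trait at quantiles giving the requested level frequencies.
#' Uses the current RNG state (seed the caller).
#'
#' @param expr Expression matrix (features x samples); targets are rownames.
#' @param spec Data frame with columns `name`, `target` (rowname of `expr`),
#'   `effect`, `noise_sd`, and optionally `levels` (integer; > 0 makes the
#'   trait categorical with that many equal-frequency levels).
#' @return List with `traits` (data frame, samples in rows) and `truth`
#'   (the spec with the theoretical correlation added).
#' @export
simulate_traits <- function(expr, spec) {
  expr <- as.matrix(expr)
  missing <- setdiff(spec$target, rownames(expr))
  if (length(missing))
    stop("trait target(s) not in expression matrix: ",
         paste(missing, collapse = ", "))
  n <- ncol(expr)
  out <- list()
  rho <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    x <- as.numeric(scale(expr[spec$target[i], ]))
    latent <- spec$effect[i] * x + stats::rnorm(n, 0, spec$noise_sd[i])
    rho[i] <- spec$effect[i] / sqrt(spec$effect[i]^2 + spec$noise_sd[i]^2)
    k <- if ("levels" %in% names(spec)) spec$levels[i] else 0L
    if (!is.na(k) && !is.null(k) && k > 0L) {
      br <- stats::quantile(latent, probs = seq(0, 1, length.out = k + 1L))
      out[[spec$name[i]]] <- as.character(cut(latent, breaks = br,
                                              include.lowest = TRUE,
                                              labels = paste0("L", seq_len(k))))
    } else {
      out[[spec$name[i]]] <- latent
    }
  }
  traits <- as.data.frame(out, row.names = colnames(expr))
  truth <- cbind(spec, theoretical_rho = rho)
  list(traits = traits, truth = truth)
}

#' Write simulated counts as STAR SJ.out.tab files
#'
#' One 9-column file per sample, junctions sorted by coordinate; motif and
#' annotation columns are 0, the multi-mapping count is 0 and the overhang
#' 30. Zero-count junctions are omitted, as STAR does; re-importing the files
#' with [import_samples()] reproduces the simulated matrix exactly.
#'
#' @param m A `JunctionCountMatrix`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
simulate_star_files <- function(m, dir) {
  stopifnot(inherits(m, "JunctionCountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- m$meta
  ord <- order(meta$chrom, meta$start, meta$end, meta$strand)
  paths <- character(ncol(m$counts))
  names(paths) <- colnames(m$counts)
  for (s in seq_len(ncol(m$counts))) {
    cnt <- m$counts[ord, s]
    keep <- which(cnt > 0)
    nk <- length(keep)
    df <- data.frame(meta$chrom[ord][keep], meta$start[ord][keep],
                     meta$end[ord][keep], meta$strand[ord][keep],
                     rep(0L, nk), rep(0L, nk), cnt[keep], rep(0L, nk),
                     rep(30L, nk))
    path <- file.path(dir, paste0(colnames(m$counts)[s], ".SJ.out.tab"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[s] <- path
  }
  paths
}
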