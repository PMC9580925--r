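#' Build an intron index from a GTF annotation
#'
#' Every pair of consecutive exons of a transcript defines one intron
#' (upstream exon end + 1, downstream exon start - 1, both 1-based inclusive,
#' matching the STAR SJ.out.tab coordinate convention). Introns are
#' de-duplicated across transcripts; gene spans cover the exon extremes of
#' each gene. Transcripts with overlapping exons are skipped with a warning.
#'
#' @param gtf Path to a GTF file with `exon` features carrying `gene_id` and
#'   `transcript_id` attributes.
#' @return An object of class `IntronIndex`: list with data frames `introns`
#'   (`chrom`, `start`, `end`, `strand`, `gene_id`) and `gene_spans`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`). Strand is "+", "-" or "*".
#' @export
load_annotation <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) stop("no exon features found in ", gtf)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id),
    stringsAsFactors = FALSE)
  if (anyNA(df$gene_id) || anyNA(df$transcript_id))
    stop("exon features must carry gene_id and transcript_id attributes")
  introns <- list()
  for (tx in split(df, df$transcript_id)) {
    tx <- tx[order(tx$start, tx$end), , drop = FALSE]
    if (nrow(tx) < 2L) next
    if (any(tx$start[-1L] <= tx$end[-nrow(tx)])) {
      warning("transcript ", tx$transcript_id[1L],
              " has overlapping exons; skipped")
      next
    }
    introns[[tx$transcript_id[1L]]] <- data.frame(
      chrom = tx$chrom[1L],
      start = tx$end[-nrow(tx)] + 1L,
      end = tx$start[-1L] - 1L,
      strand = tx$strand[1L],
      gene_id = tx$gene_id[1L],
      stringsAsFactors = FALSE)
  }
  introns <- if (length(introns)) do.call(rbind, introns) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), gene_id = character())
  introns <- introns[introns$start <= introns$end, , drop = FALSE]
  introns <- unique(introns)
  rownames(introns) <- NULL
  spans <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1L], stringsAsFactors = FALSE)
  }))
  rownames(spans) <- NULL
  structure(list(introns = introns, gene_spans = spans), class = "IntronIndex")
}

#' @export
print.IntronIndex <- function(x, ...) {
  cat(sprintf("IntronIndex: %d introns, %d genes\n",
              nrow(x$introns), nrow(x$gene_spans)))
  invisible(x)
}

# strand compatibility: junction codes 0/1/2 vs annotation "+","-","*".
# Code 0 (undefined motif) is compatible with both strands.
.strand_compatible <- function(jcode, astrand) {
  jcode == 0L | astrand == "*" |
    (jcode == 1L & astrand == "+") | (jcode == 2L & astrand == "-")
}

#' Annotate junctions against an intron index
#'
#' A junction is `annotated` when its intron interval exactly matches an
#' annotated intron on a compatible strand. Gene assignment follows a fixed
#' priority: (1) exact intron match; (2) one shared splice site (same start or
#' same end coordinate) with an annotated intron, which marks the junction as
#' novel but within a known gene (`shares_splice_site`); (3) containment
#' within exactly the span of a gene. Ties at any step are broken by the
#' lexicographically smallest gene ID, so annotation is deterministic and
#' independent of input order. Unassignable junctions keep `gene_id = NA`.
#'
#' @param m A `JunctionCountMatrix`.
#' @param idx An `IntronIndex` from [load_annotation()].
#' @return `m` with the meta columns `gene_id`, `annotated` and
#'   `shares_splice_site` filled in.
#' @export
annotate_junctions <- function(m, idx) {
  stopifnot(inherits(m, "JunctionCountMatrix"), inherits(idx, "IntronIndex"))
  meta <- m$meta
  introns <- idx$introns
  gene_id <- rep(NA_character_, nrow(meta))
  annotated <- rep(FALSE, nrow(meta))
  shares <- rep(FALSE, nrow(meta))

  min_gene <- function(genes) sort(genes)[1L]
  if (nrow(introns) > 0L) {
    ikey <- paste(introns$chrom, introns$start, introns$end, sep = ":")
    jkey <- paste(meta$chrom, meta$start, meta$end, sep = ":")
    # (1) exact intron match
    for (j in seq_len(nrow(meta))) {
      hit <- which(ikey == jkey[j] &
                     .strand_compatible(meta$strand[j], introns$strand))
      if (length(hit)) {
        gene_id[j] <- min_gene(introns$gene_id[hit])
        annotated[j] <- TRUE
      }
    }
    # (2) shared splice site (donor or acceptor coordinate)
    todo <- which(!annotated)
    for (j in todo) {
      hit <- which(introns$chrom == meta$chrom[j] &
                     (introns$start == meta$start[j] |
                        introns$end == meta$end[j]) &
                     .strand_compatible(meta$strand[j], introns$strand))
      if (length(hit)) {
        gene_id[j] <- min_gene(introns$gene_id[hit])
        shares[j] <- TRUE
      }
    }
  }
  # (3) containment in a gene span
  spans <- idx$gene_spans
  todo <- which(is.na(gene_id))
  for (j in todo) {
    hit <- which(spans$chrom == meta$chrom[j] &
                   spans$start <= meta$start[j] &
                   spans$end >= meta$end[j] &
                   .strand_compatible(meta$strand[j], spans$strand))
    if (length(hit)) gene_id[j] <- min_gene(spans$gene_id[hit])
  }
  meta$gene_id <- gene_id
  meta$annotated <- annotated
  meta$shares_splice_site <- shares
  m$meta <- meta
  m
}

#' Assign genes from a precomputed junction-to-gene map
#'
#' Shortcut used with simulated data or externally annotated tables, where the
#' host gene of each junction is already known.
#'
#' @param m A `JunctionCountMatrix`.
#' @param gene_map Data frame with columns `junction_id` and `gene_id`
#'   (optionally `annotated`).
#' @return `m` with gene assignments filled in.
#' @export
apply_gene_map <- function(m, gene_map) {
  idx <- match(m$meta$junction_id, gene_map$junction_id)
  m$meta$gene_id <- gene_map$gene_id[idx]
  if ("annotated" %in% names(gene_map)) {
    ann <- gene_map$annotated[idx]
    m$meta$annotated <- !is.na(ann) & as.logical(ann)
  } else {
    m$meta$annotated <- !is.na(m$meta$gene_id)
  }
  m
}
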