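#' @title Junction count containers and junction quantification IO
#' @name junction_io
#' @description Readers and writers for per-sample splice-junction
#'   quantification files (STAR `SJ.out.tab` and generic two-column junction
#'   tables), the merged junction-by-sample count matrix, and the
#'   `chrom:start:end:strand` junction identifier convention.
NULL

STRAND_CODES <- c(undefined = 0L, plus = 1L, minus = 2L)

#' Construct a junction count matrix
#'
#' The central container of the package: an integer matrix of junction read
#' counts (junctions in rows, samples in columns) together with per-junction
#' metadata (coordinates, strand code, host gene, annotation status).
#'
#' @param counts Non-negative integer matrix; rownames are junction IDs of the
#'   form `chrom:start:end:strand`, colnames are unique sample IDs.
#' @param meta Optional data frame aligned with the rows of `counts`. When
#'   omitted it is derived by parsing the rownames.
#' @return An object of class `JunctionCountMatrix`: a list with elements
#'   `counts` and `meta`.
#' @export
junction_count_matrix <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry junction rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate junction IDs in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs in count matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(meta)) {
    meta <- parse_junction_id(rownames(counts))
    meta <- data.frame(junction_id = rownames(counts), meta,
                       gene_id = NA_character_, annotated = FALSE,
                       shares_splice_site = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(meta) != nrow(counts))
    stop("meta rows must align 1:1 with junctions")
  rownames(meta) <- meta$junction_id
  structure(list(counts = counts, meta = meta), class = "JunctionCountMatrix")
}

#' @export
print.JunctionCountMatrix <- function(x, ...) {
  cat(sprintf("JunctionCountMatrix: %d junctions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  annotated: %d, novel: %d, with gene: %d\n",
              sum(x$meta$annotated), sum(!x$meta$annotated),
              sum(!is.na(x$meta$gene_id))))
  invisible(x)
}

#' @export
dim.JunctionCountMatrix <- function(x) dim(x$counts)

#' Parse junction identifiers
#'
#' Junction IDs follow the convention `chrom:start:end:strand` where `start`
#' and `end` are the first and last intronic base (1-based, inclusive) and the
#' strand is coded 0 (undefined), 1 (plus) or 2 (minus).
#'
#' @param text Character vector of junction IDs.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' parse_junction_id("chr1:123:456:1")
#' @export
parse_junction_id <- function(text) {
  text <- as.character(text)
  parts <- strsplit(text, ":", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    bad <- text[which(nf != 4L)[1L]]
    stop("malformed junction ID '", bad,
         "': expected 4 colon-delimited fields chrom:start:end:strand")
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  strand <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(start)) stop("non-integer start coordinate in junction ID '",
                         text[which(is.na(start))[1L]], "'")
  if (anyNA(end)) stop("non-integer end coordinate in junction ID '",
                       text[which(is.na(end))[1L]], "'")
  if (anyNA(strand) || any(!strand %in% 0:2))
    stop("strand code must be 0, 1 or 2 in junction ID '",
         text[which(is.na(strand) | !strand %in% 0:2)[1L]], "'")
  if (any(start < 1L)) stop("start must be >= 1 in junction ID '",
                            text[which(start < 1L)[1L]], "'")
  if (any(start > end)) stop("start > end in junction ID '",
                             text[which(start > end)[1L]], "'")
  data.frame(chrom = m[, 1L], start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Format junction identifiers
#'
#' Inverse of [parse_junction_id()]: formatting a parsed ID reproduces the
#' original string.
#'
#' @param chrom,start,end,strand Components, or a data frame with those
#'   columns passed as `chrom`.
#' @return Character vector of junction IDs.
#' @export
format_junction_id <- function(chrom, start = NULL, end = NULL, strand = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(paste(df$chrom, df$start, df$end, df$strand, sep = ":"))
  }
  paste(chrom, start, end, strand, sep = ":")
}

#' Read a STAR SJ.out.tab junction file
#'
#' Nine tab-delimited columns: chromosome, intron start (1-based), intron end
#' (inclusive), strand code (0/1/2), intron motif code, annotation flag,
#' uniquely-mapping read count, multi-mapping read count, maximum overhang.
#' Only the uniquely-mapping count (column 7) is used; multi-mappers are
#' ignored as potentially unreliable evidence.
#'
#' @param path Path to an SJ.out.tab-format file.
#' @return Data frame with columns `junction_id`, `chrom`, `start`, `end`,
#'   `strand`, `count`, in file order.
#' @export
read_star_sj <- function(path) {
  if (!file.exists(path)) stop("cannot read junction file: ", path)
  if (file.size(path) == 0)
    return(data.frame(junction_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, colClasses = "character"),
    error = function(e) stop("cannot read junction file ", path, ": ",
                             conditionMessage(e)))
  if (ncol(raw) != 9L)
    stop(path, ": expected 9 tab-delimited columns, found ", ncol(raw))
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  strand <- suppressWarnings(as.integer(raw[[4L]]))
  count <- suppressWarnings(as.integer(raw[[7L]]))
  for (nm in c("start", "end", "strand", "count")) {
    v <- get(nm)
    if (anyNA(v))
      stop(path, " line ", which(is.na(v))[1L], ": non-integer ", nm)
  }
  if (any(count < 0L))
    stop(path, " line ", which(count < 0L)[1L], ": negative count")
  if (any(!strand %in% 0:2))
    stop(path, " line ", which(!strand %in% 0:2)[1L], ": invalid strand code")
  ids <- format_junction_id(raw[[1L]], start, end, strand)
  if (anyDuplicated(ids)) {
    d <- which(duplicated(ids))[1L]
    stop(path, " line ", d, ": duplicate junction ", ids[d])
  }
  data.frame(junction_id = ids, chrom = raw[[1L]], start = start, end = end,
             strand = strand, count = count, stringsAsFactors = FALSE)
}

#' Read a generic junction count table
#'
#' Two tab-delimited columns with header `junction_id` and `count`; junction
#' IDs must follow the `chrom:start:end:strand` convention.
#'
#' @param path Path to the table.
#' @return Data frame in the same shape as [read_star_sj()].
#' @export
read_junction_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("junction_id", "count") %in% names(tab)))
    stop(path, ": expected columns 'junction_id' and 'count'")
  if (anyDuplicated(tab$junction_id)) {
    d <- tab$junction_id[duplicated(tab$junction_id)][1L]
    stop(path, ": duplicate junction ", d)
  }
  coords <- parse_junction_id(tab$junction_id)
  if (any(tab$count < 0)) stop(path, ": negative count")
  data.frame(junction_id = tab$junction_id, coords,
             count = as.integer(tab$count), stringsAsFactors = FALSE)
}

#' Import and merge per-sample junction files
#'
#' Builds the junction-by-sample count matrix over the union of junctions seen
#' in any sample; junctions missing from a sample get count 0. Junctions are
#' sorted by (chrom, start, end, strand) for deterministic output.
#'
#' @param paths Character vector of file paths (SJ.out.tab or generic tables).
#' @param sample_ids Unique sample identifiers, one per path.
#' @param format `"star"` (default) or `"table"`.
#' @return A [junction_count_matrix()].
#' @export
import_samples <- function(paths, sample_ids = NULL, format = c("star", "table")) {
  format <- match.arg(format)
  if (length(paths) < 1L) stop("at least one junction file is required")
  if (is.null(sample_ids))
    sample_ids <- tools::file_path_sans_ext(basename(paths))
  if (length(sample_ids) != length(paths))
    stop("paths and sample_ids must have the same length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  reader <- if (format == "star") read_star_sj else read_junction_table
  tabs <- lapply(paths, reader)
  all_j <- unique(unlist(lapply(tabs, `[[`, "junction_id"), use.names = FALSE))
  coords <- parse_junction_id(all_j)
  ord <- order(coords$chrom, coords$start, coords$end, coords$strand)
  all_j <- all_j[ord]
  counts <- matrix(0L, nrow = length(all_j), ncol = length(paths),
                   dimnames = list(all_j, sample_ids))
  for (i in seq_along(tabs)) {
    idx <- match(tabs[[i]]$junction_id, all_j)
    counts[idx, i] <- tabs[[i]]$count
  }
  junction_count_matrix(counts)
}

#' Write / read the merged count matrix as TSV
#'
#' First column `junction_id`, then one integer column per sample.
#'
#' @param m A `JunctionCountMatrix`.
#' @param path Output path.
#' @return `path`, invisibly (writer); a `JunctionCountMatrix` (reader).
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(junction_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1L]]
  junction_count_matrix(counts)
}
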