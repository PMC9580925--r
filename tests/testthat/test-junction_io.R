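test_that("junction ID parsing and formatting are inverse operations", {
  p <- parse_junction_id("chr1:123:456:1")
  expect_equal(p$chrom, "chr1")
  expect_equal(p$start, 123L)
  expect_equal(p$end, 456L)
  expect_equal(p$strand, 1L)
  # single-base intron boundary case: start == end is allowed
  p2 <- parse_junction_id("chrX:10:10:2")
  expect_equal(unlist(p2, use.names = FALSE), c("chrX", "10", "10", "2"))
  ids <- c("chr1:123:456:1", "chrX:10:10:2", "chr2_random:5:9:0")
  expect_identical(format_junction_id(parse_junction_id(ids)), ids)
})

test_that("malformed junction IDs are rejected with the offending field", {
  expect_error(parse_junction_id("chr2:456:123:1"), "start > end")
  expect_error(parse_junction_id("chr1:1:2"), "4 colon-delimited fields")
  expect_error(parse_junction_id("chr1:a:2:1"), "non-integer start")
  expect_error(parse_junction_id("chr1:1:2:7"), "strand code")
  expect_error(parse_junction_id("chr1:0:2:1"), "start must be >= 1")
})

test_that("read_star_sj extracts the uniquely-mapping count column", {
  f <- tempfile()
  writeLines(c("chr1\t100\t200\t1\t1\t1\t42\t3\t30",
               "chr2\t50\t80\t2\t0\t0\t7\t0\t12"), f)
  tab <- read_star_sj(f)
  expect_equal(tab$junction_id, c("chr1:100:200:1", "chr2:50:80:2"))
  expect_equal(tab$count, c(42L, 7L))   # column 7, not the multi-mapper count

  writeLines(character(), f)
  expect_equal(nrow(read_star_sj(f)), 0L)

  writeLines(c("chr1\t100\t200\t1\t1\t1\t42\t3\t30",
               "chr1\t100\t200\t1\t1\t1\t10\t0\t30"), f)
  expect_error(read_star_sj(f), "duplicate junction")

  writeLines("chr1\t100\t200\t1\t1", f)
  expect_error(read_star_sj(f), "9 tab-delimited columns")

  writeLines("chr1\t100\t200\t1\t1\t1\t-5\t3\t30", f)
  expect_error(read_star_sj(f), "negative count")
})

test_that("import_samples unions junctions with zero fill and sorts rows", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("chr1\t100\t200\t1\t0\t0\t5\t0\t30",
               "chr1\t300\t400\t1\t0\t0\t8\t0\t30"), f1)  # junctions A, B
  writeLines(c("chr1\t300\t400\t1\t0\t0\t2\t0\t30",
               "chr2\t10\t20\t2\t0\t0\t9\t0\t30"), f2)    # junctions B, C
  m <- import_samples(c(f1, f2), c("s1", "s2"))
  expect_equal(dim(m$counts), c(3L, 2L))
  expect_equal(m$counts["chr1:100:200:1", ], c(s1 = 5L, s2 = 0L))
  expect_equal(m$counts["chr1:300:400:1", ], c(s1 = 8L, s2 = 2L))
  expect_equal(m$counts["chr2:10:20:2", ], c(s1 = 0L, s2 = 9L))

  m1 <- import_samples(f1, "only")
  expect_equal(unname(m1$counts[, 1]), c(5L, 8L))

  expect_error(import_samples(c(f1, f2), c("s", "s")), "duplicate sample")
  expect_error(import_samples(character(), character()), "at least one")
})

test_that("simulated SJ files round-trip bit-exactly through import", {
  cfg <- sim_config(n_genes = 10, n_test = 5, n_control = 5, seed = 42)
  sim <- simulate_junction_counts(cfg)
  dir <- tempfile(); paths <- simulate_star_files(sim$matrix, dir)
  m2 <- import_samples(paths, names(paths))
  expect_identical(m2$counts, sim$matrix$counts)
  # files are sorted by coordinate, as STAR writes them
  tab <- read_star_sj(paths[1])
  expect_false(is.unsorted(tab$start))
})

test_that("load_annotation derives introns from consecutive exons", {
  gtf <- write_test_gtf(list(
    "GENE1|T1" = data.frame(start = c(1, 201), end = c(100, 300))))
  idx <- load_annotation(gtf)
  expect_equal(nrow(idx$introns), 1L)
  expect_equal(idx$introns$start, 101L)
  expect_equal(idx$introns$end, 200L)
  expect_equal(idx$introns$strand, "+")

  # two transcripts sharing an intron: de-duplicated
  gtf2 <- write_test_gtf(list(
    "GENE1|T1" = data.frame(start = c(1, 201), end = c(100, 300)),
    "GENE1|T2" = data.frame(start = c(1, 201), end = c(100, 350))))
  expect_equal(nrow(load_annotation(gtf2)$introns), 1L)

  # 3-exon transcript: exactly the two hand-enumerated introns
  gtf3 <- write_test_gtf(list(
    "GENE2|T3" = data.frame(start = c(10, 500, 900), end = c(99, 600, 1000))))
  idx3 <- load_annotation(gtf3)
  expect_equal(idx3$introns[, c("start", "end")],
               data.frame(start = c(100L, 601L), end = c(499L, 899L)))
  expect_equal(idx3$gene_spans$start, 10L)
  expect_equal(idx3$gene_spans$end, 1000L)
})

test_that("transcripts with overlapping exons are skipped with a warning", {
  gtf <- write_test_gtf(list(
    "GENE1|T1" = data.frame(start = c(1, 50), end = c(100, 200))))
  expect_warning(idx <- load_annotation(gtf), "overlapping exons")
  expect_equal(nrow(idx$introns), 0L)
  gtf_none <- tempfile(fileext = ".gtf")
  writeLines("chr1\ttest\tgene\t1\t100\t.\t+\t.\tgene_id \"G\";", gtf_none)
  expect_error(load_annotation(gtf_none), "no exon features")
})

test_that("annotation follows exact / shared-site / span priority", {
  gtf <- write_test_gtf(list(
    "GENEA|TA" = data.frame(start = c(1, 201, 401), end = c(100, 300, 500)),
    "GENEB|TB" = data.frame(start = c(1000, 1501), end = c(1200, 1700))))
  idx <- load_annotation(gtf)
  ids <- c("chr1:101:200:1",    # exact intron of GENEA
           "chr1:101:250:1",    # shares only the donor coordinate
           "chr1:1210:1400:1",  # inside GENEB span, no shared site
           "chr1:9000:9100:1")  # nowhere
  counts <- matrix(5L, 4, 2, dimnames = list(ids, c("s1", "s2")))
  m <- annotate_junctions(junction_count_matrix(counts), idx)
  expect_equal(m$meta$gene_id, c("GENEA", "GENEA", "GENEB", NA))
  expect_equal(m$meta$annotated, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(m$meta$shares_splice_site, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("overlapping gene spans resolve to the smaller gene ID", {
  gtf <- write_test_gtf(list(
    "GENEZ|TZ" = data.frame(start = c(1, 901), end = c(100, 1000)),
    "GENEM|TM" = data.frame(start = c(1, 901), end = c(100, 1000))))
  idx <- load_annotation(gtf)
  counts <- matrix(1L, 1, 2,
                   dimnames = list("chr1:150:880:1", c("s1", "s2")))
  m <- annotate_junctions(junction_count_matrix(counts), idx)
  expect_equal(m$meta$gene_id, "GENEM")
})

test_that("strand code 0 is compatible with both annotated strands", {
  gtf <- write_test_gtf(list(
    "GENEN|TN" = data.frame(start = c(1, 201), end = c(100, 300),
                            strand = "-")))
  idx <- load_annotation(gtf)
  counts <- matrix(1L, 2, 2, dimnames = list(
    c("chr1:101:200:0", "chr1:101:200:1"), c("s1", "s2")))
  m <- annotate_junctions(junction_count_matrix(counts), idx)
  expect_true(m$meta$annotated[1])    # undefined strand matches minus intron
  expect_false(m$meta$annotated[2])   # plus junction does not
})

test_that("annotation is idempotent and independent of junction order", {
  set.seed(5)
  gtf <- write_test_gtf(list(
    "G1|T1" = data.frame(start = c(1, 201, 401), end = c(100, 300, 500)),
    "G2|T2" = data.frame(start = c(2000, 2501), end = c(2200, 2600))))
  idx <- load_annotation(gtf)
  # every junction matching an index intron must come out annotated
  ids <- with(idx$introns, sprintf("chr1:%d:%d:1", start, end))
  extra <- c("chr1:50:60:1", "chr1:2300:2400:0")
  all_ids <- c(ids, extra)
  counts <- matrix(3L, length(all_ids), 2,
                   dimnames = list(all_ids, c("a", "b")))
  m <- annotate_junctions(junction_count_matrix(counts), idx)
  expect_true(all(m$meta[ids, "annotated"]))
  m_again <- annotate_junctions(m, idx)
  expect_identical(m$meta, m_again$meta)
  perm <- sample(length(all_ids))
  mp <- annotate_junctions(junction_count_matrix(counts[perm, ]), idx)
  expect_identical(mp$meta[all_ids, ], m$meta[all_ids, ])
})

test_that("count matrix TSV writer and reader round-trip", {
  cfg <- sim_config(n_genes = 6, n_test = 3, n_control = 3, seed = 3)
  sim <- simulate_junction_counts(cfg)
  f <- tempfile()
  write_count_matrix(sim$matrix, f)
  m2 <- read_count_matrix(f)
  expect_identical(m2$counts, sim$matrix$counts)
})
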