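test_that("parse_annotation keeps exons of the requested biotype and errors on empty results", {
  gtf <- tempfile(fileext = ".gtf")
  df <- rbind(
    data.frame(contig = "chr1", start = c(101L, 301L, 601L),
               end = c(200L, 400L, 700L), strand = "+",
               gene_id = "gPC", transcript_id = "gPC.t1",
               biotype = "protein_coding"),
    data.frame(contig = "chr1", start = c(5000L, 5500L),
               end = c(5200L, 5700L), strand = "+",
               gene_id = "gNC", transcript_id = "gNC.t1",
               biotype = "lncRNA"))
  write_test_gtf(df, gtf)
  ex <- parse_annotation(gtf, "protein_coding")
  expect_length(ex, 3L)
  expect_setequal(unique(ex$gene_id), "gPC")
  # 1-based GTF coordinates are preserved in the GRanges representation
  expect_equal(GenomicRanges::start(ex)[1], 101L)
  expect_equal(GenomicRanges::end(ex)[1], 200L)
  ex_all <- parse_annotation(gtf, NULL)
  expect_length(ex_all, 5L)
  expect_error(parse_annotation(gtf, "miRNA"), "no exons left")
})

test_that("parse_annotation preserves minus-strand records and warns on missing biotype", {
  gtf <- tempfile(fileext = ".gtf")
  df <- data.frame(contig = "chr2", start = c(100L, 500L),
                   end = c(200L, 600L), strand = "-",
                   gene_id = "gM", transcript_id = "gM.t1")
  write_test_gtf(df, gtf, with_biotype = FALSE)
  expect_warning(ex <- parse_annotation(gtf, "protein_coding"),
                 "gene_biotype")
  expect_true(all(as.character(GenomicRanges::strand(ex)) == "-"))
})

test_that("transcript_ends respects strand and rejects mixed-strand transcripts", {
  mk <- function(strand) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101L, 501L), c(200L, 600L)), strand = strand,
    gene_id = "g", transcript_id = "t")
  plus <- transcript_ends(mk("+"))
  expect_equal(plus$tss, 101L)
  expect_equal(plus$tes, 600L)
  minus <- transcript_ends(mk("-"))
  expect_equal(minus$tss, 600L)
  expect_equal(minus$tes, 101L)
  single <- transcript_ends(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1L, 50L), strand = "+",
    gene_id = "g", transcript_id = "t"))
  expect_equal(c(single$tss, single$tes), c(1L, 50L))
  mixed <- mk("+")
  GenomicRanges::strand(mixed)[2] <- "-"
  expect_error(transcript_ends(mixed), "mixed strand")
})

test_that("cluster_positions merges by gap, chains, and picks modal 5'-most representatives", {
  cl <- cluster_positions(c(100L, 130L, 400L), 50)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$positions, c(100L, 130L))
  expect_equal(cl[[2]]$positions, 400L)
  # chaining: each consecutive gap <= window merges even if the span exceeds it
  chained <- cluster_positions(c(0L, 50L, 100L), 50)
  expect_length(chained, 1L)
  expect_equal(chained[[1]]$positions, c(0L, 50L, 100L))
  expect_equal(cluster_positions(7L, 1000)[[1]]$representative, 7L)
  # multiplicity wins; ties break to the transcriptional 5' side
  modal <- cluster_positions(c(10L, 20L, 20L), 50)
  expect_equal(modal[[1]]$representative, 20L)
  tie_plus <- cluster_positions(c(10L, 40L), 50, strand = "+")
  expect_equal(tie_plus[[1]]$representative, 10L)
  tie_minus <- cluster_positions(c(10L, 40L), 50, strand = "-")
  expect_equal(tie_minus[[1]]$representative, 40L)
})

test_that("clustering matches the brute-force single-linkage oracle on fuzzed inputs", {
  withr::with_seed(404, {
    for (i in 1:60) {
      n <- sample(1:50, 1)
      pos <- sample.int(2000L, n, replace = TRUE)
      w <- sample(0:100, 1)
      got <- lapply(cluster_positions(pos, w), `[[`, "positions")
      expect_identical(got, oracle_single_linkage(pos, w))
      # permutation invariance
      got2 <- lapply(cluster_positions(pos[sample.int(length(pos))], w),
                     `[[`, "positions")
      expect_identical(got2, got)
    }
  })
})

test_that("widening the window only coarsens the clustering", {
  withr::with_seed(405, {
    pos <- sample.int(5000L, 40, replace = TRUE)
    sizes <- vapply(c(0, 10, 50, 200, 1000),
                    function(w) length(cluster_positions(pos, w)),
                    integer(1))
    expect_true(all(diff(sizes) <= 0))
  })
})

test_that("prepare_isoform_database clusters ends with separate windows and enumerates pairs", {
  gtf <- tempfile(fileext = ".gtf")
  # TSSs 1000/1020 (gap 20 <= 50 -> one cluster); TESs 5000/5400 (gap
  # 400 > 150 -> two clusters)
  df <- rbind(
    data.frame(contig = "chr1", start = c(1000L, 3000L), end = c(1500L, 5000L),
               strand = "+", gene_id = "g1", transcript_id = "g1.t1"),
    data.frame(contig = "chr1", start = c(1020L, 3000L), end = c(1500L, 5400L),
               strand = "+", gene_id = "g1", transcript_id = "g1.t2"))
  write_test_gtf(df, gtf)
  db <- prepare_isoform_database(parse_annotation(gtf), 50, 150)
  expect_equal(sum(db$clusters$kind == "TSS"), 1L)
  expect_equal(sum(db$clusters$kind == "TES"), 2L)
  expect_equal(nrow(db$pairs), 2L)
  # window 0 separates the TSSs and doubles the pairs
  db0 <- prepare_isoform_database(parse_annotation(gtf), 0, 150)
  expect_equal(sum(db0$clusters$kind == "TSS"), 2L)
  expect_equal(nrow(db0$pairs), 4L)
  # one-transcript gene: 1 TSS, 1 TES, 1 pair
  gtf1 <- tempfile(fileext = ".gtf")
  write_test_gtf(data.frame(contig = "chr1", start = 100L, end = 900L,
                            strand = "+", gene_id = "g", transcript_id = "t"),
                 gtf1)
  db1 <- prepare_isoform_database(parse_annotation(gtf1))
  expect_equal(nrow(db1$clusters), 2L)
  expect_equal(nrow(db1$pairs), 1L)
})

test_that("pair count equals the TSS x TES cross-product and cluster ids follow transcriptional order", {
  cfg <- sim_config(n_genes = 6, n_tss = 3, n_tes = 2, n_reads = 0, seed = 2)
  ann <- generate_annotation(cfg)
  db <- prepare_isoform_database(ann$exons)
  cl <- as.data.frame(db$clusters)
  for (g in unique(cl$gene_id)) {
    n_tss <- sum(cl$gene_id == g & cl$kind == "TSS")
    n_tes <- sum(cl$gene_id == g & cl$kind == "TES")
    expect_equal(sum(db$pairs$gene_id == g), n_tss * n_tes)
    # ids ordered 5'->3' in transcriptional direction
    tss <- cl[cl$gene_id == g & cl$kind == "TSS", ]
    tss <- tss[order(tss$cluster_id), ]
    expect_true(all(diff(tss$representative) *
                      ifelse(tss$strand[1] == "+", 1, -1) > 0))
  }
})

test_that("database round-trips through its TSV serialization", {
  cfg <- sim_config(n_genes = 3, n_reads = 0, seed = 9)
  ann <- generate_annotation(cfg)
  db <- prepare_isoform_database(ann$exons)
  dir <- tempfile()
  write_isoform_database(db, dir)
  back <- read_isoform_database(dir)
  expect_equal(as.data.frame(back$clusters), as.data.frame(db$clusters))
  expect_equal(as.data.frame(back$pairs), as.data.frame(db$pairs))
  expect_equal(as.data.frame(back$genes), as.data.frame(db$genes))
  expect_equal(back$params, db$params)
  gff <- tempfile(fileext = ".gff3")
  export_database_gff(db, gff)
  reimported <- rtracklayer::import(gff)
  expect_equal(length(reimported), nrow(db$clusters))
})

test_that("add_end_database absorbs nearby ends and founds new clusters otherwise", {
  gtf <- tempfile(fileext = ".gtf")
  df <- rbind(
    data.frame(contig = "chr1", start = c(1000L, 3000L), end = c(1500L, 5000L),
               strand = "+", gene_id = "g1", transcript_id = "g1.t1"),
    data.frame(contig = "chr1", start = c(1000L, 3000L), end = c(1500L, 5400L),
               strand = "+", gene_id = "g1", transcript_id = "g1.t2"))
  write_test_gtf(df, gtf)
  db <- prepare_isoform_database(parse_annotation(gtf))
  n_tss0 <- sum(db$clusters$kind == "TSS")
  # 30 nt from the TSS representative, within window 50 -> absorbed
  near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1030L, 1030L),
                                 strand = "+")
  db_a <- add_end_database(db, near, "TSS")
  expect_equal(sum(db_a$clusters$kind == "TSS"), n_tss0)
  expect_equal(db_a$merge_stats$absorbed, 1L)
  # mid-gene, far from all clusters -> new cluster, pairs re-enumerated
  mid <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2500L, 2500L),
                                strand = "+")
  db_n <- add_end_database(db, mid, "TSS")
  expect_equal(sum(db_n$clusters$kind == "TSS"), n_tss0 + 1L)
  expect_equal(nrow(db_n$pairs),
               (n_tss0 + 1L) * sum(db_n$clusters$kind == "TES"))
  # off-gene record is counted as unassigned
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90000L, 90000L),
                                strand = "+")
  db_f <- add_end_database(db, far, "TSS")
  expect_equal(db_f$merge_stats$unassigned, 1L)
  # empty external set is the identity
  empty <- GenomicRanges::GRanges()
  expect_identical(add_end_database(db, empty, "TSS"), db)
  # kind mismatch with annotated records is a usage error
  ann_kind <- near
  ann_kind$kind <- "TES"
  expect_error(add_end_database(db, ann_kind, "TSS"), "kind")
})
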