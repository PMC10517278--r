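write_sj_file <- function(rows, path = tempfile(fileext = ".tab")) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

test_that("parse_star_sj filters by support, converts strand codes and drops undefined strands", {
  sj <- write_sj_file(list(
    c("chr2L", 100, 200, 1, 1, 1, 5, 0, 30),   # kept, '+'
    c("chr2L", 300, 400, 2, 2, 1, 2, 3, 25),   # kept, '-'
    c("chr2L", 500, 600, 1, 1, 0, 1, 9, 20),   # dropped: unique 1 < 2
    c("chr2L", 700, 800, 0, 0, 0, 50, 0, 20))) # dropped: undefined strand
  gr <- parse_star_sj(sj, min_jcounts = 2)
  expect_length(gr, 2L)
  expect_equal(GenomicRanges::start(gr), c(100L, 300L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))
  expect_equal(gr$short_read_count, c(5L, 2L))
  expect_equal(S4Vectors::metadata(gr)$undefined_strand_dropped, 1L)
  bad <- write_sj_file(list(c("chr1", 1, 2, 1)))
  expect_error(parse_star_sj(bad), "9")
})

test_that("create_reference_junctions merges annotation and short-read junctions with support flags", {
  gtf <- tempfile(fileext = ".gtf")
  df <- data.frame(contig = "chr1", start = c(100L, 500L), end = c(200L, 700L),
                   strand = "+", gene_id = "g", transcript_id = "g.t1")
  write_test_gtf(df, gtf)
  exons <- parse_annotation(gtf)
  # annotation implies intron 201..499; SJ adds the same plus a novel one
  sj <- write_sj_file(list(
    c("chr1", 201, 499, 1, 1, 1, 9, 0, 30),
    c("chr1", 220, 480, 1, 1, 0, 4, 0, 30),
    c("chr1", 230, 470, 1, 1, 0, 1, 0, 30)))  # below min_jcounts
  jdb <- create_reference_junctions(sj, exons, type = "short",
                                    min_jcounts = 2)
  expect_length(jdb$junctions, 2L)
  both <- jdb$junctions[jdb$junctions$support == "both"]
  expect_equal(GenomicRanges::start(both), 201L)
  expect_equal(both$short_read_count, 9L)
  expect_equal(
    GenomicRanges::start(jdb$junctions[jdb$junctions$support == "short_read"]),
    220L)
  # type = "annotation" ignores the SJ file entirely
  jdb_a <- create_reference_junctions(sj, exons, type = "annotation")
  expect_length(jdb_a$junctions, 1L)
  expect_equal(jdb_a$junctions$support, "annotation")
})

test_that("correct_junctions snaps within tolerance, rejects novel and ambiguous introns", {
  gtf <- tempfile(fileext = ".gtf")
  write_test_gtf(data.frame(contig = "chr1", start = c(100L, 1601L),
                            end = c(600L, 2000L), strand = "+",
                            gene_id = "g", transcript_id = "g.t"), gtf)
  jdb <- create_reference_junctions(NULL, parse_annotation(gtf),
                                    type = "annotation")
  # reference intron is 601..1600
  noisy <- GenomicRanges::GRanges("chr1", IRanges::IRanges(604L, 1597L),
                                  strand = "+")
  res <- correct_junctions(noisy, jdb, tol = 10)
  expect_equal(res$status, "snapped")
  expect_equal(GenomicRanges::start(res$chain), 601L)
  expect_equal(GenomicRanges::end(res$chain), 1600L)
  exact <- GenomicRanges::GRanges("chr1", IRanges::IRanges(601L, 1600L),
                                  strand = "+")
  res_e <- correct_junctions(exact, jdb, tol = 10)
  expect_equal(res_e$status, "exact")
  expect_equal(GenomicRanges::start(res_e$chain), 601L)
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(650L, 1550L),
                                strand = "+")
  res_f <- correct_junctions(far, jdb, tol = 10)
  expect_equal(res_f$status, "rejected")
  expect_equal(res_f$reason, "novel_junction")
})

test_that("ambiguous matches reject unless snap_closest is requested", {
  gtf <- tempfile(fileext = ".gtf")
  df <- rbind(
    data.frame(contig = "chr1", start = c(100L, 1601L), end = c(600L, 2000L),
               strand = "+", gene_id = "g", transcript_id = "g.t1"),
    data.frame(contig = "chr1", start = c(100L, 1607L), end = c(606L, 2000L),
               strand = "+", gene_id = "g", transcript_id = "g.t2"))
  write_test_gtf(df, gtf)
  jdb <- create_reference_junctions(NULL, parse_annotation(gtf),
                                    type = "annotation")  # 601..1600, 607..1606
  mid <- GenomicRanges::GRanges("chr1", IRanges::IRanges(603L, 1602L),
                                strand = "+")
  res <- correct_junctions(mid, jdb, tol = 10)
  expect_equal(res$status, "rejected")
  expect_equal(res$reason, "ambiguous_junction")
  res_c <- correct_junctions(mid, jdb, tol = 10, snap_closest = TRUE)
  expect_equal(res_c$status, "snapped")
  expect_equal(GenomicRanges::start(res_c$chain), 601L)
})

test_that("correction is bounded by tol, partitions reads, and is monotone in tol", {
  cfg <- sim_config(n_genes = 3, n_reads = 80, junction_noise = 6,
                    truncation_fraction = 0, seed = 101)
  ann <- generate_annotation(cfg)
  db <- prepare_isoform_database(ann$exons)
  bam <- tempfile(fileext = ".bam")
  simulate_reads(cfg, ann, bam)
  jdb <- create_reference_junctions(NULL, ann$exons, type = "annotation")
  stats_at <- function(tol) {
    elc <- read_to_junctions(bam, jdb, db, tol = tol)
    cs <- elc$correction_stats
    expect_equal(cs$exact + cs$snapped + cs$rejected, nrow(elc$reads))
    cs
  }
  cs0 <- stats_at(0)
  cs3 <- stats_at(3)
  cs6 <- stats_at(6)
  cs12 <- stats_at(12)
  accepted <- function(cs) cs$exact + cs$snapped
  expect_lte(accepted(cs0), accepted(cs3))
  expect_lte(accepted(cs3), accepted(cs6))
  expect_lte(accepted(cs6), accepted(cs12))
  # with tol at the noise bound every read is accepted and no boundary
  # moves by more than tol
  expect_equal(cs6$rejected, 0L)
  elc <- read_to_junctions(bam, jdb, db, tol = 6)
  ref <- jdb$junctions
  for (ch in strsplit(elc$reads$chain[elc$reads$chain != ""], ";")) {
    for (iv in ch) {
      se <- as.integer(strsplit(iv, "-")[[1]])
      expect_true(any(GenomicRanges::start(ref) == se[1] &
                        GenomicRanges::end(ref) == se[2]))
    }
  }
})

test_that("corrected chains equal simulated truth when tol covers the noise", {
  cfg <- sim_config(n_genes = 2, n_reads = 60, junction_noise = 4,
                    truncation_fraction = 0, end_jitter_sd = 0, seed = 111)
  ann <- generate_annotation(cfg)
  db <- prepare_isoform_database(ann$exons)
  bam <- tempfile(fileext = ".bam")
  sim <- simulate_reads(cfg, ann, bam)
  jdb <- create_reference_junctions(NULL, ann$exons, type = "annotation")
  elc <- read_to_junctions(bam, jdb, db, tol = 4)
  m <- merge(elc$reads, sim$truth, by = "read_id",
             suffixes = c("", ".true"))
  expect_true(all(m$status != "rejected"))
  expect_equal(m$chain, m$chain.true)
})

test_that("junction-TSS coupling is detected with truthful residual signs", {
  incl <- matrix(c(0.9, 1, 0.1, 1), 2, 2, byrow = TRUE)
  cfg <- sim_config(n_genes = 2, n_reads = 200, exon_inclusion = incl,
                    truncation_fraction = 0, junction_noise = 3, seed = 121)
  ann <- generate_annotation(cfg)
  exons <- ann$exons
  db <- prepare_isoform_database(exons)
  bam <- tempfile(fileext = ".bam")
  sj <- tempfile(fileext = ".tab")
  simulate_reads(cfg, ann, bam)
  write_star_sj(cfg, ann, sj, support = 50, n_decoys = 2, decoy_count = 1)
  jdb <- create_reference_junctions(sj, exons, type = "short",
                                    min_jcounts = 2)
  # decoys below min_jcounts never enter the reference
  expect_length(jdb$junctions, 8L)
  elc <- read_to_junctions(bam, jdb, db, tol = 10)
  res <- calculate_exon_couplings(elc, jdb, B = 2000, seed = 7)
  # the cassette-exon junctions couple to the TSS on both genes
  for (g in c("simg01", "simg02")) {
    t_tss <- res$tests[res$tests$gene_id == g & res$tests$axis == "TSS", ]
    expect_true(any(t_tss$coupled))
    lay <- ann$layouts[[match(g, vapply(ann$layouts, `[[`, "", "gene_id"))]]
    # the intron upstream of the cassette exon: inclusion enriched
    # under TSS1 (inclusion probability 0.9 vs 0.1)
    up_j <- paste0(cfg$contig, ":", lay$d0 + 1L, "-",
                   lay$internal_start[1] - 1L, ":", lay$strand)
    r <- res$residuals
    r1 <- r$residual[r$junction_id == up_j & r$axis == "TSS" &
                       r$cluster_id == paste0(g, ":TSS1")]
    r2 <- r$residual[r$junction_id == up_j & r$axis == "TSS" &
                       r$cluster_id == paste0(g, ":TSS2")]
    expect_gt(r1, 0)
    expect_lt(r2, 0)
  }
  # constitutive junction (included in every read): degenerate margin,
  # never tested
  lay1 <- ann$layouts[[1]]
  const_j <- paste0(cfg$contig, ":", lay1$internal_end[2] + 1L, "-",
                    lay1$aL - 1L, ":", lay1$strand)
  tc <- res$tests[res$tests$junction_id == const_j, ]
  expect_true(all(!tc$tested))
})

test_that("single-axis genes are skipped in exon coupling tests", {
  # one TSS only: the junction x TSS table has a single column
  gtf <- tempfile(fileext = ".gtf")
  df <- rbind(
    data.frame(contig = "chr1", start = c(1000L, 2001L), end = c(1500L, 2500L),
               strand = "+", gene_id = "g", transcript_id = "g.t1"),
    data.frame(contig = "chr1", start = c(1000L, 2001L), end = c(1500L, 3000L),
               strand = "+", gene_id = "g", transcript_id = "g.t2"))
  write_test_gtf(df, gtf)
  exons <- parse_annotation(gtf)
  db <- prepare_isoform_database(exons)
  jdb <- create_reference_junctions(NULL, exons, type = "annotation")
  reads <- data.frame(qname = sprintf("r%02d", 1:30), flag = 0L, pos = 1000L,
                      cigar = rep(c("501M500N500M", "501M500N1000M"), 15))
  bam <- write_test_bam(reads, tempfile(fileext = ".bam"))
  elc <- read_to_junctions(bam, jdb, db)
  res <- calculate_exon_couplings(elc, jdb, B = 200)
  expect_true(all(!res$tests$tested[res$tests$axis == "TSS"]))
})
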