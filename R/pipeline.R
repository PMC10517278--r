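# Reproducibility sidecar: parameters, package version, input checksums.
.write_sidecar <- function(out_dir, params, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  sums <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(
    list(tool = "isocouple",
         version = as.character(utils::packageVersion("isocouple")),
         params = params, input_md5 = sums),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
}

#' Run the TSS-TES coupling pipeline
#'
#' Builds the 5'-3' isoform database from the annotation (optionally
#' augmented with external TSS/TES databases), counts full-length reads
#' per (TSS, TES) cluster pair and tests per-gene couplings, writing
#' all tables plus a reproducibility sidecar to `out_dir`.
#'
#' @param bam Coordinate-sorted, indexed BAM path.
#' @param gtf Annotation GTF path.
#' @param out_dir Output directory.
#' @param tss_window,tes_window End clustering/assignment windows in nt.
#' @param biotype_filter Gene biotype filter (default
#'   `"protein_coding"`).
#' @param tss_bed,tes_gff Optional external end databases (BED6/GFF).
#' @param min_mapq,B,alpha,residual_cutoff,min_reads,seed Passed to
#'   [count_links()] and [estimate_promoter_dominance()].
#' @param write_bam Also write the full-length-only BAM (default
#'   `FALSE`).
#' @return The `CouplingResult`, invisibly; `out_dir` gains
#'   `db/`, `read_assignments.txt`, `link_counts.tsv`, `genes.tsv`,
#'   `pairs.tsv`, `dominance.tsv` and `config.json`.
#' @export
run_coupling_pipeline <- function(bam, gtf, out_dir, tss_window = 50,
                               tes_window = 150,
                               biotype_filter = "protein_coding",
                               tss_bed = NULL, tes_gff = NULL,
                               min_mapq = 10, B = 2000, alpha = 0.01,
                               residual_cutoff = 0.5, min_reads = 20,
                               seed = NULL, write_bam = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exons <- parse_annotation(gtf, biotype_filter)
  db <- prepare_isoform_database(exons, tss_window, tes_window)
  if (!is.null(tss_bed)) {
    db <- add_end_database(db, rtracklayer::import(tss_bed), "TSS")
  }
  if (!is.null(tes_gff)) {
    db <- add_end_database(db, rtracklayer::import(tes_gff), "TES")
  }
  write_isoform_database(db, file.path(out_dir, "db"))
  counts <- count_links(bam, db, min_mapq = min_mapq)
  write_read_assignments(counts, file.path(out_dir, "read_assignments.txt"))
  data.table::fwrite(counts$counts, file.path(out_dir, "link_counts.tsv"),
                     sep = "\t")
  if (write_bam) {
    filter_bam(bam, counts, file.path(out_dir, "full_length.bam"))
  }
  res <- estimate_promoter_dominance(counts, db, B = B, alpha = alpha,
                                     residual_cutoff = residual_cutoff,
                                     min_reads = min_reads, seed = seed)
  data.table::fwrite(res$genes, file.path(out_dir, "genes.tsv"), sep = "\t")
  data.table::fwrite(res$pairs, file.path(out_dir, "pairs.tsv"), sep = "\t")
  data.table::fwrite(res$dominance, file.path(out_dir, "dominance.tsv"),
                     sep = "\t")
  .write_sidecar(out_dir,
                 params = list(tss_window = tss_window,
                               tes_window = tes_window,
                               biotype_filter = biotype_filter,
                               min_mapq = min_mapq, B = B, alpha = alpha,
                               residual_cutoff = residual_cutoff,
                               min_reads = min_reads, seed = seed),
                 inputs = list(bam = bam, gtf = gtf, tss_bed = tss_bed,
                               tes_gff = tes_gff))
  invisible(res)
}

#' Run the junction-coupling pipeline
#'
#' Builds the reference junction database from the annotation plus
#' short-read STAR junctions, corrects and filters long reads and tests
#' junction-TSS and junction-TES couplings, writing all tables plus a
#' reproducibility sidecar to `out_dir`.
#'
#' @param bam Coordinate-sorted, indexed BAM path.
#' @param gtf Annotation GTF path.
#' @param sj STAR SJ.out.tab path (or `NULL` with
#'   `type = "annotation"`).
#' @param out_dir Output directory.
#' @param type,min_jcounts Passed to [create_reference_junctions()].
#' @param tol,min_mapq,snap_closest Passed to [read_to_junctions()].
#' @param tss_window,tes_window,biotype_filter Isoform database
#'   parameters.
#' @param B,alpha,min_reads,residual_cutoff,seed Passed to
#'   [calculate_exon_couplings()].
#' @return The `ExonCouplingResult`, invisibly; `out_dir` gains
#'   `junctions.tsv`, `exon_couplings.tsv`, `exon_residuals.tsv`,
#'   `correction_stats.tsv` and `config.json`.
#' @export
run_junction_pipeline <- function(bam, gtf, sj, out_dir, type = "short",
                               min_jcounts = 2, tol = 10, min_mapq = 10,
                               snap_closest = FALSE, tss_window = 50,
                               tes_window = 150,
                               biotype_filter = "protein_coding",
                               B = 2000, alpha = 0.01, min_reads = 20,
                               residual_cutoff = 0.5, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exons <- parse_annotation(gtf, biotype_filter)
  isoform_db <- prepare_isoform_database(exons, tss_window, tes_window)
  jdb <- create_reference_junctions(sj, exons, type = type,
                                    min_jcounts = min_jcounts)
  jgr <- jdb$junctions
  data.table::fwrite(data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(jgr)),
    start = GenomicRanges::start(jgr), end = GenomicRanges::end(jgr),
    strand = as.character(GenomicRanges::strand(jgr)),
    support = jgr$support, short_read_count = jgr$short_read_count),
    file.path(out_dir, "junctions.tsv"), sep = "\t")
  elc <- read_to_junctions(bam, jdb, isoform_db, tol = tol,
                           min_mapq = min_mapq, snap_closest = snap_closest)
  data.table::fwrite(data.table::as.data.table(elc$correction_stats),
                     file.path(out_dir, "correction_stats.tsv"), sep = "\t")
  res <- calculate_exon_couplings(elc, jdb, B = B, alpha = alpha,
                                  min_reads = min_reads,
                                  residual_cutoff = residual_cutoff,
                                  seed = seed)
  data.table::fwrite(res$tests, file.path(out_dir, "exon_couplings.tsv"),
                     sep = "\t")
  data.table::fwrite(res$residuals, file.path(out_dir, "exon_residuals.tsv"),
                     sep = "\t")
  .write_sidecar(out_dir,
                 params = list(type = type, min_jcounts = min_jcounts,
                               tol = tol, min_mapq = min_mapq,
                               snap_closest = snap_closest,
                               tss_window = tss_window,
                               tes_window = tes_window, B = B,
                               alpha = alpha, min_reads = min_reads,
                               residual_cutoff = residual_cutoff,
                               seed = seed),
                 inputs = list(bam = bam, gtf = gtf, sj = sj))
  invisible(res)
}
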