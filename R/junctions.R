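#' Parse STAR splice junctions (SJ.out.tab)
#'
#' Reads STAR's 9-column per-junction summary. Intron coordinates are
#' 1-based inclusive; strand codes are 0 (undefined, dropped), 1 (`+`)
#' and 2 (`-`). Junctions supported by fewer than `min_jcounts`
#' uniquely-mapping short reads are dropped: lowly supported or rare
#' junctions would otherwise contaminate the reference used for
#' long-read correction.
#'
#' @param path SJ.out.tab path.
#' @param min_jcounts Minimum unique-mapper read count (default 2).
#' @return A `GRanges` of intron intervals with metadata column
#'   `short_read_count`; the number of undefined-strand rows dropped is
#'   stored in `metadata()$undefined_strand_dropped`.
#' @export
parse_star_sj <- function(path, min_jcounts = 2) {
  if (!file.exists(path)) stop("SJ file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) != 9L) {
    stop("'", path, "' has ", ncol(dt),
         " columns; STAR SJ.out.tab requires 9")
  }
  data.table::setnames(dt, c("contig", "start", "end", "strand_code",
                             "motif", "annotated", "n_unique", "n_multi",
                             "overhang"))
  n_undef <- sum(dt$strand_code == 0L)
  dt <- dt[dt$strand_code %in% c(1L, 2L) & dt$n_unique >= min_jcounts]
  gr <- GenomicRanges::GRanges(
    dt$contig, IRanges::IRanges(dt$start, dt$end),
    strand = ifelse(dt$strand_code == 1L, "+", "-"),
    short_read_count = dt$n_unique)
  S4Vectors::metadata(gr)$undefined_strand_dropped <- n_undef
  gr
}

# Introns implied by consecutive exons of each transcript.
.annotation_junctions <- function(exons) {
  dt <- data.table::data.table(
    transcript_id = as.character(exons$transcript_id),
    contig = as.character(GenomicRanges::seqnames(exons)),
    strand = as.character(GenomicRanges::strand(exons)),
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons))
  data.table::setorder(dt, transcript_id, start)
  j <- dt[, if (.N > 1L) list(contig = contig[-.N], strand = strand[-.N],
                              jstart = end[-.N] + 1L,
                              jend = start[-1L] - 1L),
          by = "transcript_id"]
  j <- unique(j[, c("contig", "strand", "jstart", "jend"), with = FALSE])
  j <- j[j$jend >= j$jstart]
  GenomicRanges::GRanges(j$contig, IRanges::IRanges(j$jstart, j$jend),
                         strand = j$strand)
}

#' Build the reference junction database
#'
#' Combines splice junctions implied by the annotation (consecutive
#' exons of each transcript) with, when `type = "short"`, short-read
#' junctions from a STAR SJ.out.tab that pass `min_jcounts`. Junctions
#' present in both sources get support `both`.
#'
#' @param short_sj SJ.out.tab path, a `GRanges` from [parse_star_sj()],
#'   or `NULL` (required non-NULL when `type = "short"`).
#' @param exons Annotation exon `GRanges` from [parse_annotation()].
#' @param type `"short"` (annotation plus short-read junctions, the
#'   recommended mode) or `"annotation"` (annotation only; any SJ input
#'   is ignored).
#' @param min_jcounts Passed to [parse_star_sj()] when `short_sj` is a
#'   path (default 2).
#' @return An object of class `JunctionDB`: list with `junctions` (a
#'   `GRanges` with `junction_id`, `support`, `short_read_count`) and
#'   `params`.
#' @export
create_reference_junctions <- function(short_sj, exons,
                                       type = c("short", "annotation"),
                                       min_jcounts = 2) {
  type <- match.arg(type)
  annot <- .annotation_junctions(exons)
  cols <- function(gr) data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    jstart = GenomicRanges::start(gr), jend = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  adt <- cols(annot)[, from_annot := TRUE]
  if (type == "short") {
    if (is.null(short_sj)) stop("type 'short' requires a SJ.out.tab input")
    sj <- if (is.character(short_sj)) {
      parse_star_sj(short_sj, min_jcounts = min_jcounts)
    } else short_sj
    sdt <- cols(sj)[, `:=`(from_short = TRUE,
                           sr = as.integer(sj$short_read_count))]
    merged <- merge(adt, sdt, by = c("contig", "jstart", "jend", "strand"),
                    all = TRUE)
    merged[is.na(from_annot), from_annot := FALSE]
    merged[is.na(from_short), from_short := FALSE]
    merged[is.na(sr), sr := 0L]
    merged[, support := ifelse(from_annot & from_short, "both",
                               ifelse(from_annot, "annotation", "short_read"))]
  } else {
    merged <- adt
    merged[, `:=`(support = "annotation", sr = 0L)]
  }
  if (nrow(merged) == 0L) stop("empty reference junction set")
  gr <- GenomicRanges::GRanges(
    merged$contig, IRanges::IRanges(merged$jstart, merged$jend),
    strand = merged$strand,
    junction_id = paste0(merged$contig, ":", merged$jstart, "-",
                         merged$jend, ":", merged$strand),
    support = merged$support,
    short_read_count = merged$sr)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  structure(list(junctions = gr,
                 params = list(type = type, min_jcounts = min_jcounts)),
            class = "JunctionDB")
}

#' @export
print.JunctionDB <- function(x, ...) {
  cat("JunctionDB:", length(x$junctions), "reference junctions (",
      sum(x$junctions$support == "both"), "both,",
      sum(x$junctions$support == "annotation"), "annotation-only,",
      sum(x$junctions$support == "short_read"), "short-read-only )\n")
  invisible(x)
}

# Vectorized chain correction. `introns` is a data.table with columns
# read_idx, contig, strand, start, end. Returns list(introns = corrected
# per-intron table, reads = per-read status table).
.correct_chains <- function(introns, jdb, tol, snap_closest = FALSE) {
  jgr <- jdb$junctions
  ref <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(jgr)),
    strand = as.character(GenomicRanges::strand(jgr)),
    rstart = GenomicRanges::start(jgr),
    rend = GenomicRanges::end(jgr),
    junction_id = jgr$junction_id)
  it <- data.table::copy(introns)
  it[, iid := .I]
  it[, `:=`(s_lo = start - tol, s_hi = start + tol,
            e_lo = end - tol, e_hi = end + tol)]
  ref[, `:=`(js = rstart, je = rend)]
  cand <- ref[it, on = list(contig = contig, strand = strand,
                            js >= s_lo, js <= s_hi, je >= e_lo, je <= e_hi),
              allow.cartesian = TRUE]
  # after the non-equi join js/je hold i's bounds; real coords are rstart/rend
  cand <- cand[, list(iid, junction_id, rstart, rend)]
  cand <- cand[!is.na(junction_id)]
  orig <- it[, list(iid, read_idx, start, end)]
  cand <- merge(cand, orig, by = "iid")
  cand[, dist := abs(rstart - start) + abs(rend - end)]
  data.table::setorder(cand, iid, dist, rstart, rend)
  ncand <- cand[, list(n = .N), by = "iid"]
  chosen <- unique(cand, by = "iid")

  per_intron <- merge(it[, list(iid, read_idx, start, end)],
                      chosen[, list(iid, junction_id, rstart, rend,
                                    n_cand = NA_integer_)],
                      by = "iid", all.x = TRUE)
  per_intron <- merge(per_intron, ncand, by = "iid", all.x = TRUE)
  per_intron[is.na(n), n := 0L]
  per_intron[, moved := !is.na(rstart) & (rstart != start | rend != end)]

  rd <- per_intron[, list(
    n_introns = .N,
    n_novel = sum(n == 0L),
    n_ambig = sum(n > 1L),
    n_moved = sum(moved[n == 1L | (n > 1L & snap_closest)])
  ), by = "read_idx"]
  rd[, status := ifelse(n_novel > 0L, "rejected",
                        ifelse(n_ambig > 0L & !snap_closest, "rejected",
                               ifelse(n_moved > 0L, "snapped", "exact")))]
  rd[, reason := ifelse(n_novel > 0L, "novel_junction",
                        ifelse(n_ambig > 0L & !snap_closest,
                               "ambiguous_junction", NA_character_))]
  # corrected chains must stay ordered and non-overlapping
  ok_reads <- rd$read_idx[rd$status != "rejected"]
  chains <- per_intron[per_intron$read_idx %in% ok_reads & !is.na(rstart)]
  if (nrow(chains) > 0L) {
    data.table::setorder(chains, read_idx, start)
    bad <- chains[, list(bad = .N > 1L &&
                           (is.unsorted(rstart) ||
                              any(rstart[-1L] <= rend[-.N]))),
                  by = "read_idx"]
    bad_reads <- bad$read_idx[bad$bad]
    if (length(bad_reads) > 0L) {
      rd[read_idx %in% bad_reads,
         `:=`(status = "rejected", reason = "invalid_chain")]
    }
  }
  list(introns = per_intron, reads = rd)
}

#' Correct one read's intron chain against the reference junctions
#'
#' Each intron is snapped to the unique reference junction whose donor
#' and acceptor coordinates are each within `tol` nucleotides. Exact
#' matches are kept unchanged. A read with an intron matching no
#' reference junction is rejected (`novel_junction`); one matching more
#' than one is rejected (`ambiguous_junction`) unless
#' `snap_closest = TRUE`, in which case the closest (by total boundary
#' shift) wins.
#'
#' @param introns `GRanges` of one read's introns (1-based inclusive).
#' @param db A `JunctionDB`.
#' @param tol Maximum per-boundary shift in nt (default 10).
#' @param snap_closest Resolve ambiguous matches to the closest
#'   reference junction instead of rejecting (default `FALSE`).
#' @return List with `status` (`"exact"`, `"snapped"` or `"rejected"`),
#'   `reason` (for rejections) and `chain` (corrected intron `GRanges`).
#' @export
correct_junctions <- function(introns, db, tol = 10, snap_closest = FALSE) {
  stopifnot(inherits(db, "JunctionDB"), tol >= 0)
  if (length(introns) == 0L) {
    return(list(status = "exact", reason = NA_character_, chain = introns))
  }
  it <- data.table::data.table(
    read_idx = 1L,
    contig = as.character(GenomicRanges::seqnames(introns)),
    strand = as.character(GenomicRanges::strand(introns)),
    start = GenomicRanges::start(introns),
    end = GenomicRanges::end(introns))
  res <- .correct_chains(it, db, tol, snap_closest)
  status <- res$reads$status[1L]
  if (status == "rejected") {
    return(list(status = status, reason = res$reads$reason[1L],
                chain = NULL))
  }
  pi <- res$introns[order(res$introns$start)]
  chain <- GenomicRanges::GRanges(
    it$contig, IRanges::IRanges(pi$rstart, pi$rend), strand = it$strand)
  list(status = status, reason = NA_character_, chain = chain)
}

#' Assign full-length reads to corrected junction chains
#'
#' Combines the full-length (TSS, TES) read filter with junction
#' correction: reads must both span a TSS and TES cluster of one gene
#' and have every intron snap to a unique reference junction. For every
#' reference junction overlapping a gene, each accepted read of that
#' gene counts as *inclusion* when its corrected chain contains the
#' junction and as *exclusion* when its aligned span fully covers the
#' intron interval but the chain lacks it; reads not spanning the
#' junction contribute to neither. Counts are tabulated against the
#' read's TSS cluster and, separately, its TES cluster.
#'
#' @param bam Coordinate-sorted, indexed BAM path.
#' @param db A `JunctionDB`.
#' @param isoform_db An `IsoformDatabase` (for the full-length filter).
#' @param tol Junction correction tolerance in nt (default 10).
#' @param min_mapq Minimum mapping quality (default 10).
#' @param snap_closest See [correct_junctions()].
#' @param ignore_strand See [assign_read()].
#' @return An object of class `ExonLinkCounts`: list with `counts`
#'   (long table: gene_id, junction_id, axis, cluster_id, incl, excl),
#'   `reads` (per accepted read: ids, clusters, corrected chain),
#'   `correction_stats` and `params`.
#' @export
read_to_junctions <- function(bam, db, isoform_db, tol = 10, min_mapq = 10,
                              snap_closest = FALSE, ignore_strand = FALSE) {
  stopifnot(inherits(db, "JunctionDB"), inherits(isoform_db, "IsoformDatabase"))
  rf <- extract_read_features(bam, min_mapq = min_mapq)
  asg <- .assign_reads(rf$reads, isoform_db, ignore_strand)
  fl_idx <- which(asg$status == "full_length")
  empty_counts <- data.table::data.table(
    gene_id = character(), junction_id = character(), axis = character(),
    cluster_id = character(), incl = integer(), excl = integer())
  if (length(fl_idx) == 0L) {
    warning("no full-length reads; junction count tables are empty")
    return(structure(list(counts = empty_counts, reads = data.frame(),
                          correction_stats = list(exact = 0L, snapped = 0L,
                                                  rejected = 0L),
                          params = list(tol = tol, min_mapq = min_mapq)),
                     class = "ExonLinkCounts"))
  }
  intr <- rf$introns[fl_idx]
  ni <- S4Vectors::elementNROWS(intr)
  flat <- unlist(intr, use.names = FALSE)
  idt <- data.table::data.table(
    read_idx = rep(fl_idx, ni),
    contig = as.character(GenomicRanges::seqnames(flat)),
    strand = rep(rf$reads$strand[fl_idx], ni),
    start = GenomicRanges::start(flat),
    end = GenomicRanges::end(flat))
  cc <- .correct_chains(idt, db, tol, snap_closest)
  rd_status <- merge(data.table::data.table(read_idx = fl_idx),
                     cc$reads, by = "read_idx", all.x = TRUE)
  rd_status[is.na(status), status := "exact"]  # intronless reads
  accepted <- rd_status$read_idx[rd_status$status != "rejected"]

  chains <- cc$introns[cc$introns$read_idx %in% accepted &
                         !is.na(cc$introns$junction_id)]
  reads_tbl <- data.table::data.table(
    read_idx = fl_idx,
    read_id = rf$reads$read_id[fl_idx],
    gene_id = asg$gene_id[fl_idx],
    tss_id = asg$tss_id[fl_idx],
    tes_id = asg$tes_id[fl_idx],
    span_start = rf$reads$start[fl_idx],
    span_end = rf$reads$end[fl_idx])
  reads_tbl <- merge(reads_tbl,
                     rd_status[, c("read_idx", "status"), with = FALSE],
                     by = "read_idx")
  chain_str <- chains[, list(chain = paste0(rstart, "-", rend,
                                            collapse = ";")),
                      by = "read_idx"]
  reads_tbl <- merge(reads_tbl, chain_str, by = "read_idx", all.x = TRUE)
  reads_tbl[is.na(chain), chain := ""]

  # junctions per gene: reference junctions inside the gene span
  gsp <- .gene_spans(isoform_db)
  jgr <- db$junctions
  jh <- GenomicRanges::findOverlaps(jgr, gsp, type = "within",
                                    ignore.strand = ignore_strand)
  gj <- data.table::data.table(
    gene_id = gsp$gene_id[S4Vectors::subjectHits(jh)],
    junction_id = jgr$junction_id[S4Vectors::queryHits(jh)],
    jstart = GenomicRanges::start(jgr)[S4Vectors::queryHits(jh)],
    jend = GenomicRanges::end(jgr)[S4Vectors::queryHits(jh)])

  acc <- reads_tbl[reads_tbl$status != "rejected"]
  pairs <- merge(acc, gj, by = "gene_id", allow.cartesian = TRUE)
  pairs <- pairs[pairs$jstart >= pairs$span_start &
                   pairs$jend <= pairs$span_end]
  in_chain <- chains[, list(read_idx, junction_id, included = TRUE)]
  pairs <- merge(pairs, in_chain, by = c("read_idx", "junction_id"),
                 all.x = TRUE)
  pairs[is.na(included), included := FALSE]

  tab_axis <- function(cluster_col, axis) {
    t <- pairs[, list(incl = sum(included), excl = sum(!included)),
               by = c("gene_id", "junction_id", cluster_col)]
    data.table::setnames(t, cluster_col, "cluster_id")
    t[, axis := axis]
    t
  }
  counts <- rbind(tab_axis("tss_id", "TSS"), tab_axis("tes_id", "TES"))
  data.table::setcolorder(counts, c("gene_id", "junction_id", "axis",
                                    "cluster_id", "incl", "excl"))
  data.table::setorder(counts, gene_id, junction_id, axis, cluster_id)
  structure(list(
    counts = counts,
    reads = as.data.frame(reads_tbl[, c("read_id", "gene_id", "tss_id",
                                        "tes_id", "status", "chain"),
                                    with = FALSE]),
    correction_stats = list(
      exact = sum(rd_status$status == "exact"),
      snapped = sum(rd_status$status == "snapped"),
      rejected = sum(rd_status$status == "rejected")),
    params = list(tol = tol, min_mapq = min_mapq,
                  snap_closest = snap_closest)),
    class = "ExonLinkCounts")
}

#' @export
print.ExonLinkCounts <- function(x, ...) {
  cs <- x$correction_stats
  cat("ExonLinkCounts:", nrow(x$reads), "full-length reads (",
      cs$exact, "exact,", cs$snapped, "snapped,", cs$rejected,
      "rejected )\n")
  invisible(x)
}

#' Test couplings between exon junction usage and TSS/TES choice
#'
#' For every (gene, junction, axis) with enough spanning reads, tests
#' the 2 x K inclusion/exclusion-by-cluster table with the Monte-Carlo
#' chi-squared test and adjusts p values across all tested combinations
#' with Benjamini-Hochberg. Pearson residuals of the inclusion row are
#' reported per cluster: a positive residual means the junction is used
#' more often than expected under independence by reads from that
#' cluster.
#'
#' @param counts An `ExonLinkCounts` object.
#' @param db The `JunctionDB` used to build the counts (consistency
#'   check; optional).
#' @param B Monte-Carlo replicates (default 2000).
#' @param alpha Significance level on q values (default 0.01).
#' @param min_reads Minimum spanning reads per junction (default 20).
#' @param residual_cutoff Minimum absolute inclusion residual for a
#'   coupled call (default 0.5).
#' @param seed Optional integer seed.
#' @return An object of class `ExonCouplingResult`: list with `tests`
#'   (per junction/axis statistics) and `residuals` (per-cluster
#'   inclusion residuals).
#' @export
calculate_exon_couplings <- function(counts, db = NULL, B = 2000,
                                     alpha = 0.01, min_reads = 20,
                                     residual_cutoff = 0.5, seed = NULL) {
  stopifnot(inherits(counts, "ExonLinkCounts"))
  if (!is.null(db)) {
    stopifnot(inherits(db, "JunctionDB"))
    if (nrow(counts$counts) > 0L &&
        !all(counts$counts$junction_id %in% db$junctions$junction_id)) {
      stop("counts reference junctions unknown to the junction database")
    }
  }
  cdt <- counts$counts
  keys <- unique(cdt[, c("gene_id", "junction_id", "axis"), with = FALSE])
  run <- function() {
    tests <- vector("list", nrow(keys))
    resids <- vector("list", nrow(keys))
    for (i in seq_len(nrow(keys))) {
      k <- keys[i]
      sub <- cdt[cdt$gene_id == k$gene_id &
                   cdt$junction_id == k$junction_id & cdt$axis == k$axis]
      m <- rbind(inclusion = sub$incl, exclusion = sub$excl)
      colnames(m) <- sub$cluster_id
      n_span <- sum(m)
      red <- .drop_zero_margins(m, warn = FALSE)
      testable <- n_span >= min_reads && nrow(red) == 2L && ncol(red) >= 2L
      base <- data.table::data.table(
        gene_id = k$gene_id, junction_id = k$junction_id, axis = k$axis,
        n_spanning = n_span)
      if (!testable) {
        tests[[i]] <- base[, `:=`(chisq_stat = NA_real_, p_value = NA_real_,
                                  tested = FALSE)]
        next
      }
      fit <- chisq_mc_test(red, B = B)
      tests[[i]] <- base[, `:=`(chisq_stat = fit$stat, p_value = fit$p,
                                tested = TRUE)]
      resids[[i]] <- data.table::data.table(
        gene_id = k$gene_id, junction_id = k$junction_id, axis = k$axis,
        cluster_id = colnames(red),
        residual = fit$residuals["inclusion", ])
    }
    empty_res <- data.table::data.table(
      gene_id = character(), junction_id = character(), axis = character(),
      cluster_id = character(), residual = numeric())
    list(tests = data.table::rbindlist(tests),
         residuals = data.table::rbindlist(c(list(empty_res), resids)))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tests <- res$tests
  tests[, q_value := NA_real_]
  if (any(tests$tested)) {
    tests[tested == TRUE, q_value := bh_adjust(p_value)]
  }
  resids <- res$residuals
  if (nrow(resids) > 0L) {
    maxres <- resids[, list(max_abs_residual = max(abs(residual))),
                     by = c("gene_id", "junction_id", "axis")]
    tests <- merge(tests, maxres,
                   by = c("gene_id", "junction_id", "axis"), all.x = TRUE)
  } else {
    tests[, max_abs_residual := NA_real_]
  }
  tests[, coupled := tested & !is.na(q_value) & q_value <= alpha &
          !is.na(max_abs_residual) & max_abs_residual >= residual_cutoff]
  structure(list(tests = as.data.frame(tests),
                 residuals = as.data.frame(resids),
                 params = list(B = B, alpha = alpha, min_reads = min_reads,
                               residual_cutoff = residual_cutoff,
                               seed = seed)),
            class = "ExonCouplingResult")
}

#' @export
print.ExonCouplingResult <- function(x, ...) {
  t <- x$tests
  cat("ExonCouplingResult:", nrow(t), "(gene, junction, axis) combinations;",
      sum(t$tested), "tested;", sum(t$coupled), "coupled at q <=",
      x$params$alpha, "\n")
  invisible(x)
}
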