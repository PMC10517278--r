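#' Extract strand-aware read features from a BAM file
#'
#' Reads primary, mapped alignments from a coordinate-sorted, indexed
#' BAM file and reduces each to its aligned span, strand-aware 5' and 3'
#' end (soft clips excluded: the aligned span only) and intron chain
#' (genomic intervals of CIGAR `N` operations). Secondary and
#' supplementary alignments are skipped; alignments below `min_mapq` are
#' kept but flagged so that the downstream tallies conserve reads.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param min_mapq Minimum mapping quality (default 10). Records below
#'   it receive status `filtered` during assignment.
#' @return An object of class `ReadFeatures`: list with `reads` (a
#'   `data.frame` of read_id, contig, strand, start, end, five_prime,
#'   three_prime, mapq, pass_mapq), `introns` (a `GRangesList` parallel
#'   to `reads`) and `stats` (records scanned and skipped).
#' @export
extract_read_features <- function(bam, min_mapq = 10) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index not found for '", bam,
         "'; create it with Rsamtools::indexBam() or `samtools index`")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("qname", "mapq"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  n_secondary <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = TRUE)))$records
  n_supplementary <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(
      isSupplementaryAlignment = TRUE)))$records
  n_unmapped <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = TRUE)))$records

  str <- as.character(GenomicAlignments::strand(ga))
  st <- GenomicAlignments::start(ga)
  en <- GenomicAlignments::end(ga)
  mapq <- S4Vectors::mcols(ga)$mapq
  mapq[is.na(mapq)] <- 255L  # MAPQ 255 = unavailable; do not filter on it
  reads <- data.frame(
    read_id = S4Vectors::mcols(ga)$qname,
    contig = as.character(GenomicAlignments::seqnames(ga)),
    strand = str,
    start = st, end = en,
    five_prime = ifelse(str == "+", st, en),
    three_prime = ifelse(str == "+", en, st),
    mapq = mapq,
    pass_mapq = mapq >= min_mapq,
    stringsAsFactors = FALSE
  )
  structure(list(
    reads = reads,
    introns = GenomicAlignments::junctions(ga),
    stats = list(scanned = length(ga),
                 secondary_skipped = n_secondary,
                 supplementary_skipped = n_supplementary,
                 unmapped_skipped = n_unmapped,
                 min_mapq = min_mapq)
  ), class = "ReadFeatures")
}

#' @export
print.ReadFeatures <- function(x, ...) {
  cat("ReadFeatures:", nrow(x$reads), "primary alignments (",
      sum(!x$reads$pass_mapq), "below MAPQ", x$stats$min_mapq, ")\n")
  invisible(x)
}

# Vectorized assignment of read ends to (gene, TSS cluster, TES cluster).
# Returns a data.table: read_id, gene_id, tss_id, tes_id, status.
.assign_reads <- function(reads, db, ignore_strand = FALSE) {
  n <- nrow(reads)
  status <- rep("unassigned", n)
  gene_id <- tss_id <- tes_id <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.table::data.table(read_id = character(), gene_id = character(),
                                  tss_id = character(), tes_id = character(),
                                  status = character()))
  }
  status[!reads$pass_mapq] <- "filtered"
  idx_ok <- which(reads$pass_mapq)

  span <- GenomicRanges::GRanges(reads$contig,
                                 IRanges::IRanges(reads$start, reads$end),
                                 strand = reads$strand)
  gsp <- .gene_spans(db)
  cand_hits <- GenomicRanges::findOverlaps(span, gsp,
                                           ignore.strand = ignore_strand)
  cand <- data.table::data.table(
    ri = S4Vectors::queryHits(cand_hits),
    gene_id = gsp$gene_id[S4Vectors::subjectHits(cand_hits)])
  cand <- cand[cand$ri %in% idx_ok]

  hit_one_kind <- function(kind, end_pos) {
    win <- .cluster_windows(db, kind)
    pts <- GenomicRanges::GRanges(reads$contig,
                                  IRanges::IRanges(end_pos, end_pos),
                                  strand = reads$strand)
    h <- GenomicRanges::findOverlaps(pts, win, ignore.strand = ignore_strand)
    dt <- data.table::data.table(
      ri = S4Vectors::queryHits(h),
      gene_id = win$gene_id[S4Vectors::subjectHits(h)],
      cluster_id = win$cluster_id[S4Vectors::subjectHits(h)],
      dist = abs(end_pos[S4Vectors::queryHits(h)] -
                   win$representative[S4Vectors::subjectHits(h)]),
      rep = win$representative[S4Vectors::subjectHits(h)],
      strand = reads$strand[S4Vectors::queryHits(h)])
    # nearest representative wins; ties towards the 5'-most representative
    dt[, tie := ifelse(strand == "+", rep, -rep)]
    data.table::setorder(dt, ri, gene_id, dist, tie)
    unique(dt, by = c("ri", "gene_id"))[, c("ri", "gene_id", "cluster_id"),
                                        with = FALSE]
  }
  tss_hit <- hit_one_kind("TSS", reads$five_prime)
  tes_hit <- hit_one_kind("TES", reads$three_prime)
  data.table::setnames(tss_hit, "cluster_id", "tss_id")
  data.table::setnames(tes_hit, "cluster_id", "tes_id")

  m <- merge(cand, tss_hit, by = c("ri", "gene_id"), all.x = TRUE)
  m <- merge(m, tes_hit, by = c("ri", "gene_id"), all.x = TRUE)
  if (nrow(m) > 0L) {
    m[, full := !is.na(tss_id) & !is.na(tes_id)]
    per_read <- m[, list(n_full = sum(full),
                         any_tss = any(!is.na(tss_id)),
                         g = gene_id[full][1L],
                         ts = tss_id[full][1L],
                         te = tes_id[full][1L]), by = "ri"]
    ri <- per_read$ri
    st <- ifelse(per_read$n_full == 1L, "full_length",
                 ifelse(per_read$n_full > 1L, "ambiguous_gene",
                        ifelse(per_read$any_tss, "no_tes", "no_tss")))
    status[ri] <- st
    ok <- per_read$n_full == 1L
    gene_id[ri[ok]] <- per_read$g[ok]
    tss_id[ri[ok]] <- per_read$ts[ok]
    tes_id[ri[ok]] <- per_read$te[ok]
  }
  data.table::data.table(read_id = reads$read_id, gene_id = gene_id,
                         tss_id = tss_id, tes_id = tes_id, status = status)
}

#' Assign a single read to a (TSS, TES) cluster pair
#'
#' A read is `full_length` when its 5' end falls within the assignment
#' window of a TSS cluster and its 3' end within the window of a TES
#' cluster of the same, strand-matching gene. Among multiple matching
#' clusters of one kind the nearest representative wins (tie: 5'-most).
#' Reads matching both ends in more than one gene are `ambiguous_gene`;
#' otherwise the status names the first missing feature (`no_tss`,
#' `no_tes`), or `unassigned` when no gene span overlaps.
#'
#' @param features A `ReadFeatures` object (one or more reads).
#' @param db An `IsoformDatabase`.
#' @param ignore_strand Match genes regardless of alignment strand
#'   (default `FALSE`; the default assumes stranded cDNA reads).
#' @return A `data.frame` with one row per read: `read_id`, `gene_id`,
#'   `tss_id`, `tes_id`, `status`.
#' @export
assign_read <- function(features, db, ignore_strand = FALSE) {
  stopifnot(inherits(features, "ReadFeatures"), inherits(db, "IsoformDatabase"))
  as.data.frame(.assign_reads(features$reads, db, ignore_strand))
}

#' Count 5'-3' isoform links from a BAM file
#'
#' Runs full-length read assignment over all primary alignments in the
#' BAM and tabulates per-gene TSS x TES contingency counts. Only reads
#' overlapping both a TSS and a TES window of one gene contribute; every
#' TSS x TES cluster combination of a gene is present in the count table
#' (zero-filled), so downstream tests see complete tables.
#'
#' @param bam Coordinate-sorted, indexed BAM path.
#' @param db An `IsoformDatabase`.
#' @param min_mapq Minimum mapping quality (default 10).
#' @param ignore_strand See [assign_read()].
#' @return An object of class `LinkCounts`: list with `counts` (long
#'   `data.table`: gene_id, tss_id, tes_id, count), `assignments` (per
#'   read), `totals` (status tallies; scanned = sum of all statuses) and
#'   `params`.
#' @export
count_links <- function(bam, db, min_mapq = 10, ignore_strand = FALSE) {
  rf <- extract_read_features(bam, min_mapq = min_mapq)
  asg <- .assign_reads(rf$reads, db, ignore_strand)
  counts <- .tabulate_links(asg, db)
  totals <- as.list(table(factor(asg$status,
    levels = c("filtered", "unassigned", "no_tss", "no_tes",
               "ambiguous_gene", "full_length"))))
  totals <- lapply(totals, as.integer)
  totals$scanned <- nrow(asg)
  if (totals$full_length == 0L) {
    warning("no full-length reads found; count tables are empty")
  }
  structure(list(counts = counts, assignments = as.data.frame(asg),
                 totals = c(totals, rf$stats[c("secondary_skipped",
                                               "supplementary_skipped",
                                               "unmapped_skipped")]),
                 params = list(min_mapq = min_mapq,
                               ignore_strand = ignore_strand,
                               tss_window = db$params$tss_window,
                               tes_window = db$params$tes_window)),
            class = "LinkCounts")
}

# Zero-filled long count table over the full TSS x TES cross-product.
.tabulate_links <- function(asg, db) {
  cl <- db$clusters
  grid <- data.table::rbindlist(lapply(split(cl, cl$gene_id), function(g) {
    data.table::CJ(tss_id = g$cluster_id[g$kind == "TSS"],
                   tes_id = g$cluster_id[g$kind == "TES"])[
                     , gene_id := g$gene_id[1L]]
  }))
  fl <- asg[asg$status == "full_length",
            c("gene_id", "tss_id", "tes_id"), with = FALSE]
  obs <- fl[, list(count = .N), by = c("gene_id", "tss_id", "tes_id")]
  counts <- merge(grid, obs, by = c("gene_id", "tss_id", "tes_id"),
                  all.x = TRUE)
  counts[is.na(count), count := 0L]
  data.table::setorder(counts, gene_id, tss_id, tes_id)
  counts[, c("gene_id", "tss_id", "tes_id", "count"), with = FALSE]
}

#' @export
print.LinkCounts <- function(x, ...) {
  t <- x$totals
  cat("LinkCounts:", t$scanned, "primary alignments scanned;",
      t$full_length, "full-length\n")
  cat("  statuses: filtered", t$filtered, "| unassigned", t$unassigned,
      "| no_tss", t$no_tss, "| no_tes", t$no_tes,
      "| ambiguous_gene", t$ambiguous_gene, "\n")
  invisible(x)
}

#' Per-gene TSS x TES count matrix
#'
#' @param counts A `LinkCounts` object.
#' @param gene_id Gene identifier.
#' @return Integer matrix, TSS clusters as rows, TES clusters as columns.
#' @export
link_matrix <- function(counts, gene_id) {
  gid <- gene_id
  cdt <- as.data.frame(counts$counts)
  g <- cdt[cdt$gene_id == gid, ]
  if (nrow(g) == 0L) stop("unknown gene: ", gene_id)
  tss <- sort(unique(g$tss_id)); tes <- sort(unique(g$tes_id))
  m <- matrix(0L, length(tss), length(tes), dimnames = list(tss, tes))
  m[cbind(match(g$tss_id, tss), match(g$tes_id, tes))] <- g$count
  m
}

#' Write per-read assignments to TSV
#'
#' Columns `read_id`, `gene_id`, `tss_id`, `tes_id`, `status`, in BAM
#' record order.
#'
#' @param counts A `LinkCounts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_read_assignments <- function(counts, path) {
  stopifnot(inherits(counts, "LinkCounts"))
  data.table::fwrite(counts$assignments, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Subset a BAM file to its full-length reads
#'
#' Writes a BAM containing exactly the records whose read id was
#' assigned `full_length`, then indexes it.
#'
#' @param bam Source BAM path.
#' @param counts A `LinkCounts` computed from `bam`.
#' @param path Destination BAM path.
#' @return `path`, invisibly.
#' @export
filter_bam <- function(bam, counts, path) {
  stopifnot(inherits(counts, "LinkCounts"))
  keep <- counts$assignments$read_id[counts$assignments$status == "full_length"]
  rule <- S4Vectors::FilterRules(list(full_length = function(x) {
    x$qname %in% keep
  }))
  dest <- Rsamtools::filterBam(
    bam, path, filter = rule,
    param = Rsamtools::ScanBamParam(what = "qname"))
  Rsamtools::indexBam(dest)
  invisible(path)
}
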