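#' Parse a GTF annotation into an exon table
#'
#' Reads a GTF file (Ensembl attribute dialect), keeps only `exon`
#' features and, by default, only genes annotated as `protein_coding`.
#' Records must carry `gene_id` and `transcript_id` attributes; the
#' `gene_biotype` attribute is used for biotype filtering and, when it is
#' absent, all genes are kept with a warning.
#'
#' @param gtf_path Path to a GTF file.
#' @param biotype_filter Gene biotype to retain (default
#'   `"protein_coding"`), or `NULL`/`"none"` to keep all genes.
#' @return A [GenomicRanges::GRanges] of exons with metadata columns
#'   `gene_id`, `transcript_id` and `gene_biotype`.
#' @export
parse_annotation <- function(gtf_path, biotype_filter = "protein_coding") {
  if (!file.exists(gtf_path)) {
    stop("annotation file not found: ", gtf_path)
  }
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", gtf_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) {
    stop("no exon features in '", gtf_path, "'")
  }
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id) ||
      any(!nzchar(gr$gene_id)) || any(!nzchar(gr$transcript_id))) {
    stop("GTF exons must carry non-empty gene_id and transcript_id attributes")
  }
  if (any(as.character(GenomicRanges::strand(gr)) == "*")) {
    stop("unstranded exon records are not supported")
  }
  if (is.null(gr$gene_biotype)) {
    if (!is.null(biotype_filter) && !identical(biotype_filter, "none")) {
      warning("gene_biotype attribute absent; keeping all genes")
    }
    gr$gene_biotype <- NA_character_
  } else if (!is.null(biotype_filter) && !identical(biotype_filter, "none")) {
    gr <- gr[!is.na(gr$gene_biotype) & gr$gene_biotype == biotype_filter]
  }
  if (length(gr) == 0L) {
    stop("no exons left after biotype filtering ('", biotype_filter, "')")
  }
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- mc[, c("gene_id", "transcript_id", "gene_biotype")]
  gr
}

#' Transcript 5' and 3' end positions
#'
#' Reduces each transcript to its transcription start (5' end) and end
#' (3' end) position, respecting strand: on `+` the TSS is the smallest
#' exon start and the TES the largest exon end; on `-` the roles swap.
#'
#' @param exons A `GRanges` of exons as returned by [parse_annotation()].
#' @return A `data.frame` with columns `transcript_id`, `gene_id`,
#'   `contig`, `strand`, `tss`, `tes` (1-based genomic positions).
#' @export
transcript_ends <- function(exons) {
  dt <- data.table::data.table(
    transcript_id = as.character(exons$transcript_id),
    gene_id = as.character(exons$gene_id),
    contig = as.character(GenomicRanges::seqnames(exons)),
    strand = as.character(GenomicRanges::strand(exons)),
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons)
  )
  chk <- dt[, list(ns = data.table::uniqueN(strand),
                   nc = data.table::uniqueN(contig)), by = "transcript_id"]
  bad <- chk[chk$ns > 1L | chk$nc > 1L]
  if (nrow(bad) > 0L) {
    stop("transcripts with mixed strand or contig: ",
         paste(utils::head(bad$transcript_id, 5L), collapse = ", "))
  }
  res <- dt[, list(gene_id = gene_id[1L], contig = contig[1L],
                   strand = strand[1L],
                   lo = min(start), hi = max(end)),
            by = "transcript_id"]
  res[, `:=`(tss = ifelse(strand == "+", lo, hi),
             tes = ifelse(strand == "+", hi, lo))]
  as.data.frame(res[, c("transcript_id", "gene_id", "contig", "strand",
                        "tss", "tes"), with = FALSE])
}

#' Single-linkage clustering of end positions
#'
#' Clusters a multiset of genomic positions by single linkage on the
#' sorted positions: consecutive positions at most `window` nucleotides
#' apart are merged, so a chain of nearby ends can form one cluster
#' wider than `window`. The representative is the member position with
#' the highest multiplicity; ties are broken towards the 5'-most
#' position in transcriptional direction (smallest coordinate on `+`,
#' largest on `-`).
#'
#' @param positions Integer vector of positions (duplicates allowed,
#'   multiplicity feeds representative selection).
#' @param window Maximum gap (nt) merged by single linkage; `>= 0`.
#' @param strand `"+"` or `"-"`; controls representative tie-breaking.
#' @return A list of clusters, each a list with `positions` (sorted
#'   unique members), `counts` (multiplicities) and `representative`.
#' @export
cluster_positions <- function(positions, window, strand = "+") {
  stopifnot(window >= 0, strand %in% c("+", "-"))
  if (length(positions) == 0L) return(list())
  tab <- table(positions)
  pos <- as.integer(names(tab))
  cnt <- as.integer(tab)
  o <- order(pos)
  pos <- pos[o]; cnt <- cnt[o]
  grp <- cumsum(c(1L, as.integer(diff(pos) > window)))
  lapply(unname(split(seq_along(pos), grp)), function(i) {
    p <- pos[i]; n <- cnt[i]
    cand <- p[n == max(n)]
    rep_pos <- if (strand == "+") min(cand) else max(cand)
    list(positions = p, counts = n, representative = rep_pos)
  })
}

# Build the cluster table for one gene and one end kind. Cluster ids are
# numbered 5'->3' in transcriptional direction (ascending coordinate on
# '+', descending on '-').
.cluster_table <- function(positions, window, kind, gene_id, contig, strand,
                           source = "annotation") {
  cl <- cluster_positions(positions, window, strand)
  reps <- vapply(cl, `[[`, numeric(1), "representative")
  ord <- order(reps, decreasing = (strand == "-"))
  cl <- cl[ord]; reps <- reps[ord]
  data.table::data.table(
    gene_id = gene_id,
    cluster_id = paste0(gene_id, ":", kind, seq_along(cl)),
    kind = kind,
    contig = contig,
    strand = strand,
    representative = as.integer(reps),
    window_start = pmax(1L, as.integer(reps) - as.integer(window)),
    window_end = as.integer(reps) + as.integer(window),
    n_members = vapply(cl, function(x) sum(x$counts), integer(1)),
    members = vapply(cl, function(x)
      paste(rep(x$positions, x$counts), collapse = ","), character(1)),
    source = source
  )
}

# All TSS x TES combinations of one gene with the TSS 5' of the TES in
# transcriptional direction.
.enumerate_pairs <- function(clusters) {
  out <- lapply(split(clusters, clusters$gene_id), function(cl) {
    tss <- cl[cl$kind == "TSS", ]
    tes <- cl[cl$kind == "TES", ]
    if (nrow(tss) == 0L || nrow(tes) == 0L) return(NULL)
    g <- data.table::CJ(ti = seq_len(nrow(tss)), tj = seq_len(nrow(tes)))
    keep <- if (cl$strand[1L] == "+") {
      tss$representative[g$ti] < tes$representative[g$tj]
    } else {
      tss$representative[g$ti] > tes$representative[g$tj]
    }
    g <- g[keep]
    if (nrow(g) == 0L) return(NULL)
    data.table::data.table(gene_id = cl$gene_id[1L],
                           tss_id = tss$cluster_id[g$ti],
                           tes_id = tes$cluster_id[g$tj])
  })
  dt <- data.table::rbindlist(out)
  data.table::setorder(dt, gene_id, tss_id, tes_id)
  dt
}

#' Build the 5'-3' isoform database
#'
#' Clusters the transcript TSS and TES positions of every gene with
#' single linkage ([cluster_positions()]) and enumerates all TSS x TES
#' cluster combinations as candidate 5'-3' isoforms. Clustering the ends
#' of all annotated transcripts, rather than keeping only annotated
#' (TSS, TES) combinations, is what makes novel 5'-3' links countable.
#'
#' @param exons Exon `GRanges` from [parse_annotation()].
#' @param tss_window Clustering/assignment window for TSSs in nt
#'   (default 50).
#' @param tes_window Clustering/assignment window for TESs in nt
#'   (default 150).
#' @return An object of class `IsoformDatabase`: a list with elements
#'   `clusters` (one row per end cluster with representative and
#'   assignment window), `pairs` (candidate TSS/TES combinations),
#'   `genes` (gene spans), `params` and `provenance`.
#' @export
prepare_isoform_database <- function(exons, tss_window = 50, tes_window = 150) {
  stopifnot(tss_window >= 0, tes_window >= 0)
  if (length(exons) == 0L) stop("no exons supplied")
  ends <- data.table::as.data.table(transcript_ends(exons))
  genes <- ends[, list(contig = contig[1L], strand = strand[1L],
                       start = min(pmin(tss, tes)),
                       end = max(pmax(tss, tes))), by = "gene_id"]
  clusters <- data.table::rbindlist(lapply(split(ends, ends$gene_id), function(g) {
    rbind(
      .cluster_table(g$tss, tss_window, "TSS", g$gene_id[1L], g$contig[1L],
                     g$strand[1L]),
      .cluster_table(g$tes, tes_window, "TES", g$gene_id[1L], g$contig[1L],
                     g$strand[1L])
    )
  }))
  pairs <- .enumerate_pairs(clusters)
  db <- structure(list(
    clusters = clusters,
    pairs = pairs,
    genes = genes,
    params = list(tss_window = as.integer(tss_window),
                  tes_window = as.integer(tes_window)),
    provenance = "annotation"
  ), class = "IsoformDatabase")
  db
}

#' @export
print.IsoformDatabase <- function(x, ...) {
  cat("IsoformDatabase:", nrow(x$genes), "genes,",
      sum(x$clusters$kind == "TSS"), "TSS clusters,",
      sum(x$clusters$kind == "TES"), "TES clusters,",
      nrow(x$pairs), "candidate 5'-3' isoform pairs\n")
  cat("windows: tss", x$params$tss_window, "nt; tes", x$params$tes_window,
      "nt\n")
  invisible(x)
}

#' Merge an external TSS or TES database into an isoform database
#'
#' Each external end is reduced to its stranded point (5' end of the
#' record for TSSs, 3' end for TESs; 1-bp promoter records work as-is)
#' and assigned to every gene whose span, extended by `window` on both
#' sides, contains it on the matching strand. Ends within `window` of an
#' existing same-kind cluster representative are absorbed without
#' changing the representative; others found a new cluster, after which
#' cluster ids are renumbered 5'->3' and the pair cross-product is
#' re-enumerated. Unassignable records are counted in the returned
#' object's `merge_stats`.
#'
#' @param db An `IsoformDatabase`.
#' @param external A stranded `GRanges` of external ends (e.g. from
#'   [rtracklayer::import()] of a BED6 or GFF file). If it carries a
#'   `kind` metadata column it must agree with `kind`.
#' @param kind `"TSS"` or `"TES"`.
#' @param window Absorption window in nt; defaults to the database's
#'   window for `kind`.
#' @return The augmented `IsoformDatabase`; `db$merge_stats` reports
#'   counts of absorbed, added and unassigned records.
#' @export
add_end_database <- function(db, external, kind = c("TSS", "TES"),
                             window = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(db, "IsoformDatabase"))
  if (is.null(window)) {
    window <- if (kind == "TSS") db$params$tss_window else db$params$tes_window
  }
  stopifnot(window >= 0)
  if (!is.null(external$kind) &&
      !all(as.character(external$kind) == kind)) {
    stop("external records annotate a different end kind than '", kind, "'")
  }
  if (length(external) == 0L) return(db)
  str <- as.character(GenomicRanges::strand(external))
  if (any(str == "*")) stop("external end records must be stranded")
  # stranded point: TSS -> 5' end of the record, TES -> 3' end
  at_start <- (str == "+") == (kind == "TSS")
  point <- ifelse(at_start, GenomicRanges::start(external),
                  GenomicRanges::end(external))
  ext <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(external)),
    strand = str, pos = as.integer(point))

  genes <- data.table::as.data.table(db$genes)
  gspan <- GenomicRanges::GRanges(genes$contig,
                                  IRanges::IRanges(pmax(1L, genes$start - window),
                                                   genes$end + window),
                                  strand = genes$strand)
  pts <- GenomicRanges::GRanges(ext$contig, IRanges::IRanges(ext$pos, ext$pos),
                                strand = ext$strand)
  hits <- GenomicRanges::findOverlaps(pts, gspan)
  n_unassigned <- length(external) - length(unique(S4Vectors::queryHits(hits)))

  want_kind <- kind
  clusters <- data.table::copy(db$clusters)
  same <- as.data.frame(clusters)[as.data.frame(clusters)$kind == want_kind, ]
  n_absorbed <- 0L; n_added <- 0L
  if (length(hits) > 0L) {
    asg <- data.table::data.table(
      pos = ext$pos[S4Vectors::queryHits(hits)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])
    asg <- unique(asg)
    for (i in seq_len(nrow(asg))) {
      g <- asg$gene_id[i]; p <- asg$pos[i]
      reps <- same$representative[same$gene_id == g]
      if (length(reps) > 0L && min(abs(reps - p)) <= window) {
        n_absorbed <- n_absorbed + 1L
      } else {
        gi <- genes[genes$gene_id == g]
        newc <- data.table::data.table(
          gene_id = g, cluster_id = "pending", kind = kind,
          contig = gi$contig, strand = gi$strand,
          representative = p,
          window_start = max(1L, p - as.integer(window)),
          window_end = p + as.integer(window),
          n_members = 1L, members = as.character(p), source = "external")
        clusters <- rbind(clusters, newc)
        same <- as.data.frame(clusters)[as.data.frame(clusters)$kind ==
                                          want_kind, ]
        n_added <- n_added + 1L
      }
    }
  }
  # renumber ids 5'->3' per gene/kind and rebuild the pair cross-product
  data.table::setorder(clusters, gene_id, kind, representative)
  clusters[, cluster_id := {
    dec <- strand[1L] == "-"
    o <- order(representative, decreasing = dec)
    id <- integer(.N); id[o] <- seq_len(.N)
    paste0(gene_id, ":", kind, id)
  }, by = c("gene_id", "kind")]
  db$clusters <- clusters
  db$pairs <- .enumerate_pairs(clusters)
  db$provenance <- c(db$provenance, paste0("external_", tolower(kind)))
  db$merge_stats <- list(absorbed = n_absorbed, added = n_added,
                         unassigned = n_unassigned)
  db
}
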