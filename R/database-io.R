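#' Write an isoform database to a directory
#'
#' Serializes the database as plain TSV tables (`clusters.tsv`,
#' `pairs.tsv`, `genes.tsv`) plus a JSON parameter sidecar
#' (`params.json`).
#'
#' @param db An `IsoformDatabase`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_isoform_database <- function(db, dir) {
  stopifnot(inherits(db, "IsoformDatabase"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(db$clusters, file.path(dir, "clusters.tsv"), sep = "\t")
  data.table::fwrite(db$pairs, file.path(dir, "pairs.tsv"), sep = "\t")
  data.table::fwrite(db$genes, file.path(dir, "genes.tsv"), sep = "\t")
  jsonlite::write_json(list(params = db$params, provenance = db$provenance),
                       file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an isoform database written by [write_isoform_database()]
#'
#' @param dir Database directory.
#' @return An `IsoformDatabase`.
#' @export
read_isoform_database <- function(dir) {
  need <- file.path(dir, c("clusters.tsv", "pairs.tsv", "genes.tsv",
                           "params.json"))
  if (!all(file.exists(need))) {
    stop("'", dir, "' is not an isoform database directory")
  }
  meta <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  structure(list(
    clusters = data.table::fread(need[1L], sep = "\t",
                                 colClasses = list(character = "members")),
    pairs = data.table::fread(need[2L], sep = "\t"),
    genes = data.table::fread(need[3L], sep = "\t"),
    params = list(tss_window = as.integer(meta$params$tss_window),
                  tes_window = as.integer(meta$params$tes_window)),
    provenance = meta$provenance
  ), class = "IsoformDatabase")
}

#' Export cluster windows as GFF3 for genome-browser inspection
#'
#' Each TSS/TES cluster's assignment window becomes one GFF3 feature
#' (type `TSS_cluster` / `TES_cluster`).
#'
#' @param db An `IsoformDatabase`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
export_database_gff <- function(db, path) {
  cl <- db$clusters
  gr <- GenomicRanges::GRanges(
    cl$contig, IRanges::IRanges(cl$window_start, cl$window_end),
    strand = cl$strand,
    type = paste0(cl$kind, "_cluster"),
    ID = cl$cluster_id, gene_id = cl$gene_id,
    representative = cl$representative)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# GRanges of cluster assignment windows, used for read assignment.
.cluster_windows <- function(db, kind) {
  want <- kind
  cl <- as.data.frame(db$clusters)
  cl <- cl[cl$kind == want, ]
  GenomicRanges::GRanges(cl$contig,
                         IRanges::IRanges(cl$window_start, cl$window_end),
                         strand = cl$strand,
                         gene_id = cl$gene_id, cluster_id = cl$cluster_id,
                         representative = cl$representative)
}

# GRanges of gene spans.
.gene_spans <- function(db) {
  g <- db$genes
  GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}
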