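#' Write link counts to a directory
#'
#' Serializes a `LinkCounts` object as `link_counts.tsv` (long format),
#' `read_assignments.txt` and a `counts.json` sidecar with status
#' tallies and parameters, so counting and testing can run as separate,
#' file-driven stages.
#'
#' @param counts A `LinkCounts`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_link_counts <- function(counts, dir) {
  stopifnot(inherits(counts, "LinkCounts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(counts$counts, file.path(dir, "link_counts.tsv"),
                     sep = "\t")
  write_read_assignments(counts, file.path(dir, "read_assignments.txt"))
  jsonlite::write_json(list(totals = counts$totals, params = counts$params),
                       file.path(dir, "counts.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read link counts written by [write_link_counts()]
#'
#' @param dir Counts directory.
#' @return A `LinkCounts`.
#' @export
read_link_counts <- function(dir) {
  need <- file.path(dir, c("link_counts.tsv", "read_assignments.txt",
                           "counts.json"))
  if (!all(file.exists(need))) {
    stop("'", dir, "' is not a link-counts directory")
  }
  meta <- jsonlite::read_json(need[3L], simplifyVector = TRUE)
  structure(list(
    counts = data.table::fread(need[1L], sep = "\t"),
    assignments = as.data.frame(data.table::fread(need[2L], sep = "\t",
                                                  na.strings = "NA")),
    totals = meta$totals, params = meta$params), class = "LinkCounts")
}
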