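# Independent oracles and tiny fixture builders shared across tests.

# Brute-force single-linkage clustering: repeatedly merge any two
# groups containing positions within `window` of each other, until a
# fixed point. Order-independent by construction.
oracle_single_linkage <- function(positions, window) {
  groups <- as.list(sort(unique(positions)))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i >= j) next
        d <- min(abs(outer(groups[[i]], groups[[j]], "-")))
        if (d <= window) {
          groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups[order(vapply(groups, min, numeric(1)))]
}

# Exact conditional p value for a 2x2 table by exhaustive enumeration
# of all tables with the observed margins (hypergeometric weights).
oracle_2x2_exact_p <- function(m) {
  stopifnot(dim(m) == c(2L, 2L))
  r <- rowSums(m); cc <- colSums(m)
  E <- outer(r, cc) / sum(m)
  stat_of <- function(x) {
    t <- matrix(c(x, cc[1] - x, r[1] - x, r[2] - cc[1] + x), 2, 2)
    sum((t - E)^2 / E)
  }
  obs <- stat_of(m[1, 1])
  xs <- max(0, cc[1] - r[2]):min(r[1], cc[1])
  probs <- stats::dhyper(xs, r[1], r[2], cc[1])
  stats <- vapply(xs, stat_of, numeric(1))
  sum(probs[stats >= obs - 1e-9])
}

# Minimal GTF writer for crafted fixtures. `df` needs columns contig,
# start, end, strand, gene_id, transcript_id and optionally biotype.
write_test_gtf <- function(df, path, with_biotype = TRUE) {
  bt <- if (!is.null(df$biotype)) df$biotype else "protein_coding"
  attrs <- if (with_biotype) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
            df$gene_id, df$transcript_id, bt)
  } else {
    sprintf('gene_id "%s"; transcript_id "%s";', df$gene_id,
            df$transcript_id)
  }
  writeLines(paste(df$contig, "test", "exon", df$start, df$end, ".",
                   df$strand, ".", attrs, sep = "\t"), path)
  invisible(path)
}

# Minimal aligned-read writer. `df` needs qname, flag, pos, cigar;
# returns an indexed BAM path.
write_test_bam <- function(df, path, contig = "chr1", contig_len = 100000L,
                           mapq = NULL) {
  if (is.null(mapq)) mapq <- rep(60L, nrow(df))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", contig, "\tLN:", contig_len),
    paste(df$qname, df$flag, contig, df$pos, mapq, df$cigar,
          "*", 0L, 0L, "*", "*", sep = "\t")[order(df$pos)]
  ), sam)
  Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                   indexDestination = TRUE)
  path
}

# A two-TSS / two-TES gene annotation used by several tests:
# '+' gene with TSSs 1000/1500, TESs 6000/6500, single junction-free
# structure per transcript (2 exons around one intron).
two_by_two_gtf <- function(path) {
  rows <- list()
  for (k in 1:2) {
    for (j in 1:2) {
      tssp <- c(1000L, 1500L)[k]
      tesp <- c(6000L, 6500L)[j]
      tid <- sprintf("gA.t%d%d", k, j)
      rows[[tid]] <- data.frame(
        contig = "chr1", start = c(tssp, 4000L), end = c(2000L, tesp),
        strand = "+", gene_id = "gA", transcript_id = tid)
    }
  }
  write_test_gtf(do.call(rbind, rows), path)
}
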