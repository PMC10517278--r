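#' Simulation configuration
#'
#' Describes a synthetic multi-gene locus and a long-read experiment
#' over it with known coupling structure. Each gene carries `n_tss`
#' alternative start positions and `n_tes` alternative end positions,
#' spaced `cluster_spacing` nt apart (well beyond the default assignment
#' windows, so recovery is unambiguous), plus `n_internal_exons`
#' internal exons that may be skipped with a TSS-dependent probability.
#'
#' @param n_genes Number of genes (default 10).
#' @param n_tss,n_tes Alternative TSS/TES positions per gene (default 2
#'   each).
#' @param n_internal_exons Internal exons per gene (default 2).
#' @param cluster_spacing Distance between alternative end positions in
#'   nt (default 500).
#' @param exon_length,intron_length Internal exon and intron lengths in
#'   nt (defaults 150 / 300).
#' @param utr_length Length of the constitutive part of the first and
#'   last exon (default 100).
#' @param intergenic_gap Gap between genes (default 1000).
#' @param contig Contig name (default "simchr").
#' @param strands `"both"` (alternate + and -), `"+"` or `"-"`.
#' @param n_reads Reads per gene (default 200).
#' @param tss_weights Marginal TSS usage probabilities (default
#'   uniform).
#' @param coupling TSS x TES conditional probability matrix (rows sum
#'   to 1), a list of one matrix per gene, or `NULL` for independence
#'   with uniform TES usage.
#' @param exon_inclusion Matrix (`n_tss` x `n_internal_exons`) of
#'   junction/exon inclusion probabilities conditional on the TSS, a
#'   per-gene list, or `NULL` for constitutive inclusion.
#' @param end_jitter_sd Standard deviation (nt) of the truncated-normal
#'   jitter applied to both read ends; jitter is capped at half the
#'   respective assignment window so an unjittered identity between
#'   simulated and recovered clusters is preserved (default 10).
#' @param truncation_fraction Fraction of reads whose 5' end is
#'   truncated beyond the TSS assignment window (default 0.2, a typical
#'   share of incomplete cDNAs in long-read libraries).
#' @param truncation_scale Mean of the exponential exonic-distance tail
#'   added beyond the TSS window for truncated reads (default 150 nt).
#' @param junction_noise Bound (nt) of the uniform noise applied to
#'   each intron boundary of emitted alignments (default 0).
#' @param tss_window,tes_window Assignment windows the experiment is
#'   meant to be analysed with; used for jitter caps and truncation
#'   distances (defaults 50 / 150).
#' @param seed Integer seed (default 1).
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 10, n_tss = 2, n_tes = 2,
                       n_internal_exons = 2, cluster_spacing = 500,
                       exon_length = 150, intron_length = 300,
                       utr_length = 100, intergenic_gap = 1000,
                       contig = "simchr", strands = c("both", "+", "-"),
                       n_reads = 200, tss_weights = NULL, coupling = NULL,
                       exon_inclusion = NULL, end_jitter_sd = 10,
                       truncation_fraction = 0.2, truncation_scale = 150,
                       junction_noise = 0, tss_window = 50,
                       tes_window = 150, seed = 1) {
  strands <- match.arg(strands)
  stopifnot(n_genes >= 1, n_tss >= 1, n_tes >= 1, n_internal_exons >= 0,
            cluster_spacing > 0, exon_length > 0, intron_length > 0,
            utr_length > 0, n_reads >= 0, end_jitter_sd >= 0,
            truncation_fraction >= 0, truncation_fraction <= 1,
            junction_noise >= 0)
  if (junction_noise > 0 && junction_noise * 2 >= min(exon_length, utr_length,
                                                      intron_length)) {
    stop("junction_noise too large for the exon/intron geometry")
  }
  if (is.null(tss_weights)) tss_weights <- rep(1 / n_tss, n_tss)
  stopifnot(length(tss_weights) == n_tss, all(tss_weights >= 0),
            abs(sum(tss_weights) - 1) < 1e-8)
  chk_coupling <- function(m) {
    stopifnot(is.matrix(m), nrow(m) == n_tss, ncol(m) == n_tes,
              all(m >= 0), all(abs(rowSums(m) - 1) < 1e-8))
  }
  if (is.matrix(coupling)) chk_coupling(coupling)
  if (is.list(coupling)) {
    stopifnot(length(coupling) == n_genes)
    lapply(coupling, chk_coupling)
  }
  chk_incl <- function(m) {
    stopifnot(is.matrix(m), nrow(m) == n_tss, ncol(m) == n_internal_exons,
              all(m >= 0), all(m <= 1))
  }
  if (is.matrix(exon_inclusion)) chk_incl(exon_inclusion)
  if (is.list(exon_inclusion)) {
    stopifnot(length(exon_inclusion) == n_genes)
    lapply(exon_inclusion, chk_incl)
  }
  structure(as.list(environment()), class = "SimConfig")
}

#' 2x2 TSS-TES coupling matrix with a given odds ratio
#'
#' Symmetric coupling where each TSS prefers its "own" TES:
#' `[[a, 1-a], [1-a, a]]` with `(a / (1-a))^2 = odds_ratio`.
#'
#' @param odds_ratio Target odds ratio (1 = independence).
#' @return A 2x2 row-stochastic matrix.
#' @export
coupling_from_odds_ratio <- function(odds_ratio) {
  stopifnot(odds_ratio > 0)
  a <- sqrt(odds_ratio) / (1 + sqrt(odds_ratio))
  matrix(c(a, 1 - a, 1 - a, a), 2, 2, byrow = TRUE)
}

.gene_coupling <- function(config, gi) {
  cp <- config$coupling
  if (is.null(cp)) {
    return(matrix(1 / config$n_tes, config$n_tss, config$n_tes))
  }
  if (is.list(cp)) cp[[gi]] else cp
}

.gene_inclusion <- function(config, gi) {
  inc <- config$exon_inclusion
  if (is.null(inc)) {
    return(matrix(1, config$n_tss, max(config$n_internal_exons, 1L))[
      , seq_len(config$n_internal_exons), drop = FALSE])
  }
  if (is.list(inc)) inc[[gi]] else inc
}

# Geometry of one gene, laid out left to right. "left"/"right" anchor
# positions become TSSs or TESs depending on strand.
.gene_layout <- function(config, gi, offset) {
  strand <- if (config$strands == "both") {
    if (gi %% 2L == 1L) "+" else "-"
  } else config$strands
  n_left <- if (strand == "+") config$n_tss else config$n_tes
  n_right <- if (strand == "+") config$n_tes else config$n_tss
  left <- offset + (seq_len(n_left) - 1L) * config$cluster_spacing
  d0 <- left[n_left] + config$utr_length
  M <- config$n_internal_exons
  a <- b <- integer(M)
  prev <- d0
  for (m in seq_len(M)) {
    a[m] <- prev + config$intron_length + 1L
    b[m] <- a[m] + config$exon_length - 1L
    prev <- b[m]
  }
  aL <- prev + config$intron_length + 1L
  right <- aL + config$utr_length + (seq_len(n_right) - 1L) *
    config$cluster_spacing
  # transcriptional 5'->3' order of the anchors
  if (strand == "+") {
    tss_pos <- left; tes_pos <- right
  } else {
    tss_pos <- rev(right); tes_pos <- rev(left)
  }
  list(gene_id = sprintf("simg%02d", gi), strand = strand,
       left = left, right = right, d0 = d0, aL = aL,
       internal_start = a, internal_end = b,
       tss_pos = tss_pos, tes_pos = tes_pos,
       span = c(offset, right[n_right]),
       coupling = .gene_coupling(config, gi),
       inclusion = .gene_inclusion(config, gi))
}

# Exon blocks (genomic, left to right) of a transcript anchored at the
# given left/right outer positions, with the logical inclusion vector
# selecting internal exons.
.transcript_blocks <- function(layout, left_pos, right_pos, incl) {
  starts <- c(left_pos, layout$internal_start[incl], layout$aL)
  ends <- c(layout$d0, layout$internal_end[incl], right_pos)
  cbind(start = starts, end = ends)
}

#' Generate a synthetic annotation
#'
#' Lays out `n_genes` non-overlapping genes on one contig and emits a
#' transcript for every TSS x TES combination (all internal exons
#' included) plus, for every subset of skippable internal exons (those
#' with an inclusion probability below 1 for any TSS), a transcript
#' lacking them — so every junction the read simulator can produce is
#' annotated. The layout is deterministic given the configuration.
#'
#' @param config A `SimConfig`.
#' @param gtf_path Optional path; when given, the annotation is written
#'   as GTF (Ensembl attribute dialect, `gene_biotype`
#'   `"protein_coding"`).
#' @return An object of class `SimAnnotation`: list with `exons` (a
#'   `GRanges` suitable for [prepare_isoform_database()]), `layouts`
#'   (per-gene geometry and generating parameters), `contig_length` and
#'   `config`.
#' @export
generate_annotation <- function(config, gtf_path = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  layouts <- vector("list", config$n_genes)
  offset <- 1001L
  for (gi in seq_len(config$n_genes)) {
    layouts[[gi]] <- .gene_layout(config, gi, offset)
    offset <- layouts[[gi]]$span[2L] + config$intergenic_gap
  }
  contig_length <- offset + 10000L

  rows <- list()
  for (lay in layouts) {
    M <- config$n_internal_exons
    skippable <- if (M > 0L) which(apply(lay$inclusion < 1, 2L, any)) else integer()
    tn <- 0L
    add_tx <- function(left_pos, right_pos, incl) {
      tn <<- tn + 1L
      blocks <- .transcript_blocks(lay, left_pos, right_pos, incl)
      data.table::data.table(
        contig = config$contig, start = blocks[, "start"],
        end = blocks[, "end"], strand = lay$strand,
        gene_id = lay$gene_id,
        transcript_id = sprintf("%s.t%02d", lay$gene_id, tn))
    }
    all_in <- rep(TRUE, M)
    for (l in lay$left) {
      for (r in lay$right) {
        rows[[length(rows) + 1L]] <- add_tx(l, r, all_in)
      }
    }
    if (length(skippable) > 0L) {
      subsets <- unlist(lapply(seq_along(skippable), function(k)
        utils::combn(skippable, k, simplify = FALSE)), recursive = FALSE)
      for (s in subsets) {
        incl <- all_in; incl[s] <- FALSE
        rows[[length(rows) + 1L]] <- add_tx(lay$left[1L], lay$right[1L], incl)
      }
    }
  }
  ex <- data.table::rbindlist(rows)
  exons <- GenomicRanges::GRanges(
    ex$contig, IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
    type = "exon", gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    gene_biotype = "protein_coding")
  ann <- structure(list(exons = exons, layouts = layouts,
                        contig_length = contig_length, config = config),
                   class = "SimAnnotation")
  if (!is.null(gtf_path)) write_sim_gtf(ann, gtf_path)
  ann
}

#' Write a simulated annotation as GTF
#'
#' @param annotation A `SimAnnotation`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_sim_gtf <- function(annotation, path) {
  ex <- annotation$exons
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$gene_id, ex$transcript_id, ex$gene_biotype)
  lines <- paste(as.character(GenomicRanges::seqnames(ex)), "isocouple_sim",
                 "exon", GenomicRanges::start(ex), GenomicRanges::end(ex),
                 ".", as.character(GenomicRanges::strand(ex)), ".", attrs,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# truncated-normal integer jitter, |delta| <= cap
.rjitter <- function(n, sd, cap) {
  if (sd == 0 || cap == 0 || n == 0L) return(integer(n))
  x <- stats::rnorm(n, 0, sd)
  while (any(abs(x) > cap)) {
    bad <- abs(x) > cap
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  as.integer(round(x))
}

#' Simulate aligned long reads with known coupling structure
#'
#' For every gene and read, samples a TSS from the marginal weights, a
#' TES from the gene's coupling matrix row, and internal-exon
#' inclusions conditional on the TSS; applies bounded end jitter, 5'
#' truncation (moving the 5' end beyond the TSS assignment window along
#' the spliced transcript) and bounded junction-boundary noise; and
#' emits spliced alignments as a coordinate-sorted, indexed BAM
#' together with a per-read truth table.
#'
#' @param config A `SimConfig`.
#' @param annotation The matching `SimAnnotation`.
#' @param bam_path Output BAM path (a temporary SAM is converted with
#'   [Rsamtools::asBam()]).
#' @param truth_path Optional TSV path for the truth table.
#' @param seed Seed; defaults to `config$seed`.
#' @return List with `bam` (path) and `truth` (`data.frame`: read_id,
#'   gene_id, tss_id, tes_id, chain, truncated).
#' @export
simulate_reads <- function(config, annotation, bam_path, truth_path = NULL,
                           seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"), inherits(annotation, "SimAnnotation"))
  cap5 <- floor(config$tss_window / 2)
  cap3 <- floor(config$tes_window / 2)
  sim <- function() {
    out <- list()
    for (lay in annotation$layouts) {
      n <- config$n_reads
      if (n == 0L) next
      k <- sample.int(config$n_tss, n, replace = TRUE,
                      prob = config$tss_weights)
      j <- vapply(k, function(ki) sample.int(config$n_tes, 1L,
                                             prob = lay$coupling[ki, ]),
                  integer(1))
      M <- config$n_internal_exons
      d5 <- .rjitter(n, config$end_jitter_sd, cap5)
      d3 <- .rjitter(n, config$end_jitter_sd, cap3)
      trunc <- stats::runif(n) < config$truncation_fraction
      recs <- vector("list", n)
      for (r in seq_len(n)) {
        incl <- if (M > 0L) {
          stats::runif(M) < lay$inclusion[k[r], ]
        } else logical(0)
        tssp <- lay$tss_pos[k[r]]
        tesp <- lay$tes_pos[j[r]]
        plus <- lay$strand == "+"
        j5 <- if (trunc[r]) 0L else d5[r]  # truncation supersedes 5' jitter
        left_pos <- if (plus) tssp + j5 else tesp + d3[r]
        right_pos <- if (plus) tesp + d3[r] else tssp - j5
        blocks <- .transcript_blocks(lay, left_pos, right_pos, incl)
        if (trunc[r]) {
          # move the 5' end past the assignment window of every TSS of
          # the gene (measured in spliced-transcript coordinates), so a
          # truncated read is by construction not full length
          anchor_dist <- if (plus) max(lay$tss_pos) - tssp else {
            tssp - min(lay$tss_pos)
          }
          shift <- anchor_dist + config$tss_window + 1L +
            as.integer(floor(stats::rexp(1L, 1 / config$truncation_scale)))
          total <- sum(blocks[, "end"] - blocks[, "start"] + 1L)
          shift <- min(shift, total - 50L)
          blocks <- .truncate_blocks(blocks, shift, from_left = plus)
        }
        chain <- .blocks_chain(blocks)
        if (config$junction_noise > 0 && nrow(blocks) > 1L) {
          nz <- config$junction_noise
          for (bi in seq_len(nrow(blocks) - 1L)) {
            blocks[bi, "end"] <- blocks[bi, "end"] +
              sample.int(2L * nz + 1L, 1L) - nz - 1L
            blocks[bi + 1L, "start"] <- blocks[bi + 1L, "start"] +
              sample.int(2L * nz + 1L, 1L) - nz - 1L
          }
        }
        recs[[r]] <- list(blocks = blocks, chain = chain)
      }
      out[[lay$gene_id]] <- list(lay = lay, k = k, j = j, trunc = trunc,
                                 recs = recs)
    }
    out
  }
  res <- withr::with_seed(seed, sim())

  sam_rows <- list(); truth_rows <- list()
  for (gene in res) {
    lay <- gene$lay
    n <- length(gene$k)
    for (r in seq_len(n)) {
      blocks <- gene$recs[[r]]$blocks
      read_id <- sprintf("%s_r%05d", lay$gene_id, r)
      cigar <- .blocks_cigar(blocks)
      sam_rows[[length(sam_rows) + 1L]] <- data.table::data.table(
        qname = read_id, flag = if (lay$strand == "+") 0L else 16L,
        rname = config$contig, pos = blocks[1L, "start"], mapq = 60L,
        cigar = cigar)
      truth_rows[[length(truth_rows) + 1L]] <- data.table::data.table(
        read_id = read_id, gene_id = lay$gene_id,
        tss_id = paste0(lay$gene_id, ":TSS", gene$k[r]),
        tes_id = paste0(lay$gene_id, ":TES", gene$j[r]),
        chain = gene$recs[[r]]$chain,
        truncated = gene$trunc[r])
    }
  }
  sam <- data.table::rbindlist(sam_rows)
  truth <- as.data.frame(data.table::rbindlist(truth_rows))
  .write_sam_bam(sam, config$contig, annotation$contig_length, bam_path)
  if (!is.null(truth_path)) {
    data.table::fwrite(truth, truth_path, sep = "\t")
  }
  invisible(list(bam = bam_path, truth = truth))
}

# Remove `shift` exonic bases from the transcript 5' end of a block
# matrix (left end for plus-strand genes, right end otherwise).
.truncate_blocks <- function(blocks, shift, from_left) {
  if (shift <= 0L) return(blocks)
  if (from_left) {
    for (i in seq_len(nrow(blocks))) {
      w <- blocks[i, "end"] - blocks[i, "start"] + 1L
      if (shift < w) {
        blocks[i, "start"] <- blocks[i, "start"] + shift
        return(blocks[i:nrow(blocks), , drop = FALSE])
      }
      shift <- shift - w
    }
  } else {
    for (i in rev(seq_len(nrow(blocks)))) {
      w <- blocks[i, "end"] - blocks[i, "start"] + 1L
      if (shift < w) {
        blocks[i, "end"] <- blocks[i, "end"] - shift
        return(blocks[1:i, , drop = FALSE])
      }
      shift <- shift - w
    }
  }
  blocks[1L, , drop = FALSE]
}

.blocks_chain <- function(blocks) {
  if (nrow(blocks) < 2L) return("")
  paste0(blocks[-nrow(blocks), "end"] + 1L, "-",
         blocks[-1L, "start"] - 1L, collapse = ";")
}

.blocks_cigar <- function(blocks) {
  nb <- nrow(blocks)
  m <- blocks[, "end"] - blocks[, "start"] + 1L
  if (nb == 1L) return(paste0(m, "M"))
  gaps <- blocks[-1L, "start"] - blocks[-nb, "end"] - 1L
  paste0(paste0(m[-nb], "M", gaps, "N", collapse = ""), m[nb], "M")
}

# Write alignment rows as SAM and convert to a sorted, indexed BAM.
.write_sam_bam <- function(sam, contig, contig_length, bam_path) {
  data.table::setorder(sam, pos, qname)
  sam_file <- tempfile(fileext = ".sam")
  on.exit(unlink(sam_file), add = TRUE)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", contig, "\tLN:", contig_length))
  body <- paste(sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                sam$cigar, "*", 0L, 0L, "*", "*", sep = "\t")
  writeLines(c(header, body), sam_file)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam_file, dest, overwrite = TRUE,
                   indexDestination = TRUE)
  invisible(bam_path)
}

#' Write the simulated truth junctions as a STAR SJ.out.tab file
#'
#' Emits every junction of the simulated annotation with a declared
#' unique-read support count, optionally adding decoy junctions (offset
#' copies of real ones) with low support, so that `min_jcounts`
#' filtering is exercised.
#'
#' @param config A `SimConfig`.
#' @param annotation The matching `SimAnnotation`.
#' @param path Output path.
#' @param support Unique-mapper count for true junctions (default 50).
#' @param n_decoys Number of decoy junctions (default 0).
#' @param decoy_count Unique-mapper count for decoys (default 1).
#' @return `path`, invisibly.
#' @export
write_star_sj <- function(config, annotation, path, support = 50,
                          n_decoys = 0, decoy_count = 1) {
  jj <- .annotation_junctions(annotation$exons)
  dt <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(jj)),
    start = GenomicRanges::start(jj),
    end = GenomicRanges::end(jj),
    strand_code = ifelse(as.character(GenomicRanges::strand(jj)) == "+",
                         1L, 2L),
    motif = 1L, annotated = 1L, n_unique = as.integer(support),
    n_multi = 0L, overhang = 30L)
  if (n_decoys > 0L) {
    n_decoys <- min(n_decoys, nrow(dt))
    dec <- dt[seq_len(n_decoys)]
    dec[, `:=`(start = start + 37L, end = end + 37L,
               annotated = 0L, n_unique = as.integer(decoy_count))]
    dt <- rbind(dt, dec)
  }
  data.table::setorder(dt, contig, start, end)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
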