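#' Expected counts under independence
#'
#' For a contingency table of observed counts, the expected count in
#' cell (i, j) under row/column independence is
#' `rowsum_i * colsum_j / total`.
#'
#' @param observed Non-negative integer matrix with positive total.
#' @return Real matrix of expected counts with the same dimnames.
#' @export
expected_table <- function(observed) {
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed must contain non-negative integer counts")
  }
  total <- sum(observed)
  if (total == 0) stop("degenerate input: all-zero count table")
  outer(rowSums(observed), colSums(observed)) / total
}

# Drop all-zero rows/columns (their expected counts are zero and the
# chi-squared statistic is undefined there).
.drop_zero_margins <- function(m, warn = TRUE) {
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (warn && (!all(keep_r) || !all(keep_c))) {
    warning("dropping ", sum(!keep_r), " zero row(s) and ", sum(!keep_c),
            " zero column(s) before testing")
  }
  m[keep_r, keep_c, drop = FALSE]
}

#' Monte-Carlo chi-squared test of independence
#'
#' Computes the Pearson chi-squared statistic of a contingency table and
#' a Monte-Carlo p value. Null tables are, by default, drawn uniformly
#' from the set of tables with the observed row and column margins
#' (Patefield sampling via [stats::r2dtable()]), i.e. the conditional
#' test; `null = "multinomial"` instead resamples the table from the
#' independence multinomial with the observed margins as probabilities,
#' for sensitivity analysis. The p value is
#' `(1 + #\{simulated stat >= observed\}) / (B + 1)`, so its floor is
#' `1 / (B + 1)`.
#'
#' @param observed Count matrix with at least two positive rows and two
#'   positive columns (all-zero margins are dropped with a warning).
#' @param B Number of Monte-Carlo null tables (default 2000).
#' @param seed Optional integer seed; the global RNG state is left
#'   untouched when it is supplied.
#' @param null `"patefield"` (fixed margins, default) or
#'   `"multinomial"`.
#' @return List with `stat`, `p`, `df`, `expected`, `residuals`
#'   (Pearson, `(O - E) / sqrt(E)`), `observed` (after margin drop) and
#'   `B`.
#' @export
chisq_mc_test <- function(observed, B = 2000, seed = NULL,
                          null = c("patefield", "multinomial")) {
  null <- match.arg(null)
  stopifnot(B >= 1)
  m <- .drop_zero_margins(as.matrix(observed))
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 rows and 2 columns with positive margins")
  }
  E <- expected_table(m)
  stat <- sum((m - E)^2 / E)
  rs <- as.integer(rowSums(m)); cs <- as.integer(colSums(m)); n <- sum(rs)
  sim_stats <- function() {
    if (null == "patefield") {
      sims <- stats::r2dtable(B, rs, cs)
      vapply(sims, function(s) sum((s - E)^2 / E), numeric(1))
    } else {
      pr <- as.vector(E) / n
      sims <- stats::rmultinom(B, n, pr)
      apply(sims, 2L, function(v) {
        s <- matrix(v, nrow(m), ncol(m))
        Es <- expected_table(s)
        sum((s - Es)^2 / Es, na.rm = TRUE)
      })
    }
  }
  stats_sim <- if (is.null(seed)) sim_stats() else {
    withr::with_seed(seed, sim_stats())
  }
  p <- (1 + sum(stats_sim >= stat - 1e-9)) / (B + 1)
  list(stat = stat, p = p, df = (nrow(m) - 1L) * (ncol(m) - 1L),
       expected = E, residuals = (m - E) / sqrt(E), observed = m, B = B)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control across a family of p values,
#' preserving input order.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted q values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Test TSS-TES couplings and promoter dominance
#'
#' For every gene with at least two TSS and two TES clusters and at
#' least `min_reads` full-length reads, tests the TSS x TES count table
#' for independence with the Monte-Carlo chi-squared test, adjusts p
#' values across tested genes with Benjamini-Hochberg, flags coupled
#' (TSS, TES) pairs and summarizes promoter dominance as the per-TSS
#' contribution fractions to each 3' end.
#'
#' A pair is `coupled` when its gene's q value is at most `alpha` and
#' the absolute Pearson residual of the cell is at least
#' `residual_cutoff`. A TES has a `dominant_tss` when its gene is
#' significant and the largest contribution fraction reaches
#' `dominance_threshold`.
#'
#' @param counts A `LinkCounts` object.
#' @param db The `IsoformDatabase` the counts were made with.
#' @param method Test method; only `"chisq"` (Monte-Carlo chi-squared)
#'   is implemented.
#' @param B Monte-Carlo replicates per gene (default 2000).
#' @param alpha Significance level on BH-adjusted q values (default
#'   0.01).
#' @param residual_cutoff Minimum absolute Pearson residual for a pair
#'   to be called coupled (default 0.5).
#' @param min_reads Minimum full-length reads for a gene to be tested
#'   (default 20).
#' @param dominance_threshold Minimum contribution fraction for a
#'   dominant TSS call (default 0.5).
#' @param seed Optional integer seed for reproducible Monte-Carlo
#'   p values.
#' @param null Null sampling scheme, see [chisq_mc_test()].
#' @return An object of class `CouplingResult`: list with `genes`
#'   (gene-level statistics, one row per multi-TSS/multi-TES gene),
#'   `pairs` (per tested cell: observed, expected, residual, coupled)
#'   and `dominance` (per TES: contribution fraction of each TSS and
#'   the dominant TSS, if any), plus `params`.
#' @export
estimate_promoter_dominance <- function(counts, db, method = "chisq",
                                        B = 2000, alpha = 0.01,
                                        residual_cutoff = 0.5,
                                        min_reads = 20,
                                        dominance_threshold = 0.5,
                                        seed = NULL,
                                        null = c("patefield", "multinomial")) {
  method <- match.arg(method, "chisq")
  null <- match.arg(null)
  stopifnot(inherits(counts, "LinkCounts"), inherits(db, "IsoformDatabase"))
  known <- db$clusters$cluster_id
  used <- unique(c(counts$counts$tss_id, counts$counts$tes_id))
  if (!all(used %in% known)) {
    stop("counts reference cluster ids unknown to the database; ",
         "counts and database are inconsistent")
  }
  cl <- db$clusters
  shape <- data.table::as.data.table(cl)[
    , list(n_tss = sum(kind == "TSS"), n_tes = sum(kind == "TES")),
    by = "gene_id"]
  eligible <- shape[shape$n_tss >= 2L & shape$n_tes >= 2L]

  run <- function() {
    genes_out <- vector("list", nrow(eligible))
    pairs_out <- vector("list", nrow(eligible))
    dom_out <- vector("list", nrow(eligible))
    for (i in seq_len(nrow(eligible))) {
      g <- eligible$gene_id[i]
      m <- link_matrix(counts, g)
      n_fl <- sum(m)
      red <- .drop_zero_margins(m, warn = FALSE)
      testable <- n_fl >= min_reads && nrow(red) >= 2L && ncol(red) >= 2L
      if (!testable) {
        genes_out[[i]] <- data.table::data.table(
          gene_id = g, n_full_length = n_fl,
          n_tss = eligible$n_tss[i], n_tes = eligible$n_tes[i],
          chisq_stat = NA_real_, p_value = NA_real_, tested = FALSE)
        next
      }
      fit <- chisq_mc_test(red, B = B, null = null)
      genes_out[[i]] <- data.table::data.table(
        gene_id = g, n_full_length = n_fl,
        n_tss = eligible$n_tss[i], n_tes = eligible$n_tes[i],
        chisq_stat = fit$stat, p_value = fit$p, tested = TRUE)
      idx <- expand.grid(ti = seq_len(nrow(red)), tj = seq_len(ncol(red)))
      pairs_out[[i]] <- data.table::data.table(
        gene_id = g,
        tss_id = rownames(red)[idx$ti], tes_id = colnames(red)[idx$tj],
        observed_count = as.integer(red[as.matrix(idx)]),
        expected_count = fit$expected[as.matrix(idx)],
        residual = fit$residuals[as.matrix(idx)])
      frac <- sweep(red, 2L, colSums(red), "/")
      dom_out[[i]] <- data.table::data.table(
        gene_id = g,
        tes_id = rep(colnames(red), each = nrow(red)),
        tss_id = rep(rownames(red), times = ncol(red)),
        fraction = as.vector(frac))
    }
    list(genes = data.table::rbindlist(genes_out),
         pairs = data.table::rbindlist(pairs_out),
         dominance = data.table::rbindlist(dom_out))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  genes <- res$genes
  genes[, q_value := NA_real_]
  genes[tested == TRUE, q_value := bh_adjust(p_value)]
  sig <- genes$gene_id[genes$tested & !is.na(genes$q_value) &
                         genes$q_value <= alpha]
  pairs <- res$pairs
  if (nrow(pairs) > 0L) {
    pairs[, coupled := gene_id %in% sig & abs(residual) >= residual_cutoff]
  }
  dominance <- res$dominance
  if (nrow(dominance) > 0L) {
    dominance[, `:=`(is_max = fraction == max(fraction),
                     max_frac = max(fraction)), by = c("gene_id", "tes_id")]
    dominance[, dominant_tss := ifelse(
      gene_id %in% sig & max_frac >= dominance_threshold,
      tss_id[which.max(fraction)], NA_character_),
      by = c("gene_id", "tes_id")]
    dominance[, c("is_max", "max_frac") := NULL]
  }
  structure(list(genes = as.data.frame(genes), pairs = as.data.frame(pairs),
                 dominance = as.data.frame(dominance),
                 params = list(method = method, B = B, alpha = alpha,
                               residual_cutoff = residual_cutoff,
                               min_reads = min_reads,
                               dominance_threshold = dominance_threshold,
                               null = null, seed = seed)),
            class = "CouplingResult")
}

#' @export
print.CouplingResult <- function(x, ...) {
  g <- x$genes
  cat("CouplingResult:", nrow(g), "multi-TSS/multi-TES genes;",
      sum(g$tested), "tested;",
      sum(g$tested & g$q_value <= x$params$alpha, na.rm = TRUE),
      "significant at q <=", x$params$alpha, "\n")
  invisible(x)
}

#' Gene-level coupling statistics
#' @param x A `CouplingResult`.
#' @return `data.frame` of gene-level test results.
#' @export
gene_results <- function(x) {
  stopifnot(inherits(x, "CouplingResult"))
  x$genes
}

#' Pair-level coupling statistics
#' @param x A `CouplingResult`.
#' @return `data.frame` of per-pair observed/expected counts, residuals
#'   and coupled flags.
#' @export
pair_stats <- function(x) {
  stopifnot(inherits(x, "CouplingResult"))
  x$pairs
}

#' Promoter-dominance fractions
#' @param x A `CouplingResult`.
#' @return `data.frame` of per-TES TSS contribution fractions.
#' @export
dominance <- function(x) {
  stopifnot(inherits(x, "CouplingResult"))
  x$dominance
}
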