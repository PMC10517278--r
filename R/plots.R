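#' Transcriptome-wide coupling bias scatter plot
#'
#' Scatter of log10 expected versus log10 observed counts over all
#' tested (TSS, TES) pairs; pairs passing both the significance and the
#' residual cut-off are highlighted.
#'
#' @param results A `CouplingResult`.
#' @param xlim,ylim Upper axis limits on the log10 count scale
#'   (default 2.5).
#' @param residual Absolute Pearson residual cut-off used for
#'   highlighting (default 0.5).
#' @param show_genes Label highlighted pairs with their gene id.
#' @return A `ggplot` object.
#' @export
plot_bias <- function(results, xlim = 2.5, ylim = 2.5, residual = 0.5,
                      show_genes = FALSE) {
  stopifnot(inherits(results, "CouplingResult"))
  p <- results$pairs
  if (nrow(p) == 0L) stop("no tested pairs to plot")
  sig <- results$genes$gene_id[results$genes$tested &
                                 results$genes$q_value <= results$params$alpha]
  df <- data.frame(
    x = log10(p$expected_count + 0.5),
    y = log10(p$observed_count + 0.5),
    highlighted = p$gene_id %in% sig & abs(p$residual) >= residual,
    gene_id = p$gene_id)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(data = df[!df$highlighted, ], colour = "grey30",
                        alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = df[df$highlighted, ], colour = "red",
                        size = 1.4) +
    ggplot2::coord_cartesian(xlim = c(0, xlim), ylim = c(0, ylim)) +
    ggplot2::labs(x = "log10 expected count", y = "log10 observed count") +
    ggplot2::theme_classic()
  if (show_genes && any(df$highlighted)) {
    gg <- gg + ggplot2::geom_text(
      data = df[df$highlighted, ],
      ggplot2::aes(label = .data$gene_id),
      size = 2.5, vjust = -0.8, colour = "red")
  }
  gg
}

#' Per-gene promoter-dominance plot
#'
#' Stacked bars of the contribution of each TSS to the expression of
#' each 3' end of one gene.
#'
#' @param results A `CouplingResult`.
#' @param gene_id Gene to plot; must be among the tested genes.
#' @return A `ggplot` object.
#' @export
plot_gene <- function(results, gene_id) {
  stopifnot(inherits(results, "CouplingResult"))
  d <- results$dominance[results$dominance$gene_id == gene_id, ]
  if (nrow(d) == 0L) stop("no dominance records for gene: ", gene_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tes_id, y = .data$fraction,
                                  fill = .data$tss_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = gene_id, x = "3' end (TES cluster)",
                  y = "TSS contribution fraction", fill = "TSS") +
    ggplot2::theme_classic()
}

#' Per-gene exon-coupling residual plot
#'
#' Pearson residuals of junction inclusion per TSS (or TES) cluster for
#' every tested junction of one gene.
#'
#' @param results An `ExonCouplingResult`.
#' @param gene_id Gene to plot.
#' @param axis `"TSS"` or `"TES"`.
#' @return A `ggplot` object.
#' @export
plot_exon_couplings <- function(results, gene_id, axis = c("TSS", "TES")) {
  axis <- match.arg(axis)
  stopifnot(inherits(results, "ExonCouplingResult"))
  r <- results$residuals[results$residuals$gene_id == gene_id &
                           results$residuals$axis == axis, ]
  if (nrow(r) == 0L) stop("no tested junctions for gene: ", gene_id)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$cluster_id,
                                  y = .data$residual,
                                  fill = .data$residual > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~junction_id) +
    ggplot2::labs(title = gene_id, x = axis,
                  y = "Pearson residual (inclusion)") +
    ggplot2::theme_classic()
}
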