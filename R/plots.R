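#' Volcano plot of paired snoRNA differential expression
#'
#' log2 fold change (A/B) against -log10 p, with the threshold lines that
#' define the enriched/depleted flags drawn dashed.
#'
#' @param de A [paired_de()] result.
#' @param lfc_threshold,p_threshold Thresholds to draw (defaults mirror
#'   the flags: 1.5 and 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_threshold = 1.5, p_threshold = 0.05) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$lfc,
                                   y = -log10(.data$p),
                                   colour = .data$flag)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.6) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(enriched = "#c0392b",
                                            depleted = "#2980b9",
                                            none = "grey60")) +
    ggplot2::labs(x = "log2 fold change (A/B)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of target-level screen selection
#'
#' Targets ranked by pooled median gRNA log2 fold change; called targets
#' are colored by direction.
#'
#' @param selection An [aggregate_targets()] result.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(selection) {
  sel <- selection |>
    filter(.data$status == "tested") |>
    arrange(.data$median_lfc) |>
    mutate(rank = row_number())
  ggplot2::ggplot(sel, ggplot2::aes(x = .data$rank, y = .data$median_lfc,
                                    fill = .data$direction)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(negative = "#2980b9",
                                          positive = "#c0392b",
                                          none = "grey70")) +
    ggplot2::labs(x = "target rank", y = "median gRNA log2 LFC",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Replicate scatter of gRNA log2 fold changes
#'
#' One point per gRNA shared between two replicates, the least-squares
#' line, and the Pearson correlation in the subtitle.
#'
#' @param lfc_a,lfc_b Per-replicate [grna_lfc()] tables.
#' @return A ggplot object.
#' @export
plot_replicates <- function(lfc_a, lfc_b) {
  stats <- replicate_correlation(lfc_a, lfc_b)
  shared <- inner_join(select(lfc_a, "grna_id", lfc_a = "lfc"),
                       select(lfc_b, "grna_id", lfc_b = "lfc"),
                       by = "grna_id")
  ggplot2::ggplot(shared, ggplot2::aes(.data$lfc_a, .data$lfc_b)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "#c0392b") +
    ggplot2::labs(x = "replicate A log2 LFC", y = "replicate B log2 LFC",
                  subtitle = sprintf("R = %.2f (n = %d gRNAs)",
                                     stats$r, stats$n)) +
    ggplot2::theme_minimal()
}

#' Termination profile around a site
#'
#' Psi-ratio track (starts / overlaps per position) for one molecule,
#' annotated sites marked.
#'
#' @param profile A [build_profile()] result.
#' @param molecule Molecule to plot.
#' @param sites Optional site table; positions on `molecule` are marked.
#' @param window Optional `c(from, to)` positional window.
#' @return A ggplot object.
#' @export
plot_termination_profile <- function(profile, molecule, sites = NULL,
                                     window = NULL) {
  dat <- profile |>
    filter(.data$molecule == !!molecule) |>
    mutate(ratio = if_else(.data$n_overlap > 0,
                           .data$n_start / .data$n_overlap, NA_real_))
  if (!is.null(window)) {
    dat <- filter(dat, .data$position >= window[1],
                  .data$position <= window[2])
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$ratio)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::labs(x = sprintf("%s position (nt)", molecule),
                  y = "termination fraction") +
    ggplot2::theme_minimal()
  if (!is.null(sites)) {
    pos <- sites$position[sites$molecule == molecule]
    if (!is.null(window)) pos <- pos[pos >= window[1] & pos <= window[2]]
    if (length(pos)) {
      p <- p + ggplot2::geom_vline(xintercept = pos, colour = "#c0392b",
                                   linetype = "dotted", linewidth = 0.3)
    }
  }
  p
}

#' @method autoplot snorna_de_tbl
#' @export
autoplot.snorna_de_tbl <- function(object, ...) plot_volcano(object, ...)

#' @method autoplot target_selection_tbl
#' @export
autoplot.target_selection_tbl <- function(object, ...) {
  plot_waterfall(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
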