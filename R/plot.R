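#' Plot composite candidate loci
#'
#' Draws each locus as a horizontal track with one coloured segment per
#' member TE, positioned relative to the locus start, so the side-by-side
#' arrangement and inter-member gaps are visible at a glance.
#'
#' @param loci tibble from [chain_proximal()]; by default only composite
#'   loci (`n_members >= 2`) are shown.
#' @param composites_only drop singleton loci before plotting.
#' @return a ggplot object.
#' @export
plot_loci <- function(loci, composites_only = TRUE) {
  if (composites_only) loci <- loci[loci$is_composite, , drop = FALSE]
  if (nrow(loci) == 0) stop("no loci to plot", call. = FALSE)
  seg <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    m <- loci$members[[i]]
    tibble(
      locus = sprintf("%s:%d (%d)", loci$chrom[i], loci$start[i],
                      loci$locus_id[i]),
      xstart = m$start - loci$start[i],
      xend = m$end - loci$start[i],
      family = m$repeat_name
    )
  })
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$xstart, xend = .data$xend,
                                    y = .data$locus, yend = .data$locus,
                                    colour = .data$family)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::labs(x = "position within locus (bp)", y = NULL,
                  colour = "TE family",
                  title = "Composite TE-derived CNE loci") +
    ggplot2::theme_minimal()
}

#' Plot inferred integration order on the species tree scale
#'
#' Shows each element's gain clade and rank: lower ranks are older
#' integrations (gain nodes closer to the root); elements sharing a rank
#' are tied (equal or phylogenetically incomparable gain nodes).
#'
#' @param order tibble from [integration_order()].
#' @return a ggplot object.
#' @export
plot_integration_order <- function(order) {
  ggplot2::ggplot(order, ggplot2::aes(x = .data$rank,
                                      y = stats::reorder(.data$element,
                                                         -.data$rank))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$clade_name),
                       vjust = -1, size = 3) +
    ggplot2::scale_x_continuous(breaks = unique(order$rank)) +
    ggplot2::labs(x = "integration rank (1 = oldest)", y = NULL,
                  title = "Inferred TE integration order") +
    ggplot2::theme_minimal()
}
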