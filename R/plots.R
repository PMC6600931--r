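#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a genome-scan profile
#'
#' Support for QTL (-log10 P) along the genetic map, faceted by linkage
#' group, with an optional genome-wide threshold line.
#'
#' @param object A `qtl_scan`.
#' @param threshold Optional genome-wide P threshold to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  d <- tidy.qtl_scan(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$cM, .data$neglog10p)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)",
                  y = expression(-log[10] ~ italic(P))) +
    ggplot2::theme_bw()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot per-environment QTL effects
#'
#' Additive effects (with 2-SE ribbons) of each retained QTL across
#' environments, the reaction-norm view of G-by-E.
#'
#' @param object A `qtl_fit`.
#' @param terms Effect terms to show (default the two additive contrasts).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qtl_fit <- function(object, terms = c("a", "a2"), ...) {
  d <- object$effects |>
    dplyr::filter(.data$term %in% terms, .data$retained)
  ggplot2::ggplot(d, ggplot2::aes(.data$env, .data$estimate,
                                  group = .data$term,
                                  colour = .data$term)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 2 * .data$se,
      ymax = .data$estimate + 2 * .data$se
    ), size = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~qtl) +
    ggplot2::labs(x = "environment (site:year)", y = "allelic effect",
                  colour = "contrast") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Map a masked QTL effect surface
#'
#' @param object An `effect_surface`.
#' @param ... Unused.
#' @return A ggplot; masked cells are blank.
#' @export
autoplot.effect_surface <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d[!d$masked, ],
                  ggplot2::aes(.data$longitude, .data$latitude,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  fill = "predicted\neffect") +
    ggplot2::theme_bw()
}

#' Best-site versus worst-site trade-off plot
#'
#' Scatter of the absolute allelic effect at the best site against the
#' worst site; points on the diagonal are perfect trade-offs
#' (antagonistic pleiotropy), points on the x axis are conditionally
#' neutral.
#'
#' @param tradeoffs Output of [tradeoff_table()].
#' @param sums Plot benefit/cost sums instead of best/worst.
#' @return A ggplot.
#' @export
plot_tradeoffs <- function(tradeoffs, sums = FALSE) {
  if (sums) {
    d <- dplyr::mutate(tradeoffs, x = .data$benefit_sum,
                       y = abs(.data$cost_sum))
    labs <- c("sum of beneficial effects", "|sum of opposing effects|")
  } else {
    d <- dplyr::mutate(tradeoffs, x = .data$best, y = .data$worst)
    labs <- c("|effect| at best site", "|effect| at worst site")
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$term)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = labs[1], y = labs[2], colour = "contrast") +
    ggplot2::theme_bw()
}
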