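# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_segment geom_point
#'   labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a chromatogram
#'
#' @param object A `chromatogram` (TIC, EIC or ECC).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.chromatogram <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(.data$rt, .data$intensity)) +
    geom_line(colour = "grey20") +
    labs(x = "Retention time (min)", y = "Intensity",
         title = attr(object, "kind")) +
    theme_minimal()
}

#' Plot a quantification result
#'
#' Bar chart of valid per-state peak areas with the fraction modified in
#' the title.
#'
#' @param object A `quant_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.quant_result <- function(object, ...) {
  st <- object$states
  ggplot(st, aes(x = .data$state, y = .data$area, fill = .data$valid)) +
    ggplot2::geom_col() +
    labs(x = NULL, y = "Peak area (intensity · min)",
         title = sprintf("%s: fraction modified %s", object$sequence,
                         ifelse(object$detected,
                                sprintf("%.2f", object$fraction_modified),
                                "undetected"))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an annotated MS/MS spectrum
#'
#' Draws the filtered spectrum as sticks and overlays matched fragment ions.
#'
#' @param object An `annotation_result`.
#' @param spec The spectrum that was annotated (for the stick background).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.annotation_result <- function(object, spec = NULL, ...) {
  p <- ggplot()
  if (!is.null(spec)) {
    p <- p + geom_segment(
      data = tibble::as_tibble(spec),
      aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$intensity),
      colour = "grey70")
  }
  hits <- dplyr::filter(object$matches, !is.na(.data$matched_mz))
  if (nrow(hits) > 0) {
    p <- p + geom_segment(
      data = hits,
      aes(x = .data$matched_mz, xend = .data$matched_mz, y = 0,
          yend = .data$matched_intensity, colour = .data$series)) +
      geom_point(data = hits,
                 aes(x = .data$matched_mz, y = .data$matched_intensity,
                     colour = .data$series))
  }
  p + labs(x = "m/z", y = "Intensity",
           title = sprintf("%d/%d ions matched", object$n_matched,
                           object$n_ions)) +
    theme_minimal()
}
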