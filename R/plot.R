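# Convenience plot of observed proportions and fitted curves.

#' Plot psychometric data and fits
#'
#' Observed proportions of "simultaneous" responses against SOA, one panel
#' per condition, with the fitted scaled-Gaussian curves overlaid when a fits
#' table is supplied. Point size tracks the per-SOA presentation count (the
#' fitting weight). Intended as a quick diagnostic, not a publication figure.
#'
#' @param agg Aggregated response table ([aggregate_responses()]).
#' @param fits Optional fits table ([fit_all()]), matched by subject and
#'   condition.
#' @param subjects Optional character vector restricting the plotted
#'   subjects.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(agg, fits = NULL, subjects = NULL) {
  stopifnot(is.data.frame(agg))
  if (!is.null(subjects)) agg <- agg[agg$subject_id %in% subjects, ]
  agg <- dplyr::mutate(agg,
                       prop = .data$n_simultaneous / .data$n_presented,
                       condition = condition_label(.data$adaptation_order,
                                                   .data$outcome_predicted))
  gg <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$soa_ms, y = .data$prop)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_presented,
                                     colour = .data$subject_id),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "SOA (ms; negative = audio first)",
                  y = "P(\"simultaneous\")", size = "presentations") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    if (!is.null(subjects)) fits <- fits[fits$subject_id %in% subjects, ]
    grid <- seq(min(agg$soa_ms), max(agg$soa_ms), length.out = 201)
    curves <- fits |>
      dplyr::rowwise() |>
      dplyr::reframe(condition = condition_label(.data$adaptation_order,
                                                 .data$outcome_predicted),
                     subject_id = .data$subject_id,
                     soa_ms = grid,
                     prop = .data$scale *
                       exp(-(grid - .data$alpha_ms)^2 / (2 * .data$sigma_ms^2)))
    gg <- gg + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(group = .data$subject_id, colour = .data$subject_id),
      linewidth = 0.4, show.legend = FALSE
    )
  }
  gg
}
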