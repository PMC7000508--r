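#' Plot response-probability curves
#'
#' Probability of pCR as a function of the standardized score, one curve per
#' signature, from marginally standardized model predictions.
#'
#' @param object A `response_curve` tibble (see
#'   [response_probability_curve()]); curves for several signatures may be
#'   row-bound.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$probability,
                                       colour = .data$signature)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "score (z, SD units)",
                  y = "probability of pCR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a proliferation-floor sensitivity sweep
#'
#' Odds ratios per 1 SD (with 95% CI ribbons) against the floor percentile,
#' faceted by model block.
#'
#' @param object A `sensitivity_table` (see [sensitivity_sweep()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_table
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$percentile, y = .data$or,
                                       colour = .data$signature,
                                       fill = .data$signature)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(x = "proliferation floor percentile",
                  y = "OR per 1 SD", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of the two standardized scores
#'
#' One point per analysis sample, coloured by cohort: the visual analog of
#' the score-correlation estimate.
#'
#' @param object A `score_table` from [compute_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot score_table
#' @export
autoplot.score_table <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  if ("analysis" %in% names(dat)) dat <- dplyr::filter(dat, .data$analysis)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$z_ms12, y = .data$z_rs21,
                                    colour = .data$cohort)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "12-gene MS (z)", y = "21-gene RS (z)", colour = NULL) +
    ggplot2::theme_minimal()
}
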