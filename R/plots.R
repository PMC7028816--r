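#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

predictive_bands <- function(pred) {
  qs <- apply(pred$draws, 2, quantile, c(0.05, 0.25, 0.5, 0.75, 0.95))
  tibble::tibble(date = pred$times, lo90 = qs[1, ], lo50 = qs[2, ],
                 median = qs[3, ], hi50 = qs[4, ], hi90 = qs[5, ])
}

#' Plot observed series against the counterfactual predictive bands
#'
#' Reproduces the study's display: the observed focal series as a line over
#' the posterior-predictive median and 50%/90% bands, with the fitted
#' (pre-intervention) window in grey and the forecast (post-intervention)
#' window highlighted.
#'
#' @param impact A `cf_impact` from [evaluate_impact()].
#' @return A ggplot object.
#' @export
plot_counterfactual <- function(impact) {
  stopifnot(inherits(impact, "cf_impact"))
  pre <- predictive_bands(impact$pre_predictive)
  post <- predictive_bands(impact$predictive)
  pre$window <- "fitted"
  post$window <- "forecast"
  bands <- dplyr::bind_rows(pre, post)
  obs <- tibble::tibble(
    date = c(pre$date, post$date),
    observed = c(impact$observed_pre, impact$summary$observed))
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo90, ymax = .data$hi90,
                                      fill = .data$window), alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo50, ymax = .data$hi50,
                                      fill = .data$window), alpha = 0.45) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median,
                                    colour = .data$window)) +
    ggplot2::geom_line(data = obs, ggplot2::aes(y = .data$observed),
                       colour = "blue", linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = impact$study$intervention_date,
                        linetype = 2) +
    ggplot2::scale_fill_manual(values = c(fitted = "grey30",
                                          forecast = "firebrick")) +
    ggplot2::scale_colour_manual(values = c(fitted = "grey30",
                                            forecast = "firebrick")) +
    ggplot2::labs(x = NULL, y = "outcome",
                  title = "Observed series vs counterfactual expectation") +
    ggplot2::theme_minimal()
}

#' Plot the observed/expected impact ratio
#'
#' Per-period median ratio with 50% and 90% credible bands; values above the
#' dashed line at 1 indicate a higher-than-expected outcome.
#'
#' @param impact A `cf_impact` from [evaluate_impact()].
#' @return A ggplot object.
#' @export
plot_impact_ratio <- function(impact) {
  stopifnot(inherits(impact, "cf_impact"))
  s <- impact$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ratio_lo90,
                                      ymax = .data$ratio_hi90),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ratio_lo50,
                                      ymax = .data$ratio_hi50),
                         fill = "firebrick", alpha = 0.45) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ratio_median),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "observed / expected",
                  title = "Impact ratio with 50% and 90% credible bands") +
    ggplot2::theme_minimal()
}

#' @rdname plot_counterfactual
#' @param object A `cf_impact`.
#' @param type `"counterfactual"` or `"ratio"`.
#' @param ... Unused.
#' @export
autoplot.cf_impact <- function(object, type = c("counterfactual", "ratio"),
                               ...) {
  switch(match.arg(type),
         counterfactual = plot_counterfactual(object),
         ratio = plot_impact_ratio(object))
}
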