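#' Plot a deterministic trajectory
#'
#' One panel per state variable (internal concentration, nrf2 fold-change,
#' scaled protein, cumulative hazard, survival) over time.
#'
#' @param object A `gp_trajectory` from [simulate_guts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gp_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h post exposure)", y = NULL,
                  title = attr(object, "treatment_id")) +
    ggplot2::theme_minimal()
}

#' Plot posterior parameter distributions
#'
#' Histograms of the promoted start's posterior draws, one facet per free
#' parameter, on the log scale.
#'
#' @param object A `gp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gp_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws, -".draw",
                              names_to = "term", values_to = "log_value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$log_value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "log parameter value", y = "draws") +
    ggplot2::theme_minimal()
}

#' Plot credible-interval envelopes
#'
#' Ribbon plot of [posterior_trajectory_bci()] output, optionally overlaying
#' the observations of the scenario's treatment.
#'
#' @param bci Envelope tibble from [posterior_trajectory_bci()].
#' @param observations Optional observation table; rows matching
#'   `treatment_id` are drawn as points (`cint` on `C_i`, `nrf2` on the RNA
#'   state, survivor fractions on `S`).
#' @param treatment_id Treatment whose observations to overlay.
#' @return A ggplot object.
#' @export
plot_trajectory_bci <- function(bci, observations = NULL, treatment_id = NULL) {
  p <- ggplot2::ggplot(bci, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), color = "steelblue4") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h post exposure)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(observations) && !is.null(treatment_id)) {
    obs <- observations[observations$treatment_id == treatment_id, ]
    map_var <- c(cint = "C_i",
                 nrf2 = if ("R" %in% bci$variable) "R" else "D",
                 survival = "S")
    obs$variable <- unname(map_var[obs$endpoint])
    obs$value <- ifelse(obs$endpoint == "survival",
                        obs$value / obs$n_at_risk, obs$value)
    obs <- obs[obs$variable %in% unique(bci$variable), ]
    p <- p + ggplot2::geom_point(
      data = obs, ggplot2::aes(y = .data$value), size = 1, color = "grey30"
    )
  }
  p
}
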