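#' Plot tumor trajectories
#'
#' Draws the sensitive, resistant and total normalized burden against time in
#' days, with the applied dose as a step ribbon along the bottom and the
#' progression threshold `1.2 * n0` as a dashed line.
#'
#' @param traj Trajectory tibble from [simulate_tumor()].
#' @param n0 Initial burden (defaults to the stored attribute).
#' @return A ggplot object, faceted by ensemble member when several are
#'   present.
#' @export
plot_trajectory <- function(traj, n0 = attr(traj, "n0")) {
  long <- tidyr::pivot_longer(
    traj[c("theta_id", "day", "s", "r", "n")],
    cols = c("s", "r", "n"), names_to = "series", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value,
                                          color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_step(
      data = dplyr::filter(traj, !is.na(.data$u)),
      ggplot2::aes(x = .data$day, y = .data$u * 0.1 - 0.12),
      inherit.aes = FALSE, linewidth = 0.3, color = "grey40"
    ) +
    ggplot2::labs(x = "time (days)", y = "normalized burden",
                  color = NULL,
                  caption = "lower ribbon: applied dose u (scaled)") +
    ggplot2::theme_minimal()
  if (!is.null(n0)) {
    p <- p + ggplot2::geom_hline(yintercept = 1.2 * n0, linetype = "dashed")
  }
  if (length(unique(traj$theta_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~theta_id)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an optimized schedule
#'
#' Shows the final dose profile over time together with the convergence
#' history of the functional value.
#'
#' @param object A `schedule_opt` from [optimize_schedule()].
#' @param which `"control"`, `"history"` or `"gradient"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.schedule_opt <- function(object, which = c("control", "history",
                                                    "gradient"), ...) {
  which <- match.arg(which)
  if (which == "control") {
    ggplot2::ggplot(object$control, ggplot2::aes(x = .data$day, y = .data$u)) +
      ggplot2::geom_step() +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "time (days)", y = "dose u",
                    title = paste(object$settings$mode, object$cost$kind,
                                  "cost, n0 =", object$cost$n0)) +
      ggplot2::theme_minimal()
  } else if (which == "history") {
    ggplot2::ggplot(object$history, ggplot2::aes(x = .data$iter, y = .data$J)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "iteration", y = "functional value J") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$gradient, ggplot2::aes(x = .data$day, y = .data$grad)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (days)", y = "L2 gradient of J") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-member progression times over the parameter grid
#'
#' Heatmap of progression time (days) across the `(r_hat_R, f_hat_0)` grid.
#'
#' @param ttp Per-member tibble from [ttp_ensemble()].
#' @param metric `"ttp"` or `"ttp_prime"`.
#' @return A ggplot object.
#' @export
plot_ttp_grid <- function(ttp, metric = c("ttp", "ttp_prime")) {
  metric <- match.arg(metric)
  col <- if (metric == "ttp") "ttp_days" else "ttp_prime_days"
  ggplot2::ggplot(ttp, ggplot2::aes(x = .data$r_hat_R, y = .data$f_hat_0,
                                    fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "relative resistant proliferation rate",
                  y = "initial resistant fraction",
                  fill = "days") +
    ggplot2::theme_minimal()
}
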