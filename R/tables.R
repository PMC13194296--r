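#' Benchmark horizon for a given initial burden
#'
#' The benchmark experiments pair each initial burden with a fixed horizon
#' long enough to observe progression for (almost) every ensemble member:
#' 750 days for `n0 = 0.25`, 1000 days for `n0 = 0.50`, 1500 days for
#' `n0 = 0.75` (normalized horizons `T = 20.25, 27, 40.5`).
#'
#' @param n0 Initial burden, one of 0.25, 0.5, 0.75.
#' @return Horizon in days.
#' @export
default_horizon_days <- function(n0) {
  horizons <- c("0.25" = 750, "0.5" = 1000, "0.75" = 1500)
  key <- as.character(n0)
  if (!key %in% names(horizons)) {
    abort("no default horizon for this n0; supply horizon_days explicitly")
  }
  unname(horizons[key])
}

#' Compare feedback protocols over the reference ensemble
#'
#' Runs the named feedback protocols on the full 1225-member grid for each
#' initial burden and summarizes progression times (max / min / mean, whole
#' days). MTD and On-Off adaptive therapy are scored with `ttp`; Off-On
#' adaptive therapy with `ttp_prime`, since its surveillance phase touches
#' the progression threshold at every cycle by construction.
#'
#' @param policies Character vector of protocol names among `"mtd"`,
#'   `"on_off_at"`, `"off_on_at"`.
#' @param n0 Initial burdens to evaluate.
#' @param horizon_days Optional named or positional horizons; defaults to
#'   [default_horizon_days()] per `n0`.
#' @inheritParams simulate_tumor
#' @return A tibble with one row per (policy, n0): `policy`, `n0`,
#'   `horizon_days`, `metric`, `max_days`, `min_days`, `mean_days`.
#' @examples
#' \donttest{
#' benchmark_policies(policies = "mtd", n0 = 0.25)
#' }
#' @export
benchmark_policies <- function(policies = c("mtd", "on_off_at"),
                               n0 = c(0.25, 0.5, 0.75),
                               horizon_days = NULL,
                               r_S = r_S_default, steps_per_day = 8L) {
  grid <- tidyr::expand_grid(policy = policies, n0 = n0)
  purrr::pmap_dfr(grid, function(policy, n0) {
    hor <- horizon_days %||% default_horizon_days(n0)
    metric <- if (policy == "off_on_at") "ttp_prime" else "ttp"
    ens <- theta_grid(n0)
    ttp <- ttp_ensemble(ens, policy, hor, r_S = r_S,
                        steps_per_day = steps_per_day)
    dplyr::bind_cols(
      tibble(policy = policy, n0 = n0, horizon_days = hor),
      ttp_summary(ttp, metric)
    )
  })
}

#' Compare On-Off and Off-On adaptive therapy
#'
#' @inheritParams benchmark_policies
#' @return As [benchmark_policies()], for the two adaptive protocols.
#' @export
benchmark_adaptive <- function(n0 = c(0.25, 0.5, 0.75),
                               r_S = r_S_default, steps_per_day = 8L) {
  benchmark_policies(policies = c("on_off_at", "off_on_at"), n0 = n0,
                     r_S = r_S, steps_per_day = steps_per_day)
}

#' Progression times of ensemble-optimized schedules
#'
#' For each requested (cost, mode, n0) combination, optimizes a schedule over
#' the full 1225-member grid with the reference optimizer settings
#' (`eta = 0.125`, 500 iterations, `u_init = 0.5`) and scores the resulting
#' open-loop control on the same ensemble. Linear-cost schedules are scored
#' with `ttp`; hyperbolic-cost schedules with `ttp_prime`, because the
#' optimal hyperbolic policy deliberately lets the burden exceed the
#' progression threshold early on and re-descends later.
#'
#' @param kind Cost kinds: subset of `c("linear", "hyperbolic")`.
#' @param mode Formulations: subset of `c("averaged", "minimax")`.
#' @param n0 Initial burdens.
#' @param iterations,eta,u_init Optimizer settings (see
#'   [optimize_schedule()]).
#' @inheritParams simulate_tumor
#' @return A tibble with one row per combination: settings columns plus
#'   `max_days`, `min_days`, `mean_days` and the final functional value
#'   `J_final`. The fitted `schedule_opt` objects are attached in a
#'   list-column `fit`.
#' @export
benchmark_schedules <- function(kind = c("linear", "hyperbolic"),
                                mode = "averaged",
                                n0 = c(0.25, 0.5, 0.75),
                                iterations = 500L, eta = 0.125, u_init = 0.5,
                                r_S = r_S_default, steps_per_day = 8L) {
  grid <- tidyr::expand_grid(kind = kind, mode = mode, n0 = n0)
  purrr::pmap_dfr(grid, function(kind, mode, n0) {
    hor <- default_horizon_days(n0)
    ens <- theta_grid(n0)
    fit <- optimize_schedule(ens, cost_spec(kind, n0), mode = mode,
                             horizon_days = hor, eta = eta,
                             iterations = iterations, u_init = u_init,
                             r_S = r_S, steps_per_day = steps_per_day)
    metric <- if (kind == "hyperbolic") "ttp_prime" else "ttp"
    summ <- ttp_summary(schedule_ttp(fit), metric)
    dplyr::bind_cols(
      tibble(kind = kind, mode = mode, n0 = n0, horizon_days = hor,
             J_final = utils::tail(fit$history$J, 1)),
      summ,
      tibble(fit = list(fit))
    )
  })
}
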