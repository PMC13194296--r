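#' Integral tumor-burden penalties
#'
#' Running costs measuring the deviation of the total burden `n` from its
#' initial value `n0`:
#' * linear: `ell(n) = n - n0`, symmetric around `n0` — shrinking the tumor
#'   is rewarded exactly as much as growth is penalized;
#' * hyperbolic: `ell(n) = sqrt(1 + (n - n0)^2) - 1 + (n - n0)`, asymmetric —
#'   a growth `+delta` costs more than the matching shrinkage `-delta`
#'   earns, reflecting that long-term disease control, not eradication, is
#'   the clinical goal. For any `delta > 0`,
#'   `ell(n0 + delta) + ell(n0 - delta) = 2 (sqrt(1 + delta^2) - 1) > 0`.
#'
#' @param n Burden value(s).
#' @param n0 Reference burden in `(0, 1)`.
#' @param kind `"linear"` or `"hyperbolic"`.
#' @return Cost values, vectorized over `n`.
#' @examples
#' ell(0.6, 0.5, "linear")
#' ell(1.5, 0.5, "hyperbolic")  # sqrt(2)
#' @export
ell <- function(n, n0, kind = c("linear", "hyperbolic")) {
  kind <- match.arg(kind)
  d <- n - n0
  if (kind == "linear") d else sqrt(1 + d^2) - 1 + d
}

#' Derivative of the running cost with respect to the burden
#' @rdname ell
#' @export
ell_prime <- function(n, n0, kind = c("linear", "hyperbolic")) {
  kind <- match.arg(kind)
  if (kind == "linear") rep(1, length(n)) else {
    d <- n - n0
    d / sqrt(1 + d^2) + 1
  }
}

#' Cost specification
#'
#' @param kind `"linear"` or `"hyperbolic"` (see [ell()]).
#' @param n0 Reference burden in `(0, 1)`.
#' @return A list of class `cost_spec`.
#' @export
cost_spec <- function(kind = c("linear", "hyperbolic"), n0) {
  kind <- match.arg(kind)
  stopifnot(n0 > 0, n0 < 1)
  structure(list(kind = kind, n0 = n0, code = if (kind == "linear") 1L else 2L),
            class = "cost_spec")
}

#' Evaluate the ensemble cost functional of a schedule
#'
#' Integrates the running cost [ell()] of each member's Euler trajectory over
#' the horizon by the left-endpoint Riemann rule on the Euler grid (the final
#' state carries no quadrature weight), giving per-member contributions
#' `h * sum_k ell(n_k)`. In `"averaged"` mode the functional is the
#' weight-weighted sum of contributions; in `"minimax"` mode it is their
#' maximum, and the attaining member (lowest index on ties) is recorded.
#' Left-endpoint quadrature is chosen so the discrete adjoint of
#' [functional_gradient()] is the exact derivative of this value.
#'
#' @param ensemble Ensemble tibble.
#' @param control Open-loop control: tibble from [control_grid()] or a bare
#'   numeric vector of per-step doses. Values outside `[0, 1]` are clamped
#'   with a warning.
#' @param cost A [cost_spec()], or a kind string (then `n0` is taken from the
#'   ensemble).
#' @param mode `"averaged"` or `"minimax"`.
#' @inheritParams simulate_tumor
#' @return A list of class `functional_value`: `value`, `mode`, per-member
#'   `contrib` tibble, and `argmax` (minimax only). `tidy()` returns the
#'   per-member contributions.
#' @examples
#' ens <- theta_grid(0.5)[c(1, 600, 1225), ]
#' ens$weight <- rep(1 / 3, 3)
#' evaluate_functional(ens, control_grid(100, u = 1), "linear")
#' @export
evaluate_functional <- function(ensemble, control, cost,
                                mode = c("averaged", "minimax"),
                                r_S = r_S_default, steps_per_day = 8L) {
  mode <- match.arg(mode)
  ensemble <- validate_ensemble(ensemble)
  if (is.character(cost)) cost <- cost_spec(cost, ensemble$n0[1])
  u <- if (is.data.frame(control)) control$u else as.numeric(control)
  if (any(u < 0 | u > 1)) {
    warn("control outside [0, 1]; clamping to the admissible box")
    u <- pmin(pmax(u, 0), 1)
  }
  h <- r_S / steps_per_day
  contrib <- cpp_functional(
    ensemble$d_hat_D, ensemble$d_hat_T, ensemble$r_hat_R, ensemble$f_hat_0,
    ensemble$n0[1], length(u), h, u, cost$code
  )
  value <- if (mode == "averaged") sum(ensemble$weight * contrib) else max(contrib)
  out <- list(
    value = value,
    mode = mode,
    cost = cost,
    contrib = dplyr::bind_cols(ensemble, tibble(contrib = contrib)),
    argmax = if (mode == "minimax") which.max(contrib) else NA_integer_
  )
  class(out) <- "functional_value"
  out
}

#' @export
print.functional_value <- function(x, ...) {
  cat("<functional_value>", x$mode, x$cost$kind, "cost: J =",
      format(x$value, digits = 8), "\n")
  if (!is.na(x$argmax)) cat("  worst member: index", x$argmax, "\n")
  invisible(x)
}

#' @export
tidy.functional_value <- function(x, ...) {
  x$contrib
}

#' @export
glance.functional_value <- function(x, ...) {
  tibble(value = x$value, mode = x$mode, kind = x$cost$kind,
         n0 = x$cost$n0, n_members = nrow(x$contrib))
}
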