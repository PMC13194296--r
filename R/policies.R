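#' Feedback therapy protocols
#'
#' A therapy policy is a finite-state controller that maps the observed total
#' tumor burden `n = s + r` (never the subpopulations separately, which are
#' not clinically observable) to a normalized dose `u`. Three named protocols
#' are provided:
#'
#' * `policy_mtd()`: maximum tolerated dose, `u == 1` at all times.
#' * `policy_on_off(n0)`: adaptive therapy starting in a treatment period.
#'   Treat (`u = 1`) until the burden shrinks to `n <= n0 / 2`, then pause
#'   (`u = 0`) until it regrows to `n >= n0`, and repeat. Switches happen
#'   exactly at threshold equality.
#' * `policy_off_on(n0)`: adaptive therapy starting with surveillance. Hold
#'   `u = 0` until the burden reaches the progression threshold
#'   `n >= 1.2 * n0`, then treat until `n <= n0 / 2`, and repeat. The initial
#'   drug-free phase lets sensitive cells suppress the resistant clone through
#'   resource competition before any selective pressure is applied.
#'
#' `policy_constant(level)` applies a fixed dose; [as_policy()] resolves
#' policies from names (`"mtd"`, `"on_off_at"`, `"off_on_at"`,
#' `"constant:<level>"`, `"schedule:<csv>"`) or passes through policy objects
#' and control tibbles.
#'
#' @param n0 Initial normalized burden the thresholds refer to, in `(0, 1)`.
#' @param level Constant dose level in `[0, 1]`.
#' @return An object of class `therapy_policy`.
#' @examples
#' p <- policy_on_off(0.5)
#' policy_step(p, n = 0.26, mode = "TREAT")
#' policy_step(p, n = 0.25, mode = "TREAT")
#' @export
policy_mtd <- function() {
  new_policy("mtd", code = 1L)
}

#' @rdname policy_mtd
#' @export
policy_on_off <- function(n0) {
  stopifnot(n0 > 0, n0 < 1)
  new_policy("on_off_at", code = 2L, lower = n0 / 2, upper = n0,
             init_mode = "TREAT", n0 = n0)
}

#' @rdname policy_mtd
#' @export
policy_off_on <- function(n0) {
  stopifnot(n0 > 0, n0 < 1)
  new_policy("off_on_at", code = 3L, lower = n0 / 2, upper = 1.2 * n0,
             init_mode = "VACATION", n0 = n0)
}

#' @rdname policy_mtd
#' @export
policy_constant <- function(level) {
  stopifnot(level >= 0, level <= 1)
  new_policy(paste0("constant:", level), code = 0L, level = level)
}

new_policy <- function(name, code, lower = NA_real_, upper = NA_real_,
                       init_mode = "TREAT", n0 = NA_real_, level = NA_real_) {
  if (!is.na(lower) && !is.na(upper) && lower >= upper) {
    abort("policy thresholds must satisfy lower < upper")
  }
  structure(
    list(name = name, code = code, lower = lower, upper = upper,
         init_mode = init_mode, n0 = n0, level = level),
    class = "therapy_policy"
  )
}

#' @export
print.therapy_policy <- function(x, ...) {
  cat("<therapy_policy>", x$name, "\n")
  if (!is.na(x$lower)) {
    cat("  thresholds: treat while n >", format(x$lower),
        "| vacation while n <", format(x$upper), "\n")
  }
  invisible(x)
}

#' Advance a feedback policy by one observation
#'
#' Pure single-step transition used by the reference (non-compiled) simulator
#' and by unit tests: given the observed burden and the current controller
#' mode, returns the emitted dose and the next mode. Threshold ties switch
#' the mode.
#'
#' @param policy A `therapy_policy`.
#' @param n Observed total burden.
#' @param mode Current mode, `"TREAT"` or `"VACATION"`.
#' @return A list with elements `u` and `mode`.
#' @export
policy_step <- function(policy, n, mode = policy$init_mode) {
  u <- switch(
    as.character(policy$code),
    "1" = 1,
    "0" = policy$level,
    {
      if (identical(mode, "TREAT") && n <= policy$lower) {
        mode <- "VACATION"
      } else if (identical(mode, "VACATION") && n >= policy$upper) {
        mode <- "TREAT"
      }
      if (identical(mode, "TREAT")) 1 else 0
    }
  )
  list(u = u, mode = mode)
}

#' Resolve a policy specification
#'
#' @param x A `therapy_policy`, a control tibble (columns `tau`/`day` and `u`,
#'   see [control_grid()]), or a name: `"mtd"`, `"on_off_at"`, `"off_on_at"`,
#'   `"constant:<level>"`, or `"schedule:<path>"` pointing to a control CSV.
#' @param n0 Initial burden, required for the adaptive protocols.
#' @return A `therapy_policy` or a control tibble.
#' @export
as_policy <- function(x, n0 = NULL) {
  if (inherits(x, "therapy_policy")) return(x)
  if (is.data.frame(x)) return(validate_control(x))
  if (is.numeric(x)) return(validate_control(tibble(u = x)))
  if (!is.character(x) || length(x) != 1) abort("cannot interpret policy")
  if (x == "mtd") return(policy_mtd())
  need_n0 <- function() {
    if (is.null(n0)) abort("adaptive policies need n0")
    n0
  }
  if (x == "on_off_at") return(policy_on_off(need_n0()))
  if (x == "off_on_at") return(policy_off_on(need_n0()))
  if (grepl("^constant:", x)) {
    return(policy_constant(as.numeric(sub("^constant:", "", x))))
  }
  if (grepl("^schedule:", x)) {
    return(read_control(sub("^schedule:", "", x)))
  }
  abort(paste0("unknown policy: ", x))
}
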