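#' Default kinetic constants of the prostate-cancer calibration
#'
#' The two-population experiments shipped with the package use the standard
#' intermittent androgen-deprivation calibration: sensitive-cell proliferation
#' rate `r_S = 0.027 / day` (which sets the time scale of the non-dimensional
#' model) and rescaled drug sensitivity `d_hat_D = 1.5`.
#'
#' @format Named numeric constants.
#' @keywords internal
#' @name oncoctrl-constants
NULL

#' Sensitive-cell proliferation rate (per day) used for time normalization
#' @rdname oncoctrl-constants
#' @export
r_S_default <- 0.027

#' Default rescaled drug sensitivity coefficient
#' @rdname oncoctrl-constants
#' @export
d_hat_D_default <- 1.5

theta_cols <- c("d_hat_D", "d_hat_T", "r_hat_R", "f_hat_0", "n0", "weight")

#' Validate a parameter-ensemble tibble
#'
#' An ensemble is a tibble with one row per parameter tuple
#' `theta = (d_hat_D, d_hat_T, r_hat_R, f_hat_0)` plus the shared initial
#' burden `n0` and a probability `weight`. Validation enforces: all rate and
#' fraction parameters nonnegative, `f_hat_0` in `[0, 1]`, `n0` in `(0, 1)`,
#' weights nonnegative summing to 1 (within 1e-12), no duplicated tuples, and
#' a common `n0` across rows.
#'
#' @param ensemble A data frame with columns `d_hat_D`, `d_hat_T`, `r_hat_R`,
#'   `f_hat_0`, `n0` and (optionally) `weight`; a missing `weight` column is
#'   filled in as uniform.
#' @return The validated ensemble as a tibble, invisibly usable downstream.
#' @examples
#' validate_ensemble(tibble::tibble(
#'   d_hat_D = 1.5, d_hat_T = 0, r_hat_R = 0.8, f_hat_0 = 0.01, n0 = 0.5
#' ))
#' @export
validate_ensemble <- function(ensemble) {
  ensemble <- as_tibble(ensemble)
  if (!"weight" %in% names(ensemble)) {
    ensemble$weight <- 1 / nrow(ensemble)
  }
  missing <- setdiff(theta_cols, names(ensemble))
  if (length(missing) > 0) {
    abort(paste0("ensemble is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(ensemble) == 0) abort("ensemble support must be non-empty")
  num <- ensemble[theta_cols]
  if (!all(vapply(num, is.numeric, logical(1)))) {
    abort("all ensemble columns must be numeric")
  }
  if (anyNA(num)) abort("ensemble contains missing values")
  with(ensemble, {
    if (any(d_hat_D < 0) || any(d_hat_T < 0) || any(r_hat_R < 0)) {
      abort("d_hat_D, d_hat_T and r_hat_R must be nonnegative")
    }
    if (any(f_hat_0 < 0 | f_hat_0 > 1)) abort("f_hat_0 must lie in [0, 1]")
    if (any(n0 <= 0 | n0 >= 1)) abort("n0 must lie in (0, 1)")
    if (length(unique(n0)) != 1) abort("all ensemble members must share the same n0")
    if (any(weight < 0)) abort("weights must be nonnegative")
    if (abs(sum(weight) - 1) > 1e-12) abort("weights must sum to 1 (within 1e-12)")
  })
  if (anyDuplicated(ensemble[c("d_hat_D", "d_hat_T", "r_hat_R", "f_hat_0")])) {
    abort("ensemble support contains duplicated parameter tuples")
  }
  ensemble
}

#' Build the reference 1225-member parameter grid
#'
#' Constructs the uniform product ensemble used throughout the package's
#' benchmark experiments: `d_hat_D = 1.5` and `d_hat_T = 0` fixed (the most
#' adverse, zero-turnover scenario), the relative resistant proliferation rate
#' on 25 nodes `r_hat_R = 0.5, 0.52, ..., 0.98` and the initial resistant
#' fraction on 49 nodes `f_hat_0 = 0.002, 0.004, ..., 0.098`, each node
#' carrying weight `1/1225`. Both axes are equispaced half-open grids: the
#' lower endpoint is included and the node count (25 and 49) fixes the upper
#' node at one step below the nominal interval ends 1 and 0.1.
#'
#' @param n0 Initial normalized tumor burden shared by all members, in
#'   `(0, 1)`. The benchmark studies use 0.25, 0.50 or 0.75; other values are
#'   accepted with a warning.
#' @return A 1225-row ensemble tibble (see [validate_ensemble()]).
#' @examples
#' nrow(theta_grid(0.5))
#' @export
theta_grid <- function(n0) {
  stopifnot(is.numeric(n0), length(n0) == 1, n0 > 0, n0 < 1)
  if (!n0 %in% c(0.25, 0.5, 0.75)) {
    warn("n0 is outside the benchmark set {0.25, 0.5, 0.75}")
  }
  grid <- tidyr::expand_grid(
    r_hat_R = 0.5 + 0.02 * (0:24),
    f_hat_0 = 0.002 + 0.002 * (0:48)
  )
  validate_ensemble(tibble(
    d_hat_D = d_hat_D_default,
    d_hat_T = 0,
    r_hat_R = grid$r_hat_R,
    f_hat_0 = grid$f_hat_0,
    n0 = n0,
    weight = 1 / nrow(grid)
  ))
}

#' Draw a random parameter ensemble
#'
#' Samples parameter tuples uniformly from the boxes spanned by the reference
#' grid (`r_hat_R` in `[0.5, 1]`, `f_hat_0` in `[0.002, 0.1]`, `d_hat_D = 1.5`,
#' `d_hat_T = 0`) with uniform weights. Used as a test fixture generator;
#' deterministic given `seed`.
#'
#' @param n Number of members.
#' @param n0 Shared initial burden in `(0, 1)`.
#' @param seed Integer seed.
#' @return An ensemble tibble.
#' @export
sample_theta <- function(n, n0 = 0.5, seed = 1L) {
  stopifnot(n >= 1)
  withr::local_seed(seed)
  validate_ensemble(tibble(
    d_hat_D = d_hat_D_default,
    d_hat_T = 0,
    r_hat_R = stats::runif(n, 0.5, 1),
    f_hat_0 = stats::runif(n, 0.002, 0.1),
    n0 = n0,
    weight = 1 / n
  ))
}

#' Non-dimensionalize two-population model parameters
#'
#' Rescales the dimensional sensitive/resistant competition model to the
#' non-dimensional form: time is measured in units of `1 / r_S`, populations
#' as fractions of the carrying capacity `K`, and the dose as a fraction of
#' the maximum dose. The returned tuple is
#' `d_hat_D = 2 d_D`, `d_hat_T = d_T / r_S`, `r_hat_R = r_R / r_S`,
#' `f_hat_0 = R0 / (S0 + R0)`, `n0 = (S0 + R0) / K`, and the normalized
#' horizon is `T = T_hor * r_S`.
#'
#' @param r_S Sensitive proliferation rate (per day), positive.
#' @param r_R Resistant proliferation rate (per day).
#' @param d_D Drug sensitivity coefficient (dimensionless).
#' @param d_T Turnover (natural death) rate (per day).
#' @param K Carrying capacity (cells), positive.
#' @param S0,R0 Initial sensitive / resistant population sizes (cells),
#'   with `S0 + R0 <= K`.
#' @param T_hor Simulation horizon in days.
#' @return A one-row tibble with the ensemble columns plus `T_norm`, the
#'   normalized horizon.
#' @examples
#' nondimensionalize(r_S = 0.027, r_R = 0.027 * 0.66, d_D = 0.75, d_T = 0,
#'                   K = 1e10, S0 = 4.95e9, R0 = 5e7, T_hor = 750)
#' @export
nondimensionalize <- function(r_S, r_R, d_D, d_T, K, S0, R0, T_hor) {
  if (r_S <= 0 || K <= 0) abort("r_S and K must be positive")
  if (S0 < 0 || R0 < 0 || S0 + R0 > K) abort("need 0 <= S0 + R0 <= K")
  tibble(
    d_hat_D = 2 * d_D,
    d_hat_T = d_T / r_S,
    r_hat_R = r_R / r_S,
    f_hat_0 = R0 / (S0 + R0),
    n0 = (S0 + R0) / K,
    weight = 1,
    T_norm = T_hor * r_S
  )
}

#' Right-hand side of the non-dimensional two-population model
#'
#' Evaluates the vector field of the competition model
#' \deqn{\dot s = (1 - s - r)(1 - \hat d_D u) s - \hat d_T s, \qquad
#'       \dot r = \hat r_R (1 - s - r) r - \hat d_T r,}
#' where `u` in `[0, 1]` is the normalized dose. Vectorized over ensemble rows.
#'
#' @param theta One-row (or multi-row) ensemble tibble.
#' @param s,r State components (recycled against `theta` rows).
#' @param u Control value(s) in `[0, 1]`.
#' @return A tibble with columns `ds` and `dr`.
#' @examples
#' th <- tibble::tibble(d_hat_D = 1.5, d_hat_T = 0, r_hat_R = 0.66,
#'                      f_hat_0 = 0.01, n0 = 0.5, weight = 1)
#' rhs_two_pop(th, s = 0.495, r = 0.005, u = 1)
#' @export
rhs_two_pop <- function(theta, s, r, u) {
  if (anyNA(s) || anyNA(r) || anyNA(u)) abort("NaN/NA state or control")
  if (any(u < 0 | u > 1)) abort("u must lie in [0, 1]")
  g <- 1 - s - r
  tibble(
    ds = g * (1 - theta$d_hat_D * u) * s - theta$d_hat_T * s,
    dr = theta$r_hat_R * g * r - theta$d_hat_T * r
  )
}

#' Read / write ensembles as CSV
#'
#' The on-disk format has the header
#' `d_hat_D,d_hat_T,r_hat_R,f_hat_0,n0,weight`, one row per support point.
#' Reading validates all ensemble invariants.
#'
#' @param path File path.
#' @param ensemble Ensemble tibble to write.
#' @return `read_ensemble()` returns a validated ensemble tibble;
#'   `write_ensemble()` returns `ensemble` invisibly.
#' @export
read_ensemble <- function(path) {
  validate_ensemble(readr::read_csv(path, col_types = readr::cols(.default = "d")))
}

#' @rdname read_ensemble
#' @export
write_ensemble <- function(ensemble, path) {
  ensemble <- validate_ensemble(ensemble)
  readr::write_csv(ensemble[theta_cols], path)
  invisible(ensemble)
}
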