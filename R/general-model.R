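#' Specify an n-species control-affine tumor model
#'
#' The general model tracks `n` subpopulations `X_i` (cells) with logistic
#' competition for a shared carrying capacity `K`, per-species drug
#' sensitivities and turnover, and (possibly drug-induced) transitions between
#' species:
#' \deqn{\dot X_i = r_i \Big(1 - \tfrac{1}{K}\sum_j X_j\Big)
#'       \Big(1 - 2 d_i^I \tfrac{D}{D_{max}}\Big) X_i - d_i^T X_i
#'       + \sum_j \Big(A_{ij} + A^I_{ij} \tfrac{D}{D_{max}}\Big) X_j.}
#' Transition matrices must have nonnegative off-diagonal entries, nonpositive
#' diagonals, and zero column sums, so transitions redistribute but never
#' create total population.
#'
#' @param r Per-species proliferation rates (per unit time).
#' @param K Carrying capacity (cells), positive.
#' @param d_I Per-species drug sensitivity coefficients, nonnegative.
#' @param d_T Per-species turnover rates, nonnegative.
#' @param A,A_I Spontaneous / drug-induced transition-rate matrices
#'   (per unit time); defaults are zero matrices.
#' @param f Initial fractions, nonnegative summing to 1.
#' @param N0 Initial total population, in `[0, K]`.
#' @param D_max Maximum dose (the control ranges over `[0, D_max]`).
#' @param K_min,K_max Carrying-capacity bounds delimiting the invariant
#'   simplex; they default to `K` (single-capacity ensembles) and only enter
#'   through the runaway guard of the integrator.
#' @return An object of class `general_model_spec`.
#' @examples
#' spec <- general_model_spec(r = c(0.027, 0.0178), K = 1, d_I = c(0.75, 0),
#'                            d_T = c(0, 0), f = c(0.99, 0.01), N0 = 0.5)
#' rhs_general(c(0.495, 0.005), D = 1, spec = spec)
#' @export
general_model_spec <- function(r, K, d_I, d_T, A = NULL, A_I = NULL, f, N0,
                               D_max = 1, K_min = K, K_max = K) {
  n <- length(r)
  if (n < 1) abort("need at least one species")
  A <- A %||% matrix(0, n, n)
  A_I <- A_I %||% matrix(0, n, n)
  spec <- structure(
    list(n_species = n, r = r, K = K, d_I = d_I, d_T = d_T, A = A, A_I = A_I,
         f = f, N0 = N0, D_max = D_max, K_min = K_min, K_max = K_max),
    class = "general_model_spec"
  )
  validate_model_spec(spec)
}

check_transition_matrix <- function(M, name) {
  n <- nrow(M)
  if (!is.matrix(M) || ncol(M) != n) abort(paste0(name, " must be a square matrix"))
  off <- M[row(M) != col(M)]
  if (any(off < 0)) abort(paste0(name, ": off-diagonal entries must be >= 0"))
  if (any(diag(M) > 0)) abort(paste0(name, ": diagonal entries must be <= 0"))
  if (any(abs(colSums(M)) > 1e-12)) abort(paste0(name, ": columns must sum to 0"))
  invisible(M)
}

#' @rdname general_model_spec
#' @param spec A `general_model_spec` object.
#' @export
validate_model_spec <- function(spec) {
  n <- spec$n_species
  lens <- vapply(spec[c("r", "d_I", "d_T", "f")], length, integer(1))
  if (any(lens != n)) abort("r, d_I, d_T and f must all have length n_species")
  if (spec$K <= 0) abort("K must be positive")
  if (any(spec$d_I < 0)) abort("d_I must be nonnegative")
  if (any(spec$d_T < 0)) abort("d_T must be nonnegative")
  if (any(spec$f < 0) || abs(sum(spec$f) - 1) > 1e-12) {
    abort("f must be nonnegative and sum to 1")
  }
  if (spec$N0 < 0 || spec$N0 > spec$K) abort("need 0 <= N0 <= K")
  if (!(spec$K_min <= spec$K && spec$K <= spec$K_max)) {
    abort("need K_min <= K <= K_max")
  }
  if (spec$D_max <= 0) abort("D_max must be positive")
  check_transition_matrix(spec$A, "A")
  check_transition_matrix(spec$A_I, "A_I")
  spec
}

#' Right-hand side of the general n-species model
#'
#' Evaluates `F0(X) + F1(X) D` for the control-affine dynamics of
#' [general_model_spec()]. States far outside the invariant region (norm
#' beyond `2 * K_max`) raise a guard error: under admissible doses the
#' dynamics never leave the simplex, so the guard firing indicates a misuse
#' (e.g. an inconsistent initial state), not a model property.
#'
#' @param X State vector (cells), length `n_species`.
#' @param D Dose in `[0, D_max]`.
#' @param spec A `general_model_spec`.
#' @return Named list with the drift `F0`, control field `F1`, and total
#'   derivative `dX = F0 + F1 * D`.
#' @export
rhs_general <- function(X, D, spec) {
  validate_model_spec(spec)
  if (length(X) != spec$n_species) abort("X has the wrong length")
  if (anyNA(X)) abort("NaN/NA state")
  if (D < 0 || D > spec$D_max) abort("D must lie in [0, D_max]")
  if (sqrt(sum(X^2)) > 2 * spec$K_max) {
    abort("state outside the 2*K_max guard ball")
  }
  crowd <- 1 - sum(X) / spec$K
  F0 <- spec$r * crowd * X - spec$d_T * X + drop(spec$A %*% X)
  F1 <- (-2 * spec$d_I * spec$r * crowd * X + drop(spec$A_I %*% X)) / spec$D_max
  list(F0 = F0, F1 = F1, dX = F0 + F1 * D)
}

#' Read / write a general model specification (YAML or JSON)
#'
#' Matrices are stored row-major as nested lists. Reading re-validates every
#' invariant and names the violated one on failure.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param spec A `general_model_spec` to write.
#' @return `read_model_spec()` returns a validated `general_model_spec`.
#' @export
read_model_spec <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  n <- length(raw$r)
  as_mat <- function(m) {
    if (is.null(m)) return(NULL)
    if (is.matrix(m)) return(m)
    matrix(unlist(m), nrow = n, byrow = TRUE)
  }
  general_model_spec(
    r = as.numeric(raw$r), K = raw$K, d_I = as.numeric(raw$d_I),
    d_T = as.numeric(raw$d_T), A = as_mat(raw$A), A_I = as_mat(raw$A_I),
    f = as.numeric(raw$f), N0 = raw$N0,
    D_max = raw$D_max %||% 1, K_min = raw$K_min %||% raw$K,
    K_max = raw$K_max %||% raw$K
  )
}

#' @rdname read_model_spec
#' @export
write_model_spec <- function(spec, path) {
  validate_model_spec(spec)
  out <- list(
    r = spec$r, K = spec$K, d_I = spec$d_I, d_T = spec$d_T,
    A = lapply(seq_len(nrow(spec$A)), function(i) spec$A[i, ]),
    A_I = lapply(seq_len(nrow(spec$A_I)), function(i) spec$A_I[i, ]),
    f = spec$f, N0 = spec$N0, D_max = spec$D_max,
    K_min = spec$K_min, K_max = spec$K_max
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(spec)
}
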