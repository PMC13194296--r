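# Independent reference implementations used as oracles. These deliberately
# re-derive the numerics in plain R, step by step, without touching the
# package's compiled path.

one_theta <- function(r_hat_R = 0.66, f_hat_0 = 0.01, n0 = 0.5,
                      d_hat_D = 1.5, d_hat_T = 0, weight = 1) {
  tibble::tibble(d_hat_D = d_hat_D, d_hat_T = d_hat_T, r_hat_R = r_hat_R,
                 f_hat_0 = f_hat_0, n0 = n0, weight = weight)
}

# Plain-R explicit Euler for one parameter tuple under an open-loop control.
euler_oracle <- function(theta, u, h) {
  K <- length(u)
  s <- numeric(K + 1)
  r <- numeric(K + 1)
  s[1] <- (1 - theta$f_hat_0) * theta$n0
  r[1] <- theta$f_hat_0 * theta$n0
  for (k in seq_len(K)) {
    g <- 1 - s[k] - r[k]
    ds <- g * (1 - theta$d_hat_D * u[k]) * s[k] - theta$d_hat_T * s[k]
    dr <- theta$r_hat_R * g * r[k] - theta$d_hat_T * r[k]
    s[k + 1] <- s[k] + h * ds
    r[k + 1] <- r[k] + h * dr
  }
  list(s = s, r = r, n = s + r)
}

# Naive left-endpoint Riemann quadrature of the running cost on an Euler path.
riemann_oracle <- function(theta, u, h, kind) {
  path <- euler_oracle(theta, u, h)
  n0 <- theta$n0
  total <- 0
  for (k in seq_along(u)) {
    d <- path$n[k] - n0
    total <- total + if (kind == "linear") d else sqrt(1 + d^2) - 1 + d
  }
  h * total
}

# Central finite differences of the averaged functional with respect to each
# control step; returns the raw derivative dJ/du_k (the package's L2 gradient
# times h).
fd_gradient_oracle <- function(ensemble, u, kind, eps = 1e-6,
                               steps_per_day = 8L) {
  vapply(seq_along(u), function(k) {
    up <- u; up[k] <- u[k] + eps
    dn <- u; dn[k] <- u[k] - eps
    Jp <- evaluate_functional(ensemble, up, kind,
                              steps_per_day = steps_per_day)$value
    Jm <- evaluate_functional(ensemble, dn, kind,
                              steps_per_day = steps_per_day)$value
    (Jp - Jm) / (2 * eps)
  }, numeric(1))
}

# Expensive optimizer fits shared across test files, computed once per run.
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, kind, mode, n0) {
  if (!exists(key, envir = .fit_cache)) {
    fit <- optimize_schedule(theta_grid(n0), cost_spec(kind, n0), mode = mode,
                             horizon_days = default_horizon_days(n0))
    assign(key, fit, envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

fit_lin_averaged <- function(n0) {
  cached_fit(paste0("lin_avg_", n0), "linear", "averaged", n0)
}
fit_hyp_averaged <- function(n0) {
  cached_fit(paste0("hyp_avg_", n0), "hyperbolic", "averaged", n0)
}
fit_minimax <- function(kind, n0) {
  cached_fit(paste0(kind, "_mm_", n0), kind, "minimax", n0)
}

mtd_summary <- function(n0) {
  key <- paste0("mtd_", n0)
  if (!exists(key, envir = .fit_cache)) {
    s <- ttp_summary(ttp_ensemble(theta_grid(n0), "mtd",
                                  default_horizon_days(n0)))
    assign(key, s, envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}
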