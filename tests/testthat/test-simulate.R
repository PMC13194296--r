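test_that("a single Euler step matches the hand-computed update", {
  th <- one_theta()
  traj <- simulate_tumor(th, control_grid(1 / 8, u = 1), horizon_days = 1 / 8)
  expect_equal(traj$s[1], 0.495)
  expect_equal(traj$r[1], 0.005)
  expect_equal(traj$s[2], 0.49458234375, tolerance = 1e-15)
  expect_equal(traj$r[2], 0.00500556875, tolerance = 1e-15)
})

test_that("compiled path agrees with the plain-R Euler oracle", {
  withr::local_seed(5)
  th <- one_theta(r_hat_R = 0.8, f_hat_0 = 0.05, d_hat_T = 0.1)
  u <- stats::runif(200)
  h <- r_S_default / 8
  ref <- euler_oracle(th, u, h)
  traj <- simulate_tumor(th, u, horizon_days = 25)
  expect_equal(traj$s, ref$s, tolerance = 1e-15)
  expect_equal(traj$r, ref$r, tolerance = 1e-15)
})

test_that("untreated tumor approaches carrying capacity; resistant-free stays resistant-free", {
  th <- one_theta(d_hat_T = 0)
  traj <- simulate_tumor(th, "constant:0", horizon_days = 1000)
  expect_equal(dplyr::last(traj$n), 1, tolerance = 1e-3)
  th0 <- one_theta(f_hat_0 = 0, d_hat_T = 0)
  tr <- simulate_tumor(th0, "mtd", horizon_days = 200)
  expect_true(all(tr$r == 0))
  expect_true(all(diff(tr$s) < 0))  # d_hat_D > 1 shrinks s below capacity
})

test_that("Euler trajectories track an adaptive ODE solver at the default step", {
  # independent oracle: lsoda at tight tolerance on the continuous system
  th <- one_theta(r_hat_R = 0.9, f_hat_0 = 0.08)
  deriv <- function(t, y, parms) {
    g <- 1 - y[1] - y[2]
    list(c(g * (1 - th$d_hat_D * 1) * y[1], th$r_hat_R * g * y[2]))
  }
  taus <- seq(0, 300 * r_S_default, by = r_S_default / 8)
  y0 <- c((1 - th$f_hat_0) * th$n0, th$f_hat_0 * th$n0)
  ref <- deSolve::ode(y = y0, times = taus, func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  traj <- simulate_tumor(th, "mtd", horizon_days = 300)
  expect_lt(max(abs(traj$s - ref[, 2])), 5e-4)
  expect_lt(max(abs(traj$r - ref[, 3])), 5e-4)
  # the induced progression day agrees to within one day
  n_ref <- ref[, 2] + ref[, 3]
  ttp_ref <- (min(which(n_ref >= 0.6)) - 2) / 8  # last sub-threshold node
  ttp <- compute_ttp(traj)
  expect_lt(abs(ttp$ttp_days - ttp_ref), 1)
})

test_that("progression metrics follow the sup-of-subthreshold convention", {
  # synthetic path: crosses 0.6 at node 2, re-descends at 3, re-crosses at 4
  traj <- tibble::tibble(
    theta_id = 1L, step = 0:4,
    n = c(0.5, 0.55, 0.62, 0.59, 0.61)
  )
  out <- compute_ttp(traj, n0 = 0.5, steps_per_day = 1L)
  expect_equal(out$ttp_days, 1)        # last node strictly below threshold
  expect_equal(out$ttp_prime_days, 3)  # last node at or below threshold
  expect_false(out$censored)

  # a path never crossing is censored at the horizon for both metrics
  flat <- tibble::tibble(theta_id = 1L, step = 0:4, n = rep(0.5, 5))
  cens <- compute_ttp(flat, n0 = 0.5, steps_per_day = 1L)
  expect_equal(cens$ttp_days, 4)
  expect_equal(cens$ttp_prime_days, 4)
  expect_true(cens$censored && cens$censored_prime)

  expect_error(compute_ttp(flat[0, ], n0 = 0.5), "empty")
})

test_that("trajectory-based and streaming TTP computations agree exactly", {
  ens <- theta_grid(0.5)[seq(1, 1225, by = 120), ]
  ens$weight <- rep(1 / nrow(ens), nrow(ens))
  for (pol in c("mtd", "on_off_at", "off_on_at")) {
    fast <- ttp_ensemble(ens, pol, 1000)
    traj <- simulate_tumor(ens, pol, 1000)
    slow <- compute_ttp(traj)
    expect_equal(fast$ttp_days, slow$ttp_days)
    expect_equal(fast$ttp_prime_days, slow$ttp_prime_days)
    expect_equal(fast$censored, slow$censored)
  }
})

test_that("progression time never precedes its prime variant", {
  withr::local_seed(13)
  ens <- sample_theta(40, n0 = 0.5, seed = 21)
  for (pol in c("mtd", "on_off_at", "off_on_at", "constant:0.4")) {
    ttp <- ttp_ensemble(ens, pol, 1000)
    expect_true(all(ttp$ttp_days <= ttp$ttp_prime_days))
  }
  # and under a rough random open-loop schedule
  u <- rep(stats::runif(125), each = 64)
  ttp <- ttp_ensemble(ens, u, 1000)
  expect_true(all(ttp$ttp_days <= ttp$ttp_prime_days))
})

test_that("MTD and On-Off progression metrics coincide member-by-member", {
  ens <- theta_grid(0.5)
  for (pol in c("mtd", "on_off_at")) {
    ttp <- ttp_ensemble(ens, pol, 1000)
    expect_equal(ttp$ttp_days_reported, ttp$ttp_prime_days_reported)
  }
})

test_that("halving the step changes reported whole-day TTPs by at most one day", {
  ens <- theta_grid(0.5)[seq(1, 1225, by = 49), ]
  ens$weight <- rep(1 / nrow(ens), nrow(ens))
  for (pol in c("mtd", "on_off_at")) {
    t8 <- ttp_ensemble(ens, pol, 1000, steps_per_day = 8L)
    t16 <- ttp_ensemble(ens, pol, 1000, steps_per_day = 16L)
    expect_true(all(abs(t8$ttp_days_reported - t16$ttp_days_reported) <= 1))
  }
})

test_that("a larger resistant seed never delays progression under MTD", {
  ttp <- ttp_ensemble(theta_grid(0.5), "mtd", 1000)
  by_r <- split(ttp, ttp$r_hat_R)
  for (g in by_r) {
    g <- g[order(g$f_hat_0), ]
    expect_true(all(diff(g$ttp_days) <= 0))
  }
})

test_that("trajectories stay in the (slightly inflated) simplex under random controls", {
  withr::local_seed(99)
  ens <- theta_grid(0.5)
  h <- r_S_default / 8
  for (i in 1:200) {
    th <- ens[sample.int(1225, 1), ]
    th$weight <- 1
    # random bang-bang-ish admissible control over 150 days
    u <- rep(stats::runif(30), each = 40)
    traj <- simulate_tumor(th, u, horizon_days = 150)
    expect_true(all(traj$s >= -10 * h))
    expect_true(all(traj$r >= -10 * h))
    expect_true(all(traj$n <= 1 + 10 * h))
  }
})

test_that("singleton ensembles and support permutations behave trivially", {
  ens <- theta_grid(0.5)[c(3, 700, 1100), ]
  ens$weight <- rep(1 / 3, 3)
  single <- ens[2, ]; single$weight <- 1
  full <- ttp_ensemble(ens, "mtd", 500)
  one <- ttp_ensemble(single, "mtd", 500)
  expect_identical(one$ttp_days, full$ttp_days[2])
  perm <- c(3, 1, 2)
  shuffled <- ttp_ensemble(ens[perm, ], "mtd", 500)
  expect_identical(shuffled$ttp_days, full$ttp_days[perm])
})

test_that("control grids validate dose bounds and uniform spacing", {
  expect_error(control_grid(10, u = 1.2), "\\[0, 1\\]")
  g <- control_grid(10, u = 0.5)
  expect_equal(nrow(g), 80)
  expect_equal(g$tau[2] - g$tau[1], r_S_default / 8)
  bad <- g; bad$tau[3] <- bad$tau[2]
  expect_error(validate_control(bad), "uniform")
  # schedule round-trip through CSV
  p <- withr::local_tempfile(fileext = ".csv")
  write_control(g, p)
  back <- read_control(p)
  expect_equal(back$u, g$u)
})
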