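test_that("reference grid has 1225 members with uniform weights and stated ranges", {
  ens <- theta_grid(0.5)
  expect_equal(nrow(ens), 1225)
  expect_equal(length(unique(ens$r_hat_R)), 25)
  expect_equal(length(unique(ens$f_hat_0)), 49)
  expect_true(all(ens$weight == 1 / 1225))
  expect_equal(sum(ens$weight), 1, tolerance = 1e-12)
  expect_equal(min(ens$r_hat_R), 0.5)
  expect_equal(min(ens$f_hat_0), 0.002)
  expect_equal(diff(sort(unique(ens$r_hat_R)))[1], 0.02, tolerance = 1e-12)
  expect_equal(diff(sort(unique(ens$f_hat_0)))[1], 0.002, tolerance = 1e-12)
  expect_true(all(ens$d_hat_D == 1.5) && all(ens$d_hat_T == 0))
})

test_that("ensemble validation rejects broken inputs", {
  ok <- one_theta()
  expect_silent(validate_ensemble(ok))
  bad <- ok; bad$f_hat_0 <- 1.5
  expect_error(validate_ensemble(bad), "f_hat_0")
  bad <- ok; bad$n0 <- 0
  expect_error(validate_ensemble(bad), "n0")
  two <- dplyr::bind_rows(ok, ok)
  two$weight <- c(0.5, 0.5)
  expect_error(validate_ensemble(two), "duplicated")
  two$f_hat_0[2] <- 0.02
  two$weight <- c(0.7, 0.7)
  expect_error(validate_ensemble(two), "sum to 1")
})

test_that("nondimensionalization applies the stated transforms", {
  out <- nondimensionalize(r_S = 0.027, r_R = 0.027, d_D = 0.75, d_T = 0.0135,
                           K = 1e10, S0 = 2.45e9, R0 = 5e7, T_hor = 750)
  expect_equal(out$d_hat_D, 1.5)        # 2 * d_D
  expect_equal(out$r_hat_R, 1)          # r_R == r_S
  expect_equal(out$d_hat_T, 0.5)        # d_T / r_S
  expect_equal(out$f_hat_0, 5e7 / 2.5e9)
  expect_equal(out$n0, 0.25)
  expect_equal(out$T_norm, 20.25)       # 750 days * 0.027 per day
  expect_error(nondimensionalize(0, 1, 1, 0, 1, 0.1, 0.1, 1), "positive")
  expect_error(nondimensionalize(1, 1, 1, 0, 1, 0.9, 0.2, 1), "K")
})

test_that("two-population vector field matches hand evaluation and fixed points", {
  th <- one_theta()
  f <- rhs_two_pop(th, s = 0.495, r = 0.005, u = 1)
  expect_equal(f$ds, -0.12375)
  expect_equal(f$dr, 0.00165)
  # extinction is a fixed point
  f0 <- rhs_two_pop(th, s = 0, r = 0, u = 0.3)
  expect_equal(c(f0$ds, f0$dr), c(0, 0))
  # carrying capacity is a fixed point without turnover
  fc <- rhs_two_pop(th, s = 0.6, r = 0.4, u = 1)
  expect_equal(c(fc$ds, fc$dr), c(0, 0))
  expect_error(rhs_two_pop(th, s = NaN, r = 0, u = 1), "NaN")
  expect_error(rhs_two_pop(th, s = 0.1, r = 0.1, u = 2), "0, 1")
})

test_that("general n-species model specializes to the two-population system", {
  withr::local_seed(42)
  r_S <- 0.027
  for (i in 1:100) {
    r_R <- stats::runif(1, 0.5, 1) * r_S
    d_D <- stats::runif(1, 0, 1)
    d_T <- stats::runif(1, 0, 0.5) * r_S
    spec <- general_model_spec(r = c(r_S, r_R), K = 1, d_I = c(d_D, 0),
                               d_T = c(d_T, d_T), f = c(0.99, 0.01), N0 = 0.5)
    s <- stats::runif(1, 0, 0.6); rr <- stats::runif(1, 0, 0.3)
    u <- stats::runif(1)
    gen <- rhs_general(c(s, rr), D = u, spec = spec)
    th <- nondimensionalize(r_S, r_R, d_D, d_T, K = 1, S0 = 0.3, R0 = 0.2,
                            T_hor = 1)
    two <- rhs_two_pop(th, s = s, r = rr, u = u)
    # d/dtau = (d/dt) / r_S under the time normalization
    expect_equal(gen$dX[1] / r_S, two$ds, tolerance = 1e-12)
    expect_equal(gen$dX[2] / r_S, two$dr, tolerance = 1e-12)
  }
})

test_that("population transitions redistribute but never create total mass", {
  withr::local_seed(7)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    A <- matrix(stats::runif(n * n, 0, 0.1), n, n)
    diag(A) <- 0
    diag(A) <- -colSums(A)
    A_I <- matrix(stats::runif(n * n, 0, 0.1), n, n)
    diag(A_I) <- 0
    diag(A_I) <- -colSums(A_I)
    spec <- general_model_spec(r = rep(0, n), K = 1, d_I = rep(0, n),
                               d_T = rep(0, n), A = A, A_I = A_I,
                               f = rep(1 / n, n), N0 = 0.5)
    X <- stats::runif(n, 0, 1 / n)
    out <- rhs_general(X, D = stats::runif(1), spec = spec)
    expect_equal(sum(out$dX), 0, tolerance = 1e-12)
  }
  # zero state maps to zero fields
  spec <- general_model_spec(r = c(0.03, 0.02), K = 1, d_I = c(1, 0),
                             d_T = c(0, 0), f = c(0.5, 0.5), N0 = 0.5)
  z <- rhs_general(c(0, 0), D = 1, spec = spec)
  expect_equal(z$F0, c(0, 0))
  expect_equal(z$F1, c(0, 0))
})

test_that("model spec validation names the violated invariant", {
  expect_error(
    general_model_spec(r = c(1, 1), K = 1, d_I = c(0, 0), d_T = c(0, 0),
                       A = matrix(c(-1, 1, 0.5, -0.5), 2, 2) + 0.01,
                       f = c(0.5, 0.5), N0 = 0.5),
    "columns must sum to 0"
  )
  expect_error(
    general_model_spec(r = c(1, 1), K = 1, d_I = c(-0.1, 0), d_T = c(0, 0),
                       f = c(0.5, 0.5), N0 = 0.5),
    "d_I"
  )
  expect_error(
    general_model_spec(r = c(1, 1), K = 1, d_I = c(0, 0), d_T = c(0, 0),
                       f = c(0.6, 0.5), N0 = 0.5),
    "sum to 1"
  )
})

test_that("ensemble and model-spec files round-trip", {
  ens <- sample_theta(10, n0 = 0.5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(ens, path)
  expect_equal(as.data.frame(read_ensemble(path)), as.data.frame(ens),
               tolerance = 1e-12)

  spec <- general_model_spec(r = c(0.027, 0.018), K = 2, d_I = c(0.75, 0),
                             d_T = c(0.01, 0.01),
                             A = matrix(c(-0.1, 0.1, 0.2, -0.2), 2, 2),
                             f = c(0.99, 0.01), N0 = 1)
  for (ext in c(".yaml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_model_spec(spec, p)
    back <- read_model_spec(p)
    expect_equal(back$A, spec$A, tolerance = 1e-12)
    expect_equal(back$r, spec$r, tolerance = 1e-12)
  }
})

test_that("random fixture ensembles are seeded and stay in the parameter box", {
  a <- sample_theta(50, n0 = 0.5, seed = 11)
  b <- sample_theta(50, n0 = 0.5, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$r_hat_R >= 0.5 & a$r_hat_R <= 1))
  expect_true(all(a$f_hat_0 >= 0.002 & a$f_hat_0 <= 0.1))
  big <- sample_theta(1225, n0 = 0.5, seed = 1)
  # quantile coverage of the sampling boxes
  expect_lt(stats::quantile(big$r_hat_R, 0.05), 0.55)
  expect_gt(stats::quantile(big$r_hat_R, 0.95), 0.95)
})
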