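test_that("Gompertz curve has the right limits, asymptote and inflection value", {
  gp <- truth_params()$growth
  expect_equal(gompertz_growth(-1e6, gp), gp[["X0"]])
  expect_equal(gompertz_growth(1e6, gp), gp[["X0"]] + gp[["C"]])
  expect_equal(gp[["X0"]] + gp[["C"]], 5.9468, tolerance = 1e-12)
  # at t = M the curve passes through X0 + C/e
  expect_equal(gompertz_growth(gp[["M"]], gp),
               gp[["X0"]] + gp[["C"]] / exp(1), tolerance = 1e-12)
  expect_equal(gompertz_growth(3.2823, gp), 2.2281, tolerance = 1e-4)
  # monotone non-decreasing
  tt <- seq(-5, 30, by = 0.1)
  expect_true(all(diff(gompertz_growth(tt, gp)) >= 0))
})

test_that("rate terms obey the half-saturation and zero-state identities", {
  qp <- truth_params()$qs
  # production half-saturation at X = km1, for any exponent
  mu <- rate_terms(qp[["km1"]], c(A = 0, L = 0), qp)
  expect_equal(mu[["muA"]], qp[["kA"]] / 2, tolerance = 1e-12)
  expect_equal(mu[["muA"]], 780.84, tolerance = 1e-12)
  # A = 0, L = 0 kills every consumption and expression term
  expect_equal(unname(mu[c("muXA", "muLA", "muL", "muAL", "muR")]),
               rep(0, 5))
  expect_gt(mu[["muA"]], 0)
  # LsrACDB terms reduce to their rate constants at X = Xdelta, A = L = 1
  mu1 <- rate_terms(qp[["Xdelta"]], c(A = 1, L = 1), qp)
  expect_equal(mu1[["muLA"]], qp[["kLA"]], tolerance = 1e-12)
  expect_equal(mu1[["muAL"]], qp[["kAL"]], tolerance = 1e-12)
  # saturation limit of the production Hill term
  mu_sat <- rate_terms(1000 * qp[["km1"]], c(A = 0, L = 0), qp)
  expect_equal(mu_sat[["muA"]], qp[["kA"]], tolerance = 1e-3)
  # domain errors
  expect_error(rate_terms(-1, c(A = 0, L = 0), qp), "X >= 0")
  expect_error(rate_terms(1, c(A = -1, L = 0), qp), "A >= 0")
})

test_that("model right-hand side matches its rate-term decomposition", {
  tr <- truth_params()
  # at the origin of (A, L) only production remains
  d0 <- model_rhs(3, c(A = 0, L = 0), tr$growth, tr$qs)
  mu <- rate_terms(gompertz_growth(3, tr$growth), c(A = 0, L = 0), tr$qs)
  expect_equal(d0[["dA"]], mu[["muA"]])
  expect_equal(d0[["dL"]], 0)
  # with no production the origin is a fixed point
  qp0 <- tr$qs
  qp0[["kA"]] <- 0
  qp0 <- do.call(qs_params, as.list(unclass(qp0)))
  expect_equal(unname(model_rhs(3, c(A = 0, L = 0), tr$growth, qp0)),
               c(0, 0))
  # consumption terms are non-negative, so dA/dt <= muA
  set.seed(11)
  for (i in 1:20) {
    st <- c(A = runif(1, 0, 2000), L = runif(1, 0, 2000))
    t <- runif(1, 0, 12)
    mu <- rate_terms(gompertz_growth(t, tr$growth), st, tr$qs)
    expect_lte(model_rhs(t, st, tr$growth, tr$qs)[["dA"]], mu[["muA"]])
  }
})

test_that("simulated trajectories are non-negative with exact closed-form growth", {
  tr <- truth_params()
  grid <- seq(0, 12, by = 0.1)
  traj <- simulate_qs(tr$growth, tr$qs, t_grid = grid)
  expect_identical(traj$X, gompertz_growth(grid, tr$growth))
  expect_true(all(traj$A >= 0))
  expect_true(all(traj$L >= 0))
  # AI-2 rises to a single interior maximum and is depleted afterwards;
  # expression rises and declines after its later peak
  iA <- which.max(traj$A)
  expect_gt(iA, 1); expect_lt(iA, length(grid))
  expect_true(all(diff(traj$A[1:iA]) >= -1e-9))
  expect_true(all(diff(traj$A[iA:length(grid)]) <= 1e-9))
  expect_lt(traj$A[length(grid)], 0.2 * max(traj$A))
  iL <- which.max(traj$L)
  expect_gt(iL, iA)  # expression follows the signal
  expect_lt(iL, length(grid))
  expect_lt(traj$L[length(grid)], max(traj$L))
})

test_that("origin is invariant when production is off", {
  tr <- truth_params()
  qp0 <- unclass(tr$qs); qp0[["kA"]] <- 0
  traj <- simulate_qs(tr$growth, do.call(qs_params, as.list(qp0)),
                      t_grid = seq(0, 12, by = 0.5))
  expect_equal(max(abs(traj$A)), 0)
  expect_equal(max(abs(traj$L)), 0)
})

test_that("halving solver tolerances leaves reported values unchanged to 1e-4", {
  tr <- truth_params()
  grid <- seq(0, 12, by = 0.25)
  t1 <- simulate_qs(tr$growth, tr$qs, t_grid = grid)
  t2 <- simulate_qs(tr$growth, tr$qs, t_grid = grid,
                    rel_tol = 5e-9, abs_tol = 5e-11)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-8))
  expect_lt(rel(t1$A, t2$A), 1e-4)
  expect_lt(rel(t1$L, t2$L), 1e-4)
})

test_that("with uptake off, AI-2 equals the quadrature of the production rate", {
  tr <- truth_params()
  qp <- unclass(tr$qs)
  qp[["kXA"]] <- 0; qp[["kLA"]] <- 0
  qp <- do.call(qs_params, as.list(qp))
  grid <- seq(0, 10, by = 0.5)
  traj <- simulate_qs(tr$growth, qp, t_grid = grid)
  # independent oracle: high-resolution trapezoid rule on muA(X(s))
  fine <- seq(0, 10, by = 0.001)
  muA <- vapply(fine, function(s)
    rate_terms(gompertz_growth(s, tr$growth), c(A = 0, L = 0), qp)[["muA"]],
    numeric(1))
  cum <- c(0, cumsum((muA[-1] + muA[-length(muA)]) / 2 * diff(fine)))
  oracle <- cum[match(round(grid, 3), round(fine, 3))]
  expect_equal(traj$A, oracle, tolerance = 1e-5)
})

test_that("AI-2 responds monotonically to the production velocity", {
  tr <- truth_params()
  # the first grid point is the shared initial state A = 0; strict
  # dominance applies to every later time
  grid <- seq(0, 12, by = 0.5)
  prev <- NULL
  for (kA in c(800, 1561.68, 3000)) {
    qp <- unclass(tr$qs); qp[["kA"]] <- kA
    A <- simulate_qs(tr$growth, do.call(qs_params, as.list(qp)),
                     t_grid = grid)$A[-1]
    if (!is.null(prev)) expect_true(all(A > prev))
    prev <- A
  }
})

test_that("trajectories survive a CSV round trip", {
  tr <- truth_params()
  traj <- simulate_qs(tr$growth, tr$qs, t_grid = seq(0, 6, by = 0.5))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_s3_class(back, "qs_trajectory")
  expect_equal(back$A, traj$A, tolerance = 1e-12)
  expect_equal(back$time, traj$time)
})
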