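test_that("growth parameters are recovered from noiseless data", {
  tr <- truth_params()
  g <- growth_fit_noiseless()
  rel <- abs(unclass(g$par) / unclass(tr$growth) - 1)
  expect_true(all(rel < 0.01))
})

test_that("growth recovery tolerates 5% observation noise", {
  tr <- truth_params()
  ds <- generate_dataset(tr$growth, tr$qs,
                         design_spec(span = c(0, 12), dt_XA = 0.5, dt_L = 3,
                                     cv = c(X = 0.05, A = 0, L = 0),
                                     seed = 31))
  g <- fit_growth(ds, control = de_control(max_gen = 400, seed = 8))
  rel <- abs(unclass(g$par) / unclass(tr$growth) - 1)
  # C, B, M are set by the bulk of the curve and recover to relative
  # accuracy; the inoculum X0 is ~1% of the normalization scale, so
  # only absolute accuracy at the noise level is attainable
  expect_true(all(rel[c("C", "B", "M")] < 0.10))
  expect_lt(abs(g$par[["X0"]] - tr$growth[["X0"]]), 0.05)
})

test_that("constant density data trigger a degenerate-fit warning", {
  ds <- qs_data(X = data.frame(time = 0:9, value = rep(2, 10)))
  expect_warning(fit_growth(ds, control = de_control(max_gen = 150, seed = 4)),
                 "degenerate")
  expect_error(fit_growth(qs_data(X = data.frame(time = 0:2,
                                                 value = c(1, 2, 3)))),
               "at least 5")
})

test_that("the generating truth is a minimizer of the noiseless cost", {
  tr <- truth_params()
  ds <- noiseless_dataset()
  fd <- qsdyn:::prepare_fit_data(ds)
  fitds <- qs_data(A = fd$A, L = fd$L)
  at_cost <- function(qp) {
    traj <- simulate_qs(tr$growth, qp, t_grid = fd$sim_times)
    sswr(fitds, traj)
  }
  base <- at_cost(tr$qs)
  expect_lt(base, 1e-10)
  for (pm in c("kA", "kXA", "kR", "kL")) {
    qp <- unclass(tr$qs)
    qp[[pm]] <- 2 * qp[[pm]]
    expect_gt(at_cost(do.call(qs_params, as.list(qp))), base)
  }
})

test_that("kinetic fitting penalizes failed integrations instead of crashing", {
  tr <- truth_params()
  ds <- noiseless_dataset()
  # absurd bounds force stiff blow-ups for some population members
  bounds <- default_qs_bounds()
  bounds$upper[["kAL"]] <- 1e8
  bounds$lower[["kAL"]] <- 1e6
  k <- suppressWarnings(
    fit_qs(ds, tr$growth, bounds = bounds,
           control = de_control(pop_size = 8, max_gen = 2, seed = 1)))
  expect_true(is.finite(k$value))
})

test_that("the two-stage fit object supports the standard methods", {
  tr <- truth_params()
  ds <- noiseless_dataset()
  fit <- qs_fit(ds,
                growth_control = de_control(max_gen = 200, seed = 5),
                qs_control = de_control(pop_size = 20, max_gen = 25, seed = 6))
  cf <- coef(fit)
  expect_length(cf, 17)
  expect_named(cf, c("X0", "C", "B", "M", "kA", "km1", "n1", "kXA", "km2",
                     "n2", "kLA", "Xdelta", "kL", "km3", "n3", "kAL", "kR"))
  traj <- predict(fit, times = seq(0, 8, by = 0.5))
  expect_s3_class(traj, "qs_trajectory")
  res <- residuals(fit)
  expect_named(res, c("X", "A", "L"))
  expect_length(res$A, nrow(ds$A))
  expect_output(print(fit), "Two-stage")
  expect_output(print(summary(fit)), "Residual sum of squares")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_fit_report(fit, path, seed = 5)
  rep <- jsonlite::fromJSON(path)
  expect_equal(rep$theta$kA, unname(cf[["kA"]]))
  expect_false(is.null(rep$kinetic$fixed$n3))
})
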