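test_that("bootstrap weights are Exponential(1) with unit mean and variance", {
  w <- draw_weights(1e5, seed = 123)
  expect_true(all(w > 0))
  expect_gt(mean(w), 0.99); expect_lt(mean(w), 1.01)
  expect_gt(var(w), 0.97); expect_lt(var(w), 1.03)
  expect_identical(w, draw_weights(1e5, seed = 123))
  expect_error(draw_weights(0), ">= 1")
})

test_that("interval endpoints follow the type-7 quantile rule", {
  reps <- cbind(a = 1:1000, b = (1:1000) * 2)
  ci <- qsdyn:::boot_ci(reps)
  expect_equal(unname(ci[, "a"]), c(25.975, 975.025), tolerance = 1e-12)
  expect_equal(unname(ci[, "b"]), 2 * c(25.975, 975.025), tolerance = 1e-12)
})

test_that("degenerate unit-weight bootstrap collapses to zero-width intervals", {
  ds <- noiseless_dataset()
  g <- growth_fit_noiseless()
  k <- fit_qs(ds, g$par,
              control = de_control(pop_size = 20, max_gen = 30, seed = 2))
  bs <- weighted_bootstrap(ds, k, n_reps = 4, seed = 3,
                           control = de_control(pop_size = 10, max_gen = 8),
                           weight_sampler = function(n, seed) rep(1, n))
  expect_equal(max(bs$ci["hi", ] - bs$ci["lo", ]), 0)
  expect_equal(nrow(unique(bs$replicates)), 1)
})

test_that("bootstrap results are reproducible and medians sit inside the intervals", {
  ds <- noiseless_dataset()
  g <- growth_fit_noiseless()
  k <- fit_qs(ds, g$par,
              control = de_control(pop_size = 20, max_gen = 30, seed = 2))
  bs1 <- weighted_bootstrap(ds, k, n_reps = 8, seed = 5,
                            control = de_control(pop_size = 10, max_gen = 10))
  bs2 <- weighted_bootstrap(ds, k, n_reps = 8, seed = 5,
                            control = de_control(pop_size = 10, max_gen = 10))
  expect_identical(bs1$replicates, bs2$replicates)
  med <- apply(bs1$replicates, 2, stats::median)
  expect_true(all(med >= bs1$ci["lo", ] - 1e-12))
  expect_true(all(med <= bs1$ci["hi", ] + 1e-12))
})

test_that("parameter dependency is a valid correlation matrix", {
  set.seed(77)
  a <- rnorm(500)
  fake <- structure(list(replicates = cbind(pa = a, pb = 2 * a,
                                            pc = rnorm(500))),
                    class = "qs_bootstrap")
  dep <- parameter_dependency(fake)
  expect_equal(dep["pa", "pb"], 1, tolerance = 1e-12)
  expect_lt(abs(dep["pa", "pc"]), 0.15)
  expect_identical(dep, t(dep))
  expect_equal(unname(diag(dep)), rep(1, 3))
  const <- structure(list(replicates = cbind(pa = a, pb = rep(1, 500))),
                     class = "qs_bootstrap")
  expect_error(parameter_dependency(const), "constant")
  tiny <- structure(list(replicates = fake$replicates[1:5, ]),
                    class = "qs_bootstrap")
  expect_error(parameter_dependency(tiny), "at least 10")
})

test_that("replicates and interval summaries are written to disk", {
  fake <- structure(list(replicates = cbind(kA = c(1, 2, 3, 4),
                                            kR = c(4, 3, 2, 1)),
                         sswr = c(0.1, 0.2, 0.3, 0.4),
                         converged = c(TRUE, TRUE, FALSE, TRUE),
                         ci = qsdyn:::boot_ci(cbind(kA = c(1, 2, 3, 4),
                                                    kR = c(4, 3, 2, 1))),
                         n_fail = 0, seed = 1),
                    class = "qs_bootstrap")
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  on.exit(unlink(c(csv, json)))
  write_bootstrap(fake, csv_path = csv, json_path = json)
  back <- utils::read.csv(csv)
  expect_named(back, c("kA", "kR", "sswr", "converged"))
  ci <- jsonlite::fromJSON(json)$confidence_interval
  expect_equal(ci$kA$lo, unname(fake$ci["lo", "kA"]))
})
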