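# construct a profile object directly for classification-logic tests
mk_profile <- function(scan, sswr, best_value = scan[which.min(sswr)],
                       best_sswr = min(sswr), n_data = 28, n_free = 11) {
  structure(list(param = "kA", scan = scan, sswr = sswr,
                 best_value = best_value, best_sswr = best_sswr,
                 n_data = n_data, n_free = n_free),
            class = "qs_profile")
}

test_that("classification separates concave, one-sided-flat and flat profiles", {
  scan <- seq(1, 21)
  parab <- mk_profile(scan, 0.1 + 0.01 * (scan - 11)^2)
  expect_equal(classify_identifiability(parab, delta = 0.05), "identifiable")
  # decreasing to a plateau: no rise to the right of the minimum
  dec <- mk_profile(scan, c(seq(2, 0.2, length.out = 10), rep(0.1, 11)))
  expect_equal(classify_identifiability(dec, delta = 0.05),
               "practically non-identifiable (flat right)")
  flat <- mk_profile(scan, rep(0.1, 21))
  expect_match(classify_identifiability(flat, delta = 0.05),
               "flat\\)$")
  rising <- mk_profile(scan, c(rep(0.1, 11), seq(0.12, 2, length.out = 10)))
  expect_equal(classify_identifiability(rising, delta = 0.05),
               "practically non-identifiable (flat left)")
  # an infinite threshold makes everything non-identifiable
  expect_match(classify_identifiability(parab, delta = Inf),
               "non-identifiable")
  # incomplete profiles are refused
  broken <- mk_profile(scan, c(0.1, 0.2, NA, NA, rep(NA, 17)))
  expect_error(classify_identifiability(broken), "incomplete")
})

test_that("a clamp at the optimum re-fits to (at least) the optimal cost", {
  ds <- noiseless_dataset()
  tr <- truth_params()
  g <- growth_fit_noiseless()
  k <- fit_qs(ds, g$par,
              control = de_control(pop_size = 40, max_gen = 200,
                                   tol = 1e-12, seed = 3))
  est <- k$theta[["kR"]]
  prof <- profile_likelihood(ds, k, "kR", n_points = 5, span = 1.5,
                             control = de_control(pop_size = 12,
                                                  max_gen = 12, seed = 4))
  expect_true(all(is.finite(prof$sswr)))
  # lower envelope: clamping is a constraint, so no profile point beats
  # the (well-converged) global optimum by more than numerical noise
  expect_true(all(prof$sswr >= k$value - 1e-6 * max(1, k$value)))
  # the scan point nearest the optimum re-fits essentially to the optimum
  at_opt <- prof$sswr[which.min(abs(prof$scan - est))]
  expect_lt(at_opt, k$value + 1e-6)
})

test_that("a larger re-optimization budget never raises the first profile point", {
  ds <- noiseless_dataset()
  g <- growth_fit_noiseless()
  k <- fit_qs(ds, g$par,
              control = de_control(pop_size = 40, max_gen = 120, seed = 3))
  p_small <- profile_likelihood(ds, k, "kA", n_points = 3, span = 2,
                                control = de_control(pop_size = 10,
                                                     max_gen = 5, seed = 6))
  p_large <- profile_likelihood(ds, k, "kA", n_points = 3, span = 2,
                                control = de_control(pop_size = 10,
                                                     max_gen = 25, seed = 6))
  # same seed: the longer run extends the shorter one's search, and DE
  # selection is greedy, so each point can only improve
  expect_true(all(p_large$sswr <= p_small$sswr + 1e-12))
})

test_that("profile CSV output is long-format and complete", {
  prof <- mk_profile(1:6, c(3, 2, 1, 1.2, 2.2, 3.1))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_profile(prof, path)
  back <- utils::read.csv(path)
  expect_named(back, c("param", "scan_value", "sswr"))
  expect_equal(nrow(back), 6)
})
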