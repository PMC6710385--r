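test_that("capacity is partitioned exactly between the strains", {
  gp <- truth_params()$growth
  for (f in c(0.1, 0.37, 0.5, 0.9)) {
    cfg <- cocult_config(f, 0)
    Cw <- f * gp[["C"]]
    Cko <- (1 - f) * gp[["C"]]
    expect_equal(Cw + Cko, gp[["C"]], tolerance = 1e-15)
    # asymptotes: X_w + X_ko -> 2 X0 + C
    X <- cocult_growth(1e6, gp, cfg)
    expect_equal(X$X_w + X$X_ko, 2 * gp[["X0"]] + gp[["C"]],
                 tolerance = 1e-9)
  }
  expect_equal(0.5 * 5.8828, 2.9414)
  expect_error(cocult_config(0), "wild_fraction")
  expect_error(cocult_config(0.5, -1), "preculture")
})

test_that("without pre-culture the strains differ only through their capacity", {
  gp <- truth_params()$growth
  tt <- seq(0, 12, by = 0.5)
  X <- cocult_growth(tt, gp, cocult_config(0.5, 0))
  expect_equal(X$X_w, X$X_ko, tolerance = 1e-9)
  X2 <- cocult_growth(tt, gp, cocult_config(0.3, 0))
  g <- (X2$X_w - gp[["X0"]]) / (0.3 * gp[["C"]])
  g2 <- (X2$X_ko - gp[["X0"]]) / (0.7 * gp[["C"]])
  expect_equal(g, g2, tolerance = 1e-9)
})

test_that("co-culture derivatives reduce toward the single culture", {
  tr <- truth_params()
  st <- c(A = 200, L = 50)
  # wild fraction ~ 1: knockout sits at the inoculum density only
  d_co <- cocult_rhs(4, st, tr$growth, tr$qs, cocult_config(1 - 1e-9, 0))
  d_mono <- model_rhs(4, st, tr$growth, tr$qs)
  mu_ko <- rate_terms(tr$growth[["X0"]], st, tr$qs)
  expect_equal(d_co[["dA"]],
               d_mono[["dA"]] - mu_ko[["muXA"]] - mu_ko[["muLA"]],
               tolerance = 1e-6)
  # at A = 0 only production remains and it is non-negative
  d0 <- cocult_rhs(4, c(A = 0, L = 10), tr$growth, tr$qs,
                   cocult_config(0.5, 0))
  expect_gte(d0[["dA"]], 0)
})

test_that("knockout scavenging only lowers the AI-2 pool", {
  tr <- truth_params()
  grid <- seq(0, 12, by = 0.25)
  co <- simulate_cocult(tr$growth, tr$qs, cocult_config(0.5, 0), grid)
  # single culture on the same wild-strain growth path (capacity C_w)
  gp_half <- growth_params(tr$growth[["X0"]], 0.5 * tr$growth[["C"]],
                           tr$growth[["B"]], tr$growth[["M"]])
  mono_w <- simulate_qs(gp_half, tr$qs, t_grid = grid)
  expect_true(all(co$A <= mono_w$A + 1e-6))
})

test_that("co-culture trajectories converge to the single culture in the limit", {
  tr <- truth_params()
  gp_small <- growth_params(1e-6, tr$growth[["C"]], tr$growth[["B"]],
                            tr$growth[["M"]])
  grid <- seq(0, 12, by = 0.25)
  mono <- simulate_qs(gp_small, tr$qs, t_grid = grid)
  co <- simulate_cocult(gp_small, tr$qs, cocult_config(0.999, 0), grid)
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(rel(co$A, mono$A), 0.01)
  expect_lt(rel(co$L, mono$L), 0.01)
})

test_that("fraction sweep reports the expected rows and monotone onset", {
  tr <- truth_params()
  grid <- seq(0, 24, by = 0.1)
  sw <- sweep_fractions(tr$growth, tr$qs, t_grid = grid)
  expect_equal(sw$fraction, c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_true(all(sw$peak_A >= 0) && all(sw$peak_L >= 0))
  # expression onset: ratios rise over the low fractions
  expect_true(all(diff(sw$L_ratio[1:3]) > 0))
  expect_error(sweep_fractions(tr$growth, tr$qs, fractions = numeric(0)),
               "non-empty")
})

test_that("pre-culture sweep is consistent and dominance holds", {
  tr <- truth_params()
  grid <- seq(0, 24, by = 0.1)
  sw <- sweep_preculture(tr$growth, tr$qs, t_grid = grid)
  expect_equal(sw$tau_h, c(0, 2, 3, 4, 5))
  # peak expression never increases with a longer knockout head start
  expect_true(all(diff(sw$peak_L) <= 1e-6))
  # the tau = 0 row reproduces the fraction-0.5 co-culture peak
  fr <- sweep_fractions(tr$growth, tr$qs, fractions = 0.5, t_grid = grid)
  expect_equal(sw$peak_L[sw$tau_h == 0], fr$peak_L, tolerance = 1e-2)
  expect_error(sweep_preculture(tr$growth, tr$qs, taus = numeric(0)),
               "non-empty")
})
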