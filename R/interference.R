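#' Co-culture configuration
#'
#' Settings for the shared-medium co-culture of a producing wild-type
#' strain and a non-producing, sensing LuxS-knockout strain. The two
#' strains partition the medium's carrying capacity: the wild strain
#' grows by `C_w = wild_fraction * C` and the knockout by
#' `C_ko = (1 - wild_fraction) * C`, so `C_w + C_ko = C` exactly.
#' `preculture_hours` is the time the knockout has already spent
#' growing alone before being added to the co-culture at `t = 0`.
#'
#' @param wild_fraction Fraction of the capacity taken by the wild
#'   strain, in (0, 1).
#' @param preculture_hours Knockout head-start growth time (h), >= 0.
#' @return An object of class `"cocult_config"`.
#' @export
cocult_config <- function(wild_fraction = 0.5, preculture_hours = 0) {
  if (!is.finite(wild_fraction) || wild_fraction <= 0 || wild_fraction >= 1)
    stop("wild_fraction must be in (0, 1)", call. = FALSE)
  if (!is.finite(preculture_hours) || preculture_hours < 0)
    stop("preculture_hours must be >= 0", call. = FALSE)
  structure(list(wild_fraction = wild_fraction,
                 preculture_hours = preculture_hours),
            class = "cocult_config")
}

# Pre-grown biomass the knockout carries into the co-culture beyond the
# shared inoculum X0. During pre-culture the knockout grows alone in
# its own medium, so the full-capacity Gompertz curve applies; the
# increment is measured from t = 0 so that preculture_hours = 0 reduces
# exactly to the plain co-culture.
preculture_biomass <- function(gp, tau) {
  g <- function(t) exp(-exp(-gp[["B"]] * (t - gp[["M"]])))
  gp[["C"]] * (g(tau) - g(0))
}

#' Co-culture growth curves
#'
#' Closed-form cell densities of both strains. The wild strain follows
#' the Gompertz law with its capacity share `C_w`. The knockout enters
#' at `X0` plus whatever biomass it gained during pre-culture (grown
#' alone at full capacity `C`), and then grows by its co-culture share
#' `C_ko` on the same Gompertz schedule.
#'
#' @param t Time(s) in hours.
#' @param gp A [growth_params()] object (shared `X0`, `B`, `M`).
#' @param cfg A [cocult_config()] object.
#' @return A data frame with columns `X_w` and `X_ko`.
#' @export
cocult_growth <- function(t, gp, cfg) {
  gp <- if (inherits(gp, "growth_params")) gp else do.call(growth_params, as.list(gp))
  g <- exp(-exp(-gp[["B"]] * (t - gp[["M"]])))
  Cw <- cfg$wild_fraction * gp[["C"]]
  Cko <- (1 - cfg$wild_fraction) * gp[["C"]]
  ko_base <- gp[["X0"]] + preculture_biomass(gp, cfg$preculture_hours)
  data.frame(X_w = gp[["X0"]] + Cw * g, X_ko = ko_base + Cko * g)
}

#' Co-culture time derivatives
#'
#' Reference R implementation of the co-culture right-hand side: AI-2
#' is produced by the wild strain only; consumption sums the PTS and
#' LsrACDB terms of both strains (the knockout's LsrACDB uptake is
#' driven by the shared expression level `L`); operon expression
#' follows the wild strain's density.
#'
#' @inheritParams cocult_growth
#' @param state Named vector/list with `A` and `L`.
#' @param qp A [qs_params()] object.
#' @return Named numeric vector `c(dA, dL)`.
#' @export
cocult_rhs <- function(t, state, gp, qp, cfg) {
  X <- cocult_growth(t, gp, cfg)
  mu_w <- rate_terms(X$X_w, state, qp)
  mu_ko <- rate_terms(X$X_ko, state, qp)
  c(dA = mu_w[["muA"]] -
      (mu_w[["muXA"]] + mu_ko[["muXA"]] + mu_w[["muLA"]] + mu_ko[["muLA"]]),
    dL = mu_w[["muL"]] + mu_w[["muAL"]] - mu_w[["muR"]])
}

#' Simulate the co-culture interference model
#'
#' Integrates the shared AI-2 pool and the wild strain's operon
#' expression under scavenging by the knockout. The default horizon is
#' 24 h: with the capacity split between the strains, neither reaches
#' the density that switches on strong PTS uptake, so the expression
#' dynamics are slower than in monoculture and need the longer window
#' to be fully realized.
#'
#' @inheritParams simulate_qs
#' @param cfg A [cocult_config()] object.
#' @return A `"qs_cocult_trajectory"` data frame with columns `time`,
#'   `X_w`, `X_ko`, `A`, `L`.
#' @export
#' @examples
#' truth <- default_truth()
#' co <- simulate_cocult(truth$growth, truth$qs, cocult_config(0.5, 0))
#' max(co$L) / max(simulate_qs(truth$growth, truth$qs,
#'                             t_grid = co$time)$L)
simulate_cocult <- function(gp, qp, cfg = cocult_config(),
                            t_grid = seq(0, 24, by = 0.05),
                            init = default_init(),
                            rel_tol = 1e-8, abs_tol = 1e-10) {
  gp <- if (inherits(gp, "growth_params")) gp else do.call(growth_params, as.list(gp))
  qp <- if (inherits(qp, "qs_params")) qp else as_qs_params(qp)
  t_grid <- check_grid(t_grid)
  init <- check_state(init)

  ko_base <- gp[["X0"]] + preculture_biomass(gp, cfg$preculture_hours)
  parms <- c(X0 = gp[["X0"]], B = gp[["B"]], M = gp[["M"]],
             Cw = cfg$wild_fraction * gp[["C"]],
             Cko = (1 - cfg$wild_fraction) * gp[["C"]],
             koBase = ko_base, unclass(qp))

  times <- t_grid
  single <- length(times) == 1
  if (single) times <- c(times, times + 1e-6)
  out <- tryCatch(
    deSolve::lsoda(y = init, times = times, func = "qsdyn_cocult_derivs",
                   parms = parms, dllname = "qsdyn",
                   initfunc = "qsdyn_cocult_init",
                   rtol = rel_tol, atol = abs_tol),
    warning = function(w) stop("ODE integration failed: ",
                               conditionMessage(w), call. = FALSE),
    error = function(e) stop("ODE integration failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (single) out <- out[1, , drop = FALSE]
  X <- cocult_growth(t_grid, gp, cfg)
  traj <- data.frame(time = t_grid, X_w = X$X_w, X_ko = X$X_ko,
                     A = clip_nonneg(out[, "A"], abs_tol, "A"),
                     L = clip_nonneg(out[, "L"], abs_tol, "L"))
  class(traj) <- c("qs_cocult_trajectory", "qs_trajectory", "data.frame")
  attr(traj, "growth") <- gp
  attr(traj, "qs") <- qp
  attr(traj, "config") <- cfg
  traj
}

#' Capacity-fraction sweep
#'
#' Simulates co-cultures in which the wild strain takes a range of
#' capacity fractions (the knockout the complement) and compares the
#' wild strain's peak operon expression with the monoculture reference
#' simulated once on the same grid from the same initial state.
#'
#' @inheritParams simulate_cocult
#' @param fractions Wild-strain capacity fractions, all in (0, 1).
#' @return A data frame of class `"qs_fraction_sweep"` with columns
#'   `fraction`, `peak_A`, `peak_L`, `L_ratio` (co-culture peak L over
#'   monoculture peak L). The monoculture peaks are stored in
#'   attributes `mono_peak_A`, `mono_peak_L`.
#' @export
sweep_fractions <- function(gp, qp, fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            t_grid = seq(0, 24, by = 0.05),
                            init = default_init()) {
  if (!length(fractions)) stop("fractions must be non-empty", call. = FALSE)
  mono <- simulate_qs(gp, qp, t_grid = t_grid, init = init)
  mono_peak_L <- max(mono$L)
  rows <- lapply(fractions, function(f) {
    co <- simulate_cocult(gp, qp, cocult_config(f, 0), t_grid, init)
    data.frame(fraction = f, peak_A = max(co$A), peak_L = max(co$L),
               L_ratio = max(co$L) / mono_peak_L)
  })
  out <- do.call(rbind, rows)
  attr(out, "mono_peak_A") <- max(mono$A)
  attr(out, "mono_peak_L") <- mono_peak_L
  class(out) <- c("qs_fraction_sweep", "data.frame")
  out
}

#' Pre-culture sweep
#'
#' Simulates 50/50 co-cultures in which the knockout is pre-cultured
#' for a range of head-start times before being added to the wild
#' culture. A pre-culture time suppresses quorum sensing when the wild
#' strain's peak operon expression falls below
#' `suppression_threshold` times the no-pre-culture control peak (the
#' same co-culture at `tau = 0`, the sweep's own baseline).
#'
#' @inheritParams simulate_cocult
#' @param taus Pre-culture times (h), all >= 0.
#' @param suppression_threshold Fraction of the `tau = 0` control peak
#'   below which expression counts as suppressed, in (0, 1).
#' @return A data frame of class `"qs_preculture_sweep"` with columns
#'   `tau_h`, `peak_L`, `suppressed`. Attributes: `control_peak_L`
#'   (the `tau = 0` co-culture peak), `mono_peak_L`, and
#'   `min_suppressing_tau` (smallest suppressing tau in `taus`, or `NA`
#'   if none).
#' @export
sweep_preculture <- function(gp, qp, taus = c(0, 2, 3, 4, 5),
                             t_grid = seq(0, 24, by = 0.05),
                             init = default_init(),
                             suppression_threshold = 0.10) {
  if (!length(taus)) stop("taus must be non-empty", call. = FALSE)
  if (any(taus < 0)) stop("taus must be >= 0", call. = FALSE)
  if (suppression_threshold <= 0 || suppression_threshold >= 1)
    stop("suppression_threshold must be in (0, 1)", call. = FALSE)
  mono <- simulate_qs(gp, qp, t_grid = t_grid, init = init)
  control <- simulate_cocult(gp, qp, cocult_config(0.5, 0), t_grid, init)
  control_peak <- max(control$L)
  rows <- lapply(taus, function(tau) {
    co <- if (tau == 0) control else
      simulate_cocult(gp, qp, cocult_config(0.5, tau), t_grid, init)
    data.frame(tau_h = tau, peak_L = max(co$L),
               suppressed = max(co$L) < suppression_threshold * control_peak)
  })
  out <- do.call(rbind, rows)
  sup <- out$tau_h[out$suppressed]
  attr(out, "control_peak_L") <- control_peak
  attr(out, "mono_peak_L") <- max(mono$L)
  attr(out, "min_suppressing_tau") <- if (length(sup)) min(sup) else NA_real_
  attr(out, "suppression_threshold") <- suppression_threshold
  class(out) <- c("qs_preculture_sweep", "data.frame")
  out
}

#' @export
print.qs_preculture_sweep <- function(x, ...) {
  print.data.frame(x, ...)
  tau <- attr(x, "min_suppressing_tau")
  cat(sprintf("control (tau = 0) peak L: %.4g; threshold %.2f\n",
              attr(x, "control_peak_L"), attr(x, "suppression_threshold")))
  cat(if (is.na(tau)) "no tested pre-culture time suppresses expression\n"
      else sprintf("minimal suppressing pre-culture time: %g h\n", tau))
  invisible(x)
}

#' @export
print.qs_fraction_sweep <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("monoculture reference: peak A %.4g, peak L %.4g\n",
              attr(x, "mono_peak_A"), attr(x, "mono_peak_L")))
  invisible(x)
}
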