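#' Default optimizer bounds
#'
#' Box constraints used by [fit_growth()] and [fit_qs()] when no bounds
#' are supplied. Kinetic bounds follow the calibrated confidence ranges
#' where available (e.g. `kA` in \[1000, 2000\]); exponents default to
#' \[1e-4, 10\] and unconstrained rates to \[1e-4, 1e3\]. The `kXA`
#' range is \[100, 500\] so that the reference estimate 343.98 is
#' feasible. Bounds for `n3` and `Xdelta` are only used when those
#' parameters are freed.
#'
#' @return `default_growth_bounds()` and `default_qs_bounds()` each
#'   return a list with `lower` and `upper` named vectors.
#' @export
default_qs_bounds <- function() {
  lower <- c(kA = 1000, km1 = 0.8491, n1 = 0.8096,
             kXA = 100, km2 = 4.4554, n2 = 2.0857,
             kLA = 1e-4, Xdelta = 0.5,
             kL = 0.1, km3 = 0.001, n3 = 1e-4,
             kAL = 1e-4, kR = 0.001)
  upper <- c(kA = 2000, km1 = 10, n1 = 10,
             kXA = 500, km2 = 5.8211, n2 = 9,
             kLA = 0.0999, Xdelta = 10,
             kL = 5, km3 = 10, n3 = 10,
             kAL = 1, kR = 5)
  list(lower = lower[qs_param_names()], upper = upper[qs_param_names()])
}

#' @rdname default_qs_bounds
#' @export
default_growth_bounds <- function() {
  list(lower = c(X0 = 1e-3, C = 1, B = 0.05, M = 0.1),
       upper = c(X0 = 1, C = 20, B = 5, M = 10))
}

#' Parameters fixed by default in the kinetic fit
#'
#' The expression-term exponent `n3` and the LsrACDB density scale
#' `Xdelta` are practically non-identifiable from single-culture data
#' (see the identifiability tools), so the kinetic fit clamps them by
#' default at the values used for the reference calibration.
#'
#' @return Named vector `c(n3 = 0.001722, Xdelta = 5.7953)`.
#' @export
default_fixed <- function() c(n3 = 0.001722, Xdelta = 5.7953)

#' Fit the Gompertz growth stage
#'
#' First stage of the two-stage calibration: the growth curve is
#' independent of the kinetic equations, so its four parameters are
#' estimated alone by minimizing the cell-density term of the [sswr()]
#' objective (closed-form model evaluation, no ODE solve) with
#' differential evolution.
#'
#' @param dataset A [qs_data()] object with at least 5 cell-density
#'   points.
#' @param bounds List with `lower`/`upper` named vectors over
#'   `X0, C, B, M`; default [default_growth_bounds()].
#' @param control A [de_control()]; `pop_size = NULL` means 10 x 4.
#' @return A list of class `"qs_growth_fit"`: `par` (a
#'   [growth_params()] object), `value` (the cost), `generations`,
#'   `converged`, `lower`, `upper`.
#' @export
fit_growth <- function(dataset, bounds = default_growth_bounds(),
                       control = de_control()) {
  if (is.null(dataset$X) || nrow(dataset$X) < 5)
    stop("growth fitting needs at least 5 cell-density points", call. = FALSE)
  s <- dataset$X
  norm <- max(s$value)
  cost_fn <- function(th) {
    pred <- th[1] + th[2] * exp(-exp(-th[3] * (s$time - th[4])))
    sum(s$weight * ((s$value - pred) / norm)^2)
  }
  de <- differential_evolution(cost_fn, bounds$lower, bounds$upper, control)
  # a sigmoid fitted to a series with no observable growth is
  # meaningless however the optimizer distributes the constants
  if (diff(range(s$value)) < 0.05 * mean(s$value))
    warning("degenerate growth fit: data show no growth signal",
            call. = FALSE)
  structure(list(par = do.call(growth_params, as.list(de$par)),
                 value = de$value, generations = de$generations,
                 converged = de$converged, lower = de$lower,
                 upper = de$upper, pop = de$pop, pop_cost = de$pop_cost),
            class = "qs_growth_fit")
}

#' @export
print.qs_growth_fit <- function(x, ...) {
  cat(sprintf("Growth-stage fit: cost %.6g (%s)\n", x$value,
              if (x$converged) "converged" else "budget exhausted"))
  print(x$par)
  invisible(x)
}

# Reconcile the sparse L series with the dense A series and build the
# simulation grid (union of data times, starting at t = 0).
#
# l_align = "model": keep the L data at their native times; the model
#   is simulated on the union grid, so its values are available there
#   without any interpolation. Unbiased, and the default.
# l_align = "data": linearly interpolate the L DATA onto the A time
#   grid restricted to the L span (no extrapolation), equalizing the
#   per-variable point counts as in protocols whose objective requires
#   equal counts. Interpolation of a coarse series distorts curvature
#   around the expression peak and measurably biases the repression
#   rate, which is why it is not the default.
prepare_fit_data <- function(dataset, l_align = c("model", "data")) {
  l_align <- match.arg(l_align)
  if (is.null(dataset$A))
    stop("kinetic fitting needs AI-2 activity data", call. = FALSE)
  A <- dataset$A
  L <- dataset$L
  if (l_align == "data" && !is.null(L) && nrow(L) >= 2) {
    keep <- A$time >= min(L$time) - 1e-12 & A$time <= max(L$time) + 1e-12
    grid <- A$time[keep]
    L <- data.frame(time = grid,
                    value = interpolate_to_grid(L$time, L$value, grid),
                    weight = 1)
  }
  sim_times <- sort(unique(c(0, A$time, if (!is.null(L)) L$time)))
  list(A = A, L = L, sim_times = sim_times)
}

#' Fit the kinetic stage
#'
#' Second stage of the two-stage calibration: with the growth
#' parameters fixed at their stage-one estimates, the remaining kinetic
#' constants are estimated by differential evolution. Each cost
#' evaluation integrates the AI-2/operon dynamics on the union of the
#' data time grids and computes the [sswr()] over the `A` and `L`
#' series (cell density is excluded; its parameters are already fixed).
#' Failed integrations score a large
#' finite penalty (`1e6`) rather than aborting the optimizer.
#'
#' @param dataset A [qs_data()] object with `A` (and ideally `L`) data.
#' @param gp Fixed [growth_params()], normally from [fit_growth()].
#' @param fixed Named vector of kinetic parameters to clamp; default
#'   [default_fixed()]. Use `NULL` to free all thirteen.
#' @param bounds List with `lower`/`upper` over all thirteen kinetic
#'   names; the free subset is used. Default [default_qs_bounds()].
#' @param control A [de_control()].
#' @param weights Optional list of per-point weight vectors for `A` and
#'   `L` (on the aligned grids), as used by the weighted bootstrap.
#' @param init Optional warm-start population over the free parameters.
#' @param init_state Initial model state, default [default_init()].
#' @param l_align How to reconcile the sparse `L` series with the
#'   dense `A` series: `"model"` (default) evaluates the simulated
#'   trajectory at the `L` data's own times; `"data"` linearly
#'   interpolates the `L` data onto the `A` grid restricted to the `L`
#'   span, equalizing point counts at the price of a small
#'   interpolation bias near the expression peak.
#' @return A list of class `"qs_kinetic_fit"`: `par` (free-parameter
#'   estimates), `fixed`, `theta` (all thirteen constants as a
#'   [qs_params()] object), `value`, `generations`, `converged`,
#'   `lower`, `upper`, `n_fail` (penalized integrations), `gp`.
#' @export
fit_qs <- function(dataset, gp, fixed = default_fixed(),
                   bounds = default_qs_bounds(), control = de_control(),
                   weights = NULL, init = NULL,
                   init_state = default_init(),
                   l_align = c("model", "data")) {
  gp <- if (inherits(gp, "growth_params")) gp else do.call(growth_params, as.list(gp))
  fd <- prepare_fit_data(dataset, l_align = l_align)
  fit_dataset <- qs_data(A = fd$A, L = fd$L)

  free <- setdiff(qs_param_names(), names(fixed))
  if (!length(free)) stop("no free parameters", call. = FALSE)
  lower <- bounds$lower[free]
  upper <- bounds$upper[free]

  n_fail <- 0L
  theta_full <- stats::setNames(numeric(13), qs_param_names())
  if (length(fixed)) theta_full[names(fixed)] <- fixed
  gp_raw <- unclass(gp)

  cost_fn <- function(th) {
    theta_full[free] <- th
    parms <- c(gp_raw, theta_full)
    out <- try(deSolve::lsoda(y = init_state, times = fd$sim_times,
                              func = "qsdyn_derivs", parms = parms,
                              dllname = "qsdyn", initfunc = "qsdyn_init",
                              rtol = 1e-8, atol = 1e-10),
               silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(fd$sim_times) ||
        anyNA(out[, c("A", "L")])) {
      n_fail <<- n_fail + 1L
      return(1e6)
    }
    traj <- data.frame(time = out[, "time"], A = out[, "A"], L = out[, "L"])
    sswr(fit_dataset, traj, weights = weights)
  }

  de <- suppressWarnings(
    differential_evolution(cost_fn, lower, upper, control, init = init))
  theta_full[free] <- de$par
  structure(list(par = de$par, fixed = fixed,
                 theta = do.call(qs_params, as.list(theta_full)),
                 value = de$value, generations = de$generations,
                 converged = de$converged, lower = de$lower,
                 upper = de$upper, n_fail = n_fail, gp = gp,
                 fit_dataset = fit_dataset, sim_times = fd$sim_times,
                 pop = de$pop, pop_cost = de$pop_cost),
            class = "qs_kinetic_fit")
}

#' @export
print.qs_kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic-stage fit: cost %.6g after %d generations (%s)\n",
              x$value, x$generations,
              if (x$converged) "converged" else "budget exhausted"))
  if (x$n_fail > 0)
    cat("  penalized integration failures:", x$n_fail, "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(sprintf("%s = %g", names(x$fixed), x$fixed),
                          collapse = ", "), "\n")
  print(x$par, ...)
  invisible(x)
}

#' Two-stage calibration of the quorum-sensing model
#'
#' The package's main fitting interface. Stage one estimates the
#' Gompertz growth parameters from the cell-density series alone
#' (closed-form, no ODE solve); stage two fixes them and estimates the
#' kinetic constants against the AI-2 activity and operon-expression
#' series. Both stages use differential evolution on the normalized
#' sum-of-squares objective [sswr()].
#'
#' @inheritParams fit_qs
#' @param growth_bounds,qs_bounds Optimizer bounds per stage.
#' @param growth_control,qs_control Per-stage [de_control()] settings.
#' @return An object of class `"qs_fit"` with components `growth`
#'   (stage one), `kinetic` (stage two), `dataset`, and `value` (total
#'   cost). Supports `coef()`, `print()`, `summary()`, `predict()`,
#'   `simulate()`, `residuals()` and `plot()`.
#' @export
#' @examples
#' \donttest{
#' truth <- default_truth()
#' ds <- generate_dataset(truth$growth, truth$qs,
#'                        design_spec(cv = c(X = 0, A = 0, L = 0)))
#' fit <- qs_fit(ds, growth_control = de_control(max_gen = 150, seed = 1),
#'               qs_control = de_control(pop_size = 30, max_gen = 40, seed = 1))
#' coef(fit)
#' }
qs_fit <- function(dataset, fixed = default_fixed(),
                   growth_bounds = default_growth_bounds(),
                   qs_bounds = default_qs_bounds(),
                   growth_control = de_control(),
                   qs_control = de_control(),
                   weights = NULL, init_state = default_init(),
                   l_align = c("model", "data")) {
  g <- fit_growth(dataset, growth_bounds, growth_control)
  k <- fit_qs(dataset, g$par, fixed = fixed, bounds = qs_bounds,
              control = qs_control, weights = weights,
              init_state = init_state, l_align = l_align)
  structure(list(growth = g, kinetic = k, dataset = dataset,
                 value = g$value + k$value, init_state = init_state),
            class = "qs_fit")
}

#' @export
coef.qs_fit <- function(object, ...) {
  c(unclass(object$growth$par), unclass(object$kinetic$theta))
}

#' @export
coef.qs_growth_fit <- function(object, ...) unclass(object$par)

#' @export
coef.qs_kinetic_fit <- function(object, ...) unclass(object$theta)

#' @export
print.qs_fit <- function(x, ...) {
  cat("Two-stage quorum-sensing model fit\n")
  cat(sprintf("  growth stage:  cost %.6g (%s)\n", x$growth$value,
              if (x$growth$converged) "converged" else "budget exhausted"))
  cat(sprintf("  kinetic stage: cost %.6g (%s)\n", x$kinetic$value,
              if (x$kinetic$converged) "converged" else "budget exhausted"))
  print(coef(x))
  invisible(x)
}

#' @export
summary.qs_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 rss = vapply(res, function(r) sum(r^2), numeric(1)),
                 n = vapply(res, length, integer(1))),
            class = "summary.qs_fit")
}

#' @export
print.summary.qs_fit <- function(x, ...) {
  print(x$fit)
  cat("Residual sum of squares (raw units):\n")
  print(x$rss)
  invisible(x)
}

#' @export
predict.qs_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    hi <- max(unlist(lapply(object$dataset, function(s) max(s$time))))
    times <- seq(0, hi, length.out = 241)
  }
  simulate_qs(object$growth$par, object$kinetic$theta, t_grid = times,
              init = object$init_state)
}

#' @export
simulate.qs_fit <- function(object, nsim = 1, seed = NULL, times = NULL, ...) {
  predict.qs_fit(object, times = times, ...)
}

#' @export
residuals.qs_fit <- function(object, ...) {
  times <- sort(unique(c(0, unlist(lapply(object$dataset,
                                          function(s) s$time)))))
  traj <- predict(object, times = times)
  out <- list()
  for (v in names(object$dataset)) {
    s <- object$dataset[[v]]
    out[[v]] <- s$value - traj_at(traj, v, s$time)
  }
  out
}

#' @export
plot.qs_fit <- function(x, ...) {
  traj <- predict(x)
  vars <- names(x$dataset)
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    s <- x$dataset[[v]]
    ylim <- range(c(s$value, traj[[v]]))
    graphics::plot(s$time, s$value, xlab = "time (h)", ylab = v,
                   ylim = ylim, ...)
    graphics::lines(traj$time, traj[[v]])
  }
  invisible(x)
}

#' Write a machine-readable fit report
#'
#' JSON report carrying the estimates, cost, bounds, optimizer settings
#' and wall-clock time of a fit, for provenance alongside pipeline
#' outputs.
#'
#' @param fit A `"qs_fit"`, `"qs_growth_fit"` or `"qs_kinetic_fit"`.
#' @param path Output path.
#' @param elapsed Optional wall-clock seconds to record.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, elapsed = NULL, seed = NULL) {
  report <- list(theta = as.list(coef(fit)),
                 cost = fit$value,
                 elapsed_s = elapsed, seed = seed)
  if (inherits(fit, "qs_fit")) {
    report$growth <- list(cost = fit$growth$value,
                          converged = fit$growth$converged,
                          lower = as.list(fit$growth$lower),
                          upper = as.list(fit$growth$upper))
    report$kinetic <- list(cost = fit$kinetic$value,
                           converged = fit$kinetic$converged,
                           fixed = as.list(fit$kinetic$fixed),
                           lower = as.list(fit$kinetic$lower),
                           upper = as.list(fit$kinetic$upper))
  } else {
    report$converged <- fit$converged
    report$lower <- as.list(fit$lower)
    report$upper <- as.list(fit$upper)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
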