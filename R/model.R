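#' Gompertz growth curve
#'
#' Closed-form sigmoidal cell-density curve
#' \eqn{X(t) = X_0 + C\,e^{-e^{-B(t-M)}}}. The curve rises from `X0`
#' (as \eqn{t \to -\infty}) to `X0 + C` (as \eqn{t \to \infty}) and has
#' its inflection at `t = M`, where it takes the value `X0 + C/e`.
#'
#' @param t Time(s) in hours; any real values.
#' @param gp A [growth_params()] object.
#' @return Cell density (OD600), one value per element of `t`.
#' @export
gompertz_growth <- function(t, gp) {
  gp <- if (inherits(gp, "growth_params")) gp else do.call(growth_params, as.list(gp))
  gp[["X0"]] + gp[["C"]] * exp(-exp(-gp[["B"]] * (t - gp[["M"]])))
}

hill_term <- function(X, n, km) {
  Xn <- X^n
  Xn / (Xn + km^n)
}

#' Kinetic rate terms of the AI-2 / lsr operon model
#'
#' Evaluates the six elementary rates at a given cell density and model
#' state: AI-2 production `muA` (Hill in X), basal PTS uptake `muXA`
#' (Hill in X, linear in A), LsrACDB uptake `muLA` (proportional to
#' X/Xdelta, A and L), PTS-driven operon expression `muL`, feedback
#' expression `muAL`, and LsrR repression `muR`.
#'
#' @param X Cell density (OD600), >= 0.
#' @param state Named numeric vector or list with elements `A` (AI-2
#'   activity) and `L` (beta-gal units), both >= 0.
#' @param qp A [qs_params()] object.
#' @return Named numeric vector `muA, muXA, muLA, muL, muAL, muR`
#'   (activity/h for the first three, beta-gal/h for the last three).
#'   All six are non-negative for valid inputs.
#' @export
#' @examples
#' qp <- default_truth()$qs
#' rate_terms(qp[["km1"]], c(A = 0, L = 0), qp)[["muA"]]  # = kA/2
rate_terms <- function(X, state, qp) {
  qp <- if (inherits(qp, "qs_params")) qp else as_qs_params(qp)
  A <- state[["A"]]
  L <- state[["L"]]
  if (X < 0 || A < 0 || L < 0)
    stop("rate terms are defined for X >= 0, A >= 0, L >= 0", call. = FALSE)
  lsr_scale <- (X / qp[["Xdelta"]]) * A * L
  c(muA  = qp[["kA"]] * hill_term(X, qp[["n1"]], qp[["km1"]]),
    muXA = qp[["kXA"]] * hill_term(X, qp[["n2"]], qp[["km2"]]) * A,
    muLA = qp[["kLA"]] * lsr_scale,
    muL  = qp[["kL"]] * hill_term(X, qp[["n3"]], qp[["km3"]]) * A,
    muAL = qp[["kAL"]] * lsr_scale,
    muR  = qp[["kR"]] * L)
}

#' Time derivatives of the AI-2 / lsr operon state
#'
#' Evaluates `dA/dt = muA - muXA - muLA` and `dL/dt = muL + muAL - muR`
#' with the cell density taken from the closed-form Gompertz curve at
#' time `t`. This is the reference R implementation of the right-hand
#' side; [simulate_qs()] integrates an equivalent compiled version.
#'
#' @param t Time (h).
#' @param state Named vector/list with `A` and `L`.
#' @inheritParams simulate_qs
#' @return Named numeric vector `c(dA, dL)`.
#' @export
model_rhs <- function(t, state, gp, qp) {
  mu <- rate_terms(gompertz_growth(t, gp), state, qp)
  c(dA = mu[["muA"]] - mu[["muXA"]] - mu[["muLA"]],
    dL = mu[["muL"]] + mu[["muAL"]] - mu[["muR"]])
}

#' Default initial state
#'
#' Cultures are inoculated at low density before any AI-2 has
#' accumulated or the lsr operon is induced, so both state variables
#' start at zero.
#'
#' @return Named vector `c(A = 0, L = 0)`.
#' @export
default_init <- function() c(A = 0, L = 0)

check_state <- function(init) {
  init <- c(A = as.numeric(init[["A"]]), L = as.numeric(init[["L"]]))
  if (anyNA(init) || any(init < 0))
    stop("initial state must satisfy A >= 0, L >= 0", call. = FALSE)
  init
}

check_grid <- function(t_grid) {
  t_grid <- as.numeric(t_grid)
  if (!length(t_grid)) stop("time grid must be non-empty", call. = FALSE)
  if (length(t_grid) > 1 && any(diff(t_grid) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  t_grid
}

# Clip small solver-level negativity to zero; larger negativity means the
# model was integrated outside its domain and is reported as an error.
clip_nonneg <- function(x, abs_tol, what) {
  floor_val <- -100 * abs_tol
  if (any(x < floor_val, na.rm = TRUE))
    stop("integration produced ", what, " < ", signif(floor_val, 3),
         "; tolerance violation", call. = FALSE)
  pmax(x, 0)
}

#' Simulate the single-culture quorum-sensing model
#'
#' Integrates the AI-2 activity `A(t)` and lsr operon expression `L(t)`
#' with an adaptive-step stiff-capable solver (`deSolve::lsoda`, compiled
#' right-hand side), while the cell density column is the exact
#' closed-form Gompertz evaluation. Small negative excursions of `A` or
#' `L` (below 100 times the absolute tolerance) are clipped to zero;
#' anything larger raises an error.
#'
#' @param gp A [growth_params()] object.
#' @param qp A [qs_params()] object.
#' @param t_grid Strictly increasing times (h) at which to report the
#'   trajectory. Defaults to `[0, 12]` h at 0.05 h resolution, which
#'   covers the full growth curve.
#' @param init Initial state, default [default_init()].
#' @param rel_tol,abs_tol Solver tolerances.
#' @return A `"qs_trajectory"` data frame with columns `time`, `X`, `A`,
#'   `L`.
#' @export
#' @examples
#' truth <- default_truth()
#' traj <- simulate_qs(truth$growth, truth$qs)
#' max(traj$A)  # AI-2 peaks in mid-exponential phase, then is depleted
simulate_qs <- function(gp, qp, t_grid = seq(0, 12, by = 0.05),
                        init = default_init(),
                        rel_tol = 1e-8, abs_tol = 1e-10) {
  gp <- if (inherits(gp, "growth_params")) gp else do.call(growth_params, as.list(gp))
  qp <- if (inherits(qp, "qs_params")) qp else as_qs_params(qp)
  t_grid <- check_grid(t_grid)
  init <- check_state(init)

  parms <- c(unclass(gp), unclass(qp))
  times <- t_grid
  if (length(times) == 1) {
    times <- c(times, times + 1e-6)
    single <- TRUE
  } else single <- FALSE

  out <- tryCatch(
    deSolve::lsoda(y = init, times = times, func = "qsdyn_derivs",
                   parms = parms, dllname = "qsdyn",
                   initfunc = "qsdyn_init",
                   rtol = rel_tol, atol = abs_tol),
    warning = function(w) stop("ODE integration failed: ",
                               conditionMessage(w), call. = FALSE),
    error = function(e) stop("ODE integration failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (single) out <- out[1, , drop = FALSE]
  A <- clip_nonneg(out[, "A"], abs_tol, "A")
  L <- clip_nonneg(out[, "L"], abs_tol, "L")
  traj <- data.frame(time = t_grid,
                     X = gompertz_growth(t_grid, gp),
                     A = A, L = L)
  class(traj) <- c("qs_trajectory", "data.frame")
  attr(traj, "growth") <- gp
  attr(traj, "qs") <- qp
  traj
}

#' @export
print.qs_trajectory <- function(x, ...) {
  vars <- setdiff(names(x), "time")
  cat(sprintf("Quorum-sensing trajectory: %d time points over [%g, %g] h (%s)\n",
              nrow(x), min(x$time), max(x$time), paste(vars, collapse = ", ")))
  peaks <- vapply(vars, function(v) max(x[[v]]), numeric(1))
  cat("maxima:", paste(sprintf("%s = %.4g", vars, peaks), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.qs_trajectory <- function(x, ...) {
  vars <- intersect(c("X", "X_w", "X_ko", "A", "L"), names(x))
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in vars)
    graphics::plot(x$time, x[[v]], type = "l", xlab = "time (h)",
                   ylab = v, ...)
  invisible(x)
}

#' Read or write a trajectory CSV
#'
#' Trajectories are stored as plain CSV with header `time,X,A,L` (plus
#' `X_w`/`X_ko` for co-culture trajectories), UTF-8, `.` decimal
#' separator.
#'
#' @param traj A trajectory data frame.
#' @param path File path.
#' @return `read_trajectory()` returns the trajectory data frame;
#'   `write_trajectory()` returns `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"time" %in% names(traj))
    stop("trajectory file lacks a 'time' column: ", path, call. = FALSE)
  cls <- if (all(c("X_w", "X_ko") %in% names(traj)))
    "qs_cocult_trajectory" else "qs_trajectory"
  class(traj) <- c(cls, "data.frame")
  traj
}
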