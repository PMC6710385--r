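#' Linear interpolation onto a target grid
#'
#' Piecewise-linear interpolation used to equalize point counts between
#' the densely sampled series and the sparser operon-expression series.
#' Interpolation is exact at the original nodes; extrapolation outside
#' the data range is refused.
#'
#' @param times Strictly increasing observation times, at least 2.
#' @param values Observed values, same length as `times`.
#' @param target_grid Times to interpolate to; must lie within
#'   `[min(times), max(times)]`.
#' @return Interpolated values on `target_grid`.
#' @export
interpolate_to_grid <- function(times, values, target_grid) {
  if (length(times) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (length(values) != length(times))
    stop("times and values differ in length", call. = FALSE)
  if (any(target_grid < min(times) - 1e-12) ||
      any(target_grid > max(times) + 1e-12))
    stop("extrapolation requested: target grid outside [",
         min(times), ", ", max(times), "]", call. = FALSE)
  stats::approx(times, values, xout = target_grid, method = "linear",
                rule = 1)$y
}

# Look up trajectory values at given times; the trajectory grid must
# contain every requested time (fits simulate on the union grid).
traj_at <- function(traj, var, times, tol = 1e-9) {
  idx <- vapply(times, function(tt) {
    j <- which(abs(traj$time - tt) <= tol)
    if (!length(j)) NA_integer_ else j[1]
  }, integer(1))
  if (anyNA(idx))
    stop("trajectory does not cover dataset times: ",
         paste(times[is.na(idx)], collapse = ", "), call. = FALSE)
  traj[[var]][idx]
}

#' Normalized sum-of-squares calibration objective
#'
#' The calibration cost is
#' \deqn{SSWR = \sum_j \sum_i w_{ij}\left(\frac{y_{ij} - \hat y_{ij}}{\max_i y_{ij}}\right)^2,}
#' the sum over variables \eqn{j} and observation times \eqn{i} of the
#' squared residuals, each normalized by that variable's data maximum so
#' that observables on very different scales (OD600, activity units,
#' beta-gal units) contribute comparably. Per-point weights default to
#' those stored in the dataset (1 unless set, e.g. by the weighted
#' bootstrap).
#'
#' @param dataset A [qs_data()] object.
#' @param traj A trajectory whose time grid contains every dataset time
#'   (simulate on the union grid).
#' @param weights Optional named list of per-variable weight vectors
#'   overriding the dataset's weights.
#' @param variables Which variables to include (default: all present in
#'   both dataset and trajectory).
#' @return The cost, a non-negative number.
#' @export
sswr <- function(dataset, traj, weights = NULL, variables = NULL) {
  vars <- intersect(names(dataset), setdiff(names(traj), "time"))
  if (!is.null(variables)) vars <- intersect(vars, variables)
  total <- 0
  for (v in vars) {
    s <- dataset[[v]]
    if (!nrow(s)) next
    norm <- max(s$value)
    if (norm == 0)
      stop("variable '", v, "' has data but max(y) = 0; cannot normalize",
           call. = FALSE)
    w <- if (!is.null(weights[[v]])) weights[[v]] else s$weight
    pred <- traj_at(traj, v, s$time)
    total <- total + sum(w * ((s$value - pred) / norm)^2)
  }
  total
}
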