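#' Sampling design for synthetic datasets
#'
#' Describes how a synthetic experiment samples the model: the time
#' span, one sampling interval for the dense cell-density and AI-2
#' series, a larger interval for the sparser operon-expression series,
#' and a multiplicative-noise level (coefficient of variation) per
#' variable. The defaults emulate the structure of typical bench time
#' courses for this system: readings every half hour over 10 h, with
#' the beta-gal series measured three times less often.
#'
#' @param span Time span (h), default `c(0, 10)`.
#' @param dt_XA Sampling interval for `X` and `A` (h).
#' @param dt_L Sampling interval for `L` (h); must be >= `dt_XA`.
#' @param cv Named coefficients of variation for multiplicative
#'   Gaussian noise, e.g. `c(X = 0.05, A = 0.05, L = 0.05)`; values of
#'   0 give noiseless data.
#' @param seed Integer seed for the noise draws.
#' @return A list of class `"design_spec"`.
#' @export
design_spec <- function(span = c(0, 10), dt_XA = 0.5, dt_L = 1.5,
                        cv = c(X = 0.05, A = 0.05, L = 0.05),
                        seed = NULL) {
  if (length(span) != 2 || span[2] <= span[1])
    stop("span must be an increasing pair of times", call. = FALSE)
  if (dt_L < dt_XA)
    stop("the L series must not be denser than the X/A series", call. = FALSE)
  cv_full <- c(X = 0, A = 0, L = 0)
  cv_full[names(cv)] <- cv
  if (any(cv_full < 0)) stop("CVs must be >= 0", call. = FALSE)
  structure(list(span = span, dt_XA = dt_XA, dt_L = dt_L, cv = cv_full,
                 seed = seed), class = "design_spec")
}

#' Generate a synthetic time-series dataset
#'
#' Simulates the model at the given parameters, samples each variable
#' on its design grid, and applies multiplicative Gaussian noise
#' `value * (1 + cv * z)` with standard-normal `z`, clipped at zero.
#' The generating parameters are recorded in the dataset's `truth`
#' attribute (and serialized into the file header by
#' [write_qs_data()]), so parameter-recovery experiments are
#' self-contained.
#'
#' @inheritParams simulate_qs
#' @param design A [design_spec()] object.
#' @return A [qs_data()] object with `X`, `A` and `L` series and the
#'   generating truth attached.
#' @export
#' @examples
#' truth <- default_truth()
#' ds <- generate_dataset(truth$growth, truth$qs,
#'                        design_spec(cv = c(X = 0, A = 0, L = 0)))
#' nrow(ds$L) < nrow(ds$A)
generate_dataset <- function(gp, qp, design = design_spec(),
                             init = default_init()) {
  gp <- if (inherits(gp, "growth_params")) gp else do.call(growth_params, as.list(gp))
  qp <- if (inherits(qp, "qs_params")) qp else as_qs_params(qp)
  t_XA <- seq(design$span[1], design$span[2], by = design$dt_XA)
  t_L <- seq(design$span[1], design$span[2], by = design$dt_L)
  grid <- sort(unique(c(0, t_XA, t_L)))
  traj <- simulate_qs(gp, qp, t_grid = grid, init = init)

  if (!is.null(design$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(design$seed)
  }
  noisy <- function(values, cv) {
    if (cv == 0) return(values)
    pmax(values * (1 + cv * stats::rnorm(length(values))), 0)
  }
  pick <- function(var, times, cv) {
    v <- noisy(traj_at(traj, var, times), cv)
    if (var == "X") v <- pmax(v, 1e-6)  # densities stay positive
    data.frame(time = times, value = v, weight = 1)
  }
  qs_data(X = pick("X", t_XA, design$cv[["X"]]),
          A = pick("A", t_XA, design$cv[["A"]]),
          L = pick("L", t_L, design$cv[["L"]]),
          truth = list(growth = gp, qs = qp))
}
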