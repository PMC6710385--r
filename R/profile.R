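#' Profile-likelihood scan for one parameter
#'
#' Practical-identifiability diagnostic: the parameter is clamped at a
#' set of values around its estimate and, at each value, all remaining
#' free parameters are re-optimized (differential evolution with a
#' reduced budget, warm-started by continuation from the neighbouring
#' scan point). A parameter is practically identifiable when the
#' re-optimized cost rises on both sides of the optimum; a flat profile
#' means other parameters can absorb the change.
#'
#' Scan design: 21 points by default, log-spaced over
#' `[estimate/span, span * estimate]` (clipped to the bounds); Hill
#' exponents sitting near zero are scanned linearly from the lower
#' bound up to 1, since their action is only distinguishable on that
#' scale.
#'
#' @param dataset The calibration dataset ([qs_data()]).
#' @param fitted A `"qs_kinetic_fit"` (stage-two fit) or `"qs_fit"`.
#' @param param Name of the kinetic parameter to profile. A parameter
#'   clamped in the original fit may be profiled; it is then freed and
#'   scanned while the originally free parameters are re-optimized.
#' @param n_points Number of scan values.
#' @param span Multiplicative half-range of the scan.
#' @param control [de_control()] for the per-point re-optimizations;
#'   the default budget is deliberately small because of the warm
#'   starts.
#' @param bounds Optimizer bounds, default [default_qs_bounds()].
#' @return An object of class `"qs_profile"`: a list with `param`,
#'   `scan` (values), `sswr` (re-optimized cost per value, `NA` for
#'   recorded failures), `best_value`, `best_sswr`, `n_data`, `n_free`.
#' @seealso [classify_identifiability()]
#' @export
profile_likelihood <- function(dataset, fitted, param,
                               n_points = 21, span = 5,
                               control = de_control(pop_size = 20,
                                                    max_gen = 30),
                               bounds = default_qs_bounds()) {
  if (inherits(fitted, "qs_fit")) fitted <- fitted$kinetic
  if (!inherits(fitted, "qs_kinetic_fit"))
    stop("'fitted' must come from fit_qs() or qs_fit()", call. = FALSE)
  if (!param %in% qs_param_names())
    stop("unknown parameter: ", param, call. = FALSE)

  theta <- unclass(fitted$theta)
  est <- theta[[param]]
  fixed0 <- fitted$fixed[setdiff(names(fitted$fixed), param)]
  free <- setdiff(qs_param_names(), c(names(fixed0), param))

  # The scan range is deliberately wider than the optimizer bounds for
  # the profiled parameter itself (clamping is a constraint, not a box
  # move); the re-optimized parameters keep their bounds.
  if (param %in% c("n1", "n2", "n3") && est < 0.1) {
    scan <- seq(1e-3, 1, length.out = n_points)
  } else {
    scan <- exp(seq(log(est / span), log(est * span),
                    length.out = n_points))
  }

  np <- if (is.null(control$pop_size)) 10L * length(free)
        else control$pop_size
  if (!is.null(control$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(control$seed)
  }
  refit_at <- function(value, warm) {
    fixed_i <- c(fixed0, stats::setNames(value, param))
    jitter <- matrix(stats::rnorm((np - 1) * length(free), 0, 0.05),
                     ncol = length(free))
    init <- rbind(warm, matrix(rep(warm, each = np - 1), nrow = np - 1) *
                    (1 + jitter))
    res <- try(fit_qs(dataset, fitted$gp, fixed = fixed_i, bounds = bounds,
                      control = control, init = init),
               silent = TRUE)
    if (inherits(res, "try-error")) NULL else res
  }

  # walk outward from the optimum on each side, warm-starting every
  # point from its inner neighbour (continuation)
  prof <- rep(NA_real_, n_points)
  anchor <- which.min(abs(scan - est))
  for (side in list(anchor:1, (anchor + 1):n_points)) {
    if (side[1] > n_points) next
    warm <- theta[free]
    for (i in side) {
      res <- refit_at(scan[i], warm)
      if (!is.null(res)) {
        prof[i] <- res$value
        warm <- res$par
      }
    }
  }
  n_data <- sum(vapply(fitted$fit_dataset, nrow, integer(1)))
  structure(list(param = param, scan = scan, sswr = prof,
                 best_value = est, best_sswr = fitted$value,
                 n_data = n_data, n_free = length(free) + 1L),
            class = "qs_profile")
}

#' Default cost-increase threshold for identifiability
#'
#' Pointwise 95% threshold in the spirit of likelihood-ratio profile
#' analysis: the per-point residual variance on the normalized scale is
#' estimated from the best cost, and the allowed cost increase is the
#' 95% chi-square quantile (1 df) times that variance. A floor keeps
#' the threshold meaningful on near-noiseless data.
#'
#' @param profile A `"qs_profile"` object.
#' @return The cost-increase threshold delta.
#' @export
profile_delta <- function(profile) {
  dof <- max(profile$n_data - profile$n_free, 1)
  sigma2 <- profile$best_sswr / dof
  max(stats::qchisq(0.95, 1) * sigma2, 1e-4 * max(profile$best_sswr, 1e-8))
}

#' Classify practical identifiability from a profile
#'
#' A parameter is identifiable when the re-optimized cost exceeds
#' `best + delta` on both sides of the optimum within the scanned
#' range; otherwise it is flagged practically non-identifiable, with
#' the flat side(s) named.
#'
#' @param profile A `"qs_profile"` object with at least 5 completed
#'   points.
#' @param delta Cost-increase threshold; default [profile_delta()].
#' @return One of `"identifiable"`,
#'   `"practically non-identifiable (flat left)"`,
#'   `"practically non-identifiable (flat right)"`,
#'   `"practically non-identifiable (flat)"`.
#' @export
classify_identifiability <- function(profile, delta = profile_delta(profile)) {
  ok <- !is.na(profile$sswr)
  if (sum(ok) < 5)
    stop("incomplete profile: need at least 5 completed scan points",
         call. = FALSE)
  scan <- profile$scan[ok]
  sswr <- profile$sswr[ok]
  base <- min(c(sswr, profile$best_sswr))
  center <- scan[which.min(sswr)]
  rises <- function(side) {
    pts <- sswr[side]
    length(pts) > 0 && any(pts > base + delta)
  }
  left_up <- rises(scan < center)
  right_up <- rises(scan > center)
  if (left_up && right_up) return("identifiable")
  if (!left_up && !right_up) return("practically non-identifiable (flat)")
  if (!left_up) return("practically non-identifiable (flat left)")
  "practically non-identifiable (flat right)"
}

#' @export
print.qs_profile <- function(x, ...) {
  cat(sprintf("Profile likelihood for %s (estimate %.6g, best cost %.6g)\n",
              x$param, x$best_value, x$best_sswr))
  print(data.frame(scan = x$scan, sswr = x$sswr), ...)
  invisible(x)
}

#' @export
plot.qs_profile <- function(x, ...) {
  graphics::plot(x$scan, x$sswr, type = "b", log = "x",
                 xlab = x$param, ylab = "re-optimized cost", ...)
  graphics::abline(v = x$best_value, col = 2)
  invisible(x)
}

#' Write a profile scan as CSV
#'
#' Long format `param,scan_value,sswr`, appendable across parameters.
#'
#' @param profile A `"qs_profile"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(param = profile$param,
                              scan_value = profile$scan,
                              sswr = profile$sswr),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
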