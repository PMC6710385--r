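#' Exponential bootstrap weights
#'
#' Draws i.i.d. Exponential(1) weights (mean and variance one), one per
#' data point, as used by the weighted bootstrap.
#'
#' @param n Number of weights, >= 1.
#' @param seed Integer seed; the session RNG state is restored
#'   afterwards.
#' @return Numeric vector of `n` positive weights.
#' @export
draw_weights <- function(n, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(seed)
  }
  stats::rexp(n, rate = 1)
}

#' Weighted bootstrap for kinetic-parameter uncertainty
#'
#' Re-fits the kinetic stage under random reweighting of the data: for
#' each replicate, fresh Exponential(1) weights are attached to every
#' point's squared normalized residual in the [sswr()] and the fit is
#' re-run with a reduced, warm-started differential-evolution budget
#' (the initial population is seeded around the baseline estimates).
#' Replicate seeds derive from the master seed as `seed + replicate`.
#' Confidence intervals are the 2.5% and 97.5% quantiles (linear
#' interpolation between order statistics, R's default type 7) of the
#' replicate estimates. Only the kinetic stage is bootstrapped; the
#' growth parameters stay at their stage-one values.
#'
#' @param dataset The calibration dataset.
#' @param baseline A `"qs_kinetic_fit"` (or `"qs_fit"`) to perturb.
#' @param n_reps Number of bootstrap replicates (default 500).
#' @param control [de_control()] for the replicate fits; by default the
#'   baseline generation budget is halved.
#' @param seed Master seed for the weight draws and replicate fits.
#' @param bounds Optimizer bounds, default [default_qs_bounds()].
#' @param max_fail_frac Error out when more than this fraction of
#'   replicates fail (default 0.2); failures below that are recorded
#'   and excluded.
#' @param weight_sampler Function `(n, seed)` returning `n` positive
#'   weights; default [draw_weights()] (Exponential(1)). Injecting
#'   `function(n, seed) rep(1, n)` gives the degenerate bootstrap whose
#'   replicates are bit-identical (zero-width intervals).
#' @return An object of class `"qs_bootstrap"`: `replicates` (matrix,
#'   one row per successful replicate), `sswr`, `converged`, `ci`
#'   (matrix with rows `lo`/`hi`), `n_fail`, `seed`.
#' @export
weighted_bootstrap <- function(dataset, baseline, n_reps = 500,
                               control = NULL, seed = 1,
                               bounds = default_qs_bounds(),
                               max_fail_frac = 0.2,
                               weight_sampler = draw_weights) {
  if (inherits(baseline, "qs_fit")) baseline <- baseline$kinetic
  if (!inherits(baseline, "qs_kinetic_fit"))
    stop("'baseline' must come from fit_qs() or qs_fit()", call. = FALSE)
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (is.null(control))
    control <- de_control(pop_size = 20,
                          max_gen = max(10L, baseline$generations %/% 2L))

  nA <- nrow(baseline$fit_dataset$A)
  nL <- if (!is.null(baseline$fit_dataset$L)) nrow(baseline$fit_dataset$L) else 0L
  free <- names(baseline$par)
  np <- if (is.null(control$pop_size)) 10L * length(free) else control$pop_size

  reps <- matrix(NA_real_, n_reps, length(free),
                 dimnames = list(NULL, free))
  rep_sswr <- rep(NA_real_, n_reps)
  rep_conv <- rep(NA, n_reps)

  # Warm-start jitter drawn once from the master seed: replicate
  # variation is then attributable to the weight draws alone, and the
  # degenerate unit-weight bootstrap is exactly reproducible per
  # replicate (common random numbers).
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  jitter <- matrix(stats::rnorm((np - 1) * length(free), 0, 0.1),
                   ncol = length(free))
  init <- rbind(baseline$par,
                matrix(rep(baseline$par, each = np - 1),
                       nrow = np - 1) * (1 + jitter))
  ctrl <- control
  ctrl$seed <- seed

  for (r in seq_len(n_reps)) {
    w <- weight_sampler(nA + nL, seed + r)
    if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
    weights <- list(A = w[seq_len(nA)],
                    L = if (nL) w[nA + seq_len(nL)] else NULL)
    res <- try(fit_qs(dataset, baseline$gp, fixed = baseline$fixed,
                      bounds = bounds, control = ctrl, weights = weights,
                      init = init),
               silent = TRUE)
    if (!inherits(res, "try-error")) {
      reps[r, ] <- res$par
      rep_sswr[r] <- res$value
      rep_conv[r] <- res$converged
    }
  }

  ok <- !is.na(rep_sswr)
  n_fail <- sum(!ok)
  if (n_fail > max_fail_frac * n_reps)
    stop(n_fail, " of ", n_reps, " bootstrap replicates failed", call. = FALSE)
  reps <- reps[ok, , drop = FALSE]
  ci <- boot_ci(reps)
  structure(list(replicates = reps, sswr = rep_sswr[ok],
                 converged = rep_conv[ok], ci = ci,
                 n_fail = n_fail, seed = seed),
            class = "qs_bootstrap")
}

# 2.5%/97.5% quantiles of the replicate matrix, by linear interpolation
# between order statistics (quantile type 7)
boot_ci <- function(reps) {
  ci <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975),
              type = 7, names = FALSE)
  ci <- matrix(ci, nrow = 2, dimnames = list(c("lo", "hi"), colnames(reps)))
  ci
}

#' @export
print.qs_bootstrap <- function(x, ...) {
  cat(sprintf("Weighted bootstrap: %d successful replicates (%d failed)\n",
              nrow(x$replicates), x$n_fail))
  cat("95% confidence intervals (2.5%/97.5% quantiles):\n")
  print(t(x$ci), ...)
  invisible(x)
}

#' Pairwise parameter dependency from bootstrap replicates
#'
#' Pearson correlations of the replicate estimates; strong off-diagonal
#' entries flag parameter combinations the data only constrain jointly.
#'
#' @param result A `"qs_bootstrap"` with at least 10 successful
#'   replicates.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
parameter_dependency <- function(result) {
  reps <- result$replicates
  if (nrow(reps) < 10)
    stop("need at least 10 successful replicates", call. = FALSE)
  sds <- apply(reps, 2, stats::sd)
  if (any(sds == 0))
    stop("constant replicate column(s): ",
         paste(colnames(reps)[sds == 0], collapse = ", "), call. = FALSE)
  stats::cor(reps)
}

#' Write bootstrap replicates and interval summary
#'
#' Replicates go to CSV (one row per replicate, named parameter columns
#' plus `sswr` and `converged`); the interval summary goes to JSON with
#' per-parameter `lo`/`hi` fields.
#'
#' @param result A `"qs_bootstrap"`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, a list of the written paths.
#' @export
write_bootstrap <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- cbind(as.data.frame(result$replicates),
                sswr = result$sswr, converged = result$converged)
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    ci <- lapply(seq_len(ncol(result$ci)), function(j)
      list(lo = result$ci["lo", j], hi = result$ci["hi", j]))
    names(ci) <- colnames(result$ci)
    jsonlite::write_json(list(n_reps = nrow(result$replicates),
                              n_fail = result$n_fail,
                              seed = result$seed,
                              confidence_interval = ci),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}
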