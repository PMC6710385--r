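#' Differential-evolution settings
#'
#' Control object for the global optimizer. Defaults follow the
#' standard Storn-Price recommendations: population of 10 times the
#' problem dimension (set at run time when `pop_size = NULL`),
#' mutation factor `F = 0.5`, crossover rate `CR = 0.9`, at most 300
#' generations, and convergence when the population cost spread falls
#' below `1e-8`.
#'
#' @param pop_size Population size (>= 4), or `NULL` for 10 x dimension.
#' @param F Mutation factor in (0, 2].
#' @param CR Crossover rate in \[0, 1\].
#' @param max_gen Maximum number of generations.
#' @param tol Convergence tolerance on the population cost spread.
#' @param seed Integer seed making the run fully reproducible, or
#'   `NULL` to draw from the session RNG.
#' @return A list of class `"de_control"`.
#' @export
de_control <- function(pop_size = NULL, F = 0.5, CR = 0.9,
                       max_gen = 300, tol = 1e-8, seed = NULL) {
  if (!is.null(pop_size) && pop_size < 4)
    stop("population size must be >= 4", call. = FALSE)
  if (F <= 0 || F > 2) stop("F must be in (0, 2]", call. = FALSE)
  if (CR < 0 || CR > 1) stop("CR must be in [0, 1]", call. = FALSE)
  structure(list(pop_size = pop_size, F = F, CR = CR,
                 max_gen = as.integer(max_gen), tol = tol, seed = seed),
            class = "de_control")
}

reflect_into <- function(x, lo, hi) {
  # reflect out-of-bounds genes back into range, then clamp for safety
  span <- hi - lo
  out <- x
  below <- out < lo
  out[below] <- lo[below] + (lo[below] - out[below])
  above <- out > hi
  out[above] <- hi[above] - (out[above] - hi[above])
  pmin(pmax(out, lo), hi)
}

#' Differential evolution (rand/1/bin)
#'
#' Classic population-based global minimizer: for each target vector a
#' mutant `a + F (b - c)` is built from three distinct other members,
#' mixed in by binomial crossover with one guaranteed gene, and kept
#' only if it does not worsen the cost (greedy selection).
#' Out-of-bounds genes are reflected back into range. The best cost
#' never worsens across generations, and a run is bit-reproducible
#' given `control$seed`.
#'
#' @param cost_fn Function mapping a numeric vector to a finite cost.
#' @param lower,upper Finite bounds, `lower < upper` elementwise.
#'   Names, if present, are carried into the result.
#' @param control A [de_control()] object.
#' @param init Optional initial population matrix (rows = members) used
#'   for warm starts; rows are clamped to the bounds and the population
#'   is padded with uniform draws if too small.
#' @return A list of class `"de_fit"`: `par` (best vector), `value`
#'   (best cost), `generations`, `converged`, `lower`, `upper`,
#'   `n_eval`, `pop` (final population), `pop_cost`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- differential_evolution(sphere, rep(-5, 3), rep(5, 3),
#'                               de_control(seed = 1))
#' fit$value < 1e-6
differential_evolution <- function(cost_fn, lower, upper,
                                   control = de_control(), init = NULL) {
  nm <- names(lower)
  if (is.null(nm)) nm <- names(upper)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(lower)
  if (length(upper) != d || !all(is.finite(c(lower, upper))) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)

  if (!is.null(control$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(control$seed)
  }

  np <- if (is.null(control$pop_size)) max(10L * d, 4L)
        else as.integer(control$pop_size)

  pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                             rep(upper, each = np)), nrow = np)
  if (!is.null(init)) {
    init <- matrix(as.numeric(init), ncol = d)
    take <- min(nrow(init), np)
    pop[seq_len(take), ] <- t(apply(init[seq_len(take), , drop = FALSE], 1,
                                    function(r) pmin(pmax(r, lower), upper)))
  }
  cost <- apply(pop, 1, cost_fn)
  n_eval <- np

  gen <- 0L
  converged <- FALSE
  while (gen < control$max_gen) {
    gen <- gen + 1L
    for (i in seq_len(np)) {
      others <- sample(setdiff(seq_len(np), i), 3L)
      mutant <- pop[others[1], ] +
        control$F * (pop[others[2], ] - pop[others[3], ])
      mutant <- reflect_into(mutant, lower, upper)
      cross <- stats::runif(d) < control$CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      tc <- cost_fn(trial)
      n_eval <- n_eval + 1L
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
    if (max(cost) - min(cost) < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && gen >= control$max_gen)
    warning("differential evolution budget exhausted (", control$max_gen,
            " generations); returning best found", call. = FALSE)

  best <- which.min(cost)
  par <- pop[best, ]
  names(par) <- nm
  structure(list(par = par, value = cost[best], generations = gen,
                 converged = converged, lower = stats::setNames(lower, nm),
                 upper = stats::setNames(upper, nm), n_eval = n_eval,
                 pop = pop, pop_cost = cost),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("Differential-evolution fit: cost %.6g after %d generations (%s)\n",
              x$value, x$generations,
              if (x$converged) "converged" else "budget exhausted"))
  print(x$par, ...)
  invisible(x)
}
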