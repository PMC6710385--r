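#' Run one stage of the analysis workflow
#'
#' Programmatic pipeline tying the stages together in the order of a
#' full study: `synth` (generate a dataset), `fit` (two-stage
#' calibration), `simulate` (single-culture trajectory), `cocult`
#' (interference sweeps), `profile` (identifiability scans) and
#' `bootstrap` (confidence intervals). Every run writes its outputs
#' plus a `manifest.json` echoing the resolved configuration and seeds,
#' and logs one line per stage to stderr. All randomness flows from
#' `seed`; inputs are never mutated. A thin command-line wrapper around
#' this function ships in `inst/scripts/qs-pipeline.R`.
#'
#' @param command One of `"synth"`, `"fit"`, `"simulate"`, `"cocult"`,
#'   `"profile"`, `"bootstrap"`.
#' @param config Named list of stage settings; unrecognized keys are an
#'   error. Common keys: `params` (path to a parameter file, default
#'   the reference set), `dataset` (path to a dataset CSV). Stage keys:
#'   `span`, `dt_XA`, `dt_L`, `cv` (synth); `max_gen`, `pop_size`
#'   (fit/profile/bootstrap); `t_max`, `dt` (simulate/cocult);
#'   `fractions`, `taus`, `suppression_threshold` (cocult);
#'   `profile_params`, `n_points` (profile); `n_reps` (bootstrap).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer master seed.
#' @return Invisibly, a list with the written file paths and the main
#'   in-memory result of the stage.
#' @export
run_qs_pipeline <- function(command, config = list(), out_dir = ".",
                            seed = 1) {
  commands <- c("synth", "fit", "simulate", "cocult", "profile", "bootstrap")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "), call. = FALSE)
  allowed <- c("params", "dataset", "span", "dt_XA", "dt_L", "cv",
               "max_gen", "pop_size", "t_max", "dt", "fractions", "taus",
               "suppression_threshold", "profile_params", "n_points",
               "n_reps", "init_A", "init_L")
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cfg <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  params <- if (!is.null(config$params)) read_params(config$params)
            else default_truth()
  init <- c(A = cfg("init_A", 0), L = cfg("init_L", 0))
  outputs <- character()
  started <- Sys.time()
  message(sprintf("[qsdyn] %s: start (seed %s, out_dir %s)",
                  command, seed, out_dir))

  result <- switch(
    command,
    synth = {
      design <- design_spec(span = cfg("span", c(0, 10)),
                            dt_XA = cfg("dt_XA", 0.5),
                            dt_L = cfg("dt_L", 1.5),
                            cv = unlist(cfg("cv", c(X = 0.05, A = 0.05,
                                                    L = 0.05))),
                            seed = seed)
      ds <- generate_dataset(params$growth, params$qs, design, init = init)
      p <- file.path(out_dir, "dataset.csv")
      write_qs_data(ds, p)
      outputs <- c(outputs, p)
      ds
    },
    fit = {
      ds <- read_qs_data(cfg("dataset",
                             stop("fit needs config$dataset", call. = FALSE)))
      ctrl_g <- de_control(max_gen = cfg("max_gen", 300), seed = seed)
      ctrl_q <- de_control(pop_size = cfg("pop_size", NULL),
                           max_gen = cfg("max_gen", 300), seed = seed + 1)
      fit <- qs_fit(ds, growth_control = ctrl_g, qs_control = ctrl_q,
                    init_state = init)
      pg <- file.path(out_dir, "growth_fit.json")
      pq <- file.path(out_dir, "qs_fit.json")
      write_fit_report(fit$growth, pg, seed = seed)
      write_fit_report(fit$kinetic, pq, seed = seed + 1)
      outputs <- c(outputs, pg, pq)
      fit
    },
    simulate = {
      grid <- seq(0, cfg("t_max", 12), by = cfg("dt", 0.05))
      traj <- simulate_qs(params$growth, params$qs, t_grid = grid,
                          init = init)
      p <- file.path(out_dir, "trajectory.csv")
      write_trajectory(traj, p)
      outputs <- c(outputs, p)
      traj
    },
    cocult = {
      grid <- seq(0, cfg("t_max", 24), by = cfg("dt", 0.05))
      fr <- sweep_fractions(params$growth, params$qs,
                            fractions = cfg("fractions",
                                            c(0.1, 0.3, 0.5, 0.7, 0.9)),
                            t_grid = grid, init = init)
      pc <- sweep_preculture(params$growth, params$qs,
                             taus = cfg("taus", c(0, 2, 3, 4, 5)),
                             t_grid = grid, init = init,
                             suppression_threshold =
                               cfg("suppression_threshold", 0.10))
      pf <- file.path(out_dir, "fraction_sweep.csv")
      pp <- file.path(out_dir, "preculture_sweep.csv")
      utils::write.csv(data.frame(fraction = fr$fraction,
                                  peak_A = fr$peak_A, peak_L = fr$peak_L,
                                  L_ratio = fr$L_ratio),
                       pf, row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(tau_h = pc$tau_h, peak_L = pc$peak_L,
                                  suppressed = pc$suppressed),
                       pp, row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, pf, pp)
      list(fractions = fr, preculture = pc)
    },
    profile = {
      ds <- read_qs_data(cfg("dataset",
                             stop("profile needs config$dataset",
                                  call. = FALSE)))
      ctrl <- de_control(pop_size = cfg("pop_size", 30),
                         max_gen = cfg("max_gen", 60), seed = seed)
      fit <- qs_fit(ds, growth_control = de_control(seed = seed),
                    qs_control = ctrl, init_state = init)
      pcontrol <- de_control(pop_size = 20,
                             max_gen = max(10, cfg("max_gen", 60) %/% 2),
                             seed = seed + 1)
      labels <- list()
      for (pm in cfg("profile_params", c("kA", "n3", "Xdelta"))) {
        prof <- profile_likelihood(ds, fit, pm,
                                   n_points = cfg("n_points", 21),
                                   control = pcontrol)
        pp <- file.path(out_dir, paste0("profile_", pm, ".csv"))
        write_profile(prof, pp)
        outputs <- c(outputs, pp)
        labels[[pm]] <- classify_identifiability(prof)
      }
      pj <- file.path(out_dir, "identifiability.json")
      jsonlite::write_json(labels, pj, auto_unbox = TRUE, pretty = TRUE)
      outputs <- c(outputs, pj)
      labels
    },
    bootstrap = {
      ds <- read_qs_data(cfg("dataset",
                             stop("bootstrap needs config$dataset",
                                  call. = FALSE)))
      ctrl <- de_control(pop_size = cfg("pop_size", 30),
                         max_gen = cfg("max_gen", 60), seed = seed)
      fit <- qs_fit(ds, growth_control = de_control(seed = seed),
                    qs_control = ctrl, init_state = init)
      bs <- weighted_bootstrap(ds, fit, n_reps = cfg("n_reps", 500),
                               seed = seed + 1)
      pc <- file.path(out_dir, "bootstrap_replicates.csv")
      pj <- file.path(out_dir, "bootstrap_ci.json")
      write_bootstrap(bs, csv_path = pc, json_path = pj)
      outputs <- c(outputs, pc, pj)
      bs
    })

  manifest <- list(command = command, seed = seed,
                   config = config, outputs = outputs,
                   elapsed_s = as.numeric(difftime(Sys.time(), started,
                                                   units = "secs")))
  pm <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  message(sprintf("[qsdyn] %s: done in %.1fs -> %s",
                  command, manifest$elapsed_s,
                  paste(basename(outputs), collapse = ", ")))
  invisible(list(outputs = c(outputs, pm), result = result))
}
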