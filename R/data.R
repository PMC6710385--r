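#' Time-series dataset of growth, AI-2 activity and operon expression
#'
#' Container for observed (or synthetic) time courses of the three model
#' observables, each on its own time grid: cell density `X` (OD600),
#' extracellular AI-2 activity `A` (arbitrary activity units) and lsr
#' operon expression `L` (beta-gal units). The `L` series typically has
#' fewer points than the other two. Optional per-point weights default
#' to 1 and are used by the weighted bootstrap.
#'
#' @param X,A,L Each `NULL` or a data frame (or list) with components
#'   `time` (h, strictly increasing), `value`, and optionally `weight`
#'   (positive, default 1).
#' @param truth Optional list with `growth`/`qs` components recording
#'   the generating parameters of a synthetic dataset.
#' @return An object of class `"qs_data"`: a named list of per-variable
#'   data frames with columns `time`, `value`, `weight`.
#' @seealso [generate_dataset()], [sswr()], [fit_growth()], [fit_qs()]
#' @export
qs_data <- function(X = NULL, A = NULL, L = NULL, truth = NULL) {
  series <- list(X = X, A = A, L = L)
  series <- series[!vapply(series, is.null, logical(1))]
  if (!length(series)) stop("at least one variable is required", call. = FALSE)
  series <- lapply(names(series), function(v) {
    s <- as.data.frame(series[[v]])
    if (!all(c("time", "value") %in% names(s)))
      stop("series '", v, "' needs 'time' and 'value'", call. = FALSE)
    if (is.null(s$weight)) s$weight <- 1
    if (nrow(s) > 1 && any(diff(s$time) <= 0))
      stop("series '", v, "' times must be strictly increasing", call. = FALSE)
    if (any(s$weight <= 0))
      stop("series '", v, "' weights must be positive", call. = FALSE)
    if (v == "X" && any(s$value <= 0))
      stop("cell-density values must be > 0", call. = FALSE)
    if (v != "X" && any(s$value < 0))
      stop("series '", v, "' values must be >= 0", call. = FALSE)
    s[, c("time", "value", "weight")]
  })
  names(series) <- names(list(X = X, A = A, L = L)[
    !vapply(list(X = X, A = A, L = L), is.null, logical(1))])
  structure(series, truth = truth, class = "qs_data")
}

#' @export
print.qs_data <- function(x, ...) {
  cat("Quorum-sensing time-series dataset:\n")
  for (v in names(x))
    cat(sprintf("  %s: %d points over [%g, %g] h\n", v, nrow(x[[v]]),
                min(x[[v]]$time), max(x[[v]]$time)))
  if (!is.null(attr(x, "truth"))) cat("  (generating truth attached)\n")
  invisible(x)
}

#' Read or write a dataset as long-format CSV
#'
#' The on-disk format is a long table `variable,time,value[,weight]`.
#' Generating truth, when present, is stored in `# truth: key=value`
#' comment lines before the header, so recovery experiments are
#' self-contained in one file.
#'
#' @param dataset A [qs_data()] object.
#' @param path File path.
#' @return `read_qs_data()` returns a [qs_data()] object (with `truth`
#'   restored if the file records it); `write_qs_data()` returns `path`,
#'   invisibly.
#' @export
write_qs_data <- function(dataset, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    flat <- c(as.list(unclass(truth$growth)), as.list(unclass(truth$qs)))
    for (k in names(flat))
      writeLines(sprintf("# truth: %s=%.17g", k, flat[[k]]), con)
  }
  long <- do.call(rbind, lapply(names(dataset), function(v)
    cbind(variable = v, dataset[[v]])))
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qs_data
#' @export
read_qs_data <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  truth_lines <- grep("^# truth:", lines, value = TRUE)
  truth <- NULL
  if (length(truth_lines)) {
    kv <- sub("^# truth:\\s*", "", truth_lines)
    keys <- sub("=.*$", "", kv)
    vals <- as.numeric(sub("^.*=", "", kv))
    names(vals) <- keys
    gnames <- c("X0", "C", "B", "M")
    truth <- list()
    if (all(gnames %in% keys))
      truth$growth <- do.call(growth_params, as.list(vals[gnames]))
    if (all(qs_param_names() %in% keys))
      truth$qs <- do.call(qs_params, as.list(vals[qs_param_names()]))
  }
  body <- lines[!startsWith(lines, "#")]
  long <- utils::read.csv(text = paste(body, collapse = "\n"))
  series <- lapply(split(long, long$variable), function(s)
    s[order(s$time), setdiff(names(s), "variable"), drop = FALSE])
  qs_data(X = series[["X"]], A = series[["A"]], L = series[["L"]],
          truth = truth)
}
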