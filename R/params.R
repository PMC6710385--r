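#' Gompertz growth parameters
#'
#' Bundles the four constants of the Gompertz growth law
#' \eqn{X(t) = X_0 + C\,e^{-e^{-B(t-M)}}}: the inoculum density, the
#' additional density gained (asymptote), the growth rate and the
#' inflection time.
#'
#' @param X0 Initial cell density (OD600), > 0.
#' @param C Maximum additional cell density, i.e. the asymptote above
#'   `X0` (OD600), > 0.
#' @param B Growth rate (1/h), > 0.
#' @param M Inflection time (h), >= 0.
#'
#' @return An object of class `"growth_params"`: a named numeric vector
#'   with elements `X0`, `C`, `B`, `M`.
#' @seealso [gompertz_growth()], [default_truth()]
#' @export
#' @examples
#' gp <- growth_params(X0 = 0.064, C = 5.8828, B = 0.6384, M = 3.2823)
#' gompertz_growth(c(0, 3.2823, 24), gp)
growth_params <- function(X0, C, B, M) {
  p <- c(X0 = as.numeric(X0), C = as.numeric(C),
         B = as.numeric(B), M = as.numeric(M))
  if (anyNA(p) || any(!is.finite(p)))
    stop("growth parameters must be finite numbers", call. = FALSE)
  if (p[["X0"]] <= 0) stop("X0 must be > 0", call. = FALSE)
  if (p[["C"]] <= 0) stop("C must be > 0", call. = FALSE)
  if (p[["B"]] <= 0) stop("B must be > 0", call. = FALSE)
  if (p[["M"]] < 0) stop("M must be >= 0", call. = FALSE)
  structure(p, class = "growth_params")
}

#' Quorum-sensing kinetic parameters
#'
#' Bundles the thirteen kinetic constants of the AI-2 / lsr operon
#' dynamics: production (`kA`, `km1`, `n1`), basal PTS uptake (`kXA`,
#' `km2`, `n2`), LsrACDB uptake (`kLA`, `Xdelta`), operon expression
#' (`kL`, `km3`, `n3`), feedback expression (`kAL`) and LsrR repression
#' (`kR`).
#'
#' @param kA AI-2 production velocity (activity/h).
#' @param km1 Cell density at half-maximal production (OD600).
#' @param n1 Hill exponent of the production term.
#' @param kXA PTS uptake rate (1/h).
#' @param km2 Cell density at half-maximal PTS uptake (OD600).
#' @param n2 Hill exponent of the PTS term.
#' @param kLA AI-2 uptake rate through LsrACDB (1/(beta-gal h)).
#' @param Xdelta Cell density scaling the LsrACDB terms (OD600),
#'   expected near the late-exponential-phase density.
#' @param kL Operon expression rate (beta-gal/(activity h)).
#' @param km3 Cell density at half-maximal expression (OD600).
#' @param n3 Hill exponent of the expression term.
#' @param kAL Feedback operon expression rate (1/(activity h)).
#' @param kR Operon repression rate (1/h).
#'
#' @return An object of class `"qs_params"`: a named numeric vector of
#'   the thirteen constants.
#' @seealso [rate_terms()], [simulate_qs()], [default_truth()]
#' @export
qs_params <- function(kA, km1, n1, kXA, km2, n2, kLA, Xdelta,
                      kL, km3, n3, kAL, kR) {
  p <- c(kA = as.numeric(kA), km1 = as.numeric(km1), n1 = as.numeric(n1),
         kXA = as.numeric(kXA), km2 = as.numeric(km2), n2 = as.numeric(n2),
         kLA = as.numeric(kLA), Xdelta = as.numeric(Xdelta),
         kL = as.numeric(kL), km3 = as.numeric(km3), n3 = as.numeric(n3),
         kAL = as.numeric(kAL), kR = as.numeric(kR))
  if (anyNA(p) || any(!is.finite(p)))
    stop("kinetic parameters must be finite numbers", call. = FALSE)
  if (any(p < 0))
    stop("kinetic parameters must be >= 0; offending: ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  # half-saturation densities, the LsrACDB scale and exponents sit in
  # denominators or powers and must be strictly positive
  strict <- c("km1", "km2", "km3", "Xdelta", "n1", "n2", "n3")
  if (any(p[strict] <= 0))
    stop("parameters ", paste(strict[p[strict] <= 0], collapse = ", "),
         " must be > 0", call. = FALSE)
  structure(p, class = "qs_params")
}

qs_param_names <- function() {
  c("kA", "km1", "n1", "kXA", "km2", "n2", "kLA", "Xdelta",
    "kL", "km3", "n3", "kAL", "kR")
}

as_qs_params <- function(x) {
  x <- unclass(x)[qs_param_names()]
  do.call(qs_params, as.list(x))
}

#' Reference parameter set (synthetic-data ground truth)
#'
#' Returns the parameter values used throughout the package as the
#' generating truth of the synthetic-data module and the default for
#' simulations: the calibrated single-culture values for E. coli AI-2
#' dynamics (growth saturating near OD600 5.9, AI-2 peaking in
#' mid-exponential phase, operon expression following with delay).
#'
#' @return A list with components `growth` (a [growth_params()] object)
#'   and `qs` (a [qs_params()] object).
#' @export
#' @examples
#' truth <- default_truth()
#' truth$growth
#' truth$qs[["kA"]]
default_truth <- function() {
  list(
    growth = growth_params(X0 = 0.064, C = 5.8828, B = 0.6384, M = 3.2823),
    qs = qs_params(kA = 1561.68, km1 = 1.5793, n1 = 2.9302,
                   kXA = 343.98, km2 = 5.8205, n2 = 8.9542,
                   kLA = 0.0044, Xdelta = 5.7953,
                   kL = 0.5825, km3 = 3.9128, n3 = 0.0017,
                   kAL = 0.0028, kR = 0.1037)
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Gompertz growth parameters (X(t) = X0 + C exp(-exp(-B(t - M)))):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.qs_params <- function(x, ...) {
  cat("AI-2 quorum-sensing kinetic parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Read or write a flat parameter file
#'
#' Parameters are serialized as a flat JSON or YAML map keyed by the
#' symbol names `X0, C, B, M, kA, km1, n1, kXA, km2, n2, kLA, Xdelta,
#' kL, km3, n3, kAL, kR`. Either the growth block, the kinetic block or
#' both may be present.
#'
#' @param path File path; format is chosen by extension (`.json`,
#'   `.yaml`/`.yml`).
#' @param params A list with components `growth` and/or `qs` as returned
#'   by [default_truth()].
#'
#' @return `read_params()` returns a list with whichever of `growth` and
#'   `qs` the file defines; `write_params()` returns `path`, invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  raw <- lapply(raw, as.numeric)
  out <- list()
  gnames <- c("X0", "C", "B", "M")
  if (all(gnames %in% names(raw)))
    out$growth <- do.call(growth_params, raw[gnames])
  if (all(qs_param_names() %in% names(raw)))
    out$qs <- do.call(qs_params, raw[qs_param_names()])
  if (!length(out))
    stop("no complete parameter block (growth or kinetic) in ", path,
         call. = FALSE)
  out
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  flat <- c(
    if (!is.null(params$growth)) as.list(unclass(params$growth)),
    if (!is.null(params$qs)) as.list(unclass(params$qs))
  )
  if (!length(flat)) stop("nothing to write", call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(flat, path, precision = 17L)
  } else {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
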