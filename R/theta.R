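#' Model parameter vector for the dual-pathway AV-node network
#'
#' The AV-node network model is parameterized by 12 values: for each of the
#' two pathways (fast, FP; slow, SP) a minimum refractory period `R_min`, a
#' maximum refractory prolongation `delta_R` with time constant `tau_R`, and
#' a minimum conduction delay `D_min` with maximum prolongation `delta_D` and
#' time constant `tau_D`.  All values are in milliseconds.  The fixed vector
#' order used everywhere in the package is
#' `R_min_FP, delta_R_FP, tau_R_FP, R_min_SP, delta_R_SP, tau_R_SP,
#'  D_min_FP, delta_D_FP, tau_D_FP, D_min_SP, delta_D_SP, tau_D_SP`.
#'
#' @param x numeric vector of length 12 in the fixed order (names optional).
#' @return an object of class `avn_theta`: a named numeric vector of length
#'   12.
#' @examples
#' theta <- avn_theta(c(435, 403, 175, 241, 231, 180,
#'                      5.3, 18.9, 141, 21, 26.3, 185))
#' avn_pathway(theta, "SP")
#' @export
avn_theta <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 12L)
    stop("theta must have exactly 12 elements", call. = FALSE)
  if (any(!is.finite(x)))
    stop("theta must be finite", call. = FALSE)
  if (any(x < 0))
    stop("theta elements must be non-negative", call. = FALSE)
  tau <- x[c(3L, 6L, 9L, 12L)]
  if (any(tau <= 0))
    stop("time constants tau_R and tau_D must be positive", call. = FALSE)
  names(x) <- avn_param_names()
  structure(x, class = "avn_theta")
}

#' Names of the 12 model parameters in fixed order
#' @return character vector of length 12.
#' @export
avn_param_names <- function() {
  c("R_min_FP", "delta_R_FP", "tau_R_FP",
    "R_min_SP", "delta_R_SP", "tau_R_SP",
    "D_min_FP", "delta_D_FP", "tau_D_FP",
    "D_min_SP", "delta_D_SP", "tau_D_SP")
}

#' Extract the six parameters of one pathway
#'
#' @param theta an [avn_theta()] vector.
#' @param pathway `"FP"` or `"SP"`.
#' @return named numeric vector `R_min, delta_R, tau_R, D_min, delta_D,
#'   tau_D` for the requested pathway.
#' @export
avn_pathway <- function(theta, pathway = c("FP", "SP")) {
  pathway <- match.arg(pathway)
  x <- unclass(theta)
  idx <- if (pathway == "FP") c(1L, 2L, 3L, 7L, 8L, 9L)
         else c(4L, 5L, 6L, 10L, 11L, 12L)
  stats::setNames(as.numeric(x[idx]),
                  c("R_min", "delta_R", "tau_R", "D_min", "delta_D", "tau_D"))
}

#' Rebuild a theta vector from two pathway parameter sets
#'
#' Inverse of [avn_pathway()]: the round trip
#' `avn_theta_from_pathways(avn_pathway(theta, "FP"), avn_pathway(theta, "SP"))`
#' is lossless.
#'
#' @param fp,sp named numeric vectors as returned by [avn_pathway()].
#' @return an [avn_theta()] vector.
#' @export
avn_theta_from_pathways <- function(fp, sp) {
  avn_theta(c(fp[c("R_min", "delta_R", "tau_R")],
              sp[c("R_min", "delta_R", "tau_R")],
              fp[c("D_min", "delta_D", "tau_D")],
              sp[c("D_min", "delta_D", "tau_D")]))
}

#' @export
print.avn_theta <- function(x, ...) {
  cat("AV-node model parameters (ms):\n")
  m <- rbind(FP = avn_pathway(x, "FP"), SP = avn_pathway(x, "SP"))
  print(round(m, 2))
  invisible(x)
}

#' Parameter search ranges
#'
#' Box constraints for the 12 model parameters used both to initialize and to
#' bound the genetic-algorithm search: `R_min` in \[150, 650\] ms, `delta_R`
#' in \[0, 700\] ms, `tau_R` in \[40, 300\] ms, `D_min` in \[0, 30\] ms,
#' `delta_D` in \[0, 75\] ms, `tau_D` in \[40, 300\] ms, identical for both
#' pathways.  The implied maximal single-node refractory period is
#' `650 + 700 = 1350` ms and the maximal whole-pathway conduction delay is
#' `10 * (30 + 75) = 1050` ms.
#'
#' @return a list with named numeric 12-vectors `lower`, `upper` and
#'   `range` (`upper - lower`, the quantity `r(p)` used by the uncertainty
#'   and goodness-of-fit weighting).
#' @export
avn_bounds <- function() {
  lower <- c(150, 0, 40, 150, 0, 40, 0, 0, 40, 0, 0, 40)
  upper <- c(650, 700, 300, 650, 700, 300, 30, 75, 300, 30, 75, 300)
  names(lower) <- names(upper) <- avn_param_names()
  list(lower = lower, upper = upper, range = upper - lower)
}

#' Representative physiologic parameter values
#'
#' A typical parameter set for a patient in permanent atrial fibrillation,
#' taken from recording-average estimates in untreated (baseline) 24-hour
#' recordings.  Useful as a starting point for simulations and as the
#' default ground truth of the synthetic-cohort generator.
#'
#' @return an [avn_theta()] vector.
#' @export
avn_theta_baseline <- function() {
  avn_theta(c(435, 403, 175, 241, 231, 180,
              5.3, 18.9, 141, 21.0, 26.3, 185))
}

#' Read or write a parameter vector as a flat YAML mapping
#'
#' Serializes the 12 parameters as a flat key-value mapping using the fixed
#' parameter names, so parameter files are human-editable and orderless.
#'
#' @param theta an [avn_theta()] vector.
#' @param path file path.
#' @return `read_theta` returns an [avn_theta()]; `write_theta` returns
#'   `path` invisibly.
#' @export
write_theta <- function(theta, path) {
  stopifnot(inherits(theta, "avn_theta"))
  yaml::write_yaml(as.list(unclass(theta)), path)
  invisible(path)
}

#' @rdname write_theta
#' @export
read_theta <- function(path) {
  x <- yaml::read_yaml(path)
  missing <- setdiff(avn_param_names(), names(x))
  if (length(missing))
    stop("parameter file is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  avn_theta(unlist(x[avn_param_names()]))
}
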