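# Typed containers for the diffraction pipeline.

#' Measurement context of a lamellar diffraction scan
#'
#' Bundles the instrument and environment parameters under which a set of
#' Bragg peaks was recorded.
#'
#' @param wavelength neutron wavelength in Angstrom
#' @param mu linear absorption coefficient in 1/cm
#' @param t deposited (dry) sample thickness in micrometres
#' @param temperature sample temperature in K
#' @param relative_humidity relative humidity as a fraction in (0, 1]
#' @param d2o_fraction D2O fraction of the vapour in \[0, 1\]
#' @return an object of class `diffraction_condition`
#' @examples
#' diffraction_condition(relative_humidity = 0.96, d2o_fraction = 0.08)
#' @export
diffraction_condition <- function(wavelength = 4.47, mu = 5, t = 50,
                                  temperature = 323.15,
                                  relative_humidity = 1,
                                  d2o_fraction = 0.08) {
  check_number(wavelength, "wavelength", 0, strict_lower = TRUE)
  check_number(mu, "mu", 0)
  check_number(t, "t", 0, strict_lower = TRUE)
  check_number(temperature, "temperature", 0, strict_lower = TRUE)
  check_number(relative_humidity, "relative_humidity", 0, 1, strict_lower = TRUE)
  check_number(d2o_fraction, "d2o_fraction", 0, 1)
  structure(
    list(wavelength = wavelength, mu = mu, t = t, temperature = temperature,
         relative_humidity = relative_humidity, d2o_fraction = d2o_fraction),
    class = "diffraction_condition"
  )
}

#' @export
print.diffraction_condition <- function(x, ...) {
  cat(sprintf(
    "diffraction condition: lambda = %.3f A, mu = %g /cm, t = %g um,\n  T = %.2f K, RH = %.1f%%, D2O = %.0f%%\n",
    x$wavelength, x$mu, x$t, x$temperature,
    100 * x$relative_humidity, 100 * x$d2o_fraction))
  invisible(x)
}

#' One indexed set of Bragg peaks belonging to a single lamellar phase
#'
#' Validates the peak records and derives the lamellar period d (with its
#' standard deviation across diffraction orders) from Bragg's law.  A
#' disagreement larger than 1% between the per-order d values triggers a
#' warning, since it usually indicates mis-indexing or phase mixing.
#'
#' @param peaks data frame with columns `order`, `two_theta` (degrees),
#'   `intensity`, and optionally `intensity_err`
#' @param condition a [diffraction_condition()]
#' @param phase_label one of "gel", "fluid", "unassigned"
#' @return an object of class `lamellar_dataset` with elements `peaks`,
#'   `condition`, `phase_label`, `d`, `d_err`
#' @export
lamellar_dataset <- function(peaks, condition,
                             phase_label = c("unassigned", "gel", "fluid")) {
  phase_label <- match.arg(phase_label)
  stopifnot(inherits(condition, "diffraction_condition"))
  req <- c("order", "two_theta", "intensity")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) {
    lam_abort("peak table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (!"intensity_err" %in% names(peaks)) peaks$intensity_err <- NA_real_
  if (anyDuplicated(peaks$order)) {
    lam_abort("duplicate diffraction order(s) within phase '%s'", phase_label)
  }
  if (any(peaks$order < 1 | peaks$order != round(peaks$order))) {
    lam_abort("diffraction orders must be positive integers")
  }
  if (any(peaks$two_theta <= 0 | peaks$two_theta >= 180)) {
    lam_abort("two_theta must lie in (0, 180) degrees")
  }
  if (any(peaks$intensity < 0)) {
    lam_abort("negative intensity in validated peak set")
  }
  peaks <- peaks[order(peaks$order), , drop = FALSE]
  rownames(peaks) <- NULL

  dvals <- bragg_d_spacing(peaks$two_theta, peaks$order, condition$wavelength)
  d <- mean(dvals)
  d_err <- if (length(dvals) > 1L) sd(dvals) else 0
  if (length(dvals) > 1L && diff(range(dvals)) / d > 0.01) {
    lam_log("warning", "datamodel",
            "per-order d-spacings disagree by more than 1%% (phase '%s'): %s",
            phase_label, paste(signif(dvals, 5), collapse = ", "))
  }
  structure(
    list(peaks = peaks, condition = condition, phase_label = phase_label,
         d = d, d_err = d_err),
    class = "lamellar_dataset"
  )
}

#' @export
print.lamellar_dataset <- function(x, ...) {
  cat(sprintf("lamellar dataset (%s phase): %d peaks, d = %.2f +/- %.2f A\n",
              x$phase_label, nrow(x$peaks), x$d, x$d_err))
  invisible(x)
}
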