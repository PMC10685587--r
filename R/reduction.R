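# Reduction of indexed Bragg-peak intensities to corrected structure-factor
# magnitudes, lamellar d-spacings, and osmotic pressures.

#' Lamellar d-spacing from Bragg's law
#'
#' d = n * lambda / (2 sin(theta)) with theta half the scattering angle.
#'
#' @param two_theta scattering angle(s) in degrees, in (0, 180)
#' @param order diffraction order(s), positive integer(s)
#' @param wavelength neutron wavelength in Angstrom
#' @return d-spacing(s) in Angstrom
#' @examples
#' bragg_d_spacing(4.2692, 1, 4.47) # ~ 60 A
#' @export
bragg_d_spacing <- function(two_theta, order, wavelength) {
  if (any(!is.finite(two_theta)) || any(two_theta <= 0) || any(two_theta >= 180)) {
    lam_abort("two_theta must lie strictly inside (0, 180) degrees")
  }
  if (any(order < 1) || any(order != round(order))) {
    lam_abort("order must be a positive integer")
  }
  check_number(wavelength, "wavelength", 0, strict_lower = TRUE)
  order * wavelength / (2 * sin(deg2rad(two_theta) / 2))
}

#' Neutron absorption correction
#'
#' C_abs = alpha / (1 - exp(-alpha)) with alpha = 2 mu t / sin(theta),
#' theta half the scattering angle.  Units are harmonised internally
#' (mu in 1/cm, t in micrometres).  C_abs >= 1, approaching 1 as mu -> 0.
#'
#' @param two_theta scattering angle in degrees
#' @param mu linear absorption coefficient in 1/cm
#' @param t sample thickness in micrometres
#' @return dimensionless correction factor(s)
#' @examples
#' absorption_correction(4.2692, 5, 50) # ~ 1.817
#' @export
absorption_correction <- function(two_theta, mu, t) {
  if (any(two_theta <= 0) || any(two_theta >= 180)) {
    lam_abort("two_theta must lie strictly inside (0, 180) degrees")
  }
  if (any(mu < 0)) lam_abort("mu must be non-negative")
  if (any(t <= 0)) lam_abort("t must be positive")
  theta <- deg2rad(two_theta) / 2
  alpha <- 2 * (mu / 1e4 * t) / sin(theta)  # mu[1/cm] * t[um] -> dimensionless
  if (any(!is.finite(alpha)) || any(alpha > 700)) {
    lam_abort("absorption argument alpha overflows (theta too close to 0 for mu > 0)")
  }
  ifelse(alpha == 0, 1, alpha / (1 - exp(-alpha)))
}

#' Lorentz correction for a lamellar reflection
#'
#' C_Lor = sin(2 theta), where 2 theta is the scattering angle.
#'
#' @param two_theta scattering angle in degrees
#' @return dimensionless correction factor(s)
#' @export
lorentz_correction <- function(two_theta) {
  if (any(two_theta <= 0) || any(two_theta >= 180)) {
    lam_abort("two_theta must lie strictly inside (0, 180) degrees")
  }
  sin(deg2rad(two_theta))
}

new_structure_factor_set <- function(orders, f, f_err, signs, d, d_err,
                                     condition, phase_label,
                                     d_spacing_only = FALSE) {
  structure(
    list(orders = as.integer(orders), f = as.numeric(f),
         f_err = as.numeric(f_err), signs = as.integer(signs),
         d = d, d_err = d_err, condition = condition,
         phase_label = phase_label, d_spacing_only = d_spacing_only),
    class = "structure_factor_set"
  )
}

#' Corrected structure-factor magnitudes from a peak set
#'
#' Applies the absorption and Lorentz corrections to the integrated
#' intensities, |F_n| = sqrt(C_abs C_Lor I_n), with first-order error
#' propagation.  Counting errors default to sqrt(I) when no intensity error
#' is recorded.  Signs are left unassigned (see [assign_phases()]).
#'
#' Sets with fewer than three orders carry too little information for NSLD
#' synthesis; they are flagged `d_spacing_only` with a logged warning.
#'
#' @param dataset a [lamellar_dataset()]
#' @return an object of class `structure_factor_set`
#' @export
structure_factors <- function(dataset) {
  stopifnot(inherits(dataset, "lamellar_dataset"))
  pk <- dataset$peaks
  cond <- dataset$condition
  corr <- absorption_correction(pk$two_theta, cond$mu, cond$t) *
    lorentz_correction(pk$two_theta)
  f <- sqrt(corr * pk$intensity)
  ierr <- pk$intensity_err
  ierr[!is.finite(ierr)] <- sqrt(pk$intensity[!is.finite(ierr)])
  # delta |F| = C * delta I / (2 |F|); one-sided rule at |F| = 0
  f_err <- ifelse(f > 0, corr * ierr / (2 * f), sqrt(corr * ierr))
  d_only <- nrow(pk) < 3L
  if (d_only) {
    lam_log("warning", "reduction",
            "only %d order(s) in phase '%s': flagged d-spacing only",
            nrow(pk), dataset$phase_label)
  }
  new_structure_factor_set(pk$order, f, f_err, rep(NA_integer_, nrow(pk)),
                           dataset$d, dataset$d_err, cond,
                           dataset$phase_label, d_spacing_only = d_only)
}

#' @export
print.structure_factor_set <- function(x, ...) {
  sg <- ifelse(is.na(x$signs), "?", ifelse(x$signs > 0, "+", "-"))
  cat(sprintf("structure factors (%s phase), d = %.2f A:\n", x$phase_label, x$d))
  cat(sprintf("  n=%d  |F| = %.4g (%s)\n", x$orders, x$f, sg), sep = "")
  invisible(x)
}

#' Osmotic pressure applied by a humid atmosphere
#'
#' The osmotic-stress (Kelvin) relation Pi = -(k_B T / v_w) ln(RH): an
#' undersaturated vapour lowers the water chemical potential by
#' k_B T ln(RH), equivalent to a dehydrating pressure across the water
#' layer.  Saturation (RH = 1) gives Pi = 0.
#'
#' @param rh relative humidity as a fraction in (0, 1]
#' @param temperature temperature in K
#' @param v_w molecular volume of water in Angstrom^3 (default 30)
#' @return osmotic pressure in Pa
#' @examples
#' osmotic_pressure_from_rh(0.99, 323.15) # ~ 1.49 MPa
#' @export
osmotic_pressure_from_rh <- function(rh, temperature, v_w = 30) {
  if (any(rh <= 0) || any(rh > 1)) lam_abort("rh must lie in (0, 1]")
  check_number(v_w, "v_w", 0, strict_lower = TRUE)
  -(kBT_joule(temperature) / (v_w * 1e-30)) * log(rh)
}
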