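# Analytics for z-resolved density profiles exported from MD
# post-processing: water polarization, leaflet dipole moments, Gibbs-Duhem
# osmotic pressure, truncated-Fourier NSLD, headgroup orientation medians.

#' Container for z-resolved component density profiles
#'
#' @param z grid in Angstrom spanning one lamellar repeat, strictly
#'   increasing
#' @param mass named list/data frame of per-component mass densities (kg/m^3)
#' @param charge named list/data frame of per-component charge densities
#'   (e/A^3)
#' @param centering either "bilayer" (bilayer mid-plane at z = 0) or
#'   "water" (middle of the water layer at z = 0); conversions must be
#'   explicit via [recenter_profiles()], never silent
#' @param area_per_lipid lateral area per lipid in A^2
#' @param temperature temperature in K
#' @param d lamellar repeat in Angstrom (defaults to the grid span)
#' @return object of class `density_profile_set`
#' @export
density_profile_set <- function(z, mass = list(), charge = list(),
                                centering = c("bilayer", "water"),
                                area_per_lipid = 60, temperature = 330,
                                d = NULL) {
  centering <- match.arg(centering)
  if (any(diff(z) <= 0)) lam_abort("z grid must be strictly increasing")
  for (nm in names(mass)) {
    if (length(mass[[nm]]) != length(z)) {
      lam_abort("mass component '%s' does not share the z grid", nm)
    }
  }
  for (nm in names(charge)) {
    if (length(charge[[nm]]) != length(z)) {
      lam_abort("charge component '%s' does not share the z grid", nm)
    }
  }
  d <- d %||% diff(range(z))
  obj <- structure(
    list(z = z, mass = as.data.frame(mass), charge = as.data.frame(charge),
         centering = centering, area_per_lipid = area_per_lipid,
         temperature = temperature, d = d),
    class = "density_profile_set")
  net <- .net_charge_per_lipid(obj)
  if (is.finite(net) && abs(net) > 1e-6) {
    lam_log("warning", "md_profiles",
            "profile set is not charge neutral: net %.3g e per lipid", net)
  }
  obj
}

.net_charge_per_lipid <- function(profiles) {
  if (ncol(profiles$charge) == 0L) return(NA_real_)
  tot <- rowSums(profiles$charge)
  pracma::trapz(profiles$z, tot) * profiles$area_per_lipid
}

#' Shift a profile set between bilayer- and water-centred conventions
#'
#' Rolls the periodic z grid by half a repeat.  The grid must be (close to)
#' uniform for the circular shift to be exact.
#'
#' @param profiles a [density_profile_set()]
#' @param to target centering, "bilayer" or "water"
#' @return the recentred `density_profile_set`
#' @export
recenter_profiles <- function(profiles, to = c("bilayer", "water")) {
  to <- match.arg(to)
  if (identical(profiles$centering, to)) return(profiles)
  n <- length(profiles$z)
  half <- n %/% 2
  roll <- function(v) v[c((half + 1):n, 1:half)]
  mass <- as.data.frame(lapply(profiles$mass, roll))
  charge <- as.data.frame(lapply(profiles$charge, roll))
  density_profile_set(profiles$z[seq_len(n)], mass, charge, centering = to,
                      area_per_lipid = profiles$area_per_lipid,
                      temperature = profiles$temperature, d = profiles$d)
}

#' Water polarization profile from the water charge density
#'
#' m_w(z) = integral from -d/2 to z of the water charge density, by
#' cumulative trapezoid.  Requires the water-centred convention, in which
#' the integration starts inside a bilayer where the water density vanishes.
#' For a neutral water population m_w returns to zero at +d/2.
#'
#' @param profiles a water-centred [density_profile_set()] with a `water`
#'   charge component
#' @return data frame with columns `z` and `m_w` (e/A^2)
#' @export
water_polarization <- function(profiles) {
  stopifnot(inherits(profiles, "density_profile_set"))
  if (!identical(profiles$centering, "water")) {
    lam_abort_state("water_polarization requires the water-centred convention; use recenter_profiles()")
  }
  if (!"water" %in% names(profiles$charge)) {
    lam_abort("no 'water' charge density component present")
  }
  rho <- profiles$charge$water
  net <- pracma::trapz(profiles$z, rho) * profiles$area_per_lipid
  if (abs(net) > 1e-6) {
    lam_log("warning", "md_profiles",
            "water charge not neutral (net %.3g e per lipid); polarization endpoint will not close", net)
  }
  data.frame(z = profiles$z,
             m_w = c(0, pracma::cumtrapz(profiles$z, rho)[-1]))
}

#' Dipole moment of one leaflet's polar heads, normal to the membrane
#'
#' M_z = A_l * integral over the repeat of m_l(z), where m_l is the
#' cumulative integral of the selected leaflet's lipid charge density (only
#' lipid charges enter the double integration).  Reported per lipid in
#' e * Angstrom.  Requires the bilayer-centred convention, in which the
#' upper/lower leaflets are the z > 0 / z < 0 halves.
#'
#' @param profiles a bilayer-centred [density_profile_set()] with a `lipid`
#'   charge component
#' @param leaflet "upper" (z > 0) or "lower" (z < 0)
#' @return object of class `leaflet_dipole` with elements `M_z` and
#'   `leaflet`
#' @export
leaflet_dipole_moment <- function(profiles, leaflet = c("upper", "lower")) {
  stopifnot(inherits(profiles, "density_profile_set"))
  leaflet <- match.arg(leaflet)
  if (!identical(profiles$centering, "bilayer")) {
    lam_abort_state("leaflet_dipole_moment requires the bilayer-centred convention; use recenter_profiles()")
  }
  if (!"lipid" %in% names(profiles$charge)) {
    lam_abort("no 'lipid' charge density component present")
  }
  mask <- if (leaflet == "upper") profiles$z >= 0 else profiles$z < 0
  if (!any(mask)) lam_abort("leaflet selection '%s' is empty", leaflet)
  rho <- ifelse(mask, profiles$charge$lipid, 0)
  m_l <- c(0, pracma::cumtrapz(profiles$z, rho)[-1])
  M_z <- profiles$area_per_lipid * pracma::trapz(profiles$z, m_l)
  structure(list(M_z = M_z, leaflet = leaflet), class = "leaflet_dipole")
}

#' @export
print.leaflet_dipole <- function(x, ...) {
  cat(sprintf("leaflet dipole (%s): M_z = %.4g e*A per lipid\n", x$leaflet, x$M_z))
  invisible(x)
}

#' Osmotic pressure from the water chemical potential (Gibbs-Duhem)
#'
#' Pi = -(mu - mu0) / v_w0: a chemical-potential deficit of the confined
#' water relative to bulk is equivalent to a dehydrating pressure.  mu and
#' mu0 are taken in k_B T at `temperature`; v_w0 is the bulk partial
#' molecular volume of water.
#'
#' @param mu water chemical potential between the bilayers, in k_B T
#' @param mu0 bulk reference chemical potential, in k_B T
#' @param v_w0 partial molecular volume of water in Angstrom^3
#' @param temperature temperature in K
#' @return osmotic pressure in Pa
#' @examples
#' gibbs_duhem_pressure(-0.01, 0, 30, 330) # ~ 1.52 MPa
#' @export
gibbs_duhem_pressure <- function(mu, mu0 = 0, v_w0 = 30, temperature = 330) {
  check_number(v_w0, "v_w0", 0, strict_lower = TRUE)
  -(mu - mu0) * kBT_joule(temperature) / (v_w0 * 1e-30)
}

#' Truncated-Fourier NSLD from component densities
#'
#' Converts component mass densities to an NSLD profile using supplied
#' scattering lengths, computes the forward cosine coefficients, truncates
#' the series to `n_terms` (the typical number of Bragg peaks available
#' experimentally), resynthesizes the band-limited profile, and evaluates
#' the bilayer thickness on it.  An optional constant shift `delta_d` can be
#' applied to d and d_b when comparing to experiment.
#'
#' @param profiles a bilayer-centred [density_profile_set()]
#' @param scattering_lengths named list, one entry per mass component, each
#'   `list(b_fm = <molecular scattering length sum, fm>, molar_mass =
#'   <g/mol>)`
#' @param n_terms number of Fourier terms retained (default 3)
#' @param delta_d constant shift in Angstrom added to `d` and `d_b` in the
#'   returned geometry (0 disables the comparison shift)
#' @return list with `profile` (truncated `nsld_profile`), `geometry`
#'   (a `bilayer_geometry`, shifted if requested), `coefficients` (signed
#'   F_n) and `sld` (the untruncated SLD curve)
#' @export
truncated_nsld_from_profiles <- function(profiles, scattering_lengths,
                                         n_terms = 3L, delta_d = 0) {
  stopifnot(inherits(profiles, "density_profile_set"))
  if (!identical(profiles$centering, "bilayer")) {
    lam_abort_state("truncated_nsld_from_profiles requires the bilayer-centred convention")
  }
  comps <- names(profiles$mass)
  if (length(comps) == 0L) lam_abort("no mass density components present")
  miss <- setdiff(comps, names(scattering_lengths))
  if (length(miss)) {
    lam_abort("missing scattering length for component(s): %s",
              paste(miss, collapse = ", "))
  }
  z <- profiles$z
  d <- profiles$d
  sld <- rep(0, length(z))
  for (nm in comps) {
    sl <- scattering_lengths[[nm]]
    # kg/m^3 -> number density in A^-3, times b in fm -> SLD in 1e-6 A^-2
    n_dens <- profiles$mass[[nm]] * 6.02214076e-4 / sl$molar_mass
    sld <- sld + n_dens * sl$b_fm * 10     # fm * A^-3 = 1e-5 A^-2 = 10 * 1e-6
  }
  sld <- sld - mean(sld)
  orders <- seq_len(n_terms)
  Fn <- vapply(orders, function(n) {
    pracma::trapz(z, sld * cos(2 * pi * n * z / d))
  }, numeric(1))
  fset <- new_structure_factor_set(
    orders, abs(Fn), rep(0, n_terms), sign(Fn), d, 0,
    diffraction_condition(temperature = profiles$temperature,
                          relative_humidity = 1),
    "unassigned")
  prof <- synthesize_profile(fset, n_points = max(513L, 8L * n_terms))
  geom <- fit_bilayer_thickness(prof)
  if (delta_d != 0) {
    geom$d <- geom$d + delta_d
    geom$d_b <- geom$d_b + delta_d
  }
  list(profile = prof, geometry = geom, coefficients = Fn, sld = sld)
}

#' Median headgroup orientation relative to the membrane normal
#'
#' Median over molecules of the angle between each headgroup vector and the
#' z axis; 90 degrees corresponds to an orientation parallel to the
#' membrane plane.  Vectors are auto-normalised with a warning when they
#' are not unit length.
#'
#' @param vectors numeric matrix with 3 columns (one headgroup vector per
#'   row)
#' @return median angle in degrees
#' @export
headgroup_orientation_median <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0L || ncol(vectors) != 3L) {
    lam_abort("vectors must be a non-empty n x 3 matrix")
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) lam_abort("zero-length headgroup vector at row %d",
                               which(nrm == 0)[1])
  if (any(abs(nrm - 1) > 1e-6)) {
    lam_log("warning", "md_profiles", "normalising non-unit headgroup vectors")
  }
  ang <- rad2deg(acos(pmin(1, pmax(-1, vectors[, 3] / nrm))))
  median(ang)
}
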