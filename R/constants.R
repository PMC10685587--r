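# Physical constants and neutron scattering lengths.

#' Boltzmann constant in J/K (exact SI value)
#' @export
kB_SI <- 1.380649e-23

#' Thermal energy in Joules
#'
#' @param temperature temperature in K
#' @return k_B * T in J
#' @export
kBT_joule <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  kB_SI * temperature
}

#' Coherent neutron scattering lengths
#'
#' Bound coherent scattering lengths of the elements relevant for lipid/water
#' systems, in fm, as tabulated in the standard neutron data tables.
#'
#' @return named numeric vector (fm)
#' @export
neutron_scattering_lengths <- function() {
  c(H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803, P = 5.13)
}

# SLD of pure H2O and D2O in 1e-6 A^-2, from the scattering lengths above and
# a 30 A^3 molecular volume.
.sld_h2o <- -0.558
.sld_d2o <- 6.382

#' Scattering-length density of an H2O/D2O mixture
#'
#' Linear mixing of the H2O and D2O endpoint SLDs; around 8% D2O the water
#' SLD passes through zero, the contrast-matched condition used for phasing.
#'
#' @param d2o_fraction D2O mole fraction in \[0, 1\]
#' @return SLD in 1e-6 A^-2
#' @export
water_sld <- function(d2o_fraction) {
  if (any(d2o_fraction < 0 | d2o_fraction > 1)) {
    lam_abort("d2o_fraction must lie in [0, 1]")
  }
  (1 - d2o_fraction) * .sld_h2o + d2o_fraction * .sld_d2o
}
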