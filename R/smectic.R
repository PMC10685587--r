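# Smectic mechanics: Caille and de Gennes parameters, their closed-form
# inversion, and exact Gaussian sampling of the discrete smectic Hamiltonian
#
#   H = sum_n int d2r [ B/(2d) (u_{n+1} - u_n)^2 + (kappa/2) (lap u_n)^2 ]
#
# for a stack of N membranes with periodic boundaries across the stack.

.kappa_to_joule <- function(kappa, temperature, kappa_in) {
  switch(kappa_in,
         kBT = kappa * kBT_joule(temperature),
         J = kappa,
         lam_abort("kappa_in must be 'kBT' or 'J'"))
}

#' Caille parameter of a smectic stack
#'
#' eta = pi k_B T / (2 d^2 sqrt(kappa B / d)): the dimensionless strength of
#' thermal undulations, which controls how much specular intensity is
#' redistributed into diffuse scattering.
#'
#' @param kappa bending modulus, in units of k_B T at `temperature` (default)
#'   or in Joule with `kappa_in = "J"`
#' @param b_mod inter-membrane compression modulus in Pa
#' @param d lamellar period in Angstrom
#' @param temperature temperature in K
#' @param kappa_in unit of `kappa`: "kBT" or "J"
#' @return dimensionless Caille parameter
#' @examples
#' caille_parameter(14, 29e6, 50, 323.15) # ~ 0.0147
#' @export
caille_parameter <- function(kappa, b_mod, d, temperature, kappa_in = "kBT") {
  stopifnot(all(kappa > 0), all(b_mod > 0), all(d > 0), all(temperature > 0))
  kJ <- .kappa_to_joule(kappa, temperature, kappa_in)
  bA <- b_mod * 1e-30                     # Pa = J/m^3 -> J/A^3
  pi * kBT_joule(temperature) / (2 * d^2 * sqrt(kJ * bA / d))
}

#' de Gennes parameter of a smectic stack
#'
#' Lambda = sqrt(kappa / (B d)), the smectic penetration length in Angstrom.
#' With `kappa` in Joule the relation is temperature-free; with the default
#' k_B T unit a temperature is needed for the unit conversion only.
#'
#' @inheritParams caille_parameter
#' @return de Gennes parameter in Angstrom
#' @examples
#' degennes_parameter(14, 29e6, 50, 323.15) # ~ 6.56 A
#' @export
degennes_parameter <- function(kappa, b_mod, d, temperature = NULL,
                               kappa_in = "kBT") {
  stopifnot(all(kappa > 0), all(b_mod > 0), all(d > 0))
  if (identical(kappa_in, "kBT") && is.null(temperature)) {
    lam_abort("temperature is required to convert kappa from k_B T to Joule")
  }
  kJ <- .kappa_to_joule(kappa, temperature %||% NA_real_, kappa_in)
  sqrt(kJ / (b_mod * 1e-30 * d))
}

#' Invert the Caille/de Gennes relations for kappa and B
#'
#' Closed form: B = pi k_B T / (2 d^2 Lambda eta) and
#' kappa = Lambda^2 B d, so that computing (eta, Lambda) forward and
#' inverting is the identity on (kappa, B).
#'
#' @param eta Caille parameter (dimensionless)
#' @param lambda_dg de Gennes parameter in Angstrom
#' @param d lamellar period in Angstrom
#' @param temperature temperature in K
#' @return list with `kappa` (k_B T units at `temperature`), `kappa_J` (J)
#'   and `b_mod` (Pa)
#' @export
invert_mechanics <- function(eta, lambda_dg, d, temperature) {
  stopifnot(eta > 0, lambda_dg > 0, d > 0, temperature > 0)
  kT <- kBT_joule(temperature)
  bA <- pi * kT / (2 * d^2 * lambda_dg * eta)   # J/A^3
  kJ <- lambda_dg^2 * bA * d                    # J
  list(kappa = kJ / kT, kappa_J = kJ, b_mod = bA * 1e30)
}

#' Mechanical description of a smectic stack
#'
#' @param kappa bending modulus, by default in k_B T at `temperature`
#' @param b_mod compression modulus in Pa
#' @param d lamellar period in Angstrom
#' @param temperature temperature in K
#' @param r_cutoff empirical lateral cut-off R in Angstrom (`Inf` disables
#'   the damping of inter-layer cross-correlations)
#' @param kappa_in unit of `kappa`: "kBT" (default) or "J"; the stored
#'   `kappa` field is always in k_B T at `temperature`
#' @return object of class `smectic_mechanics` carrying (kappa, B, d, T)
#'   together with the derived eta and Lambda
#' @export
smectic_mechanics <- function(kappa, b_mod, d, temperature, r_cutoff = Inf,
                              kappa_in = "kBT") {
  if (identical(kappa_in, "J")) kappa <- kappa / kBT_joule(temperature)
  check_number(kappa, "kappa", 0, strict_lower = TRUE)
  check_number(b_mod, "b_mod", 0, strict_lower = TRUE)
  check_number(d, "d", 0, strict_lower = TRUE)
  check_number(temperature, "temperature", 0, strict_lower = TRUE)
  structure(
    list(kappa = kappa, b_mod = b_mod, d = d, temperature = temperature,
         eta = caille_parameter(kappa, b_mod, d, temperature),
         lambda_dg = degennes_parameter(kappa, b_mod, d, temperature),
         r_cutoff = r_cutoff),
    class = "smectic_mechanics")
}

#' @export
print.smectic_mechanics <- function(x, ...) {
  cat(sprintf(
    "smectic mechanics: kappa = %.3g kBT, B = %.3g MPa, d = %.4g A, T = %.2f K\n  eta = %.4g, Lambda = %.4g A, R = %s A\n",
    x$kappa, x$b_mod / 1e6, x$d, x$temperature, x$eta, x$lambda_dg,
    format(x$r_cutoff)))
  invisible(x)
}

# Mode stiffnesses K(q, m) of the discretised Hamiltonian (J/A^2 per site
# weight a^2), as a [grid, grid, layers] array matching fft() layout.
.stack_stiffness <- function(n_layers, lateral_size, grid_points, mech) {
  a <- lateral_size / grid_points
  kJ <- mech$kappa * kBT_joule(mech$temperature)
  bA <- mech$b_mod * 1e-30
  j <- c(0:(grid_points / 2),
         if (grid_points >= 4) -((grid_points / 2 - 1):1))
  q <- 2 * pi * j / lateral_size
  q2 <- outer(q^2, q^2, `+`)
  lam_m <- 2 * (1 - cos(2 * pi * (0:(n_layers - 1)) / n_layers))
  K <- outer(kJ * q2^2, rep(1, n_layers)) +
    outer(matrix(bA / mech$d, grid_points, grid_points), lam_m)
  a^2 * K
}

#' Sample the Gaussian equilibrium ensemble of a discrete smectic stack
#'
#' Draws membrane displacement fields u_n(x, y) from the Boltzmann
#' distribution of the discrete smectic Hamiltonian by exact spectral
#' decomposition: in-plane Fourier modes times periodic layer eigenmodes,
#' each mode amplitude Gaussian with variance k_B T over its stiffness
#' eigenvalue.  All laterally uniform (q_par = 0) modes are pinned to zero,
#' so every layer has exactly zero spatial mean.
#'
#' @param n_layers number of membranes in the stack (>= 2)
#' @param lateral_size lateral box edge L in Angstrom
#' @param grid_points lateral grid points per direction (a power of two)
#' @param mechanics a [smectic_mechanics()]
#' @param seed optional integer seed
#' @return object of class `fluctuation_field`: displacement array `u`
#'   (grid x grid x layers, Angstrom) plus the generating geometry
#' @export
sample_smectic_stack <- function(n_layers, lateral_size, grid_points,
                                 mechanics, seed = NULL) {
  stopifnot(inherits(mechanics, "smectic_mechanics"))
  if (n_layers < 2L) lam_abort("n_layers must be at least 2")
  if (grid_points < 2L || bitwAnd(grid_points, grid_points - 1L) != 0L) {
    lam_abort("grid_points must be a power of two")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- .stack_stiffness(n_layers, lateral_size, grid_points, mechanics)
  kT <- kBT_joule(mechanics$temperature)
  amp <- sqrt(kT / K)
  amp[1, 1, ] <- 0                        # pin all q_par = 0 modes
  w <- array(rnorm(grid_points^2 * n_layers),
             dim = c(grid_points, grid_points, n_layers))
  u <- Re(fft(amp * fft(w), inverse = TRUE)) / (grid_points^2 * n_layers)
  structure(
    list(u = u, n_layers = n_layers, lateral_size = lateral_size,
         grid_points = grid_points, a = lateral_size / grid_points,
         d = mechanics$d, mechanics = mechanics, seed = seed),
    class = "fluctuation_field")
}

# Stiffness eigenvalues and sampled-mode variances, used by the
# equipartition tests: returns expected variance kT/K per retained mode.
.stack_mode_variances <- function(n_layers, lateral_size, grid_points, mechanics) {
  K <- .stack_stiffness(n_layers, lateral_size, grid_points, mechanics)
  v <- kBT_joule(mechanics$temperature) / K
  v[1, 1, ] <- 0
  v
}
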