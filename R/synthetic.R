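# Forward generators: every input the analysis consumes, with known ground
# truth and seeded noise.

#' Parametric centrosymmetric bilayer SLD model
#'
#' Builds a continuous one-repeat SLD profile (in 1e-6 A^-2): a water slab
#' whose SLD interpolates linearly between the H2O and D2O endpoints, a
#' hydrocarbon-chain plateau bounded by smooth (thermally smeared)
#' interfaces, two headgroup Gaussians at +/- z_head, and a negative
#' terminal-methyl Gaussian at the bilayer mid-plane.  The defaults emulate
#' a fluid-phase phosphatidylcholine multilayer with 3-4 visible
#' diffraction orders of decaying magnitude.
#'
#' @param d lamellar period in Angstrom
#' @param z_head headgroup Gaussian centre, so the ground-truth bilayer
#'   thickness is d_b = 2 z_head
#' @param amp_head,width_head headgroup Gaussian amplitude (1e-6 A^-2) and
#'   sigma (A)
#' @param amp_methyl,width_methyl methyl-trough Gaussian amplitude
#'   (negative) and sigma
#' @param sld_chain chain plateau SLD (1e-6 A^-2)
#' @param interface_width sigma-like width of the chain/water interface (A)
#' @param head_water_offset distance from z_head to the chain/water
#'   interface midpoint (A)
#' @param d2o_fraction D2O fraction fixing the water SLD
#' @return object of class `sld_model`
#' @export
make_sld_model <- function(d = 50, z_head = 18.05,
                           amp_head = 2.2, width_head = 3.5,
                           amp_methyl = -1.0, width_methyl = 3.0,
                           sld_chain = -0.4, interface_width = 3.0,
                           head_water_offset = 2.0, d2o_fraction = 0.08) {
  check_number(d, "d", 0, strict_lower = TRUE)
  check_number(z_head, "z_head", 0, d / 2, strict_lower = TRUE,
               strict_upper = TRUE)
  check_number(width_head, "width_head", 0, strict_lower = TRUE)
  check_number(width_methyl, "width_methyl", 0, strict_lower = TRUE)
  z_edge <- z_head + head_water_offset
  if (z_edge + interface_width > d / 2) {
    lam_log("warning", "synthetic",
            "water and headgroup supports overlap strongly (z_edge + 2w = %.1f > d/2 = %.1f)",
            z_edge + 2 * interface_width, d / 2)
  }
  params <- list(d = d, z_head = z_head, amp_head = amp_head,
                 width_head = width_head, amp_methyl = amp_methyl,
                 width_methyl = width_methyl, sld_chain = sld_chain,
                 interface_width = interface_width,
                 head_water_offset = head_water_offset,
                 d2o_fraction = d2o_fraction)
  structure(params, class = "sld_model")
}

#' Evaluate an SLD model on a z grid
#' @param model an [make_sld_model()] object
#' @param z positions in Angstrom
#' @return SLD values in 1e-6 A^-2
#' @export
eval_sld_model <- function(model, z) {
  p <- model
  sld_w <- water_sld(p$d2o_fraction)
  z_edge <- p$z_head + p$head_water_offset
  box <- stats::plogis((z + z_edge) / p$interface_width) -
    stats::plogis((z - z_edge) / p$interface_width)
  sld_w * (1 - box) + p$sld_chain * box +
    p$amp_head * (exp(-(z - p$z_head)^2 / (2 * p$width_head^2)) +
                  exp(-(z + p$z_head)^2 / (2 * p$width_head^2))) +
    p$amp_methyl * exp(-z^2 / (2 * p$width_methyl^2))
}

#' Exact band-limited cosine coefficients of an SLD model
#'
#' F_n = integral over one repeat of rho(z) cos(2 pi n z / d) dz, by dense
#' trapezoidal quadrature (the profile is smooth, so this is exact to many
#' digits for the orders of interest).
#'
#' @param model an `sld_model`
#' @param orders integer vector of diffraction orders
#' @return signed coefficients F_n (1e-6 A^-1 units)
#' @export
sld_model_coefficients <- function(model, orders = 1:4) {
  z <- seq(-model$d / 2, model$d / 2, length.out = 8193L)
  rho <- eval_sld_model(model, z)
  vapply(orders, function(n) {
    pracma::trapz(z, rho * cos(2 * pi * n * z / model$d))
  }, numeric(1))
}

#' Band-limited NSLD profile of an SLD model
#'
#' Synthesizes the model's own truncated Fourier representation, i.e. what
#' an ideal diffraction experiment with `n_orders` visible peaks would
#' reconstruct.  With `n_orders = 0` the continuous (untruncated) profile
#' is returned on the grid (zero-mean).
#'
#' @param model an `sld_model`
#' @param n_orders number of Fourier orders (0 for continuous)
#' @param n_points grid size
#' @return an `nsld_profile`
#' @export
model_nsld_profile <- function(model, n_orders = 0L, n_points = 513L) {
  n_points <- odd_at_least(n_points)
  z <- seq(-model$d / 2, model$d / 2, length.out = n_points)
  if (n_orders >= 1L) {
    Fn <- sld_model_coefficients(model, seq_len(n_orders))
    rho <- .cosine_series(z, Fn, seq_len(n_orders), model$d)
    new_nsld_profile(z, rho, model$d, n_orders, sign(Fn))
  } else {
    rho <- eval_sld_model(model, z)
    new_nsld_profile(z - 0, rho - mean(rho), model$d, 0L, integer(0))
  }
}

#' Generate a synthetic Bragg-peak table from an SLD model
#'
#' Inverts the reduction: peak positions follow Bragg's law at the model's
#' period and the condition's wavelength; intensities are
#' I_n = F_n^2 / (C_abs C_Lor), scaled so the strongest peak has `scale`
#' counts, with optional seeded Gaussian (counting-like) noise.  The water
#' SLD is re-mixed at the condition's D2O fraction, so one structural model
#' serves several contrasts.  A ground-truth record accompanies the table.
#'
#' @param model an `sld_model`
#' @param condition a [diffraction_condition()]
#' @param n_orders number of diffraction orders to emit (>= 3)
#' @param noise_fraction relative Gaussian noise on intensities
#' @param seed optional integer seed
#' @param scale intensity of the strongest peak (counts)
#' @param phase_label phase label written to the table
#' @param path optional output stem; when given, the table is written to
#'   `path` and the truth record to `paste0(path, ".truth.tsv")`
#' @return list with `peaks` (data frame), `truth` (list: `d`, `z_head`,
#'   `d_b`, `orders`, `F`, `signs`) and `condition`
#' @export
gen_peak_table <- function(model, condition, n_orders = 4L,
                           noise_fraction = 0, seed = NULL, scale = 1e4,
                           phase_label = "fluid", path = NULL) {
  stopifnot(inherits(model, "sld_model"),
            inherits(condition, "diffraction_condition"))
  if (n_orders < 3L) lam_abort("n_orders must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  model$d2o_fraction <- condition$d2o_fraction
  orders <- seq_len(n_orders)
  Fn <- sld_model_coefficients(model, orders)
  sin_th <- orders * condition$wavelength / (2 * model$d)
  if (any(sin_th >= 1)) lam_abort("order %d violates Bragg's law at d = %g",
                                  orders[which(sin_th >= 1)[1]], model$d)
  two_theta <- rad2deg(2 * asin(sin_th))
  corr <- absorption_correction(two_theta, condition$mu, condition$t) *
    lorentz_correction(two_theta)
  I <- Fn^2 / corr
  I <- I * scale / max(I)
  if (noise_fraction > 0) {
    I_obs <- I * (1 + noise_fraction * rnorm(length(I)))
    err <- noise_fraction * I
  } else {
    I_obs <- I
    err <- rep(0, length(I))
  }
  keep <- I_obs > 0
  if (any(!keep)) {
    lam_log("warning", "synthetic", "dropped %d peak(s) with non-positive noisy intensity",
            sum(!keep))
  }
  peaks <- data.frame(order = orders, two_theta = two_theta,
                      intensity = I_obs, intensity_err = err,
                      phase_label = phase_label)[keep, ]
  truth <- list(d = model$d, z_head = model$z_head, d_b = 2 * model$z_head,
                orders = orders, F = Fn, signs = as.integer(sign(Fn)),
                d2o_fraction = condition$d2o_fraction)
  if (!is.null(path)) {
    write_peak_table(peaks, path)
    .write_tsv(data.frame(order = orders, F = Fn, sign = sign(Fn)),
               paste0(path, ".truth.tsv"),
               meta = list(type = "peak_table_truth",
                           d_angstrom = format(model$d, digits = 17),
                           z_head_angstrom = format(model$z_head, digits = 17),
                           d_b_angstrom = format(2 * model$z_head, digits = 17)))
  }
  list(peaks = peaks, truth = truth, condition = condition)
}

#' Generate a synthetic pressure--distance curve
#'
#' Pi = pi0 exp(-d_w / lambda_w) with multiplicative log-normal noise
#' (relative humidity errors act multiplicatively on pressure).
#'
#' @param pi0 contact pressure in Pa
#' @param lambda_w decay length in Angstrom
#' @param d_w_range range of water thicknesses sampled (A)
#' @param n_points number of points (evenly spaced in d_w)
#' @param noise_fraction sdlog of the multiplicative noise
#' @param seed optional integer seed
#' @param phase_label phase label attached to the points
#' @param d_w_err optional per-point water-thickness error column value
#' @return data frame with columns `pi`, `d_w`, `d_w_err`, `phase_label`;
#'   the generating parameters are attached as attribute `"truth"`
#' @export
gen_pressure_curve <- function(pi0 = 1e9, lambda_w = 7.7,
                               d_w_range = c(6, 24), n_points = 12L,
                               noise_fraction = 0.05, seed = NULL,
                               phase_label = "fluid", d_w_err = 0) {
  if (n_points < 2L) lam_abort("n_points must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  d_w <- seq(d_w_range[1], d_w_range[2], length.out = n_points)
  pi_true <- pi0 * exp(-d_w / lambda_w)
  pi_obs <- if (noise_fraction > 0) {
    pi_true * exp(noise_fraction * rnorm(n_points))
  } else pi_true
  out <- data.frame(pi = pi_obs, d_w = d_w, d_w_err = d_w_err,
                    phase_label = phase_label)
  attr(out, "truth") <- list(pi0 = pi0, lambda_w = lambda_w,
                             noise_fraction = noise_fraction)
  out
}

#' Generate a synthetic Bragg-sheet dataset with known mechanics
#'
#' Samples the discrete smectic Hamiltonian at the given mechanics and
#' computes seed-averaged kinematic maps of the first two Bragg sheets.
#'
#' @param mechanics a [smectic_mechanics()] (the ground truth)
#' @param n_layers,lateral_size,grid_points stack geometry (defaults:
#'   16 layers, 1600 A box, 64 x 64 grid)
#' @param n_seeds realizations averaged (default 200)
#' @param n_qz q_z samples per sheet
#' @param seed base seed
#' @param form_profile optional `nsld_profile` form factor; defaults to a
#'   bilayer model with z_head = 0.36 d at the stack period
#' @return list with `sheet1`, `sheet2` (maps) and `truth` (the mechanics)
#' @export
gen_bragg_sheet_dataset <- function(mechanics, n_layers = 16L,
                                    lateral_size = 1600, grid_points = 64L,
                                    n_seeds = 200L, n_qz = 5L, seed = NULL,
                                    form_profile = NULL) {
  stopifnot(inherits(mechanics, "smectic_mechanics"))
  if (is.null(form_profile)) {
    form_profile <- model_nsld_profile(
      make_sld_model(d = mechanics$d, z_head = 0.36 * mechanics$d))
  }
  spec <- smectic_stack_spec(n_layers, lateral_size, grid_points, mechanics)
  maps <- kinematic_bragg_sheets(spec, form_profile, sheets = c(1, 2),
                                 n_qz = n_qz, r_cutoff = mechanics$r_cutoff,
                                 n_seeds = n_seeds, seed = seed)
  list(sheet1 = maps$sheet1, sheet2 = maps$sheet2, truth = mechanics)
}

#' Generate synthetic zwitterionic charge-density profiles
#'
#' Builds a water-centred one-repeat profile set: two mirrored leaflet
#' dipole layers (normalised Gaussian +/- charge sheets, zero net charge
#' per leaflet) and an oriented-water charge layer near each interface,
#' plus simple mass-density curves.  Ground truth (per-leaflet dipole
#' moment and polarization plateau) is attached.
#'
#' @param d lamellar repeat in Angstrom
#' @param z_lipid distance of the leaflet dipole midpoint from the water
#'   centre (A)
#' @param dz_dipole separation of the +/- charge sheets within a leaflet (A)
#' @param sheet_sd Gaussian sigma of the lipid charge sheets (A)
#' @param charge_per_lipid magnitude of each lipid sheet charge (e)
#' @param water_amplitude oriented-water sheet charge per lipid (e); 0
#'   disables water orientation
#' @param z_water position of the water orientation sheets (A)
#' @param water_decay Gaussian sigma of the water sheets (A); larger values
#'   narrow the central polarization plateau
#' @param area_per_lipid lateral area per lipid (A^2)
#' @param n_points grid size
#' @param temperature temperature in K
#' @return a water-centred [density_profile_set()]; truth as attribute
#'   `"truth"` (list `M_z_upper`, `M_z_lower`, `m_w_plateau`)
#' @export
gen_charge_profiles <- function(d = 60, z_lipid = 23, dz_dipole = 3,
                                sheet_sd = 1.5, charge_per_lipid = 1,
                                water_amplitude = 0.2, z_water = 18,
                                water_decay = 2, area_per_lipid = 60,
                                n_points = 1201L, temperature = 330) {
  if (z_lipid + dz_dipole / 2 + 3 * sheet_sd > d / 2) {
    lam_abort("leaflet charge sheets spill over the repeat boundary")
  }
  z <- seq(-d / 2, d / 2, length.out = odd_at_least(n_points))
  s <- charge_per_lipid / area_per_lipid        # sheet charge, e/A^2
  # unit-charge sheets normalised on the discrete grid, so the construction
  # is neutral to machine precision despite boundary tail truncation
  g <- function(mu, sd) {
    v <- dnorm(z, mu, sd)
    v / pracma::trapz(z, v)
  }
  # upper leaflet: + sheet towards the water (smaller |z|), - sheet beyond
  lipid <- s * (g(z_lipid - dz_dipole / 2, sheet_sd) -
                g(z_lipid + dz_dipole / 2, sheet_sd)) +
           s * (g(-(z_lipid - dz_dipole / 2), sheet_sd) -
                g(-(z_lipid + dz_dipole / 2), sheet_sd))
  sw <- water_amplitude / area_per_lipid
  water_chg <- sw * (g(-z_water, water_decay) - g(z_water, water_decay))
  # simple mass curves: water slab between the interfaces, lipid outside
  wbox <- stats::plogis((z + z_water) / 2) - stats::plogis((z - z_water) / 2)
  mass <- data.frame(water = 997 * wbox, lipid = 1000 * (1 - wbox))
  out <- density_profile_set(
    z, mass = mass, charge = data.frame(lipid = lipid, water = water_chg),
    centering = "water", area_per_lipid = area_per_lipid,
    temperature = temperature, d = d)
  attr(out, "truth") <- list(
    M_z_upper = -charge_per_lipid * dz_dipole,
    M_z_lower = charge_per_lipid * dz_dipole,
    m_w_plateau = sw)
  out
}
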