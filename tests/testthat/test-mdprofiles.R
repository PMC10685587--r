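test_that("water polarization integrates the charge density with closed endpoints", {
  prof <- gen_charge_profiles(water_amplitude = 0)
  pol <- water_polarization(prof)
  expect_equal(max(abs(pol$m_w)), 0, tolerance = 1e-12)

  prof2 <- gen_charge_profiles(water_amplitude = 0.2)
  pol2 <- water_polarization(prof2)
  truth <- attr(prof2, "truth")
  # plateau between the oriented sheets matches the generator truth
  mid <- abs(pol2$z) < 5
  expect_equal(mean(pol2$m_w[mid]), truth$m_w_plateau, tolerance = 1e-4)
  # neutrality closes the integral at +d/2
  expect_lt(abs(pol2$m_w[length(pol2$m_w)]), 1e-10)
})

test_that("polarization then differentiation recovers the charge density", {
  prof <- gen_charge_profiles()
  pol <- water_polarization(prof)
  z <- pol$z
  deriv <- diff(pol$m_w) / diff(z)
  target <- (prof$charge$water[-1] + prof$charge$water[-length(z)]) / 2
  expect_equal(deriv, target, tolerance = 1e-8)
})

test_that("polarization requires the water-centred convention explicitly", {
  prof <- gen_charge_profiles()
  bprof <- recenter_profiles(prof, "bilayer")
  err <- tryCatch(water_polarization(bprof), error = identity)
  expect_s3_class(err, "lamellar_state_error")
})

test_that("leaflet dipole moment equals the point-charge value and flips with parity", {
  d <- 60
  z <- seq(-d / 2, d / 2, length.out = 2401)
  A_l <- 60
  mk <- function(z1, z2, sd = 0.4) {
    lipid <- (dnorm(z, z1, sd) - dnorm(z, z2, sd)) / A_l
    density_profile_set(z, charge = list(lipid = lipid), centering = "bilayer",
                        area_per_lipid = A_l, d = d)
  }
  # +e and -e separated by 1 A on the upper leaflet: |M_z| = 1 e*A
  # (the double-integral definition gives M_z = -sum q_i z_i)
  p <- mk(20, 21)
  expect_equal(leaflet_dipole_moment(p, "upper")$M_z, 1, tolerance = 1e-3)
  # mirroring flips the sign
  pm <- mk(-20, -21)
  expect_equal(leaflet_dipole_moment(pm, "lower")$M_z, -1, tolerance = 1e-3)
  # smearing the sheets leaves the moment of the charges unchanged
  psm <- mk(20, 21, sd = 2.0)
  expect_equal(leaflet_dipole_moment(psm, "upper")$M_z, 1, tolerance = 1e-3)
})

test_that("M_z is invariant under rigid translation of a neutral leaflet", {
  d <- 80
  z <- seq(-d / 2, d / 2, length.out = 3201)
  A_l <- 55
  for (shift in c(0, 3, 7)) {
    lipid <- (dnorm(z, 15 + shift, 0.8) - dnorm(z, 18 + shift, 0.8)) / A_l
    p <- density_profile_set(z, charge = list(lipid = lipid),
                             centering = "bilayer", area_per_lipid = A_l, d = d)
    expect_equal(leaflet_dipole_moment(p, "upper")$M_z, 3, tolerance = 2e-3)
  }
})

test_that("mirrored leaflets of the generator cancel while each carries the truth", {
  prof <- gen_charge_profiles()
  truth <- attr(prof, "truth")
  bprof <- recenter_profiles(prof, "bilayer")
  up <- leaflet_dipole_moment(bprof, "upper")
  lo <- leaflet_dipole_moment(bprof, "lower")
  expect_equal(up$M_z, truth$M_z_upper, tolerance = 0.02)
  expect_equal(lo$M_z, truth$M_z_lower, tolerance = 0.02)
  expect_lt(abs(up$M_z + lo$M_z), 0.02)
})

test_that("Gibbs-Duhem pressure is linear with the expected magnitude and sign", {
  expect_equal(gibbs_duhem_pressure(0, 0, 30, 330), 0)
  expect_equal(gibbs_duhem_pressure(-0.01, 0, 30, 330), 1.5187e6,
               tolerance = 1e-4)
  expect_gt(gibbs_duhem_pressure(-0.5, 0, 30, 330), 0)
  mu <- seq(-0.05, 0, by = 0.01)
  p <- gibbs_duhem_pressure(mu, 0, 30, 330)
  expect_equal(diff(p, differences = 2), rep(0, length(mu) - 2),
               tolerance = 1e-6)
})

test_that("Gibbs-Duhem and Kelvin pressures agree under ideal dilution", {
  # mu - mu0 = kB T ln(RH) makes the two routes identical
  for (rh in c(0.3, 0.8, 0.99)) {
    expect_equal(gibbs_duhem_pressure(log(rh), 0, 30, 323.15),
                 osmotic_pressure_from_rh(rh, 323.15, 30),
                 tolerance = 1e-12)
  }
})

test_that("band-limited SLD inputs pass through truncation unchanged", {
  d <- 60
  z <- seq(-d / 2, d / 2, length.out = 1201)
  # mass density whose SLD has <= 3 harmonics
  b <- list(stuff = list(b_fm = 10, molar_mass = 100))
  conv <- 6.02214076e-4 / 100 * 10 * 10   # mass -> SLD factor used internally
  sld_target <- 2 - 2.0 * cos(2 * pi * z / d) - 0.8 * cos(2 * pi * 2 * z / d) +
    1.1 * cos(2 * pi * 3 * z / d)
  prof <- density_profile_set(z, mass = list(stuff = sld_target / conv),
                              centering = "bilayer", d = d)
  out <- truncated_nsld_from_profiles(prof, b, n_terms = 3)
  got <- approx(out$profile$z, out$profile$rho, xout = z)$y
  expect_lt(max(abs(got - (sld_target - mean(sld_target)))), 5e-3)
})

test_that("truncated d_b matches an independent discrete-cosine oracle", {
  d <- 60
  z <- seq(-d / 2, d / 2, length.out = 2401)
  zH <- 22.6
  sldu <- 2.0 * (exp(-(z - zH)^2 / 20) + exp(-(z + zH)^2 / 20)) -
    1.2 * exp(-z^2 / 16)
  b <- list(lipid = list(b_fm = 10, molar_mass = 100))
  conv <- 6.02214076e-4 / 100 * 10 * 10
  prof <- density_profile_set(z, mass = list(lipid = sldu / conv),
                              centering = "bilayer", d = d)
  out <- truncated_nsld_from_profiles(prof, b, n_terms = 3)
  # oracle: discrete cosine coefficients by direct summation, resynthesis on
  # a fine grid, peak positions located independently
  Fn <- sapply(1:3, function(n) {
    w <- c(0.5, rep(1, length(z) - 2), 0.5)
    sum(w * sldu * cos(2 * pi * n * z / d)) * (z[2] - z[1])
  })
  expect_equal(out$coefficients, Fn, tolerance = 1e-6)
  zf <- seq(0, d / 2, length.out = 4001)
  rec <- (2 / d) * colSums(Fn * cos(2 * pi * outer(1:3, zf) / d))
  oracle_db <- 2 * zf[which.max(rec)]
  expect_equal(out$geometry$d_b, oracle_db, tolerance = 0.2)
  # the truncation offset from the generating separation is reproduced
  expect_lt(abs(out$geometry$d_b - 2 * zH), 2.5)
})

test_that("comparison shifts are applied as constants when requested", {
  d <- 60
  z <- seq(-d / 2, d / 2, length.out = 1201)
  zH <- 22
  sldu <- 2 * (exp(-(z - zH)^2 / 20) + exp(-(z + zH)^2 / 20))
  b <- list(lipid = list(b_fm = 10, molar_mass = 100))
  conv <- 6.02214076e-4 / 100 * 10 * 10
  prof <- density_profile_set(z, mass = list(lipid = sldu / conv),
                              centering = "bilayer", d = d)
  plain <- truncated_nsld_from_profiles(prof, b)
  fluid <- truncated_nsld_from_profiles(prof, b, delta_d = 3)
  gel <- truncated_nsld_from_profiles(prof, b, delta_d = 8)
  expect_equal(fluid$geometry$d_b - plain$geometry$d_b, 3)
  expect_equal(gel$geometry$d - plain$geometry$d, 8)
})

test_that("missing scattering lengths are reported by component name", {
  prof <- gen_charge_profiles()
  bprof <- recenter_profiles(prof, "bilayer")
  expect_error(
    truncated_nsld_from_profiles(bprof, list(water = list(b_fm = 1, molar_mass = 18))),
    "lipid")
})

test_that("headgroup orientation median follows the angle convention", {
  up <- matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE)
  expect_equal(headgroup_orientation_median(up), 0)
  flat <- matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE)
  expect_equal(headgroup_orientation_median(flat), 90)
  set.seed(6)
  v <- matrix(rnorm(300), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  oracle <- median(sort(acos(v[, 3]) * 180 / pi))
  expect_equal(headgroup_orientation_median(v), oracle)
  expect_error(headgroup_orientation_median(rbind(c(0, 0, 0))), "zero")
  expect_message(headgroup_orientation_median(2 * up), "normalising")
})
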