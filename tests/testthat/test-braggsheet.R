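test_that("Caille and de Gennes parameters match their closed forms", {
  expect_equal(caille_parameter(14, 29e6, 50, 323.15), 0.01473,
               tolerance = 1e-3)
  expect_equal(degennes_parameter(14, 29e6, 50, 323.15), 6.563,
               tolerance = 1e-3)
  # eta is linear in T at fixed mechanics (kappa held in Joule)
  kJ <- 14 * kBT_joule(323.15)
  e1 <- caille_parameter(kJ, 29e6, 50, 300, kappa_in = "J")
  e2 <- caille_parameter(kJ, 29e6, 50, 600, kappa_in = "J")
  expect_equal(e2 / e1, 2, tolerance = 1e-12)
  # eta scales as (kappa B)^(-1/2): quadrupling kappa alone halves it, and
  # quadrupling both moduli quarters it
  expect_equal(caille_parameter(4 * kJ, 29e6, 50, 323.15, kappa_in = "J"),
               caille_parameter(kJ, 29e6, 50, 323.15, kappa_in = "J") / 2)
  expect_equal(caille_parameter(4 * kJ, 4 * 29e6, 50, 323.15, kappa_in = "J"),
               caille_parameter(kJ, 29e6, 50, 323.15, kappa_in = "J") / 4)
  expect_equal(degennes_parameter(4 * kJ, 29e6, 50, kappa_in = "J"),
               2 * degennes_parameter(kJ, 29e6, 50, kappa_in = "J"))
  # Lambda carries no explicit temperature dependence
  expect_equal(degennes_parameter(kJ, 29e6, 50, kappa_in = "J"),
               degennes_parameter(kJ, 29e6, 50, 999, kappa_in = "J"))
})

test_that("forward then inverse mechanics is the identity at both lipid systems", {
  for (par in list(c(14, 29e6, 50), c(22, 1.5e6, 60))) {
    eta <- caille_parameter(par[1], par[2], par[3], 323.15)
    lam <- degennes_parameter(par[1], par[2], par[3], 323.15)
    inv <- invert_mechanics(eta, lam, par[3], 323.15)
    expect_equal(inv$kappa, par[1], tolerance = 1e-12)
    expect_equal(inv$b_mod, par[2], tolerance = 1e-9)
  }
  # eta -> 2 eta at fixed Lambda halves both moduli
  inv1 <- invert_mechanics(0.02, 10, 50, 323.15)
  inv2 <- invert_mechanics(0.04, 10, 50, 323.15)
  expect_equal(inv2$kappa, inv1$kappa / 2)
  expect_equal(inv2$b_mod, inv1$b_mod / 2)
})

test_that("the forward/inverse identity holds over random log-uniform draws", {
  set.seed(17)
  for (i in 1:25) {
    kappa <- 10^runif(1, 0, 2)
    b_mod <- 10^runif(1, 5, 8)
    d <- runif(1, 40, 80)
    temp <- runif(1, 280, 350)
    inv <- invert_mechanics(caille_parameter(kappa, b_mod, d, temp),
                            degennes_parameter(kappa, b_mod, d, temp),
                            d, temp)
    expect_equal(inv$kappa, kappa, tolerance = 1e-10)
    expect_equal(inv$b_mod, b_mod, tolerance = 1e-10 * b_mod)
  }
})

test_that("the stack sampler freezes at T -> 0 and validates its inputs", {
  # freeze the thermal energy while holding the Hamiltonian (kappa in J) fixed
  mech_cold <- smectic_mechanics(14 * kBT_joule(323.15), 29e6, 50, 1e-9,
                                 kappa_in = "J")
  f <- sample_smectic_stack(4, 200, 8, mech_cold, seed = 1)
  expect_lt(max(abs(f$u)), 1e-4)
  mech <- smectic_mechanics(14, 29e6, 50, 323.15)
  expect_error(sample_smectic_stack(1, 200, 8, mech), "n_layers")
  expect_error(sample_smectic_stack(4, 200, 12, mech), "power of two")
  # every layer has zero spatial mean (q_par = 0 modes pinned)
  f2 <- sample_smectic_stack(4, 200, 16, mech, seed = 2)
  expect_equal(apply(f2$u, 3, mean), rep(0, 4), tolerance = 1e-12)
})

test_that("sampled mode variances satisfy equipartition (chi-squared per mode)", {
  mech <- smectic_mechanics(14, 29e6, 50, 323.15)
  N <- 4L; Ng <- 8L; L <- 200
  nrep <- 300
  acc <- array(0, c(Ng, Ng, N))
  set.seed(9)
  for (r in seq_len(nrep)) {
    f <- sample_smectic_stack(N, L, Ng, mech)
    U <- fft(f$u)
    acc <- acc + Re(U * Conj(U))
  }
  emp <- acc / nrep / (Ng^2 * N)
  expct <- lamellar:::.stack_mode_variances(N, L, Ng, mech)
  sel <- expct > 0
  stat <- nrep * emp[sel] / expct[sel]    # ~ chi^2_nrep per mode
  lim <- stats::qchisq(c(1e-4 / sum(sel), 1 - 1e-4 / sum(sel)), df = nrep)
  expect_true(all(stat > lim[1] & stat < lim[2]))
  expect_equal(mean(emp[sel] / expct[sel]), 1, tolerance = 0.02)
})

test_that("differential layer fluctuations shrink as compression stiffens", {
  msd <- sapply(c(0.5e6, 2e6, 8e6, 32e6), function(B) {
    mech <- smectic_mechanics(14, B, 50, 323.15)
    f <- sample_smectic_stack(8, 400, 16, mech, seed = 33)
    du <- f$u[, , c(2:8, 1)] - f$u
    mean(du^2)
  })
  expect_true(all(diff(msd) < 0))
})

test_that("a frozen stack scatters into pure specular rods", {
  mech_cold <- smectic_mechanics(14 * kBT_joule(323.15), 29e6, 50, 1e-9,
                                 kappa_in = "J")
  fp <- model_nsld_profile(make_sld_model(d = 50, z_head = 18))
  f <- sample_smectic_stack(8, 400, 16, mech_cold, seed = 2)
  maps <- kinematic_bragg_sheets(f, fp, sheets = c(1, 2), n_qz = 8)
  for (m in maps) {
    off <- m[!m$specular, ]
    ctr <- m[m$specular, ]
    expect_lt(sum(off$intensity * off$n_pix),
              1e-9 * sum(ctr$intensity))
  }
  expect_error(kinematic_bragg_sheets(f, fp, sheets = 3), "sheet index")
})

test_that("total sheet intensity is conserved while fluctuations redistribute it", {
  # near-flat form factor (narrow scatterer) so the conservation property of
  # the fluctuation dynamics is probed without form-factor weighting
  zf <- seq(-25, 25, length.out = 1001)
  fp <- lamellar:::new_nsld_profile(zf, dnorm(zf, 0, 0.5), 50, 0L, integer(0))
  totals <- sapply(c(100, 250, 400), function(temp) {
    mech <- smectic_mechanics(14, 29e6, 50, temp)
    spec <- smectic_stack_spec(8L, 400, 16L, mech)
    m1 <- kinematic_bragg_sheets(spec, fp, sheets = 1, n_qz = 8L,
                                 n_seeds = 40, seed = 5)$sheet1
    c(total = sum(m1$intensity * m1$n_pix),
      spec = sum(m1$intensity[m1$specular] * m1$n_pix[m1$specular]))
  })
  drift <- diff(range(totals["total", ])) / mean(totals["total", ])
  expect_lt(drift, 0.01)
  expect_true(all(diff(totals["spec", ]) < 0))  # specular drains with T
})

test_that("sheet observables move monotonically with eta and Lambda", {
  d <- 60; temp <- 323.15
  base_eta <- 0.039; base_lam <- 33
  summaries <- function(eta, lam) {
    inv <- invert_mechanics(eta, lam, d, temp)
    mech <- smectic_mechanics(inv$kappa, inv$b_mod, d, temp)
    ds <- gen_bragg_sheet_dataset(mech, n_layers = 8L, lateral_size = 800,
                                  grid_points = 32L, n_seeds = 40,
                                  seed = 12)
    lamellar:::.sheet_summaries(ds$sheet1, ds$sheet2)
  }
  # growing eta (via T-like softening) drains the sheet-2 specular ratio
  r2 <- sapply(c(0.5, 1, 2) * base_eta, function(e) summaries(e, base_lam)["ratio2"])
  expect_true(all(diff(r2) < 0))
  # growing Lambda (weaker conformality) spreads sheet-1 along q_z
  c1 <- sapply(c(0.5, 1, 2) * base_lam, function(l) summaries(base_eta, l)["conc1"])
  expect_true(all(diff(c1) < 0))
})

test_that("finite lateral cut-off damps the coherent inter-layer intensity", {
  mech <- smectic_mechanics(22, 1.5e6, 60, 323.15)
  fp <- model_nsld_profile(make_sld_model(d = 60, z_head = 21.6))
  spec <- smectic_stack_spec(8L, 400, 16L, mech)
  m_inf <- kinematic_bragg_sheets(spec, fp, sheets = 1, n_qz = 4L,
                                  n_seeds = 20, seed = 3)$sheet1
  m_cut <- kinematic_bragg_sheets(spec, fp, sheets = 1, n_qz = 4L,
                                  r_cutoff = 30, n_seeds = 20, seed = 3)$sheet1
  sp_inf <- sum(m_inf$intensity[m_inf$specular])
  sp_cut <- sum(m_cut$intensity[m_cut$specular])
  expect_lt(sp_cut, sp_inf)
})

test_that("fit_mechanics validates the sheet roles", {
  mech <- smectic_mechanics(22, 1.5e6, 60, 323.15)
  ds <- gen_bragg_sheet_dataset(mech, n_layers = 8L, lateral_size = 800,
                                grid_points = 32L, n_seeds = 10, seed = 2)
  expect_error(fit_mechanics(ds$sheet2, ds$sheet1, 60, 323.15), "sheet 1")
})
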