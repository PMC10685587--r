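# Shared fixtures: the standard phasing condition and the two reference
# bilayer models (PC-like fluid, betaine-like gel) used across tests.

fix_cond <- function(d2o = 0.08, rh = 0.96) {
  diffraction_condition(relative_humidity = rh, d2o_fraction = d2o)
}

fix_model_pc <- function() make_sld_model(d = 50, z_head = 18.05)
fix_model_dgts <- function() make_sld_model(d = 60, z_head = 22.6)

# full closed loop: model -> peak table -> reduce -> phase -> synthesize -> fit
fix_closed_loop <- function(model, n_orders = 4L, noise = 0, seed = NULL) {
  g <- gen_peak_table(model, fix_cond(), n_orders = n_orders,
                      noise_fraction = noise, seed = seed)
  ds <- lamellar_dataset(
    g$peaks[c("order", "two_theta", "intensity", "intensity_err")],
    fix_cond(), "fluid")
  fs <- assign_phases(structure_factors(ds))
  geom <- fit_bilayer_thickness(synthesize_profile(fs))
  list(gen = g, dataset = ds, fset = fs, geometry = geom)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
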