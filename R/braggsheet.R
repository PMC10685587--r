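# Kinematic Bragg-sheet scattering from sampled smectic stacks, and the
# (eta, Lambda) fitting procedure that inverts it into (kappa, B).
#
# The scattering density of the stack is built as
#   rho(x, y, z) = sum_n profile(z - n d - u_n(x, y)),
# whose kinematic amplitude at (q_par, q_z) factorises into the bilayer form
# factor f(q_z) times sum_n e^{i q_z n d} FFT2[e^{i q_z u_n}](q_par).
# Intensities are averaged over independently seeded realizations of the
# fluctuation field.  This treatment is only valid where the scattered
# intensity is weak, so the specular bin of the first sheet is excluded
# from all fitting.

# Form factor |f(q_z)| of a centrosymmetric profile, by trapezoidal quadrature.
.form_factor <- function(profile, qz) {
  vapply(qz, function(q) {
    pracma::trapz(profile$z, profile$rho * cos(q * profile$z))
  }, numeric(1))
}

# Integer q_z sub-grid (in units of 2 pi / (N d)) spanning one Brillouin
# zone across a sheet; n_qz = n_layers covers the zone exactly.
.qz_offsets <- function(n_layers, n_qz) {
  if (n_qz > n_layers) lam_abort("n_qz cannot exceed n_layers")
  if (n_qz == n_layers) {
    m <- 0:(n_layers - 1)
    m[m >= n_layers / 2] <- m[m >= n_layers / 2] - n_layers
    sort(m)
  } else {
    h <- (n_qz - 1) %/% 2
    (-h):(n_qz - 1 - h)
  }
}

#' Specification of a smectic stack to be sampled on the fly
#'
#' Used by [kinematic_bragg_sheets()] to average scattering maps over many
#' independently seeded fluctuation fields without holding them in memory.
#'
#' @inheritParams sample_smectic_stack
#' @return object of class `smectic_stack_spec`
#' @export
smectic_stack_spec <- function(n_layers = 16L, lateral_size = 1600,
                               grid_points = 64L, mechanics) {
  stopifnot(inherits(mechanics, "smectic_mechanics"))
  structure(list(n_layers = as.integer(n_layers), lateral_size = lateral_size,
                 grid_points = as.integer(grid_points), mechanics = mechanics),
            class = "smectic_stack_spec")
}

# One realization's intensity contribution on the (qz, q_par-grid) lattice.
# Returns a list of [Ng, Ng] matrices, one per qz value.
.sheet_intensity_once <- function(u, d, qz_values, r_cutoff) {
  n_layers <- dim(u)[3]
  lapply(qz_values, function(qz) {
    G <- vector("list", n_layers)
    for (n in seq_len(n_layers)) G[[n]] <- fft(exp(1i * qz * u[, , n]))
    if (is.infinite(r_cutoff)) {
      A <- Reduce(`+`, lapply(seq_len(n_layers), function(n) {
        exp(1i * qz * (n - 1) * d) * G[[n]]
      }))
      Re(A * Conj(A))
    } else {
      # damp inter-layer cross-correlations by exp(-l d / R) at lag l
      I <- Reduce(`+`, lapply(G, function(g) Re(g * Conj(g))))
      for (l in seq_len(n_layers - 1)) {
        damp <- exp(-l * d / r_cutoff)
        cross <- 0
        for (n in seq_len(n_layers - l)) {
          cross <- cross + G[[n + l]] * Conj(G[[n]])
        }
        I <- I + 2 * damp * Re(exp(1i * qz * l * d) * cross)
      }
      pmax(I, 0)
    }
  })
}

#' Kinematic Bragg-sheet intensity maps
#'
#' Computes seed-averaged off-specular intensity maps around the first and
#' second lamellar Bragg sheets from sampled fluctuation fields.  Each map
#' is resolved in q_z across one layer-periodicity Brillouin zone and binned
#' radially in q_par; the q_par = 0 column is the specular locus.
#'
#' @param field a `fluctuation_field` (single realization) or a
#'   [smectic_stack_spec()] to be sampled `n_seeds` times
#' @param form_profile an `nsld_profile` supplying the bilayer form factor
#' @param sheets Bragg-sheet indices, subset of `c(1, 2)`
#' @param n_qz number of q_z samples across each sheet
#' @param r_cutoff empirical lateral cut-off R in Angstrom; finite values
#'   damp inter-layer cross-correlations by exp(-l d / R) at layer lag l
#' @param n_seeds number of field realizations to average
#' @param seed base seed; realization k uses `seed + k`
#' @return list of `bragg_sheet_map` data frames (columns `sheet`,
#'   `qz_invA`, `q_par_invA`, `omega_deg`, `intensity`, `n_pix`,
#'   `specular`), one per requested sheet
#' @export
kinematic_bragg_sheets <- function(field, form_profile, sheets = c(1, 2),
                                   n_qz = 5L, r_cutoff = Inf,
                                   n_seeds = 1L, seed = NULL) {
  if (!all(sheets %in% c(1, 2))) {
    lam_abort("sheet index must be 1 or 2 (the analysis uses the first two sheets)")
  }
  stopifnot(inherits(form_profile, "nsld_profile"))
  spec <- if (inherits(field, "fluctuation_field")) {
    if (n_seeds != 1L) lam_abort("a single fluctuation_field implies n_seeds = 1")
    smectic_stack_spec(field$n_layers, field$lateral_size, field$grid_points,
                       field$mechanics)
  } else if (inherits(field, "smectic_stack_spec")) {
    field
  } else {
    lam_abort("field must be a fluctuation_field or smectic_stack_spec")
  }
  d <- spec$mechanics$d
  if (abs(form_profile$d - d) > 1e-6 * d) {
    lam_abort("form profile period (%g) does not match stack period (%g)",
              form_profile$d, d)
  }
  Ng <- spec$grid_points
  L <- spec$lateral_size
  m_off <- .qz_offsets(spec$n_layers, n_qz)

  qz_all <- lapply(sheets, function(s) {
    2 * pi * s / d + 2 * pi * m_off / (spec$n_layers * d)
  })
  acc <- lapply(qz_all, function(qz) lapply(qz, function(q) matrix(0, Ng, Ng)))

  for (k in seq_len(n_seeds)) {
    fld <- if (inherits(field, "fluctuation_field")) field else {
      sample_smectic_stack(spec$n_layers, L, Ng, spec$mechanics,
                           seed = if (is.null(seed)) NULL else seed + k)
    }
    for (si in seq_along(sheets)) {
      contrib <- .sheet_intensity_once(fld$u, d, qz_all[[si]], r_cutoff)
      for (j in seq_along(contrib)) acc[[si]][[j]] <- acc[[si]][[j]] + contrib[[j]]
    }
  }

  # radial q_par binning: bin b holds pixels with round(|j|) == b
  j <- c(0:(Ng / 2), if (Ng >= 4) -((Ng / 2 - 1):1))
  rad <- round(sqrt(outer(j^2, j^2, `+`)))
  bins <- 0:max(rad)
  npix <- tabulate(rad + 1L, nbins = length(bins))
  k0 <- 2 * pi / (4.47)                 # neutron wavenumber at lambda = 4.47 A

  out <- lapply(seq_along(sheets), function(si) {
    qz <- qz_all[[si]]
    f2 <- .form_factor(form_profile, qz)^2
    rows <- do.call(rbind, lapply(seq_along(qz), function(jz) {
      I <- acc[[si]][[jz]] / n_seeds * f2[jz]
      isum <- vapply(bins, function(b) sum(I[rad == b]), numeric(1))
      q_par <- 2 * pi * bins / L
      theta_s <- asin(pmin(1, sqrt(q_par^2 + qz[jz]^2) / (2 * k0)))
      omega <- rad2deg(theta_s + atan2(q_par, qz[jz]))
      data.frame(sheet = sheets[si], qz_invA = qz[jz], q_par_invA = q_par,
                 omega_deg = omega, intensity = isum / pmax(npix, 1L),
                 n_pix = npix, specular = bins == 0L)
    }))
    structure(rows, class = c("bragg_sheet_map", "data.frame"),
              geometry = spec, form_profile = form_profile,
              n_seeds = n_seeds, r_cutoff = r_cutoff, n_qz = n_qz)
  })
  names(out) <- paste0("sheet", sheets)
  out
}

# Summary statistics driving the mechanics fit (sheet-1 specular excluded,
# where the kinematic approximation is violated):
#  - conc1: how strongly the sheet-1 off-specular intensity is concentrated
#    at the Bragg q_z (central q_z slice over outermost slices).  Inter-layer
#    conformality -- set by Lambda through the B coupling -- sharpens the
#    sheet along q_z, so this ratio is the Lambda-sensitive observable.
#  - ratio2: specular/diffuse intensity ratio of the second sheet, the
#    eta-sensitive observable.
.sheet_summaries <- function(map1, map2) {
  conc <- function(map) {
    off <- map[!map$specular, ]
    qz0 <- unique(map$qz_invA)
    ctr <- qz0[which.min(abs(qz0 - mean(range(qz0))))]
    edge <- range(qz0)
    i_ctr <- sum(off$intensity[off$qz_invA == ctr] * off$n_pix[off$qz_invA == ctr])
    i_edge <- mean(vapply(edge, function(q) {
      sum(off$intensity[off$qz_invA == q] * off$n_pix[off$qz_invA == q])
    }, numeric(1)))
    i_ctr / i_edge
  }
  ratio <- function(map) {
    sp <- sum(map$intensity[map$specular] * map$n_pix[map$specular])
    df <- sum(map$intensity[!map$specular] * map$n_pix[!map$specular])
    sp / df
  }
  c(conc1 = conc(map1), ratio2 = ratio(map2))
}

# q_par decay constant of the (q_z-summed) off-specular sheet intensity,
# exposed as a map diagnostic.
sheet_qpar_decay <- function(map) {
  off <- map[!map$specular & map$n_pix > 0, ]
  agg <- stats::aggregate(list(I = off$intensity * off$n_pix,
                               n = off$n_pix),
                          by = list(q = off$q_par_invA), FUN = sum)
  agg$I <- agg$I / agg$n
  agg <- agg[agg$I > 0, ]
  use <- agg[2:max(3, floor(nrow(agg) * 0.6)), ]   # skip near-specular bin
  -coef(lm(log(I) ~ q, data = use))[["q"]]
}

#' Fit smectic mechanics to a pair of Bragg-sheet maps
#'
#' Recovers (eta, Lambda) -- and through [invert_mechanics()] the bending
#' modulus kappa and compression modulus B -- from the first two Bragg
#' sheets by systematic variation: candidate (eta, Lambda) pairs on a
#' log-spaced grid are forward-simulated with the same stack geometry as the
#' data, scored by least squares on two summary statistics (the sheet-2
#' specular/diffuse ratio, sensitive to eta, and the q_z concentration of
#' the sheet-1 off-specular intensity, sensitive to Lambda through the
#' inter-layer conformality; the sheet-1 specular bin is excluded where the
#' kinematic approximation fails), refined once on a finer grid around the
#' best node, and interpolated parabolically.
#'
#' @param map1,map2 `bragg_sheet_map`s of sheets 1 and 2 at one condition
#' @param d lamellar period in Angstrom
#' @param temperature temperature in K
#' @param eta_range,lambda_range search intervals for eta and Lambda
#' @param n_grid grid nodes per axis and stage
#' @param n_seeds_coarse,n_seeds_refine realizations averaged per candidate
#'   in the two stages
#' @param seed base seed for the candidate simulations
#' @return a [smectic_mechanics()] with the recovered parameters; the score
#'   landscape is attached as attribute `"landscape"`
#' @export
fit_mechanics <- function(map1, map2, d, temperature,
                          eta_range = c(0.004, 0.12),
                          lambda_range = c(3, 100), n_grid = 7L,
                          n_seeds_coarse = 16L, n_seeds_refine = 32L,
                          seed = 1L) {
  stopifnot(inherits(map1, "bragg_sheet_map"), inherits(map2, "bragg_sheet_map"))
  if (unique(map1$sheet) != 1L || unique(map2$sheet) != 2L) {
    lam_abort("map1 must hold sheet 1 and map2 sheet 2 (got %s and %s)",
              unique(map1$sheet), unique(map2$sheet))
  }
  geom <- attr(map1, "geometry")
  fp <- attr(map1, "form_profile")
  n_qz <- attr(map1, "n_qz")
  r_cutoff <- attr(map1, "r_cutoff")
  s_data <- .sheet_summaries(map1, map2)

  score_at <- function(eta, lambda, n_seeds) {
    mech <- do.call(smectic_mechanics, c(
      invert_mechanics(eta, lambda, d, temperature)[c("kappa", "b_mod")],
      list(d = d, temperature = temperature)))
    spec <- smectic_stack_spec(geom$n_layers, geom$lateral_size,
                               geom$grid_points, mech)
    maps <- kinematic_bragg_sheets(spec, fp, sheets = c(1, 2), n_qz = n_qz,
                                   r_cutoff = r_cutoff, n_seeds = n_seeds,
                                   seed = seed)
    s <- .sheet_summaries(maps$sheet1, maps$sheet2)
    (log(s[["conc1"]]) - log(s_data[["conc1"]]))^2 +
      (log(s[["ratio2"]]) - log(s_data[["ratio2"]]))^2
  }

  run_grid <- function(etas, lambdas, n_seeds) {
    sc <- matrix(NA_real_, length(etas), length(lambdas))
    for (i in seq_along(etas)) {
      for (jj in seq_along(lambdas)) {
        sc[i, jj] <- score_at(etas[i], lambdas[jj], n_seeds)
      }
    }
    sc
  }

  # parabolic vertex through three log-spaced nodes around the minimum
  vertex <- function(vals, scores, idx) {
    if (idx == 1L || idx == length(vals)) return(vals[idx])
    lv <- log(vals[(idx - 1):(idx + 1)])
    sv <- scores[(idx - 1):(idx + 1)]
    den <- sv[1] - 2 * sv[2] + sv[3]
    if (!is.finite(den) || den <= 0) return(vals[idx])
    exp(lv[2] + 0.5 * (lv[2] - lv[1]) * (sv[1] - sv[3]) / den)
  }

  etas <- exp(seq(log(eta_range[1]), log(eta_range[2]), length.out = n_grid))
  lambdas <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                     length.out = n_grid))
  sc1 <- run_grid(etas, lambdas, n_seeds_coarse)
  ij <- which(sc1 == min(sc1), arr.ind = TRUE)[1, ]
  step <- log(etas[2] / etas[1])

  etas2 <- exp(seq(log(etas[ij[1]]) - step, log(etas[ij[1]]) + step,
                   length.out = n_grid))
  step_l <- log(lambdas[2] / lambdas[1])
  lambdas2 <- exp(seq(log(lambdas[ij[2]]) - step_l,
                      log(lambdas[ij[2]]) + step_l, length.out = n_grid))
  sc2 <- run_grid(etas2, lambdas2, n_seeds_refine)
  ij2 <- which(sc2 == min(sc2), arr.ind = TRUE)[1, ]

  if (diff(range(sc2)) < 1e-3 * max(abs(sc2), 1e-12)) {
    lam_log("warning", "braggsheet",
            "score landscape is nearly flat; mechanics poorly constrained")
  }
  eta_hat <- vertex(etas2, sc2[, ij2[2]], ij2[1])
  lambda_hat <- vertex(lambdas2, sc2[ij2[1], ], ij2[2])
  inv <- invert_mechanics(eta_hat, lambda_hat, d, temperature)
  out <- smectic_mechanics(inv$kappa, inv$b_mod, d, temperature,
                           r_cutoff = r_cutoff)
  attr(out, "landscape") <- list(
    coarse = list(eta = etas, lambda = lambdas, score = sc1),
    refine = list(eta = etas2, lambda = lambdas2, score = sc2),
    summaries_data = s_data)
  lam_log("info", "braggsheet",
          "fit: eta = %.4g, Lambda = %.4g A -> kappa = %.3g kBT, B = %.3g MPa",
          eta_hat, lambda_hat, out$kappa, out$b_mod / 1e6)
  out
}
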