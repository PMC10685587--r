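# Hydration repulsion: exponential pressure-distance fits and the
# beam-theory bending-rigidity scaling.

#' Fit the exponential hydration-repulsion law
#'
#' Fits Pi = Pi0 exp(-d_w / lambda_w) to pressure--distance observations of
#' a single lamellar phase by least squares in log-pressure space,
#' ln Pi = ln Pi0 - d_w / lambda_w (the data span decades in Pi).  When
#' per-point water-thickness errors are supplied, they are propagated to
#' ln Pi through the local slope and the fit is reweighted once.
#'
#' Points with non-positive pressure (RH saturation) are excluded with a
#' logged count.  Fewer than three usable points make the decay length
#' unidentifiable and raise an error, so a two-point set is refused rather
#' than fitted.
#'
#' @param points data frame with columns `pi` (Pa), `d_w` (Angstrom),
#'   optionally `d_w_err` and `phase_label` (a single phase)
#' @return an object of class `hydration_fit`: `pi0`, `lambda_w`, standard
#'   errors, the 2x2 parameter covariance (on `log(pi0)`, `lambda_w`),
#'   per-point residuals in ln Pi, `n_points`, `phase_label`
#' @export
fit_hydration_decay <- function(points) {
  stopifnot(is.data.frame(points), all(c("pi", "d_w") %in% names(points)))
  phase <- unique(points$phase_label %||% "unassigned")
  if (length(phase) > 1L) {
    lam_abort("points mix lamellar phases (%s); fit each phase separately",
              paste(phase, collapse = ", "))
  }
  drop_n <- sum(points$pi <= 0)
  if (drop_n > 0) {
    lam_log("info", "forces", "excluding %d point(s) with Pi <= 0", drop_n)
    points <- points[points$pi > 0, , drop = FALSE]
  }
  if (any(points$d_w <= 0)) lam_abort("d_w must be positive")
  if (nrow(points) < 3L) {
    lam_abort(paste0("only ", nrow(points), " usable point(s): cannot evaluate ",
                     "the decay length; report no decay length for this phase"))
  }
  y <- log(points$pi)
  fit <- lm(y ~ d_w, data = points)
  if (!is.null(points$d_w_err) && any(points$d_w_err > 0)) {
    lambda0 <- -1 / coef(fit)[["d_w"]]
    w <- 1 / pmax(points$d_w_err^2 / lambda0^2, 1e-12)
    fit <- lm(y ~ d_w, data = points, weights = w)
  }
  b <- coef(fit)
  if (b[["d_w"]] >= 0) {
    lam_abort("fitted pressure increases with distance; no hydration decay")
  }
  lambda_w <- -1 / b[["d_w"]]
  pi0 <- exp(b[["(Intercept)"]])
  # noiseless input triggers R's benign "essentially perfect fit" warning
  V <- withCallingHandlers(vcov(fit), warning = function(w) {
    if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
  })
  lambda_se <- sqrt(V["d_w", "d_w"]) / b[["d_w"]]^2
  structure(
    list(pi0 = pi0, lambda_w = lambda_w,
         pi0_se = pi0 * sqrt(V[1, 1]), lambda_w_se = lambda_se,
         cov = V, residuals = resid(fit), n_points = nrow(points),
         phase_label = phase),
    class = "hydration_fit")
}

#' @export
print.hydration_fit <- function(x, ...) {
  cat(sprintf(
    "hydration fit (%s phase, %d points): Pi0 = %.3g Pa, lambda_w = %.3g +/- %.2g A\n",
    x$phase_label, x$n_points, x$pi0, x$lambda_w, x$lambda_w_se))
  invisible(x)
}

#' Beam-theory scaling of the bending modulus with bilayer thickness
#'
#' Classical beam theory: the bending rigidity of a homogeneous plate scales
#' with the third power of its thickness, so
#' kappa_new = kappa_ref * (d_b_new / d_b_ref)^3.
#'
#' @param kappa_ref reference bending modulus (any unit, typically k_B T)
#' @param d_b_ref,d_b_new reference and new bilayer thicknesses (Angstrom)
#' @return scaled bending modulus in the unit of `kappa_ref`
#' @examples
#' beam_theory_kappa(14, 36.1, 40.9) # ~ 20.4 kBT
#' @export
beam_theory_kappa <- function(kappa_ref, d_b_ref, d_b_new) {
  check_number(kappa_ref, "kappa_ref", 0, strict_lower = TRUE)
  check_number(d_b_ref, "d_b_ref", 0, strict_lower = TRUE)
  check_number(d_b_new, "d_b_new", 0, strict_lower = TRUE)
  kappa_ref * (d_b_new / d_b_ref)^3
}
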