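#' Fit the Hertz model to a spherical-tip curve
#'
#' Nonlinear least squares over the modulus `E` and contact point `z_A` of
#' the spherical-tip Hertz model applied to cantilever-corrected depth,
#' restricted to depths up to `max_depth`. Because the model is linear in
#' `E` at fixed `z_A`, `E` is profiled out in closed form and the fit reduces
#' to a one-dimensional search over `z_A` around the threshold-detected
#' contact point.
#'
#' @param curve A [force_curve()] with `tip_kind == "sphere"`.
#' @param max_depth Maximum corrected depth included in the fit, nm
#'   (default 1500, matching stiffness measurements at 1.5 um depth).
#' @param nu Poisson ratio (default 0.5).
#' @param z_window Half-width in nm of the `z_A` search interval around the
#'   detected contact point.
#' @return A `hertz_fit` object: `modulus` (Pa), `contact_point` (nm),
#'   `poisson_ratio`, `rms_residual` (nN), `fit_range` (nm, span of piezo
#'   positions used) and `n_points`.
#' @export
fit_hertz <- function(curve, max_depth = 1500, nu = 0.5, z_window = 500) {
  if (curve$tip_kind != "sphere")
    afm_error("afm_fit_error",
              "Hertz fitting requires a spherical tip (tip_kind = 'sphere')")
  z <- curve$piezo_z
  f <- curve$force
  k <- curve$spring_constant
  R <- curve$tip_radius

  zA0 <- as.numeric(detect_contact_point(curve))
  lo <- max(min(z), zA0 - z_window)
  hi <- min(max(z) - 10, zA0 + z_window)

  profile <- function(zA) {
    delta <- indentation_depth(z, f, k, zA)
    sel <- delta <= max_depth
    g <- hertz_force(1, R, nu, delta[sel])
    denom <- sum(g^2)
    E <- if (denom > 0) sum(f[sel] * g) / denom else 0
    res <- f[sel] - E * g
    list(E = E, rss = sum(res^2), n = sum(sel), sel = sel)
  }
  opt <- optimize(function(zA) profile(zA)$rss, c(lo, hi), tol = 1e-3)
  best <- profile(opt$minimum)
  if (!is.finite(best$E) || best$E <= 0)
    afm_error("afm_fit_error", "Hertz fit failed: non-positive modulus",
              diagnostics = list(zA = opt$minimum, rss = best$rss))
  span <- hi - lo
  if (opt$minimum - lo < 1e-6 * span || hi - opt$minimum < 1e-6 * span)
    afm_error("afm_fit_error", "Hertz fit failed: contact point at bound",
              diagnostics = list(zA = opt$minimum, bounds = c(lo, hi)))
  structure(
    list(modulus = best$E, contact_point = opt$minimum,
         poisson_ratio = nu, rms_residual = sqrt(best$rss / best$n),
         fit_range = range(z[best$sel]), n_points = best$n),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit> E = %.4g Pa | z_A = %.1f nm | nu = %.2f | rms %.3g nN (%d pts)\n",
    x$modulus, x$contact_point, x$poisson_ratio, x$rms_residual, x$n_points))
  invisible(x)
}
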