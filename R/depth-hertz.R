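#' Cantilever-corrected indentation depth
#'
#' The indentation depth is the piezo travel past the contact point minus the
#' cantilever deflection `d = F/k`. With force in nN and the spring constant
#' in N/m, `F/k` is directly in nm, so all terms are in nm. Values are
#' floored at zero (no negative depth before contact).
#'
#' @param piezo_z Piezo position in nm (vector).
#' @param force Force in nN (vector, same length).
#' @param k Cantilever spring constant in N/m (> 0).
#' @param z_A Contact-point piezo position in nm.
#' @return Depth in nm, same length as `piezo_z`.
#' @examples
#' indentation_depth(2000, 2, 0.02, 1000)  # 1000 - 100 = 900 nm
#' @export
indentation_depth <- function(piezo_z, force, k, z_A) {
  if (length(piezo_z) == 0 || length(force) == 0)
    afm_error("afm_invalid_argument", "zero-length input")
  if (length(piezo_z) != length(force))
    afm_error("afm_invalid_argument", "piezo_z and force lengths differ")
  if (!is.numeric(k) || k <= 0)
    afm_error("afm_invalid_argument", "spring constant k must be > 0")
  pmax((piezo_z - z_A) - force / k, 0)
}

#' Hertz contact force for a spherical tip
#'
#' Forward Hertz model `F = 4 sqrt(R) E / (3 (1 - nu^2)) * delta^(3/2)`,
#' evaluated in SI internally and returned in nN.
#'
#' @param E Elastic modulus in Pa (> 0).
#' @param R Tip radius in um (> 0).
#' @param nu Poisson ratio in `[0, 1)`; 0.5 is the usual value for cells.
#' @param delta Indentation depth in nm (>= 0, vectorised).
#' @return Force in nN.
#' @examples
#' hertz_force(1000, 2.25, 0.5, 500)  # ~0.943 nN
#' @export
hertz_force <- function(E, R, nu = 0.5, delta) {
  if (!is.numeric(E) || E <= 0)
    afm_error("afm_invalid_argument", "E must be > 0")
  if (!is.numeric(R) || R <= 0)
    afm_error("afm_invalid_argument", "R must be > 0")
  if (!is.numeric(nu) || nu < 0 || nu >= 1)
    afm_error("afm_invalid_argument", "nu must be in [0, 1)")
  if (any(delta < 0))
    afm_error("afm_invalid_argument", "delta must be >= 0")
  f_si <- 4 * sqrt(R * 1e-6) * E / (3 * (1 - nu^2)) * (delta * 1e-9)^1.5
  f_si * 1e9
}
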