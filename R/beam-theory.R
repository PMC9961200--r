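#' Midspan deflection of a tensioned, simply supported beam
#'
#' Closed-form solution of the beam-column equation for a simply supported
#' span under a central transverse load `F2` and axial tension `F1`: the
#' bending moment satisfies `M(x) = (F2/2) x - F1 w`, so tension reduces the
#' net moment and stiffens the beam. With `u = (L/2) sqrt(F1 / EI)`,
#'
#'   `w_mid = F2 L^3 / (48 EI) * 3 (u - tanh u) / u^3`
#'
#' which reduces to the classical `F2 L^3 / (48 EI)` as `F1 -> 0` and to the
#' taut-string limit `F2 L / (4 F1)` as `F1 -> Inf`.
#'
#' @param L Span, nm (> 0).
#' @param EI Flexural rigidity, nN nm^2 (> 0).
#' @param F1 Axial tension, nN (>= 0, vectorised).
#' @param F2 Central transverse load, nN.
#' @return Midspan deflection in nm.
#' @examples
#' beam_tension_deflection(1000, 1e6, 0, 1)  # classical 20.83 nm
#' @export
beam_tension_deflection <- function(L, EI, F1 = 0, F2) {
  if (L <= 0 || EI <= 0)
    afm_error("afm_invalid_argument", "L and EI must be > 0")
  if (any(F1 < 0))
    afm_error("afm_invalid_argument", "axial tension F1 must be >= 0")
  u <- (L / 2) * sqrt(F1 / EI)
  f <- ifelse(u < 1e-3,
              1 - 2 * u^2 / 5 + 17 * u^4 / 105,   # series, avoids 0/0
              3 * (u - tanh(u)) / u^3)
  F2 * L^3 / (48 * EI) * f
}

#' Single-beam finite-element deflection (assembler validation path)
#'
#' Discretises one simply supported beam into `n_elements` of the same
#' 3D beam elements (material + geometric stiffness) used by the network
#' assembler, applies a central transverse load and the axial tension as a
#' prestress force, and returns the midspan deflection. Serves as the FE
#' counterpart of [beam_tension_deflection()] for oracle-equivalence checks.
#'
#' @param L Span, nm.
#' @param EI Flexural rigidity, nN nm^2.
#' @param F1 Axial tension, nN (>= 0).
#' @param F2 Central transverse load, nN.
#' @param n_elements Even number of elements (default 200).
#' @return Midspan deflection in nm (positive, in the load direction).
#' @export
beam_fe_deflection <- function(L, EI, F1 = 0, F2, n_elements = 200) {
  if (n_elements %% 2 != 0)
    afm_error("afm_invalid_argument", "n_elements must be even")
  nn <- n_elements + 1L
  xs <- seq(0, L, length.out = nn)
  ndof <- 6L * nn
  # unit section properties; bending controlled entirely by E = EI
  E <- EI; A <- 1; I <- 1; J <- 1; G <- E / 2.6
  ii <- jj <- vv <- vector("list", n_elements)
  for (e in seq_len(n_elements)) {
    Ke <- beam_element(c(xs[e], 0, 0), c(xs[e + 1L], 0, 0),
                       E, G, A, I, J, N_axial = F1)
    dofs <- c((e - 1L) * 6L + 1:6, e * 6L + 1:6)
    ii[[e]] <- rep(dofs, times = 12L)
    jj[[e]] <- rep(dofs, each = 12L)
    vv[[e]] <- as.numeric(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(ndof, ndof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  # simply supported: translations fixed at both ends, torsion at one end;
  # axial fixed at one end to remove the rigid axial mode
  fixed <- c(1:4, (nn - 1L) * 6L + 2:3)
  free <- setdiff(seq_len(ndof), fixed)
  f <- numeric(ndof)
  mid <- n_elements %/% 2L
  f[mid * 6L + 3L] <- -F2                 # transverse load on w at midspan
  w <- numeric(ndof)
  w[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], f[free]))
  -w[mid * 6L + 3L]
}
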