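# Pa -> nN/nm^2 (internal FE stress unit, = GPa)
PA <- 1e-9

#' Conical indenter description
#'
#' A sphere-capped cone: spherical apex of curvature radius `tip_radius`
#' blending tangentially into a cone of `half_angle_deg` measured from the
#' indentation axis. `shape(rho)` gives the height of the indenter surface
#' above its apex at in-plane distance `rho`.
#'
#' @param tip_radius Apex curvature radius, nm (default 50).
#' @param travel Total indentation travel, nm (default 100, >= 0).
#' @param steps Number of quasi-static increments (default 10).
#' @param half_angle_deg Cone half-angle from the axis, degrees.
#' @return An `afm_indenter` list with a vectorised `shape` function.
#' @export
afm_indenter <- function(tip_radius = 50, travel = 100, steps = 10,
                         half_angle_deg = 20) {
  if (tip_radius <= 0) afm_error("afm_invalid_argument", "tip_radius > 0")
  if (travel < 0) afm_error("afm_invalid_argument", "travel must be >= 0")
  if (steps < 1) afm_error("afm_invalid_argument", "steps must be >= 1")
  if (half_angle_deg <= 5 || half_angle_deg >= 85)
    afm_error("afm_invalid_argument", "half_angle_deg must be in (5, 85)")
  a <- half_angle_deg * pi / 180
  rho_t <- tip_radius * cos(a)           # sphere/cone tangency radius
  s_t <- tip_radius * (1 - sin(a))
  shape <- function(rho) {
    rho <- abs(rho)
    ifelse(rho <= rho_t,
           tip_radius - sqrt(pmax(tip_radius^2 - rho^2, 0)),
           s_t + (rho - rho_t) / tan(a))
  }
  structure(list(tip_radius = tip_radius, travel = travel, steps = steps,
                 half_angle_deg = half_angle_deg, shape = shape),
            class = "afm_indenter")
}

# Assemble the global material + geometric sparse stiffness (6 dof/node).
assemble_stiffness <- function(model) {
  nodes <- model$nodes
  ndof <- 6L * nrow(nodes)
  mat <- model$materials
  t_mem <- model$membrane_thickness
  E_mem <- mat$E_membrane * PA
  sig_mem <- model$prestress[["membrane"]] * PA
  tension <- sig_mem * t_mem            # nN/nm

  ii <- vector("list", nrow(model$beams) + 4L * nrow(model$triangles))
  jj <- ii
  vv <- ii
  blk <- 0L
  dof6 <- function(nd) rep((nd - 1L) * 6L, each = 6L) + 1:6

  for (e in seq_len(nrow(model$beams))) {
    n1 <- model$beams$n1[e]; n2 <- model$beams$n2[e]
    A <- model$beams$area[e]
    is_bundle <- model$beams$type[e] == "bundle"
    E <- (if (is_bundle) mat$E_bundle else mat$E_filament) * PA
    G <- E / (2 * (1 + mat$nu_beam))
    I <- A^2 / (4 * pi)                 # circular section
    J <- 2 * I
    sig <- model$prestress[[if (is_bundle) "bundle" else "filament"]] * PA
    Ke <- beam_element(as.numeric(nodes[n1, ]), as.numeric(nodes[n2, ]),
                       E, G, A, I, J, N_axial = sig * A)
    dofs <- c(dof6(n1), dof6(n2))
    blk <- blk + 1L
    ii[[blk]] <- rep(dofs, times = 12L)
    jj[[blk]] <- rep(dofs, each = 12L)
    vv[[blk]] <- as.numeric(Ke)
  }

  for (e in seq_len(nrow(model$triangles))) {
    tri <- model$triangles[e, ]
    xy <- as.matrix(nodes[tri, c("x", "y")])
    Km <- cst_membrane_stiffness(xy, E_mem, mat$nu_membrane, t_mem)
    duv <- as.integer(rbind((tri - 1L) * 6L + 1L, (tri - 1L) * 6L + 2L))
    blk <- blk + 1L
    ii[[blk]] <- rep(duv, times = 6L)
    jj[[blk]] <- rep(duv, each = 6L)
    vv[[blk]] <- as.numeric(Km)
    if (tension > 0) {
      Kg <- cst_geometric_stiffness(xy, tension)
      for (comp in 1:3) {
        d <- (tri - 1L) * 6L + comp
        blk <- blk + 1L
        ii[[blk]] <- rep(d, times = 3L)
        jj[[blk]] <- rep(d, each = 3L)
        vv[[blk]] <- as.numeric(Kg)
      }
    }
  }

  K <- Matrix::sparseMatrix(i = unlist(ii[seq_len(blk)]),
                            j = unlist(jj[seq_len(blk)]),
                            x = unlist(vv[seq_len(blk)]),
                            dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Simulate conical-tip indentation of the prestressed network
#'
#' Quasi-static incremental solution: the tip advances in `steps` equal
#' increments; at each depth the membrane nodes inside the cone's current
#' footprint are prescribed to follow the indenter surface, and the
#' linearised equilibrium (material + prestress geometric stiffness, constant
#' over the run) is solved for all free degrees of freedom. Edge nodes are
#' clamped. Membrane element stresses are recovered with the leading
#' deflection-gradient (von Karman) strain terms plus the isotropic prestress
#' baseline.
#'
#' @param model A [build_network()] model, optionally with
#'   [apply_prestress()] applied.
#' @param indenter An [afm_indenter()].
#' @return An `afm_simresult`: `nodal_displacement` (data frame, nm),
#'   `element_stress` (per membrane triangle: centroid, sigma_xx/yy/xy,
#'   von Mises `vm` and max principal `p1`, Pa), `max_membrane_stress`
#'   (Pa, von Mises), `step_summary` (per increment: depth, contact count,
#'   max stress, centre and first-off-centre deflection), `contact_nodes`,
#'   plus the model and indenter.
#' @export
simulate_indentation <- function(model, indenter = afm_indenter()) {
  stopifnot(inherits(model, "network_model"), inherits(indenter, "afm_indenter"))
  nodes <- model$nodes
  nn <- nrow(nodes)
  ndof <- 6L * nn
  clamped <- as.integer(outer((model$boundary_nodes - 1L) * 6L, 1:6, "+"))

  rho <- sqrt(nodes$x^2 + nodes$y^2)
  s_rho <- indenter$shape(rho)

  center_node <- which(nodes$x == 0 & nodes$y == 0)[1]
  off_node <- which(nodes$y == 0 & nodes$x == model$filament_spacing)[1]

  if (indenter$travel == 0) {
    u <- numeric(ndof)
    stress <- recover_membrane_stress(model, u)
    return(make_simresult(model, indenter, u, stress,
                          step_summary = data.frame(), contact = integer()))
  }

  K <- assemble_stiffness(model)
  free0 <- setdiff(seq_len(ndof), clamped)
  ch <- tryCatch(Matrix::Cholesky(K[free0, free0, drop = FALSE]),
                 error = function(e) e)
  if (inherits(ch, "error"))
    afm_error("afm_solver_error",
              paste("stiffness not positive definite after boundary",
                    "conditions:", conditionMessage(ch)))

  u <- numeric(ndof)
  steps <- indenter$steps
  summ <- vector("list", steps)
  contact <- integer()

  solve_at <- function(active, depth, second_pass = TRUE) {
    pres <- (active - 1L) * 6L + 3L           # uz of contact nodes
    u <- numeric(ndof)
    u[pres] <- -(depth - s_rho[active])
    fixed <- c(clamped, pres)
    free <- setdiff(seq_len(ndof), fixed)
    rhs <- -K[free, fixed, drop = FALSE] %*% u[fixed]
    sol <- tryCatch(Matrix::solve(K[free, free, drop = FALSE], rhs),
                    error = function(e) e)
    if (inherits(sol, "error"))
      afm_error("afm_solver_error",
                paste("contact solve failed:", conditionMessage(sol)))
    u[free] <- as.numeric(sol)
    if (second_pass) {
      # one von Karman correction pass: the quadratic deflection-gradient
      # membrane strain acts as an in-plane load, letting smooth far-field
      # strain relax through in-plane motion (one Picard iteration)
      fnl <- membrane_nl_forces(model, u)
      sol2 <- tryCatch(
        Matrix::solve(K[free, free, drop = FALSE], fnl[free] + rhs),
        error = function(e) e)
      if (!inherits(sol2, "error")) u[free] <- as.numeric(sol2)
    }
    u
  }

  for (s in seq_len(steps)) {
    depth <- indenter$travel * s / steps
    cand <- setdiff(which(s_rho < depth), model$boundary_nodes)
    if (length(cand) == 0)
      afm_error("afm_solver_error",
                "indenter footprint contains no mesh node; refine the mesh")
    # unilateral contact by a growing active set: prescribe only nodes that
    # would otherwise rise above the tip surface (w > -(depth - s(rho)))
    active <- sort(unique(c(contact, cand[which.min(s_rho[cand])])))
    repeat {
      u <- solve_at(active, depth, second_pass = FALSE)
      target <- -(depth - s_rho[cand])
      viol <- cand[!(cand %in% active) &
                     u[(cand - 1L) * 6L + 3L] > target + 1e-9]
      if (length(viol) == 0) break
      active <- sort(unique(c(active, viol)))
    }
    contact <- active
    u <- solve_at(active, depth, second_pass = TRUE)
    stress <- recover_membrane_stress(model, u)
    summ[[s]] <- data.frame(
      step = s, depth = depth, n_contact = length(contact),
      max_vm = max(stress$vm), max_p1 = max(stress$p1),
      w_center = u[(center_node - 1L) * 6L + 3L],
      w_first_free = if (is.na(off_node)) NA_real_
                     else u[(off_node - 1L) * 6L + 3L])
  }
  make_simresult(model, indenter, u, stress, do.call(rbind, summ), contact)
}

make_simresult <- function(model, indenter, u, stress, step_summary, contact) {
  nn <- nrow(model$nodes)
  disp <- data.frame(model$nodes,
                     ux = u[(seq_len(nn) - 1L) * 6L + 1L],
                     uy = u[(seq_len(nn) - 1L) * 6L + 2L],
                     uz = u[(seq_len(nn) - 1L) * 6L + 3L])
  structure(
    list(nodal_displacement = disp, element_stress = stress,
         max_membrane_stress = if (nrow(stress)) max(stress$vm) else NA_real_,
         step_summary = step_summary, contact_nodes = contact,
         prestressed = any(model$prestress > 0),
         model = model, indenter = indenter),
    class = "afm_simresult"
  )
}

# Equivalent nodal forces (in-plane dofs) of the quadratic deflection-
# gradient membrane strain: r = -sum_e t A B' D eps_nl.
membrane_nl_forces <- function(model, u) {
  nodes <- model$nodes
  mat <- model$materials
  E <- mat$E_membrane * PA
  nu <- mat$nu_membrane
  t_mem <- model$membrane_thickness
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3)
  r <- numeric(6L * nrow(nodes))
  for (e in seq_len(nrow(model$triangles))) {
    tri <- model$triangles[e, ]
    xy <- as.matrix(nodes[tri, c("x", "y")])
    g <- cst_geometry(xy)
    gw <- g$G %*% u[(tri - 1L) * 6L + 3L]
    eps_nl <- c(0.5 * gw[1]^2, 0.5 * gw[2]^2, gw[1] * gw[2])
    B <- matrix(0, 3, 6)
    B[1, c(1, 3, 5)] <- g$G[1, ]
    B[2, c(2, 4, 6)] <- g$G[2, ]
    B[3, c(1, 3, 5)] <- g$G[2, ]
    B[3, c(2, 4, 6)] <- g$G[1, ]
    fe <- -t_mem * g$area * as.numeric(t(B) %*% (D %*% eps_nl))
    duv <- as.integer(rbind((tri - 1L) * 6L + 1L, (tri - 1L) * 6L + 2L))
    r[duv] <- r[duv] + fe
  }
  r
}

# Membrane element stress (Pa) from the displacement vector, including the
# quadratic deflection-gradient strain and the isotropic prestress baseline.
recover_membrane_stress <- function(model, u) {
  nodes <- model$nodes
  mat <- model$materials
  E <- mat$E_membrane * PA
  nu <- mat$nu_membrane
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3)
  sig0 <- model$prestress[["membrane"]] * PA
  ntri <- nrow(model$triangles)
  out <- matrix(0, ntri, 7)
  for (e in seq_len(ntri)) {
    tri <- model$triangles[e, ]
    xy <- as.matrix(nodes[tri, c("x", "y")])
    g <- cst_geometry(xy)
    du <- u[(tri - 1L) * 6L + 1L]
    dv <- u[(tri - 1L) * 6L + 2L]
    dw <- u[(tri - 1L) * 6L + 3L]
    gu <- g$G %*% du; gv <- g$G %*% dv; gw <- g$G %*% dw
    eps <- c(gu[1] + 0.5 * gw[1]^2,
             gv[2] + 0.5 * gw[2]^2,
             gu[2] + gv[1] + gw[1] * gw[2])
    sig <- as.numeric(D %*% eps) + c(sig0, sig0, 0)
    vm <- sqrt(sig[1]^2 - sig[1] * sig[2] + sig[2]^2 + 3 * sig[3]^2)
    p1 <- (sig[1] + sig[2]) / 2 +
      sqrt(((sig[1] - sig[2]) / 2)^2 + sig[3]^2)
    out[e, ] <- c(mean(xy[, 1]), mean(xy[, 2]), sig, vm, p1)
  }
  data.frame(cx = out[, 1], cy = out[, 2],
             sxx = out[, 3] / PA, syy = out[, 4] / PA, sxy = out[, 5] / PA,
             vm = out[, 6] / PA, p1 = out[, 7] / PA)
}

#' @export
print.afm_simresult <- function(x, ...) {
  cat(sprintf(
    "<afm_simresult> %s | travel %.0f nm | max membrane stress %.4g Pa (vM)\n",
    if (x$prestressed) "prestressed" else "no prestress",
    x$indenter$travel, x$max_membrane_stress))
  invisible(x)
}

#' Midline displacement and stress profile
#'
#' Extracts the z-displacement and membrane stress along the x-axis midline
#' (y = 0): displacement at midline nodes, stress by averaging element values
#' onto nodes. Also reports the full width at half maximum (FWHM) of the
#' stress peak, measured above the profile's far-field level -- the spatial
#' extent of the stress concentration under the tip.
#'
#' @param result An `afm_simresult` from [simulate_indentation()].
#' @param measure `"vm"` (von Mises, default) or `"p1"` (max principal).
#' @return List with `x` (nm), `w_z` (nm), `stress` (Pa), `measure`,
#'   `fwhm` (nm) and `fwhm_displacement` (nm, FWHM of the deflection basin).
#' @export
midline_profile <- function(result, measure = c("vm", "p1")) {
  stopifnot(inherits(result, "afm_simresult"))
  measure <- match.arg(measure)
  model <- result$model
  nodes <- model$nodes
  mid <- which(nodes$y == 0)
  mid <- mid[order(nodes$x[mid])]
  w_z <- result$nodal_displacement$uz[mid]

  es <- result$element_stress
  val <- es[[measure]]
  nodal <- numeric(length(mid))
  for (q in seq_along(mid)) {
    nd <- mid[q]
    adj <- which(model$triangles[, 1] == nd | model$triangles[, 2] == nd |
                   model$triangles[, 3] == nd)
    nodal[q] <- mean(val[adj])
  }
  x <- nodes$x[mid]
  list(x = x, w_z = w_z, stress = nodal, measure = measure,
       fwhm = profile_fwhm(x, nodal),
       fwhm_displacement = profile_fwhm(x, -w_z))
}

# Full width at half maximum of a single-peaked profile, above its far-field
# (minimum) level, with linear interpolation at the crossings.
profile_fwhm <- function(x, y) {
  base <- min(y)
  pk <- which.max(y)
  half <- base + (y[pk] - base) / 2
  if (y[pk] <= base) return(NA_real_)
  xl <- NA_real_; xr <- NA_real_
  for (i in seq(pk, 2)) {
    if (y[i - 1] <= half && y[i] > half) {
      xl <- x[i - 1] + (x[i] - x[i - 1]) * (half - y[i - 1]) / (y[i] - y[i - 1])
      break
    }
  }
  for (i in seq(pk, length(y) - 1)) {
    if (y[i + 1] <= half && y[i] > half) {
      xr <- x[i] + (x[i + 1] - x[i]) * (y[i] - half) / (y[i] - y[i + 1])
      break
    }
  }
  xr - xl
}
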