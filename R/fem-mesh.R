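#' Build the membrane / filament-network model
#'
#' Constructs a square patch of cell cortex: a flat triangulated membrane
#' (constant-strain triangles with no bending stiffness) conforming to an
#' orthogonal grid of cross-linked actin-filament beams, with a configurable
#' number of stress-fibre lines (thicker beams) laid along the x axis, the
#' cell's long axis. Membrane, filaments and bundles share the grid nodes,
#' which realises the tie constraint (no relative motion at junctions). All
#' edge nodes are fully clamped.
#'
#' @param half_width Half-width of the square domain, nm; must be at least
#'   5 x `filament_spacing` and an integer multiple of it.
#' @param filament_spacing Grid spacing, nm.
#' @param fiber_lines Number of stress-fibre lines along x (default 3),
#'   placed on equally spaced interior grid rows, symmetric about the centre.
#' @param membrane_thickness Membrane thickness, nm (default 5).
#' @param filament_area,bundle_area Beam cross-section areas, nm^2
#'   (defaults 38.46 and 400).
#' @param materials List of material constants: `E_membrane` (Pa, default
#'   5e4), `nu_membrane` (default 0.5), `E_filament` and `E_bundle` (Pa,
#'   default 2e6), `nu_beam` (default 0.3). The defaults are coarse-grained
#'   *effective* moduli chosen so that, under the reference prestress triple
#'   (100 Pa membrane, 50 kPa filaments and fibres), the simulated membrane
#'   stress has the same order of magnitude as published indentation
#'   simulations (~0.4-0.7 kPa at 100 nm travel) and the prestress carries
#'   mechanical weight comparable to filament bending; bulk-actin GPa moduli
#'   would make a 50 kPa prestress a <1% perturbation.
#' @return An object of class `network_model` with `nodes` (data frame x, y,
#'   z in nm), `beams` (n1, n2, type, area), `triangles` (3-column index
#'   matrix), `boundary_nodes`, geometry and material fields, and a zero
#'   `prestress` triple (membrane, filament, bundle; Pa).
#' @export
build_network <- function(half_width = 1000, filament_spacing = 100,
                          fiber_lines = 3, membrane_thickness = 5,
                          filament_area = 38.46, bundle_area = 400,
                          materials = list()) {
  if (half_width < 5 * filament_spacing)
    afm_error("afm_mesh_error",
              "half_width must be at least 5 x filament_spacing")
  n_cells <- half_width / filament_spacing
  if (abs(n_cells - round(n_cells)) > 1e-9)
    afm_error("afm_mesh_error",
              "half_width must be an integer multiple of filament_spacing")
  g <- seq(-half_width, half_width, by = filament_spacing)
  n <- length(g)
  nodes <- data.frame(x = rep(g, times = n), y = rep(g, each = n), z = 0)
  nid <- function(i, j) (j - 1L) * n + i

  mat <- utils::modifyList(list(E_membrane = 5e4, nu_membrane = 0.5,
                                E_filament = 2e6, E_bundle = 2e6,
                                nu_beam = 0.3), materials)

  fiber_rows <- if (fiber_lines > 0) {
    r <- round(seq(1, n, length.out = fiber_lines + 2))[2:(fiber_lines + 1)]
    unique(as.integer(r))
  } else integer(0)

  beams <- vector("list", 2L * n * (n - 1L))
  b <- 0L
  for (j in seq_len(n)) {            # along x
    type <- if (j %in% fiber_rows) "bundle" else "filament"
    for (i in seq_len(n - 1L)) {
      b <- b + 1L
      beams[[b]] <- c(nid(i, j), nid(i + 1L, j),
                      if (type == "bundle") 2L else 1L)
    }
  }
  for (i in seq_len(n)) {            # along y (always filaments)
    for (j in seq_len(n - 1L)) {
      b <- b + 1L
      beams[[b]] <- c(nid(i, j), nid(i, j + 1L), 1L)
    }
  }
  bm <- do.call(rbind, beams)
  beams <- data.frame(n1 = bm[, 1], n2 = bm[, 2],
                      type = c("filament", "bundle")[bm[, 3]],
                      area = c(filament_area, bundle_area)[bm[, 3]],
                      stringsAsFactors = FALSE)

  tris <- matrix(0L, 2L * (n - 1L)^2, 3L)
  t_ <- 0L
  for (j in seq_len(n - 1L)) {
    for (i in seq_len(n - 1L)) {
      bl <- nid(i, j); br <- nid(i + 1L, j)
      tl <- nid(i, j + 1L); tr <- nid(i + 1L, j + 1L)
      if ((i + j) %% 2L == 0L) {     # checkerboard diagonal for symmetry
        tris[t_ + 1L, ] <- c(bl, br, tr)
        tris[t_ + 2L, ] <- c(bl, tr, tl)
      } else {
        tris[t_ + 1L, ] <- c(br, tr, tl)
        tris[t_ + 2L, ] <- c(br, tl, bl)
      }
      t_ <- t_ + 2L
    }
  }

  on_edge <- nodes$x %in% range(g) | nodes$y %in% range(g)
  structure(
    list(nodes = nodes, beams = beams, triangles = tris,
         boundary_nodes = which(on_edge),
         half_width = half_width, filament_spacing = filament_spacing,
         fiber_rows = fiber_rows, n_grid = n,
         membrane_thickness = membrane_thickness,
         materials = mat,
         prestress = c(membrane = 0, filament = 0, bundle = 0)),
    class = "network_model"
  )
}

#' Apply prestress to a network model
#'
#' Stores the prestress state used by the simulator: each beam gets an
#' initial axial force `N = sigma * A` and the membrane an isotropic tension
#' `sigma * t` per unit length; both enter the geometric (stress) stiffness
#' at assembly, and the membrane stress enters the reported stress field as
#' its baseline. A uniform prestress with clamped edges is self-equilibrated,
#' so no initial nodal forces arise.
#'
#' @param model A [build_network()] model.
#' @param membrane Membrane prestress, Pa (>= 0); 100 Pa in the prestressed
#'   reference case.
#' @param filament,bundle Axial prestress of filaments and stress fibres, Pa
#'   (>= 0); 50 kPa each in the prestressed reference case.
#' @return The model with its `prestress` field set.
#' @export
apply_prestress <- function(model, membrane = 0, filament = 0, bundle = 0) {
  stopifnot(inherits(model, "network_model"))
  if (membrane < 0 || filament < 0 || bundle < 0)
    afm_error("afm_invalid_argument", "prestress components must be >= 0")
  model$prestress <- c(membrane = membrane, filament = filament,
                       bundle = bundle)
  model
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "<network_model> %d nodes | %d beams (%d bundles) | %d membrane triangles\n",
    nrow(x$nodes), nrow(x$beams), sum(x$beams$type == "bundle"),
    nrow(x$triangles)))
  cat(sprintf(
    "  domain %.0f x %.0f nm, spacing %.0f nm | prestress m/f/b = %s Pa\n",
    2 * x$half_width, 2 * x$half_width, x$filament_spacing,
    paste(format(x$prestress, trim = TRUE), collapse = "/")))
  invisible(x)
}
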