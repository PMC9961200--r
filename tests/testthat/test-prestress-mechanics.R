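# Prestressed network mechanics: mesh construction, prestress bookkeeping,
# indentation solves, tensioned-beam theory.

test_that("mesh counts follow the grid combinatorics", {
  m <- build_network(half_width = 1000, filament_spacing = 200)
  n <- 11L  # 2*1000/200 + 1 grid lines
  expect_identical(nrow(m$nodes), n * n)
  expect_identical(nrow(m$beams), 2L * n * (n - 1L))      # 220
  expect_identical(nrow(m$triangles), 2L * (n - 1L) * (n - 1L))  # 200
  expect_identical(sum(m$beams$type == "bundle"), 3L * (n - 1L))
  expect_setequal(unique(m$beams$area[m$beams$type == "filament"]), 38.46)
  expect_setequal(unique(m$beams$area[m$beams$type == "bundle"]), 400)
})

test_that("degenerate geometry is rejected", {
  expect_error(build_network(half_width = 100, filament_spacing = 200),
               class = "afm_mesh_error")
  expect_error(build_network(half_width = 1000, filament_spacing = 300),
               class = "afm_mesh_error")
})

test_that("the node set is mirror symmetric in x and y", {
  m <- build_network(half_width = 800, filament_spacing = 100)
  key <- function(df) sort(paste(df$x, df$y))
  expect_identical(key(m$nodes),
                   key(transform(m$nodes, x = -x)))
  expect_identical(key(m$nodes),
                   key(transform(m$nodes, y = -y)))
  # edge nodes are exactly the boundary set
  expect_identical(sort(m$boundary_nodes),
                   which(abs(m$nodes$x) == 800 | abs(m$nodes$y) == 800))
})

test_that("prestress bookkeeping follows sigma * A and sigma * t", {
  m <- small_network()
  expect_identical(apply_prestress(m, 0, 0, 0), m)  # zero spec is a no-op
  mp <- apply_prestress(m, 100, 5e4, 5e4)
  expect_identical(mp$prestress,
                   c(membrane = 100, filament = 5e4, bundle = 5e4))
  expect_error(apply_prestress(m, -1, 0, 0), class = "afm_invalid_argument")
  # N = sigma A: 50 kPa on 38.46 nm^2 is 1.923e-3 nN (1.923e-12 N); the
  # element geometric stiffness must carry 6/5 * N / L on its diagonal
  N <- 5e4 * 1e-9 * 38.46
  expect_equal(N, 1.923e-3, tolerance = 1e-12)
  Kg <- afmindent:::beam_geometric_stiffness(N, 100)
  expect_equal(Kg[2, 2], 6 / 5 * N / 100)
  expect_equal(Kg[3, 3], 6 / 5 * N / 100)
})

test_that("zero travel leaves only the prestress state", {
  m <- reference_prestress(small_network())
  r <- simulate_indentation(m, afm_indenter(travel = 0))
  expect_true(all(r$nodal_displacement$uz == 0))
  expect_equal(max(abs(r$element_stress$vm - 100)), 0, tolerance = 1e-9)
  r0 <- simulate_indentation(small_network(), afm_indenter(travel = 0))
  expect_equal(max(r0$element_stress$vm), 0, tolerance = 1e-12)
})

test_that("prestress stiffens, concentrates and raises membrane stress", {
  ind <- afm_indenter(travel = 100, steps = 5)
  r0 <- cached("small_nopre", simulate_indentation(small_network(), ind))
  r1 <- cached("small_pre",
               simulate_indentation(reference_prestress(small_network()), ind))
  expect_gt(r1$max_membrane_stress, r0$max_membrane_stress)
  p0 <- midline_profile(r0); p1 <- midline_profile(r1)
  expect_lt(p1$fwhm, p0$fwhm)
  # membrane deflection next to the contact is smaller with prestress
  w0 <- tail(r0$step_summary$w_first_free, 1)
  w1 <- tail(r1$step_summary$w_first_free, 1)
  expect_lt(abs(w1), abs(w0))
  # clamped nodes do not move
  bdofs <- r1$nodal_displacement[r1$model$boundary_nodes, c("ux", "uy", "uz")]
  expect_equal(max(abs(as.matrix(bdofs))), 0)
})

test_that("midline profiles are symmetric about the indentation axis", {
  ind <- afm_indenter(travel = 100, steps = 5)
  r1 <- cached("small_pre",
               simulate_indentation(reference_prestress(small_network()), ind))
  p <- midline_profile(r1)
  expect_lt(max(abs(p$w_z - rev(p$w_z))) / max(abs(p$w_z)), 0.01)
  expect_lt(max(abs(p$stress - rev(p$stress))) / max(p$stress), 0.01)
})

test_that("response is linear in depth in the small-deformation regime", {
  m <- reference_prestress(small_network())
  r1 <- simulate_indentation(m, afm_indenter(travel = 1, steps = 1))
  r2 <- simulate_indentation(m, afm_indenter(travel = 2, steps = 1))
  off <- which(m$nodes$y == 0 & m$nodes$x == m$filament_spacing)
  w1 <- r1$nodal_displacement$uz[off]
  w2 <- r2$nodal_displacement$uz[off]
  expect_equal(w2 / w1, 2, tolerance = 0.02)
})

test_that("max membrane stress is non-decreasing in the prestress state", {
  # the full triple (100 Pa, 50 kPa, 50 kPa) scaled jointly; per-component
  # sweeps interact through load redistribution and are not monotone
  ind <- afm_indenter(travel = 100, steps = 2)
  ms <- vapply(c(0, 0.5, 1, 2), function(s) {
    m <- apply_prestress(small_network(), 100 * s, 5e4 * s, 5e4 * s)
    simulate_indentation(m, ind)$max_membrane_stress
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("boundary-distance study shows decreasing max-stress changes", {
  ind <- afm_indenter(travel = 100, steps = 2)
  ms <- vapply(c(500, 1000, 1500), function(hw) {
    m <- apply_prestress(build_network(half_width = hw,
                                       filament_spacing = 100),
                         100, 5e4, 5e4)
    simulate_indentation(m, ind)$max_membrane_stress
  }, numeric(1))
  d <- abs(diff(ms))
  expect_lt(d[2], d[1])
})

test_that("tensioned-beam closed form has the right limits", {
  # classical central-load limit F2 L^3 / (48 EI)
  expect_equal(beam_tension_deflection(1000, 1e6, 0, 1), 1000^3 / 48e6,
               tolerance = 1e-12)
  # taut-string limit F2 L / (4 F1), monotone decrease toward zero
  f1s <- 10^seq(-2, 4, by = 1)
  ws <- beam_tension_deflection(1000, 1e6, f1s, 1)
  expect_true(all(diff(ws) < 0))
  expect_equal(beam_tension_deflection(1000, 1e6, 1e6, 1),
               1 * 1000 / (4 * 1e6), tolerance = 1e-3)
  expect_error(beam_tension_deflection(-1, 1e6, 0, 1),
               class = "afm_invalid_argument")
})

test_that("closed form matches an independent finite-difference oracle", {
  # frozen from a 2000-interval central-difference solve of
  # EI w'''' - F1 w'' = F2 delta(midspan) with simply supported ends (numpy)
  expect_equal(beam_tension_deflection(1000, 1e6, 0.5, 1), 19.84187550117262,
               tolerance = 5e-5)
  expect_equal(beam_tension_deflection(1000, 1e6, 10, 1), 10.47283171945293,
               tolerance = 5e-5)
})

test_that("the beam-element path reproduces the closed form to 0.5%", {
  for (F1 in c(0, 0.05, 0.5, 10)) {
    wfe <- beam_fe_deflection(1000, 1e6, F1, 1, n_elements = 200)
    wcf <- beam_tension_deflection(1000, 1e6, F1, 1)
    expect_lt(abs(wfe - wcf) / wcf, 0.005)
  }
  # h-refinement error against the closed form strictly decreases
  errs <- vapply(c(8, 16, 32), function(ne)
    abs(beam_fe_deflection(1000, 1e6, 0.5, 1, ne) -
          beam_tension_deflection(1000, 1e6, 0.5, 1)), numeric(1))
  expect_true(all(diff(errs) < 0))
})
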