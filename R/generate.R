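# Quadratic substrate-stiffening coefficient, nN/nm^2 (2 nN/um^2). Fixed so
# the 12 nN trigger is always reachable inside the 6 um piezo range.
SUBSTRATE_QUAD <- 2e-6

# Clean elastic loading force (nN) vs piezo travel past contact u (nm),
# before any drop. Pyramid: linear in corrected depth. Sphere: Hertz in
# corrected depth, solved pointwise for the implicit deflection coupling.
elastic_force <- function(u, params) {
  k <- params$spring_constant            # N/m == nN/nm
  if (params$tip_kind == "pyramid") {
    s <- params$membrane_slope / 1000    # nN/um -> nN/nm
    s_eff <- s / (1 + s / k)
    f <- s_eff * u
  } else {
    C <- hertz_force(params$cell_modulus, params$tip_radius, 0.5, 1) # nN @ 1nm
    # solve u = delta + C*delta^1.5/k for delta, vectorised Newton
    delta <- pmax(u, 0)
    for (it in 1:60) {
      h <- delta + C * delta^1.5 / k - u
      dh <- 1 + 1.5 * C * sqrt(pmax(delta, 0)) / k
      step <- h / dh
      delta <- pmax(delta - step, 0)
      if (max(abs(step)) < 1e-12) break
    }
    f <- C * delta^1.5
  }
  f
}

substrate_force <- function(u, params) {
  onset <- params$substrate_onset_depth * 1000  # um -> nm
  SUBSTRATE_QUAD * pmax(u - onset, 0)^2
}

# Truncated-normal draw via rejection (support (lo, hi)); falls back to the
# clamped mean if the window is improbably narrow.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- rnorm(200, mean, sd)
    x <- x[x > lo & x < hi]
    out[i] <- if (length(x)) x[1] else min(max(mean, lo), hi)
  }
  out
}

#' Generate one synthetic force-distance curve
#'
#' Builds an approach trace with the four-stage morphology observed in
#' pyramidal-tip indentation of adherent cells: zero-mean noise before
#' contact (O-A), an elastic loading segment from the contact point
#' (linear for pyramids, Hertzian for spheres; A-B), an instantaneous force
#' drop at each penetration event (B, and optionally D at the nucleus), a
#' stiffer post-drop segment plus a quadratic substrate term beyond
#' `substrate_onset_depth`, and termination at the first sample reaching the
#' trigger force (C). Ground truth (true contact point, event indices,
#' insertion forces, drop magnitudes, corrected insertion displacements and
#' times) is recorded for use as a test oracle.
#'
#' The noise sample immediately after a planted drop is clamped so that the
#' observed negative step always exceeds 5 x `noise_sd`, keeping ground-truth
#' labels consistent with the trace.
#'
#' @param params A [curve_gen_params()] object.
#' @return A [force_curve()] with a `ground_truth` element.
#' @export
generate_curve <- function(params) {
  validate_curve_gen_params(params)
  with_seed(params$seed, generate_curve_impl(params))
}

generate_curve_impl <- function(params) {
  k <- params$spring_constant
  dz <- params$z_step_nm
  z <- seq(0, params$z_max_um * 1000, by = dz)
  zA <- params$contact_z * 1000
  u <- pmax(z - zA, 0)

  f_clean <- elastic_force(u, params) + substrate_force(u, params)
  if (max(f_clean) < params$trigger_force)
    afm_error("afm_trigger_unreachable",
              "trigger_force unreachable within the configured piezo range")

  s_post <- (params$membrane_slope / params$post_drop_softening) / 1000
  s_post_eff <- s_post / (1 + s_post / k)

  penetrates <- runif(1) < params$penetration_probability
  events <- data.frame(index = integer(), z_nm = numeric(),
                       force = numeric(), drop = numeric(),
                       displacement_um = numeric(), time_s = numeric(),
                       rank = character(), stringsAsFactors = FALSE)

  plant_drop <- function(f, idx, drop) {
    # linear continuation from the post-drop level, substrate term continuous
    cont <- (f[idx] - drop) + s_post_eff * (z - z[idx]) +
      substrate_force(u, params) - substrate_force(u[idx], params)
    tail_idx <- seq(idx + 1L, length(f))
    f[tail_idx] <- cont[tail_idx]
    f
  }
  # an insertion event is, by definition, a resolvable force drop: drops are
  # clamped above the detectability floor and insertion forces truncated just
  # above it (0.45 nN at the default 0.05 nN noise)
  min_drop <- max(8 * params$noise_sd, 0.3)
  f1_floor <- min_drop + 0.05
  draw_drop <- function(f_at) {
    d <- runif(1, 0.3, 0.6) * f_at
    min(max(d, min_drop), 0.95 * f_at)
  }

  if (penetrates) {
    f1 <- rtrunc_norm(1, params$insertion_force_mean,
                      params$insertion_force_sd,
                      f1_floor, 0.9 * params$trigger_force)
    b1 <- which(f_clean >= f1 & u > 0)[1]
    f1_gt <- f_clean[b1]
    drop1 <- draw_drop(f1_gt)
    f_clean <- plant_drop(f_clean, b1, drop1)
    events <- rbind(events, data.frame(
      index = b1, z_nm = z[b1], force = f1_gt, drop = drop1,
      displacement_um = (u[b1] - f1_gt / k) / 1000,
      time_s = (u[b1] - f1_gt / k) / 1000 / params$approach_speed,
      rank = "membrane_first", stringsAsFactors = FALSE))

    if (runif(1) < params$second_drop_probability) {
      c_est <- which(f_clean >= params$trigger_force)
      c_est <- c_est[c_est > b1][1]
      lo <- b1 + 60L
      hi <- c_est - 15L
      if (!is.na(c_est) && hi > lo) {
        bD <- as.integer(floor(runif(1, lo, hi + 1)))
        f2_gt <- f_clean[bD]
        if (f2_gt >= f1_floor) {
          drop2 <- draw_drop(f2_gt)
          f_clean <- plant_drop(f_clean, bD, drop2)
          events <- rbind(events, data.frame(
            index = bD, z_nm = z[bD], force = f2_gt, drop = drop2,
            displacement_um = (u[bD] - f2_gt / k) / 1000,
            time_s = (u[bD] - f2_gt / k) / 1000 / params$approach_speed,
            rank = "nucleus_second", stringsAsFactors = FALSE))
        }
      }
    }
  }

  f <- f_clean + if (params$noise_sd > 0)
    rnorm(length(f_clean), 0, params$noise_sd) else 0

  # keep planted steps detectable against noise (ground-truth consistency)
  if (params$noise_sd > 0 && nrow(events) > 0) {
    for (i in events$index) {
      f[i + 1L] <- min(f[i + 1L], f[i] - 5.5 * params$noise_sd)
    }
  }

  trig <- which(f >= params$trigger_force)[1]
  if (is.na(trig))
    afm_error("afm_trigger_unreachable",
              "trigger_force unreachable within the configured piezo range")
  keep <- seq_len(trig)
  f <- pmin(f[keep], params$trigger_force * 1.05)
  z <- z[keep]
  events <- events[events$index <= trig, , drop = FALSE]

  force_curve(
    piezo_z = z, force = f,
    spring_constant = k, approach_speed = params$approach_speed,
    trigger_force = params$trigger_force, tip_kind = params$tip_kind,
    tip_radius = params$tip_radius, strain_label = params$strain_label,
    ground_truth = list(contact_z = zA, events = events),
    seed = params$seed
  )
}

#' Generate a batch of curves for one strain condition
#'
#' Produces `n` seeded curves sharing the condition's parameters. In
#' exact-count mode the number of penetrating curves is exactly
#' `round(n * penetration_probability)` with a deterministic, seed-derived
#' subset of curves carrying the event, so published penetration fractions
#' (for example 37 of 60) are reproducible; otherwise each curve penetrates
#' independently (binomial).
#'
#' @param params A [curve_gen_params()] object; `params$seed` seeds the batch.
#' @param n Number of curves (>= 1).
#' @param exact_count Logical; fix the penetrating count to
#'   `round(n * penetration_probability)` rather than drawing it binomially.
#' @return List of `n` [force_curve()] objects.
#' @export
generate_condition_set <- function(params, n, exact_count = TRUE) {
  validate_curve_gen_params(params)
  if (!is.numeric(n) || n < 1)
    afm_error("afm_invalid_params", "n must be >= 1")
  n <- as.integer(n)
  per_curve <- lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    p
  })
  if (exact_count) {
    m <- round(n * params$penetration_probability)
    pen_idx <- with_seed(derive_seed(params$seed, 999983L),
                         sample.int(n, m))
    for (i in seq_len(n)) {
      per_curve[[i]]$penetration_probability <- as.numeric(i %in% pen_idx)
    }
  }
  lapply(per_curve, generate_curve)
}
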