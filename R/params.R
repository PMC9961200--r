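#' Parameters for the synthetic force-curve generator
#'
#' Bundles everything the generator needs to emulate one experimental
#' condition: the elastic response of the cell (Hertz modulus for spherical
#' tips, linear membrane slope for pyramidal tips), the penetration
#' statistics (probability, insertion-force distribution, optional second
#' drop at the nucleus), the substrate-stiffening regime, acquisition
#' settings (trigger force, approach speed, spring constant) and noise.
#'
#' @param cell_modulus Cell elastic modulus in Pa (spherical-tip curves).
#' @param membrane_slope Linear A-B loading slope in nN/um of corrected
#'   indentation depth (pyramidal-tip curves, and the post-drop baseline).
#' @param penetration_probability Probability in `[0,1]` that a curve shows a
#'   membrane puncture (first force drop).
#' @param insertion_force_mean,insertion_force_sd Mean and SD in nN of the
#'   insertion force at which the membrane punctures. Gaussian truncated at
#'   zero and below the trigger force.
#' @param second_drop_probability Probability in `[0,1]` that a penetrating
#'   curve shows a second drop (nucleus puncture) between the first drop and
#'   the trigger point.
#' @param post_drop_softening Dimensionless factor in (0,1]; after a drop the
#'   loading slope becomes `membrane_slope / post_drop_softening` (the
#'   post-puncture curve rises faster, as observed experimentally).
#' @param substrate_onset_depth Piezo travel past contact, in um, beyond
#'   which a quadratic substrate-stiffening term is added.
#' @param noise_sd Gaussian force noise SD in nN (i.i.d. per sample).
#' @param trigger_force Retract trigger in nN; the approach trace ends at the
#'   first sample reaching it.
#' @param approach_speed Piezo approach speed in um/s.
#' @param spring_constant Cantilever spring constant in N/m.
#' @param tip_kind `"sphere"` (Hertzian loading) or `"pyramid"` (linear).
#' @param tip_radius Tip radius in um (2.25 for the spherical glass tip,
#'   0.01 for the pyramidal silicon nitride tip).
#' @param strain_label Substrate strain of the condition, in percent.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   curves.
#' @param contact_z Piezo position of the true contact point in um.
#' @param z_step_nm Piezo sampling step in nm (uniform grid).
#' @param z_max_um Maximum piezo range in um; an error is raised if the
#'   trigger force is unreachable within it.
#'
#' @return An object of class `curve_gen_params` (a validated list).
#' @seealso [generate_curve()], [generate_condition_set()],
#'   [strain_conditions()]
#' @examples
#' p <- curve_gen_params(membrane_slope = 3, penetration_probability = 1,
#'                       noise_sd = 0, seed = 7)
#' curve <- generate_curve(p)
#' @export
curve_gen_params <- function(cell_modulus = 1000,
                             membrane_slope = 2.5,
                             penetration_probability = 0.5,
                             insertion_force_mean = 2.0,
                             insertion_force_sd = 0.3,
                             second_drop_probability = 0.15,
                             post_drop_softening = 0.7,
                             substrate_onset_depth = 2.0,
                             noise_sd = 0.05,
                             trigger_force = 12,
                             approach_speed = 1,
                             spring_constant = 0.02,
                             tip_kind = c("pyramid", "sphere"),
                             tip_radius = 0.01,
                             strain_label = 0,
                             seed = 1L,
                             contact_z = 1.0,
                             z_step_nm = 2,
                             z_max_um = 6) {
  tip_kind <- match.arg(tip_kind)
  p <- list(
    cell_modulus = cell_modulus, membrane_slope = membrane_slope,
    penetration_probability = penetration_probability,
    insertion_force_mean = insertion_force_mean,
    insertion_force_sd = insertion_force_sd,
    second_drop_probability = second_drop_probability,
    post_drop_softening = post_drop_softening,
    substrate_onset_depth = substrate_onset_depth,
    noise_sd = noise_sd, trigger_force = trigger_force,
    approach_speed = approach_speed, spring_constant = spring_constant,
    tip_kind = tip_kind, tip_radius = tip_radius,
    strain_label = strain_label, seed = as.integer(seed),
    contact_z = contact_z, z_step_nm = z_step_nm, z_max_um = z_max_um
  )
  class(p) <- "curve_gen_params"
  validate_curve_gen_params(p)
  p
}

validate_curve_gen_params <- function(p) {
  chk <- function(ok, msg) if (!ok) afm_error("afm_invalid_params", msg)
  chk(p$penetration_probability >= 0 && p$penetration_probability <= 1,
      "penetration_probability must be in [0, 1]")
  chk(p$second_drop_probability >= 0 && p$second_drop_probability <= 1,
      "second_drop_probability must be in [0, 1]")
  chk(p$noise_sd >= 0, "noise_sd must be >= 0")
  chk(p$trigger_force > 0, "trigger_force must be > 0")
  chk(p$insertion_force_mean < p$trigger_force,
      "insertion_force_mean must be below trigger_force")
  chk(p$insertion_force_sd >= 0, "insertion_force_sd must be >= 0")
  chk(p$post_drop_softening > 0 && p$post_drop_softening <= 1,
      "post_drop_softening must be in (0, 1]")
  chk(p$membrane_slope > 0, "membrane_slope must be > 0")
  chk(p$cell_modulus > 0, "cell_modulus must be > 0")
  chk(p$spring_constant > 0, "spring_constant must be > 0")
  chk(p$approach_speed > 0, "approach_speed must be > 0")
  chk(p$tip_radius > 0, "tip_radius must be > 0")
  chk(p$contact_z > 0 && p$contact_z < p$z_max_um,
      "contact_z must lie inside the piezo range")
  chk(p$z_step_nm > 0, "z_step_nm must be > 0")
  invisible(p)
}

#' @export
print.curve_gen_params <- function(x, ...) {
  cat(sprintf(
    "<curve_gen_params> %s tip | strain %s%% | slope %.3g nN/um | E %.3g Pa\n",
    x$tip_kind, format(x$strain_label), x$membrane_slope, x$cell_modulus))
  cat(sprintf(
    "  penetration p=%.3g, F_ins %.3g +/- %.3g nN, trigger %.3g nN, seed %d\n",
    x$penetration_probability, x$insertion_force_mean, x$insertion_force_sd,
    x$trigger_force, x$seed))
  invisible(x)
}

#' Generator settings mirroring the five published strain conditions
#'
#' One `curve_gen_params` per substrate-strain condition (0, 5, 10, 15, 20%)
#' with the published trigger force (12 nN), approach speed (1 um/s),
#' pyramidal-tip spring constant (0.02 N/m), penetration fractions
#' 11/60, 23/60, 31/60, 36/60 and 37/60, and insertion-force distributions
#' 2.0±0.3, 1.8±0.3, 1.5±0.2, 1.0±0.2 and 1.0±0.3 nN. The A-B slope of each
#' condition is fixed at mean insertion force / mean insertion displacement
#' (1.2, 0.7, 0.5, 0.2, 0.2 um), i.e. 1.67, 2.57, 3.0, 5.0, 5.0 nN/um, so the
#' slope increases with prestress and mean displacement and time follow the
#' published values.
#'
#' @param seed Integer base seed; each condition gets a derived child seed.
#' @param noise_sd Force noise SD in nN applied to every condition.
#' @return Named list of `curve_gen_params`, names `"0"`, `"5"`, ... `"20"`.
#' @export
strain_conditions <- function(seed = 1L, noise_sd = 0.05) {
  strain <- c(0, 5, 10, 15, 20)
  n_pen  <- c(11, 23, 31, 36, 37)
  f_mean <- c(2.0, 1.8, 1.5, 1.0, 1.0)
  f_sd   <- c(0.3, 0.3, 0.2, 0.2, 0.3)
  d_mean <- c(1.2, 0.7, 0.5, 0.2, 0.2)
  out <- lapply(seq_along(strain), function(i) {
    curve_gen_params(
      membrane_slope = f_mean[i] / d_mean[i],
      penetration_probability = n_pen[i] / 60,
      insertion_force_mean = f_mean[i],
      insertion_force_sd = f_sd[i],
      second_drop_probability = 0.15,
      noise_sd = noise_sd,
      trigger_force = 12, approach_speed = 1, spring_constant = 0.02,
      tip_kind = "pyramid", tip_radius = 0.01,
      strain_label = strain[i],
      seed = derive_seed(seed, i)
    )
  })
  names(out) <- as.character(strain)
  out
}
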