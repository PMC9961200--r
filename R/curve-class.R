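#' Construct a force-distance curve object
#'
#' A `force_curve` holds one approach trace (piezo position in nm, force in
#' nN) with its acquisition metadata. Synthetic curves additionally carry a
#' `ground_truth` attribute (true contact point and planted penetration
#' events) used as an oracle by the analysis tests.
#'
#' @param piezo_z Numeric vector, piezo position in nm, monotone
#'   non-decreasing along the approach (strictly increasing after removing
#'   duplicates).
#' @param force Numeric vector of the same length, force in nN.
#' @param spring_constant Cantilever spring constant in N/m.
#' @param approach_speed Approach speed in um/s.
#' @param trigger_force Retract trigger in nN.
#' @param tip_kind `"sphere"` or `"pyramid"`.
#' @param tip_radius Tip radius in um.
#' @param strain_label Substrate strain of the condition in percent.
#' @param ground_truth Optional list with elements `contact_z` (nm) and
#'   `events` (data frame of planted drops); `NULL` for measured data.
#' @param seed Optional integer seed recorded for provenance.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(piezo_z, force, spring_constant, approach_speed,
                        trigger_force, tip_kind, tip_radius,
                        strain_label = NA_real_, ground_truth = NULL,
                        seed = NULL) {
  piezo_z <- as.numeric(piezo_z)
  force <- as.numeric(force)
  if (length(piezo_z) != length(force))
    afm_error("afm_invalid_curve", "piezo_z and force must have equal length")
  if (length(piezo_z) < 50)
    afm_error("afm_invalid_curve", "a force curve needs at least 50 samples")
  dz <- diff(piezo_z)
  if (any(dz < 0))
    afm_error("afm_invalid_curve", "piezo_z must be monotone non-decreasing")
  if (any(diff(unique(piezo_z)) <= 0))
    afm_error("afm_invalid_curve",
              "piezo_z must be strictly increasing after de-duplication")
  if (!tip_kind %in% c("sphere", "pyramid"))
    afm_error("afm_invalid_curve", "tip_kind must be 'sphere' or 'pyramid'")
  if (spring_constant <= 0)
    afm_error("afm_invalid_curve", "spring_constant must be > 0")
  if (max(force) > trigger_force * 1.1)
    afm_error("afm_invalid_curve",
              "force exceeds trigger_force beyond tolerance")
  structure(
    list(piezo_z = piezo_z, force = force,
         spring_constant = spring_constant, approach_speed = approach_speed,
         trigger_force = trigger_force, tip_kind = tip_kind,
         tip_radius = tip_radius, strain_label = strain_label,
         ground_truth = ground_truth, seed = seed),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  n_ev <- if (is.null(x$ground_truth)) NA_integer_
          else nrow(x$ground_truth$events)
  cat(sprintf(
    "<force_curve> %d samples | %s tip (R=%.3g um) | k=%.3g N/m | strain %s%%\n",
    length(x$force), x$tip_kind, x$tip_radius, x$spring_constant,
    format(x$strain_label)))
  cat(sprintf("  z: %.0f..%.0f nm | F max %.3g nN | trigger %.3g nN%s\n",
              min(x$piezo_z), max(x$piezo_z), max(x$force), x$trigger_force,
              if (!is.na(n_ev)) sprintf(" | %d planted event(s)", n_ev)
              else ""))
  invisible(x)
}
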