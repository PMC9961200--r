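#' Detect membrane-penetration force drops
#'
#' Scans the post-contact approach segment for sudden negative force steps
#' (the signature of the tip puncturing the membrane, and possibly the
#' nucleus). A candidate is a smoothed-trace decrease of at least
#' `max(sd_mult x baseline SD, floor_nN)` completed within `window_nm` of
#' piezo travel; the event index is refined on the raw trace as the steepest
#' single-sample decrease in the candidate window, and the drop magnitude is
#' confirmed on the raw trace. The force at the pre-drop sample is the
#' insertion force; insertion displacement is the cantilever-corrected depth
#' there, and insertion time is displacement / approach speed.
#'
#' @param curve A [force_curve()].
#' @param z_A Optional contact point in nm; detected if `NULL`.
#' @param sd_mult Drop threshold in baseline-SD units (default 5).
#' @param floor_nN Absolute threshold floor in nN (default 0.05).
#' @param window_nm Piezo-travel window within which the drop must complete
#'   (default 20 nm).
#' @param smooth Running-mean window in samples for the candidate screen.
#' @return Data frame of class `insertion_events` with columns `index`,
#'   `insertion_force` (nN), `drop_magnitude` (nN), `insertion_displacement`
#'   (um), `insertion_time` (s) and `rank` (`membrane_first`,
#'   `nucleus_second`, `other`). Zero rows mean no penetration.
#' @export
detect_force_drops <- function(curve, z_A = NULL, sd_mult = 5,
                               floor_nN = 0.05, window_nm = 20, smooth = 5) {
  if (is.null(z_A)) z_A <- detect_contact_point(curve)
  idx0 <- attr(z_A, "index")
  if (is.null(idx0))
    idx0 <- which(curve$piezo_z >= as.numeric(z_A))[1]
  sb <- attr(z_A, "baseline_sd")
  if (is.null(sb)) {
    nb <- min(500L, max(50L, as.integer(0.1 * length(curve$force))))
    sb <- sd(curve$force[seq_len(nb)])
  }
  thr <- max(sd_mult * sb, floor_nN)

  f <- curve$force
  n <- length(f)
  dz <- stats::median(diff(curve$piezo_z))
  w <- max(3L, as.integer(ceiling(window_nm / dz)))
  fs <- running_mean(f, smooth)
  gap <- as.integer(ceiling(smooth / 2)) + 1L

  start <- min(idx0 + 5L, n)
  events <- list()
  i <- start
  while (i <= n - gap - 1L) {
    jmax <- min(i + gap + w, n)
    fut <- min(fs[(i + gap):jmax])
    if (fs[i] - fut >= thr) {
      # refine on the raw trace: steepest single-sample decrease nearby
      w0 <- max(idx0, i - smooth)
      w1 <- min(n - 1L, i + gap + w + smooth)
      dd <- diff(f[w0:w1])
      j <- w0 + which.min(dd) - 1L          # pre-drop sample index
      post <- min(f[(j + 1L):min(j + w, n)])
      mag <- f[j] - post
      if (mag >= thr) {
        depth_nm <- indentation_depth(curve$piezo_z[j], f[j],
                                      curve$spring_constant,
                                      as.numeric(z_A))
        events[[length(events) + 1L]] <- data.frame(
          index = j, insertion_force = f[j], drop_magnitude = mag,
          insertion_displacement = depth_nm / 1000,
          insertion_time = depth_nm / 1000 / curve$approach_speed,
          stringsAsFactors = FALSE)
        i <- j + w + gap
        next
      }
      i <- w1 + 1L
      next
    }
    i <- i + 1L
  }
  out <- if (length(events)) do.call(rbind, events) else data.frame(
    index = integer(), insertion_force = numeric(),
    drop_magnitude = numeric(), insertion_displacement = numeric(),
    insertion_time = numeric(), stringsAsFactors = FALSE)
  out$rank <- if (nrow(out)) c("membrane_first", "nucleus_second",
                               rep("other", max(nrow(out) - 2L, 0L)))[
                                 seq_len(nrow(out))] else character()
  class(out) <- c("insertion_events", "data.frame")
  out
}

#' Segment a curve into its O-A / A-B / B / B-C stages
#'
#' Labels the contact point (A), first membrane-puncture drop (B, when
#' present), trigger point (C) and nucleus drop (D, when present), and fits
#' the A-B loading segment by ordinary least squares of force against
#' cantilever-corrected depth (A to C when no drop occurred).
#'
#' @param curve A [force_curve()].
#' @param events Optional `insertion_events` from [detect_force_drops()];
#'   detected if `NULL`.
#' @param z_A Optional contact point from [detect_contact_point()].
#' @return A `curve_segmentation` list: `contact_index`, `first_drop_index`
#'   (NA if none), `second_drop_index` (NA if none), `trigger_index`,
#'   `ab_slope` (nN/um of corrected depth), `ab_slope_r2`.
#' @export
segment_curve <- function(curve, events = NULL, z_A = NULL) {
  if (is.null(z_A)) z_A <- detect_contact_point(curve)
  if (is.null(events)) events <- detect_force_drops(curve, z_A = z_A)
  a <- attr(z_A, "index")
  if (is.null(a)) a <- which(curve$piezo_z >= as.numeric(z_A))[1]
  n <- length(curve$force)
  trig <- which(curve$force >= curve$trigger_force * 0.999)[1]
  if (is.na(trig)) trig <- n
  b <- if (nrow(events) >= 1) events$index[1] else NA_integer_
  d <- if (nrow(events) >= 2) events$index[2] else NA_integer_

  end <- if (!is.na(b)) b else trig
  seg <- seq(a, end)
  if (length(seg) < 5)
    afm_error("afm_segmentation_degenerate",
              "fewer than 5 samples between contact and first drop")
  depth_um <- indentation_depth(curve$piezo_z[seg], curve$force[seg],
                                curve$spring_constant,
                                as.numeric(z_A)) / 1000
  y <- curve$force[seg]
  fit <- lm(y ~ depth_um)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(
    list(contact_index = a, first_drop_index = b, second_drop_index = d,
         trigger_index = trig,
         ab_slope = unname(coef(fit)[2]),
         ab_slope_r2 = r2),
    class = "curve_segmentation"
  )
}

#' @export
print.curve_segmentation <- function(x, ...) {
  cat(sprintf(
    "<curve_segmentation> A=%d B=%s C=%d D=%s | A-B slope %.4g nN/um (r2=%.4f)\n",
    x$contact_index, format(x$first_drop_index), x$trigger_index,
    format(x$second_drop_index), x$ab_slope, x$ab_slope_r2))
  invisible(x)
}

#' Full single-curve analysis
#'
#' Convenience wrapper running contact detection, drop detection and
#' segmentation (plus a Hertz fit for spherical-tip curves) on one curve.
#'
#' @param curve A [force_curve()].
#' @param fit_modulus Logical; attempt [fit_hertz()] for spherical tips.
#' @param ... Passed to [detect_force_drops()].
#' @return List with `contact_z` (nm), `events`, `segmentation`, `hertz`
#'   (a `hertz_fit` or `NULL`) and the curve metadata needed downstream.
#' @export
analyze_curve <- function(curve, fit_modulus = (curve$tip_kind == "sphere"),
                          ...) {
  z_A <- detect_contact_point(curve)
  events <- detect_force_drops(curve, z_A = z_A, ...)
  seg <- segment_curve(curve, events = events, z_A = z_A)
  hz <- if (isTRUE(fit_modulus) && curve$tip_kind == "sphere")
    fit_hertz(curve) else NULL
  list(contact_z = as.numeric(z_A), events = events, segmentation = seg,
       hertz = hz,
       strain_label = curve$strain_label,
       approach_speed = curve$approach_speed,
       trigger_force = curve$trigger_force)
}
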