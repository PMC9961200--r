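#' Detect the contact point of an approach curve
#'
#' Estimates the piezo position where the tip first touches the cell (point
#' A). Baseline mean and SD are computed on a leading non-contact window; the
#' contact is the first position where the smoothed force exceeds
#' `baseline mean + sd_mult x SD` and stays above it for at least `persist`
#' consecutive samples. The crossing index is then refined on the raw trace
#' (stepping back to the last sub-threshold sample) so that noiseless curves
#' are located to within one sample.
#'
#' @param curve A [force_curve()].
#' @param baseline_n Number of leading samples treated as non-contact;
#'   default `min(500, max(50, 10%))` of the trace.
#' @param sd_mult Threshold multiplier on the baseline SD (default 3).
#' @param persist Required number of consecutive above-threshold samples.
#' @param smooth Running-mean window (samples) applied before thresholding.
#' @return Contact position `z_A` in nm, with attributes `index` (sample
#'   index) and `baseline_sd` (nN).
#' @export
detect_contact_point <- function(curve, baseline_n = NULL, sd_mult = 3,
                                 persist = 10, smooth = 5) {
  f <- curve$force
  n <- length(f)
  if (is.null(baseline_n))
    baseline_n <- min(500L, max(50L, as.integer(0.1 * n)))
  if (n < baseline_n + persist)
    afm_error("afm_no_contact", "trace too short for baseline window")
  mu <- mean(f[seq_len(baseline_n)])
  s <- sd(f[seq_len(baseline_n)])
  thr <- mu + max(sd_mult * s, 1e-6)

  fs <- running_mean(f, smooth)
  above <- fs > thr
  # first index from which `persist` consecutive samples stay above threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= persist)
  if (length(ok) == 0)
    afm_error("afm_no_contact", "no sustained crossing above baseline found")
  idx <- starts[ok[1]]

  # refine on the raw trace: last sub-threshold raw sample before crossing
  back <- max(1L, idx - 3L * smooth)
  win <- seq(back, min(idx + smooth, n))
  below <- win[curve$force[win] <= thr]
  if (length(below) > 0) idx <- min(max(below) + 1L, n)
  z_A <- curve$piezo_z[idx]

  # On noisy traces the threshold crossing lags the true contact by
  # ~sd_mult x SD / slope. Refine by back-extrapolating a short linear fit of
  # the initial rise to the baseline level; the window is capped 0.3 nN above
  # threshold so it stays clear of the first puncture drop.
  if (s > 0) {
    cap <- thr + 0.3
    nmax <- min(n, idx + 150L)
    seg <- seq(idx, nmax)
    over <- which(f[seg] > cap)
    if (length(over) > 1) seg <- seg[seq_len(max(over[1] - 1L, 0L))]
    if (length(seg) >= 10) {
      zz <- curve$piezo_z[seg]
      co <- coef(lm(f[seg] ~ zz))
      if (is.finite(co[2]) && co[2] > 0) {
        zhat <- (mu - co[1]) / co[2]
        zhat <- min(max(zhat, z_A - 300), z_A)
        z_A <- zhat
        idx <- which.min(abs(curve$piezo_z - zhat))
      }
    }
  }

  structure(z_A, index = idx, baseline_sd = s, baseline_mean = mu)
}
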