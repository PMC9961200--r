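#' Engineering strain from pre/post-stretch lengths
#'
#' `epsilon = (L1 - L0) / L0`, the longitudinal strain of the substrate or of
#' a cell tracked before and after stretching. May be negative
#' (compression).
#'
#' @param L0 Length before stretching, um (> 0).
#' @param L1 Length after stretching, um.
#' @return Strain as a fraction (vectorised).
#' @examples
#' strain(50, 60)        # 0.20
#' strain(100, 113.25)   # 0.1325
#' @export
strain <- function(L0, L1) {
  if (any(!is.finite(L0)) || any(L0 <= 0))
    afm_error("afm_invalid_argument", "L0 must be > 0")
  (L1 - L0) / L0
}

#' Summarise insertion behaviour for one strain condition
#'
#' Aggregates per-curve event tables into one condition row: a curve counts
#' as penetrated iff it has at least one `membrane_first` event, and force /
#' displacement / time statistics (mean and sample SD, n-1) are computed over
#' the first event of penetrated curves only. The insertion rate is reported
#' both as the exact fraction and rounded to the nearest integer percent.
#'
#' @param events_by_curve List with one `insertion_events` data frame (or
#'   plain data frame with the same columns) per curve.
#' @param strain_label Substrate strain of the condition, percent.
#' @param indentation_speed Approach speed, um/s.
#' @param trigger_force Trigger force, nN.
#' @return A `condition_summary` list: `substrate_strain`, `n_curves`,
#'   `n_penetrated`, `insertion_rate_fraction`, `insertion_rate_percent`
#'   (rounded), `mean_insertion_force`, `sd_insertion_force`,
#'   `mean_insertion_displacement`, `sd_insertion_displacement`,
#'   `mean_insertion_time`, `sd_insertion_time`, `indentation_speed`,
#'   `trigger_force`, `has_statistics`.
#' @export
summarize_condition <- function(events_by_curve, strain_label = NA_real_,
                                indentation_speed, trigger_force) {
  if (!is.list(events_by_curve) || length(events_by_curve) == 0)
    afm_error("afm_invalid_argument",
              "events_by_curve must be a non-empty list of event tables")
  n <- length(events_by_curve)
  firsts <- lapply(events_by_curve, function(ev) {
    if (is.null(ev) || nrow(ev) == 0) return(NULL)
    m <- ev[ev$rank == "membrane_first", , drop = FALSE]
    if (nrow(m) == 0) NULL else m[1, , drop = FALSE]
  })
  pen <- !vapply(firsts, is.null, logical(1))
  m <- sum(pen)
  fe <- if (m > 0) do.call(rbind, firsts[pen]) else NULL
  stat <- function(col, fun) if (m > 0) fun(fe[[col]]) else NA_real_
  out <- list(
    substrate_strain = strain_label,
    n_curves = n, n_penetrated = m,
    insertion_rate_fraction = m / n,
    insertion_rate_percent = as.integer(round(100 * m / n)),
    mean_insertion_force = stat("insertion_force", mean),
    sd_insertion_force = stat("insertion_force", sd),
    mean_insertion_displacement = stat("insertion_displacement", mean),
    sd_insertion_displacement = stat("insertion_displacement", sd),
    mean_insertion_time = stat("insertion_time", mean),
    sd_insertion_time = stat("insertion_time", sd),
    indentation_speed = indentation_speed,
    trigger_force = trigger_force,
    has_statistics = m > 0
  )
  class(out) <- "condition_summary"
  out
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    "<condition_summary> strain %s%% | %d%% (%d/%d) penetrated\n",
    format(x$substrate_strain), x$insertion_rate_percent, x$n_penetrated,
    x$n_curves))
  if (x$has_statistics)
    cat(sprintf(
      "  F_ins %.2f +/- %.2f nN | disp %.2f +/- %.2f um | t %.2f +/- %.2f s\n",
      x$mean_insertion_force, x$sd_insertion_force,
      x$mean_insertion_displacement, x$sd_insertion_displacement,
      x$mean_insertion_time, x$sd_insertion_time))
  else cat("  no penetrated curves; force/displacement/time absent\n")
  invisible(x)
}

#' Convert condition summaries to a tidy one-row-per-condition data frame
#'
#' @param summaries List of `condition_summary` objects.
#' @return Data frame mirroring the published per-condition table layout.
#' @export
condition_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      trigger_force_nN = s$trigger_force,
      substrate_strain_pct = s$substrate_strain,
      mean_insertion_force_nN = s$mean_insertion_force,
      sd_insertion_force_nN = s$sd_insertion_force,
      mean_insertion_displacement_um = s$mean_insertion_displacement,
      sd_insertion_displacement_um = s$sd_insertion_displacement,
      indentation_speed_um_s = s$indentation_speed,
      mean_insertion_time_s = s$mean_insertion_time,
      sd_insertion_time_s = s$sd_insertion_time,
      insertion_rate_percent = s$insertion_rate_percent,
      n_penetrated = s$n_penetrated,
      n_curves = s$n_curves,
      stringsAsFactors = FALSE)
  }))
}

#' Histogram of insertion forces
#'
#' Counts insertion forces into half-open bins `[lo, hi)` defined by
#' `bin_edges`; forces at or above the last edge go to an overflow bucket
#' (and below the first edge to an underflow bucket, normally empty since
#' forces are positive).
#'
#' @param events An `insertion_events` data frame, or a numeric vector of
#'   forces in nN.
#' @param bin_edges Strictly increasing edges in nN (default `0:3`).
#' @return Data frame with columns `lo`, `hi`, `count`; the final row is the
#'   overflow bucket `[last edge, Inf)`.
#' @export
insertion_force_histogram <- function(events, bin_edges = c(0, 1, 2, 3)) {
  if (any(diff(bin_edges) <= 0) || length(bin_edges) < 2)
    afm_error("afm_invalid_argument", "bin_edges must be strictly increasing")
  forces <- if (is.data.frame(events)) events$insertion_force
            else as.numeric(events)
  forces <- forces[forces >= bin_edges[1]]
  nb <- length(bin_edges) - 1L
  counts <- integer(nb + 1L)
  for (b in seq_len(nb)) {
    counts[b] <- sum(forces >= bin_edges[b] & forces < bin_edges[b + 1L])
  }
  counts[nb + 1L] <- sum(forces >= bin_edges[nb + 1L])
  data.frame(lo = c(bin_edges[-length(bin_edges)], bin_edges[length(bin_edges)]),
             hi = c(bin_edges[-1], Inf),
             count = counts)
}
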