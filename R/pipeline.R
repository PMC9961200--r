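#' Default end-to-end run configuration
#'
#' Five conditions mirroring the published experiment (substrate strains 0,
#' 5, 10, 15, 20%; 60 curves each; exact penetration counts 11/23/31/36/37),
#' standard analysis thresholds, and a small FE case (prestressed vs
#' unprestressed pair).
#'
#' @param seed Global seed.
#' @param n_per_condition Curves per condition (default 60).
#' @param exact_count Use exact-count penetration assignment (default TRUE).
#' @param fem_run Include the FE stage (default TRUE).
#' @param fem_half_width,fem_spacing,fem_travel,fem_steps FE geometry and
#'   loading; the default 1 um half-width / 100 nm spacing mesh solves in
#'   seconds.
#' @return A run-config list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, n_per_condition = 60,
                               exact_count = TRUE, fem_run = TRUE,
                               fem_half_width = 1000, fem_spacing = 100,
                               fem_travel = 100, fem_steps = 10) {
  conds <- strain_conditions(seed = seed)
  list(
    seed = as.integer(seed),
    n_per_condition = as.integer(n_per_condition),
    exact_count = exact_count,
    conditions = lapply(conds, function(p) unclass(p)),
    analysis = list(contact_sd_mult = 3, drop_sd_mult = 5,
                    drop_floor_nN = 0.05, drop_window_nm = 20),
    fem = list(run = fem_run, half_width = fem_half_width,
               spacing = fem_spacing, fiber_lines = 3,
               prestress = list(membrane = 100, filament = 5e4, bundle = 5e4),
               travel = fem_travel, steps = fem_steps)
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    afm_error("afm_pipeline_error",
              sprintf("[stage %s] %s", stage, conditionMessage(e)),
              stage = stage)
  })
}

#' Run the full generate - analyze - summarize - simulate - report pipeline
#'
#' Generates the configured per-condition curve batches, writes them as
#' commented-header CSVs with a ground-truth sidecar JSON, analyses every
#' curve (contact point, force drops, segmentation), aggregates
#' per-condition summaries and insertion-force histograms, optionally runs
#' the prestressed / unprestressed FE pair, and writes a plain-text report.
#' With a fixed seed all outputs are bit-identical across runs.
#'
#' @param config A config list from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages (default TRUE).
#' @return Invisibly, a list with the condition summaries, the FE profiles
#'   (if run) and the output paths.
#' @export
run_pipeline <- function(config, out_dir, quiet = TRUE) {
  if (is.null(config$conditions) || length(config$conditions) == 0)
    afm_error("afm_pipeline_error", "[stage validate] config has no conditions")
  labels <- vapply(config$conditions,
                   function(p) as.character(p$strain_label), character(1))
  if (anyDuplicated(labels))
    afm_error("afm_pipeline_error",
              "[stage validate] condition strain labels must be unique")
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("curves", "analysis", "summary", "fem"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  hash <- config_hash(config)

  an <- config$analysis
  summaries <- list()
  analyses_by_cond <- list()
  for (ci in seq_along(config$conditions)) {
    pc <- config$conditions[[ci]]
    params <- do.call(curve_gen_params,
                      pc[setdiff(names(pc), character(0))])
    lab <- labels[ci]
    say("generating condition %s%% (n=%d)", lab, config$n_per_condition)
    curves <- pipeline_stage("generate",
      generate_condition_set(params, config$n_per_condition,
                             exact_count = isTRUE(config$exact_count)))
    cdir <- file.path(out_dir, "curves", paste0("strain_", lab))
    dir.create(cdir, showWarnings = FALSE)
    gt <- list()
    for (i in seq_along(curves)) {
      write_curve(curves[[i]],
                  file.path(cdir, sprintf("curve_%03d.csv", i)))
      gt[[i]] <- curves[[i]]$ground_truth
    }
    jsonlite::write_json(gt, file.path(cdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")

    say("analysing condition %s%%", lab)
    analyses <- pipeline_stage("analyze", lapply(curves, function(cv) {
      z_A <- detect_contact_point(cv, sd_mult = an$contact_sd_mult)
      ev <- detect_force_drops(cv, z_A = z_A, sd_mult = an$drop_sd_mult,
                               floor_nN = an$drop_floor_nN,
                               window_nm = an$drop_window_nm)
      seg <- segment_curve(cv, events = ev, z_A = z_A)
      list(contact_z = as.numeric(z_A), events = ev,
           segmentation = unclass(seg))
    }))
    analyses_by_cond[[lab]] <- analyses
    jsonlite::write_json(
      analyses, file.path(out_dir, "analysis",
                          sprintf("strain_%s.json", lab)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")

    events_by_curve <- lapply(analyses, `[[`, "events")
    summaries[[lab]] <- pipeline_stage("summarize",
      summarize_condition(events_by_curve,
                          strain_label = as.numeric(pc$strain_label),
                          indentation_speed = pc$approach_speed,
                          trigger_force = pc$trigger_force))
    all_first <- do.call(rbind, lapply(events_by_curve, function(ev)
      ev[ev$rank == "membrane_first", , drop = FALSE]))
    hist <- insertion_force_histogram(
      if (is.null(all_first)) numeric(0) else all_first$insertion_force)
    write.csv(hist, file.path(out_dir, "summary",
                              sprintf("histogram_strain_%s.csv", lab)),
              row.names = FALSE)
  }

  tab <- condition_table(summaries)
  write.csv(tab, file.path(out_dir, "summary", "condition_summary.csv"),
            row.names = FALSE)

  fem_out <- NULL
  if (isTRUE(config$fem$run)) {
    say("running FE pair")
    fem_out <- pipeline_stage("simulate", {
      fc <- config$fem
      model <- build_network(half_width = fc$half_width,
                             filament_spacing = fc$spacing,
                             fiber_lines = fc$fiber_lines)
      ind <- afm_indenter(travel = fc$travel, steps = fc$steps)
      res0 <- simulate_indentation(model, ind)
      res1 <- simulate_indentation(
        apply_prestress(model, membrane = fc$prestress$membrane,
                        filament = fc$prestress$filament,
                        bundle = fc$prestress$bundle), ind)
      p0 <- midline_profile(res0)
      p1 <- midline_profile(res1)
      prof <- data.frame(x_nm = p0$x,
                         w_z_nm_no_prestress = p0$w_z,
                         w_z_nm_prestress = p1$w_z,
                         vm_Pa_no_prestress = p0$stress,
                         vm_Pa_prestress = p1$stress)
      write.csv(prof, file.path(out_dir, "fem", "midline_profiles.csv"),
                row.names = FALSE)
      fsum <- data.frame(
        case = c("no_prestress", "prestress"),
        max_membrane_stress_Pa = c(res0$max_membrane_stress,
                                   res1$max_membrane_stress),
        stress_fwhm_nm = c(p0$fwhm, p1$fwhm),
        w_first_free_nm = c(tail(res0$step_summary$w_first_free, 1),
                            tail(res1$step_summary$w_first_free, 1)))
      write.csv(fsum, file.path(out_dir, "fem", "fem_summary.csv"),
                row.names = FALSE)
      list(profiles = prof, summary = fsum)
    })
  }

  report <- c(
    "afmindent pipeline report",
    sprintf("config_hash_md5: %s", hash),
    sprintf("seed: %d", config$seed),
    "",
    sprintf("conditions: %d x %d curves (exact_count=%s)",
            length(config$conditions), config$n_per_condition,
            isTRUE(config$exact_count)),
    vapply(summaries, function(s) sprintf(
      "  strain %s%%: %d%% (%d/%d) penetrated%s",
      format(s$substrate_strain), s$insertion_rate_percent,
      s$n_penetrated, s$n_curves,
      if (s$has_statistics) sprintf(
        " | F %.2f+/-%.2f nN, d %.2f+/-%.2f um, t %.2f+/-%.2f s",
        s$mean_insertion_force, s$sd_insertion_force,
        s$mean_insertion_displacement, s$sd_insertion_displacement,
        s$mean_insertion_time, s$sd_insertion_time) else ""),
      character(1)),
    if (!is.null(fem_out)) c(
      "",
      sprintf("FE max membrane stress (Pa): no prestress %.4g, prestress %.4g",
              fem_out$summary$max_membrane_stress_Pa[1],
              fem_out$summary$max_membrane_stress_Pa[2]),
      sprintf("FE stress FWHM (nm): no prestress %.4g, prestress %.4g",
              fem_out$summary$stress_fwhm_nm[1],
              fem_out$summary$stress_fwhm_nm[2])) else character(0)
  )
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(summaries = summaries, table = tab, fem = fem_out,
                 config_hash = hash, out_dir = out_dir,
                 analyses = analyses_by_cond))
}
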