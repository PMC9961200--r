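# Metadata keys that must be present in a curve file.
CURVE_META_KEYS <- c("spring_constant", "approach_speed", "trigger_force",
                     "tip_kind", "tip_radius", "strain_label")

#' Write a force curve to a commented-header CSV
#'
#' The file starts with `# key=value` metadata lines (spring constant,
#' approach speed, trigger force, tip kind, tip radius, strain label and,
#' when available, the generator seed), followed by a CSV body with columns
#' `piezo_z_nm` and `force_nN`. Numbers are written with 17 significant
#' digits so the write/read round trip is lossless.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  meta <- c(
    spring_constant = sprintf("%.17g", curve$spring_constant),
    approach_speed = sprintf("%.17g", curve$approach_speed),
    trigger_force = sprintf("%.17g", curve$trigger_force),
    tip_kind = curve$tip_kind,
    tip_radius = sprintf("%.17g", curve$tip_radius),
    strain_label = sprintf("%.17g", as.numeric(curve$strain_label))
  )
  if (!is.null(curve$seed)) meta <- c(meta, seed = sprintf("%d", curve$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), meta), con)
  writeLines("piezo_z_nm,force_nN", con)
  writeLines(sprintf("%.17g,%.17g", curve$piezo_z, curve$force), con)
  invisible(path)
}

#' Read a force curve written by [write_curve()]
#'
#' @param path Input file path.
#' @return A [force_curve()]. Missing mandatory metadata raises a format
#'   error naming the absent key.
#' @export
read_curve <- function(path) {
  if (!file.exists(path))
    afm_error("afm_format_error", paste("file not found:", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  missing <- setdiff(CURVE_META_KEYS, keys)
  if (length(missing))
    afm_error("afm_format_error",
              paste0("curve file missing mandatory metadata key(s): ",
                     paste(missing, collapse = ", ")))
  body <- lines[!grepl("^#", lines)]
  tc <- textConnection(body)
  on.exit(close(tc))
  dat <- read.csv(tc)
  if (!all(c("piezo_z_nm", "force_nN") %in% names(dat)))
    afm_error("afm_format_error",
              "curve file must have columns piezo_z_nm and force_nN")
  force_curve(
    piezo_z = dat$piezo_z_nm, force = dat$force_nN,
    spring_constant = as.numeric(vals[["spring_constant"]]),
    approach_speed = as.numeric(vals[["approach_speed"]]),
    trigger_force = as.numeric(vals[["trigger_force"]]),
    tip_kind = vals[["tip_kind"]],
    tip_radius = as.numeric(vals[["tip_radius"]]),
    strain_label = as.numeric(vals[["strain_label"]]),
    seed = if ("seed" %in% keys) as.integer(vals[["seed"]]) else NULL
  )
}

#' Read / write a run configuration (JSON)
#'
#' @param path JSON file path.
#' @return For `read_run_config`, a config list as produced by
#'   [default_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    afm_error("afm_format_error", paste("config not found:", path))
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' @rdname read_run_config
#' @param config A run-config list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
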