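# Plain-text interchange formats. Plasma CSV: subject,time_h,conc_ug_per_L.
# Dissolution CSV: time_min,pct_mean,pct_sd,medium_ph. UTF-8, "." decimal.

#' Read oral plasma concentration-time profiles from CSV
#'
#' Expects columns `subject,time_h,conc_ug_per_L`; one profile per subject,
#' ragged sampling grids allowed. Parse errors name the offending row.
#'
#' @param path CSV file path.
#' @param dose_mg dose attached to every profile, mg (optional).
#' @return named list of [plasma_profile()] objects.
#' @export
read_plasma_csv <- function(path, dose_mg = NA_real_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "time_h", "conc_ug_per_L")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing column(s) %s in %s", paste(miss, collapse = ", "), path)
  if (nrow(df) == 0L) stopf("no data rows in %s", path)
  for (col in c("time_h", "conc_ug_per_L")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad))
      stopf("invalid %s at row %d of %s", col, bad[1] + 1L, path)
  }
  out <- lapply(split(df, df$subject), function(d) {
    d <- d[order(d$time_h), ]
    dup <- which(duplicated(d$time_h))
    if (length(dup))
      stopf("duplicate time %g for subject %s in %s",
            d$time_h[dup[1]], d$subject[1], path)
    plasma_profile(d$time_h, d$conc_ug_per_L, dose_mg = dose_mg,
                   label = as.character(d$subject[1]))
  })
  out[order(names(out))]
}

#' Write plasma profiles to CSV
#'
#' @param profiles a [plasma_profile()] or list of them; subject ids come
#'   from the profile labels (or list names).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plasma_csv <- function(profiles, path) {
  if (inherits(profiles, "plasma_profile")) profiles <- list(profiles)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    id <- names(profiles)[i] %||% ""
    if (identical(id, "") || is.null(id)) id <- attr(p, "label")
    if (identical(id, "")) id <- sprintf("s%02d", i)
    data.frame(subject = id, time_h = p$time_h,
               conc_ug_per_L = p$conc_ug_per_L)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an in-vitro dissolution profile from CSV
#'
#' Expects columns `time_min,pct_mean,pct_sd,medium_ph`; all validity checks
#' of [dissolution_profile()] apply (including the bounded-decrease rule).
#'
#' @param path CSV file path.
#' @return a [dissolution_profile()].
#' @export
read_dissolution_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "pct_mean", "pct_sd", "medium_ph")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing column(s) %s in %s", paste(miss, collapse = ", "), path)
  if (nrow(df) == 0L) stopf("no data rows in %s", path)
  dissolution_profile(df$time_min, df$pct_mean, df$pct_sd,
                      medium_ph = df$medium_ph[1])
}

#' Write a dissolution profile to CSV
#'
#' @param profile a [dissolution_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dissolution_csv <- function(profile, path) {
  stopifnot(inherits(profile, "dissolution_profile"))
  utils::write.csv(data.frame(time_min = profile$times_min,
                              pct_mean = profile$mean_pct,
                              pct_sd = profile$sd_pct,
                              medium_ph = profile$medium_ph),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a structured run configuration (YAML)
#'
#' A run configuration bundles the compound, ACAT, disposition and
#' population blocks plus simulation settings; see
#' `system.file("extdata", "example_config.yaml", package = "vbesim")` for a
#' complete example. Referenced files are checked for existence relative to
#' the configuration file's directory.
#'
#' @param path YAML file path.
#' @return list with parsed blocks: `compound`, `acat`, `disp`,
#'   `population`, `simulation`, `files`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  files <- cfg$files %||% list()
  files <- lapply(files, function(f) {
    fp <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(fp)) stopf("configured file does not exist: %s", f)
    fp
  })
  cmp <- do.call(compound, cfg$compound)
  acat_args <- cfg$acat %||% list()
  if (!is.null(acat_args$transit_h)) acat_args$transit_h <- unlist(acat_args$transit_h)
  if (!is.null(acat_args$asf)) acat_args$asf <- unlist(acat_args$asf)
  acat <- do.call(acat_spec, acat_args)
  disp <- do.call(disposition_params, cfg$disposition)
  pop <- do.call(population_spec, cfg$population %||% list())
  sim <- cfg$simulation %||% list()
  list(compound = cmp, acat = acat, disp = disp, population = pop,
       simulation = sim, files = files, seed = cfg$seed %||% pop$seed,
       path = normalizePath(path))
}

# Provenance block stamped into every machine-readable report. No wall-clock
# fields: identical inputs and seed must give byte-identical reports.
provenance <- function(seed, config_path = NULL) {
  out <- list(package = "vbesim",
              version = as.character(packageVersion("vbesim")),
              seed = seed)
  if (!is.null(config_path) && file.exists(config_path))
    out$config_md5 <- unname(tools::md5sum(config_path))
  out
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
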