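# Pipeline configuration: one YAML file with a section per module. Every
# field has a default; unknown keys are rejected so typos cannot silently
# fall back to defaults; every effective value is echoed to the run log.

#' Default pipeline configuration
#'
#' @return Nested list with sections `preprocess`, `segment`, `morphometry`,
#'   `density`, and `seed`.
#' @export
default_config <- function() {
  list(
    preprocess = list(opening_radius_px = 50L, median_radius_px = 1L,
                      otsu_bins = 256L),
    segment = list(min_object_voxels = 30L, max_object_voxels = 100000L,
                   seed_smooth_sigma_px = 2, seed_min_distance_px = 8,
                   seed_rel_intensity = 0.75, min_cell_voxels = 50L,
                   max_cell_voxels = 20000L, max_elongation = 12,
                   min_extent = 0.02),
    morphometry = list(exclude_border = TRUE, aggregate = "pool"),
    density = list(threshold = "otsu-pooled", control_group = "control"),
    seed = 1L
  )
}

.merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop(sprintf("config error: unknown key '%s'", full), call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.list(user[[key]])) {
      stop(sprintf("config error: '%s' must be a section", full), call. = FALSE)
    }
    if (is.list(base[[key]])) {
      base[[key]] <- .merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, overlays it on [default_config()], and rejects unknown
#' keys. `NULL` returns the defaults.
#'
#' @param path Path to a YAML config, or `NULL`.
#' @return A validated config list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config error: file '%s' not found", path), call. = FALSE)
    }
    user <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop(sprintf("config error: cannot parse '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
    if (!is.null(user)) cfg <- .merge_config(cfg, user)
  }
  # construct parameter objects now so invalid values fail at load time
  tryCatch({
    do.call(preprocess_params, cfg$preprocess)
    do.call(segmentation_params, cfg$segment)
  }, error = function(e) {
    stop(sprintf("config error: %s", conditionMessage(e)), call. = FALSE)
  })
  if (!cfg$morphometry$aggregate %in% c("pool", "lesion-mean")) {
    stop("config error: morphometry.aggregate must be 'pool' or 'lesion-mean'",
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

.config_lines <- function(cfg, prefix = "") {
  out <- character(0)
  for (key in names(cfg)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (is.list(cfg[[key]])) {
      out <- c(out, .config_lines(cfg[[key]], full))
    } else {
      out <- c(out, sprintf("%s = %s", full,
                            paste(format(cfg[[key]]), collapse = ", ")))
    }
  }
  out
}

.write_run_log <- function(out_dir, cfg, inputs, extra = character(0)) {
  lines <- c(
    sprintf("microsol %s", as.character(packageVersion("microsol"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    "-- effective configuration --",
    .config_lines(unclass(cfg)),
    "-- inputs --",
    if (length(inputs)) {
      paste0(names(inputs) %||% inputs, " md5=", unname(inputs))
    } else "none",
    extra
  )
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(lines)
}
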