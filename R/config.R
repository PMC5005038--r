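# Run configuration: JSON configs with validated keys, explicit seeds and
# recorded defaults.

#' Default run configuration
#'
#' The parameter blocks of a full synthetic run with their defaults: the
#' acquisition timing (TR 1.8 s, 2 s cue, 10 s imagination, ITIs of 1.8, 3.6
#' or 5.4 s), the searchlight geometry (diameter 7 voxels, more than 30
#' gray-matter voxels, 4 mm FWHM smoothing), the contrast scheme, the
#' inference settings (10,000 permutations), and the cohort block. Seeds have
#' no default and must be supplied.
#'
#' @return A nested list of defaults.
#' @export
config_defaults <- function() {
  list(
    seeds = list(design = NULL, signal = NULL, permutation = NULL),
    acquisition = list(tr = 1.8, cue_s = 2, imagination_s = 10,
                       iti_s = c(1.8, 3.6, 5.4)),
    searchlight = list(diameter = 7L, min_voxels = 31L, fwhm_mm = 4),
    rsa = list(scheme = "mod60", exclude = character()),
    inference = list(n_perm = 10000L, alpha = 0.05, correction_k = 2,
                     tail = "greater"),
    cohort = list(n_subjects = 24L, n_voxels = 100L,
                  grid_amplitude = CALIBRATED_GRID_AMPLITUDE),
    out_dir = NULL
  )
}

check_unknown_keys <- function(given, defaults, path = character()) {
  if (!is.list(given) || !is.list(defaults)) return(invisible(NULL))
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0) {
    full <- paste(c(path, unknown[1]), collapse = "$")
    abort(sprintf("unknown config key: '%s'.", full))
  }
  for (nm in names(given)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      check_unknown_keys(given[[nm]], defaults[[nm]], c(path, nm))
    }
  }
  invisible(NULL)
}

merge_config <- function(defaults, given) {
  for (nm in names(given)) {
    if (is.list(given[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], given[[nm]])
    } else {
      defaults[[nm]] <- given[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a JSON config, rejects unknown keys with the offending key named,
#' fills unset parameters from [config_defaults()] and records for each block
#' whether it was supplied or defaulted. The three seeds (design, signal,
#' permutation) are mandatory.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `run_config` list with a `provenance` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  given <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- config_defaults()
  check_unknown_keys(given, defaults)
  cfg <- merge_config(defaults, given)
  for (s in c("design", "signal", "permutation")) {
    v <- cfg$seeds[[s]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L) {
      abort(sprintf("missing seed: `seeds$%s` must be a single integer.", s))
    }
    cfg$seeds[[s]] <- as.integer(v)
  }
  for (key in c("tr", "cue_s", "imagination_s")) {
    if (!is.numeric(cfg$acquisition[[key]])) {
      abort(sprintf("type mismatch: `acquisition$%s` must be numeric.", key))
    }
  }
  provenance <- purrr::imap_chr(defaults, function(v, nm) {
    if (nm %in% names(given)) "supplied" else "default"
  })
  attr(cfg, "provenance") <- provenance
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration as JSON
#'
#' @param config A `run_config` (or compatible list).
#' @param path Destination path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
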