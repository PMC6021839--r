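## Flat run configuration shared by the CLI: every named threshold of the
## box route, the shape route and the touching gate, with the published
## values as defaults. Precedence: CLI flag > config file > default.

ts_config_defaults <- function() {
  list(
    size_lo = 0.4, size_hi = 0.6, boundary_frac = 0.2,
    probability_th = 1.0, near_band = 2,
    seg_length_th = 20, seg_size_th = 1.5,
    erosion_repeat_th = 8, skeleton_scale = 0.5,
    cp_band = 0.1, cp_ratio_th = 1.05,
    size_threshold = 500, single_pig_size = 350,
    depth_delta = 20, id_switch_th = 0.85
  )
}

#' Build a run configuration
#'
#' @param file optional flat `key = value` config file (comments with `#`).
#' @param overrides named list merged on top of file values.
#' @return list of class `ts_run_config` with fields `values` and `hash`
#'   (configuration fingerprint used in run logs).
#' @export
run_config <- function(file = NULL, overrides = list()) {
  vals <- ts_config_defaults()
  if (!is.null(file)) {
    if (!file.exists(file)) ts_error("FILE_NOT_FOUND", paste("no such file:", file))
    for (ln in readLines(file)) {
      ln <- sub("#.*$", "", ln)
      if (!grepl("=", ln)) next
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (!key %in% names(vals)) {
        ts_error("UNKNOWN_KEY", paste("unknown config key:", key))
      }
      vals[[key]] <- as.numeric(trimws(kv[2]))
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(vals)) {
      ts_error("UNKNOWN_KEY", paste("unknown config key:", key))
    }
    vals[[key]] <- as.numeric(overrides[[key]])
  }
  structure(list(values = vals,
                 hash = fnv1a(paste(names(vals), unlist(vals), sep = "="))),
            class = "ts_run_config")
}

## split the flat configuration into the per-module config objects
as_module_configs <- function(rc) {
  v <- rc$values
  list(
    bb = bb_config(size_lo = v$size_lo, size_hi = v$size_hi,
                   boundary_frac = v$boundary_frac,
                   probability_th = v$probability_th, near_band = v$near_band,
                   seg_length_th = v$seg_length_th, seg_size_th = v$seg_size_th),
    shape = shape_config(erosion_repeat_th = v$erosion_repeat_th,
                         skeleton_scale = v$skeleton_scale,
                         cp_band = v$cp_band, cp_ratio_th = v$cp_ratio_th),
    gate = gate_config(size_threshold = v$size_threshold,
                       single_pig_size = v$single_pig_size)
  )
}
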