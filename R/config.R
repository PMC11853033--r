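#' Run configuration for the analysis pipeline
#'
#' Bundles every tunable parameter of the image and diagnostic stages.
#' Values resolve with precedence CLI flag > config file > these defaults.
#'
#' @param calibration_factor raw-count to cd/m^2 scale for image I/O. The
#'   default 0.025 spans 0-1638 cd/m^2 over the 16-bit range.
#' @param lesion_band_low lower bound of the lesion band, cd/m^2.
#' @param connectivity focus connectivity, 4 or 8.
#' @param min_area_px minimum focus area kept, pixels.
#' @param thresholds Lmax sweep grid, cd/m^2.
#' @param direction classification direction, `"le"` or `"ge"`.
#' @param correction chi-squared correction, `"none"` or `"yates"`.
#' @param digits display rounding, decimal places.
#' @param seed RNG seed for simulation commands.
#' @param out_dir output directory for reports.
#' @return A `run_config` list (with a `hash` entry identifying the
#'   configuration).
#' @export
run_config <- function(calibration_factor = 0.025,
                       lesion_band_low = 630,
                       connectivity = 8,
                       min_area_px = 5,
                       thresholds = table2_thresholds(),
                       direction = "le",
                       correction = "none",
                       digits = 2,
                       seed = 1L,
                       out_dir = ".") {
  cfg <- list(calibration_factor = as.numeric(calibration_factor),
              lesion_band_low = as.numeric(lesion_band_low),
              connectivity = as.integer(connectivity),
              min_area_px = as.integer(min_area_px),
              thresholds = as.numeric(thresholds),
              direction = match.arg(direction, c("le", "ge")),
              correction = match.arg(correction, c("none", "yates")),
              digits = as.integer(digits),
              seed = as.integer(seed),
              out_dir = out_dir)
  if (cfg$calibration_factor <= 0) stop_lum("calibration_factor must be > 0")
  if (!cfg$connectivity %in% c(4L, 8L)) stop_lum("connectivity must be 4 or 8")
  if (cfg$min_area_px < 1L) stop_lum("min_area_px must be >= 1")
  if (length(cfg$thresholds) < 1L) stop_lum("empty threshold grid")
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# Stable fingerprint of the analytic configuration (md5 of its canonical
# text form). The output directory is excluded: it does not affect results.
config_hash <- function(cfg) {
  cfg$hash <- NULL
  cfg$out_dir <- NULL
  txt <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Read a run configuration from a key-value file
#'
#' The file is a plain declarative `key = value` format (one per line, `#`
#' comments allowed; `thresholds` as comma-separated numbers). Unknown keys
#' are an error. Keys present in `overrides` (e.g. parsed CLI flags) win
#' over the file.
#'
#' @param path config file path, or `NULL` for defaults only.
#' @param overrides named list of values taking precedence over the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_lum("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(kv) != 3L) stop_lum("cannot parse config line: ", ln)
      vals[[kv[2]]] <- kv[3]
    }
  }
  vals <- modifyList(vals, overrides)
  known <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop_lum("unknown config key(s): ", paste(unknown, collapse = ", "))
  numeric_keys <- c("calibration_factor", "lesion_band_low", "connectivity",
                    "min_area_px", "digits", "seed")
  for (k in names(vals)) {
    if (k == "thresholds" && is.character(vals[[k]]))
      vals[[k]] <- as.numeric(strsplit(vals[[k]], ",")[[1]])
    else if (k %in% numeric_keys) vals[[k]] <- as.numeric(vals[[k]])
  }
  do.call(run_config, vals)
}
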