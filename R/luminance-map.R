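#' Calibrated luminance map
#'
#' A `luminance_map` is a numeric matrix of photometric luminance values in
#' cd/m^2, together with the linear calibration factor that converted raw
#' sensor counts to luminance and, optionally, the physical pixel pitch.
#'
#' @param values numeric matrix (rows x cols) of non-negative, finite
#'   luminance values in cd/m^2.
#' @param calibration_factor positive scalar; the raw-count to cd/m^2 scale
#'   that was (or would be) applied at load time.
#' @param pixel_pitch optional positive scalar, physical size of one pixel in
#'   mm/pixel. Enables areas in mm^2 downstream.
#'
#' @return An object of class `luminance_map`: the matrix with attributes
#'   `calibration_factor` and `pixel_pitch`.
#' @seealso [load_luminance_map()], [summarize_field()], [segment_by_bands()]
#' @export
#' @examples
#' m <- luminance_map(matrix(c(500, 510, 505, 900), 2, 2))
#' dim(m)
luminance_map <- function(values, calibration_factor = 1, pixel_pitch = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_lum("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_lum("luminance map must have at least one row and one column")
  if (anyNA(values) || any(!is.finite(values)))
    stop_lum("luminance values must all be finite")
  if (any(values < 0))
    stop_lum("luminance values must be non-negative")
  if (!is.numeric(calibration_factor) || length(calibration_factor) != 1L ||
      !is.finite(calibration_factor) || calibration_factor <= 0)
    stop_lum("'calibration_factor' must be a positive scalar")
  if (!is.null(pixel_pitch)) {
    if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L ||
        !is.finite(pixel_pitch) || pixel_pitch <= 0)
      stop_lum("'pixel_pitch' must be a positive scalar (mm/pixel) or NULL")
  }
  structure(values,
            calibration_factor = as.numeric(calibration_factor),
            pixel_pitch = if (is.null(pixel_pitch)) NULL else as.numeric(pixel_pitch),
            class = c("luminance_map", "matrix", "array"))
}

#' @export
print.luminance_map <- function(x, ...) {
  cat(sprintf("<luminance_map> %d x %d px, range [%.6g, %.6g] cd/m^2\n",
              nrow(x), ncol(x), min(x), max(x)))
  cat(sprintf("  calibration factor: %g cd/m^2 per raw count\n",
              attr(x, "calibration_factor")))
  pp <- attr(x, "pixel_pitch")
  if (!is.null(pp)) cat(sprintf("  pixel pitch: %g mm/pixel\n", pp))
  invisible(x)
}

#' Load a luminance map from a raster file or a delimited numeric grid
#'
#' Reads a single-channel 8- or 16-bit raster (uncompressed grayscale TIFF)
#' or a comma-delimited numeric grid (one CSV row per pixel row) and applies
#' a linear calibration from raw counts to cd/m^2.
#'
#' @param path file path. Format is chosen by extension: `.tif`/`.tiff` for
#'   TIFF, anything else is read as a delimited grid.
#' @param calibration_factor positive scalar multiplied into the raw counts.
#' @param pixel_pitch optional mm/pixel, stored on the result.
#' @return A [luminance_map()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.table(matrix(c(1000, 2000, 3000, 4000), 2, 2, byrow = TRUE), f,
#'             sep = ",", row.names = FALSE, col.names = FALSE)
#' m <- load_luminance_map(f, calibration_factor = 0.5)
#' m[1, 1]  # 500 cd/m^2
load_luminance_map <- function(path, calibration_factor = 1, pixel_pitch = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_lum("cannot read file: ", path)
  if (!is.numeric(calibration_factor) || length(calibration_factor) != 1L ||
      !is.finite(calibration_factor) || calibration_factor <= 0)
    stop_lum("'calibration_factor' must be a positive scalar")
  ext <- tolower(tools::file_ext(path))
  raw_counts <- if (ext %in% c("tif", "tiff")) {
    read_tiff_gray(path)
  } else {
    g <- tryCatch(
      as.matrix(read.csv(path, header = FALSE, colClasses = "numeric")),
      error = function(e) stop_lum("cannot parse '", path,
                                   "' as a delimited numeric grid: ",
                                   conditionMessage(e)))
    dimnames(g) <- NULL
    g
  }
  luminance_map(raw_counts * calibration_factor,
                calibration_factor = calibration_factor,
                pixel_pitch = pixel_pitch)
}

#' Save a luminance map as a 16-bit grayscale TIFF or a CSV grid
#'
#' For TIFF output the stored raw counts are `round(values / calibration
#' factor)`, clipped to the 16-bit range; loading the file back with the same
#' factor recovers the quantised values. CSV output stores luminance values
#' verbatim.
#'
#' @param map a [luminance_map()].
#' @param path output path; `.tif`/`.tiff` selects TIFF, else CSV.
#' @return `path`, invisibly.
#' @export
save_luminance_map <- function(map, path) {
  stopifnot(inherits(map, "luminance_map"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    cf <- attr(map, "calibration_factor")
    raw_counts <- round(unclass(map) / cf)
    if (any(raw_counts > 65535))
      warning("raw counts exceed 16-bit range; clipping to 65535")
    raw_counts[raw_counts > 65535] <- 65535
    write_tiff_gray16(raw_counts, path)
  } else {
    write.table(unclass(map), path, sep = ",",
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Define the measurement field of a luminance map
#'
#' The measurement field is the region of interest over which all statistics,
#' segmentations and focus detections are computed. It can be the whole
#' image, a rectangle, an ellipse, or an arbitrary logical mask.
#'
#' @param map a [luminance_map()] (used for shape checking).
#' @param mask logical matrix congruent with `map`; `TRUE` = inside field.
#'   If `NULL`, built from the shape arguments.
#' @param rectangle `c(row0, col0, row1, col1)` inclusive 1-based bounds.
#' @param ellipse `c(center_row, center_col, semi_row, semi_col)`.
#' @return An object of class `measurement_field`: the logical mask with a
#'   `provenance` attribute (`"whole_image"`, `"rectangle"`, `"ellipse"` or
#'   `"mask"`).
#' @export
measurement_field <- function(map, mask = NULL, rectangle = NULL, ellipse = NULL) {
  stopifnot(inherits(map, "luminance_map"))
  nr <- nrow(map); nc <- ncol(map)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), c(nr, nc)))
      stop_lum("'mask' must be a logical matrix with the map's shape")
    prov <- "mask"
  } else if (!is.null(rectangle)) {
    r <- as.integer(rectangle)
    if (length(r) != 4L || r[1] < 1L || r[2] < 1L || r[3] > nr || r[4] > nc ||
        r[1] > r[3] || r[2] > r[4])
      stop_lum("invalid rectangle bounds")
    mask <- matrix(FALSE, nr, nc)
    mask[r[1]:r[3], r[2]:r[4]] <- TRUE
    prov <- "rectangle"
  } else if (!is.null(ellipse)) {
    e <- as.numeric(ellipse)
    if (length(e) != 4L || e[3] <= 0 || e[4] <= 0)
      stop_lum("invalid ellipse parameters")
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask <- ((rows - e[1]) / e[3])^2 + ((cols - e[2]) / e[4])^2 <= 1
    prov <- "ellipse"
  } else {
    mask <- matrix(TRUE, nr, nc)
    prov <- "whole_image"
  }
  if (!any(mask))
    stop_lum("measurement field must contain at least one pixel")
  structure(mask, provenance = prov,
            class = c("measurement_field", "matrix", "array"))
}

#' @export
print.measurement_field <- function(x, ...) {
  cat(sprintf("<measurement_field> %d x %d px, %d in field (%s)\n",
              nrow(x), ncol(x), sum(x), attr(x, "provenance")))
  invisible(x)
}

check_field <- function(map, field) {
  stopifnot(inherits(map, "luminance_map"))
  if (!inherits(field, "measurement_field"))
    field <- measurement_field(map, mask = field)
  if (!identical(dim(field), dim(map)))
    stop_lum("measurement field shape does not match the map")
  field
}

#' Summarise luminance over a measurement field
#'
#' Computes the minimum, mean and maximum luminance over the in-field pixels.
#' The maximum, Lmax, is the classification feature used by the diagnostic
#' layer.
#'
#' @param map a [luminance_map()].
#' @param field a [measurement_field()]; defaults to the whole image.
#' @return A `sample_summary` list: `l_min`, `l_mean`, `l_max` (cd/m^2) and
#'   `n_pixels`.
#' @export
#' @examples
#' m <- luminance_map(matrix(c(400, 600), 1, 2))
#' summarize_field(m)
summarize_field <- function(map, field = NULL) {
  if (is.null(field)) field <- measurement_field(map)
  field <- check_field(map, field)
  v <- unclass(map)[field]
  structure(list(l_min = min(v), l_mean = mean(v), l_max = max(v),
                 n_pixels = length(v)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf(
    "<sample_summary> n = %d px | Lmin %.6g, Lmean %.6g, Lmax %.6g cd/m^2\n",
    x$n_pixels, x$l_min, x$l_mean, x$l_max))
  invisible(x)
}

#' Illumination evenness over a background region
#'
#' Evenness is the most conservative common uniformity metric,
#' `100 * min(L) / max(L)` over a designated background field, expressed as a
#' percentage. A perfectly uniform background scores 100.
#'
#' @param map a [luminance_map()].
#' @param background_field a [measurement_field()] designating background
#'   pixels; all in-field values must be strictly positive.
#' @return Evenness percentage in (0, 100].
#' @export
illumination_evenness <- function(map, background_field) {
  background_field <- check_field(map, background_field)
  v <- unclass(map)[background_field]
  if (any(v <= 0))
    stop_lum("background contains non-positive luminance; evenness undefined")
  100 * min(v) / max(v)
}
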