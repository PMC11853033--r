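#' Luminance band definition
#'
#' A half-open luminance interval `[low, high)` with a label and a
#' pseudo-colour. A pixel exactly at a band boundary belongs to the upper
#' band, so non-overlapping bands always partition the values they cover.
#'
#' @param label band name, e.g. `"healthy"` or `"lesion"`.
#' @param low inclusive lower bound, cd/m^2.
#' @param high exclusive upper bound, cd/m^2 (may be `Inf`).
#' @param pseudo_color length-3 integer RGB in \[0, 255\] used for rendering.
#' @return A `luminance_band` list.
#' @export
#' @examples
#' luminance_band("lesion", 630, Inf, c(0, 0, 255))
luminance_band <- function(label, low, high, pseudo_color = c(128, 128, 128)) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || is.na(low) || is.na(high) || low >= high)
    stop_lum("band bounds must satisfy low < high")
  pc <- as.integer(round(pseudo_color))
  if (length(pc) != 3L || anyNA(pc) || any(pc < 0L) || any(pc > 255L))
    stop_lum("'pseudo_color' must be an RGB triple in [0, 255]")
  structure(list(label = as.character(label), low = low, high = high,
                 pseudo_color = pc),
            class = "luminance_band")
}

#' @export
print.luminance_band <- function(x, ...) {
  cat(sprintf("<luminance_band> %s: [%g, %g) cd/m^2, RGB(%d,%d,%d)\n",
              x$label, x$low, x$high,
              x$pseudo_color[1], x$pseudo_color[2], x$pseudo_color[3]))
  invisible(x)
}

#' Default two-band pseudo-colour scheme
#'
#' Tissue free of lesions renders green, suspected neoplastic tissue blue.
#' The boundary separating the two is a configuration default (healthy
#' prostate tissue peaks around 500-520 cd/m^2 and lesion foci start near
#' 630 cd/m^2), not a measured constant.
#'
#' @param lesion_low lower bound of the lesion band, cd/m^2.
#' @return List of two [luminance_band()]s named `healthy` and `lesion`.
#' @export
default_bands <- function(lesion_low = 630) {
  list(healthy = luminance_band("healthy", 0, lesion_low, c(0, 170, 0)),
       lesion = luminance_band("lesion", lesion_low, Inf, c(0, 0, 255)))
}

check_bands <- function(bands) {
  if (inherits(bands, "luminance_band")) bands <- list(bands)
  if (!is.list(bands) || !all(vapply(bands, inherits, TRUE, "luminance_band")))
    stop_lum("'bands' must be a list of luminance_band objects")
  if (length(bands) > 1L) {
    iv <- cbind(vapply(bands, `[[`, 0, "low"), vapply(bands, `[[`, 0, "high"))
    o <- order(iv[, 1])
    if (any(iv[o, 2][-nrow(iv)] > iv[o, 1][-1]))
      stop_lum("bands overlap: intervals must be pairwise disjoint")
  }
  bands
}

#' Segment a measurement field into luminance bands
#'
#' Each in-field pixel whose luminance L satisfies `low <= L < high` for some
#' band is assigned to that band; in-field pixels covered by no band are
#' unassigned. Per-band pixel counts plus the unassigned count always equal
#' the field size.
#'
#' @param map a [luminance_map()].
#' @param field a [measurement_field()]; defaults to the whole image.
#' @param bands list of pairwise non-overlapping [luminance_band()]s.
#' @return A `band_segmentation` list: `band_index` (integer matrix, `NA`
#'   outside the field, `0` unassigned, `1..k` band index), `bands`,
#'   `pixel_counts` (named per-band), `unassigned` and `field_size`.
#' @export
#' @examples
#' m <- luminance_map(matrix(c(rep(500, 70), rep(900, 30)), 10, 10))
#' seg <- segment_by_bands(m, bands = default_bands())
#' seg$pixel_counts
segment_by_bands <- function(map, field = NULL, bands = default_bands()) {
  if (is.null(field)) field <- measurement_field(map)
  field <- check_field(map, field)
  bands <- check_bands(bands)
  idx <- matrix(NA_integer_, nrow(map), ncol(map))
  idx[field] <- 0L
  v <- unclass(map)
  for (b in seq_along(bands)) {
    sel <- field & v >= bands[[b]]$low & v < bands[[b]]$high
    idx[sel] <- b
  }
  counts <- vapply(seq_along(bands), function(b) sum(idx == b, na.rm = TRUE), 0L)
  names(counts) <- vapply(bands, `[[`, "", "label")
  structure(list(band_index = idx, bands = bands, pixel_counts = counts,
                 unassigned = sum(idx == 0L, na.rm = TRUE),
                 field_size = sum(field)),
            class = "band_segmentation")
}

#' @export
print.band_segmentation <- function(x, ...) {
  cat(sprintf("<band_segmentation> field of %d px, %d band(s)\n",
              x$field_size, length(x$bands)))
  for (b in seq_along(x$bands))
    cat(sprintf("  %-12s [%g, %g): %d px\n", x$bands[[b]]$label,
                x$bands[[b]]$low, x$bands[[b]]$high, x$pixel_counts[b]))
  cat(sprintf("  unassigned: %d px\n", x$unassigned))
  invisible(x)
}

#' Render a band segmentation as a pseudo-colour RGB raster
#'
#' Paints every pixel with its band's pseudo-colour; unassigned and
#' out-of-field pixels get the neutral colour.
#'
#' @param segmentation a `band_segmentation` from [segment_by_bands()].
#' @param neutral_color RGB triple for unassigned/outside pixels.
#' @param path optional; if given, the render is also written there as PNG.
#' @return A height x width x 3 integer array of RGB values in \[0, 255\].
#' @export
render_pseudo_color <- function(segmentation, neutral_color = c(40, 40, 40),
                                path = NULL) {
  stopifnot(inherits(segmentation, "band_segmentation"))
  neutral <- as.integer(round(neutral_color))
  if (length(neutral) != 3L || anyNA(neutral) || any(neutral < 0L | neutral > 255L))
    stop_lum("'neutral_color' must be an RGB triple in [0, 255]")
  idx <- segmentation$band_index
  h <- nrow(idx); w <- ncol(idx)
  palette <- rbind(neutral,
                   t(vapply(segmentation$bands, `[[`, integer(3), "pseudo_color")))
  key <- idx + 1L
  key[is.na(key) | key < 1L] <- 1L
  out <- array(0L, c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- matrix(palette[key, ch], h, w)
  if (!is.null(path)) write_png_rgb(out, path)
  out
}
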