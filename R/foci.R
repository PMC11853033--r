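#' Detect connected lesion foci
#'
#' Finds connected components of in-field pixels whose luminance falls in the
#' lesion band, discards components smaller than `min_area_px`, and returns
#' them sorted by decreasing area. Each focus carries its pixel set, area,
#' centroid and luminance summaries, supporting localisation of lesions and
#' measurement of their shape and surface area.
#'
#' @param map a [luminance_map()].
#' @param field a [measurement_field()]; defaults to the whole image.
#' @param lesion_band a [luminance_band()]; defaults to `[630, Inf)`.
#' @param connectivity `8` (default, diagonal neighbours connect) or `4`.
#' @param min_area_px minimum component size kept, pixels; the default 5
#'   suppresses isolated bright pixels such as specular-moisture artifacts.
#' @return A list of `lesion_focus` objects, each with `pixel_indices`
#'   (n x 2 matrix of 1-based row/col), `area_px`, `area_mm2` (`NA` unless
#'   the map has a pixel pitch), `centroid` (row, col), `mean_luminance`
#'   and `max_luminance`.
#' @export
#' @examples
#' m <- matrix(500, 20, 20); m[8:12, 8:12] <- 900
#' foci <- detect_foci(luminance_map(m))
#' foci[[1]]$area_px  # 25
detect_foci <- function(map, field = NULL,
                        lesion_band = default_bands()$lesion,
                        connectivity = 8, min_area_px = 5) {
  if (is.null(field)) field <- measurement_field(map)
  field <- check_field(map, field)
  if (!inherits(lesion_band, "luminance_band"))
    stop_lum("'lesion_band' must be a luminance_band")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop_lum("'connectivity' must be 4 or 8")
  min_area_px <- as.integer(min_area_px)
  if (is.na(min_area_px) || min_area_px < 1L)
    stop_lum("'min_area_px' must be >= 1")

  v <- unclass(map)
  sel <- field & v >= lesion_band$low & v < lesion_band$high
  if (!any(sel)) return(list())
  ids <- which(sel)
  membership <- label_components(sel, connectivity)
  comps <- split(ids, membership)
  comps <- comps[lengths(comps) >= min_area_px]
  if (length(comps) == 0L) return(list())

  nr <- nrow(v)
  pp <- attr(map, "pixel_pitch")
  foci <- lapply(comps, function(px) {
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    vals <- v[px]
    structure(list(
      pixel_indices = cbind(row = rows, col = cols),
      area_px = length(px),
      area_mm2 = if (is.null(pp)) NA_real_ else length(px) * pp^2,
      centroid = c(row = mean(rows), col = mean(cols)),
      mean_luminance = mean(vals),
      max_luminance = max(vals)),
      class = "lesion_focus")
  })
  # descending area; break ties by first (smallest) linear pixel index
  first_px <- vapply(comps, min, 0L)
  areas <- vapply(foci, `[[`, 0L, "area_px")
  unname(foci[order(-areas, first_px)])
}

#' @export
print.lesion_focus <- function(x, ...) {
  cat(sprintf(paste0("<lesion_focus> %d px%s, centroid (%.1f, %.1f), ",
                     "mean %.5g / max %.5g cd/m^2\n"),
              x$area_px,
              if (is.na(x$area_mm2)) "" else sprintf(" (%.4g mm^2)", x$area_mm2),
              x$centroid[1], x$centroid[2],
              x$mean_luminance, x$max_luminance))
  invisible(x)
}

# Connected-component labelling of a logical matrix via the pixel adjacency
# graph. Returns an integer membership vector aligned with which(sel).
label_components <- function(sel, connectivity = 8L) {
  nr <- nrow(sel); nc <- ncol(sel)
  ids <- which(sel)
  if (length(ids) == 0L) return(integer(0))
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L)
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r0 <- seq_len(nr - dr)
    c0 <- if (dc >= 0L) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- sel[r0, c0, drop = FALSE] & sel[r0 + dr, c0 + dc, drop = FALSE]
    if (!any(a)) next
    hit <- which(a)
    ar <- ((hit - 1L) %% length(r0)) + r0[1]
    ac <- ((hit - 1L) %/% length(r0)) + c0[1]
    edges[[length(edges) + 1L]] <-
      cbind(ar + (ac - 1L) * nr, (ar + dr) + (ac + dc - 1L) * nr)
  }
  vert <- as.character(ids)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vert)
  if (length(edges) > 0L) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(matrix(match(e, ids), ncol = 2)))
  }
  igraph::components(g)$membership
}
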