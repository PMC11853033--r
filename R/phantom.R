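#' Specification of a synthetic luminance phantom
#'
#' Describes a tissue-sample phantom on a photometric bench: a dark,
#' almost-uniformly illuminated background (a light-absorbing table cloth),
#' an elliptical tissue region at a healthy-tissue luminance level, and an
#' optional lesion variant rendered as one or more smooth radial plateaus at
#' an elevated luminance.
#'
#' Default levels follow the luminance characterisation of prostate samples:
#' healthy tissue peaks around 500-520 cd/m^2; an advanced central lesion
#' reaches about 900 cd/m^2; a small single focus 630-660 cd/m^2; diffuse
#' multifocal lesions 680-720 cd/m^2.
#'
#' @param shape `c(rows, cols)` in pixels. The default is a scaled-down
#'   field; the measuring head itself records 4008 x 2672.
#' @param background_level background luminance, cd/m^2.
#' @param background_evenness min/max ratio of the background illumination
#'   gradient, in (0, 1].
#' @param tissue_region list with `center` (row, col) and `semi`
#'   (semi-axes, px) of the tissue ellipse; `NULL` = centred, spanning ~70%
#'   of the frame.
#' @param tissue_level luminance of lesion-free tissue, cd/m^2.
#' @param lesion_variant one of `"none"`, `"advanced_central"`,
#'   `"single_focus"`, `"multifocal_diffuse"`.
#' @param lesion_peak peak luminance at focus centres, cd/m^2; default
#'   depends on the variant (900 / 645 / 700).
#' @param lesion_edge luminance at the focus boundary, cd/m^2; the profile
#'   falls smoothly from `lesion_peak` to this value.
#' @param lesion_foci list of `list(center = c(row, col), radius = px)`;
#'   `NULL` = variant-specific deterministic layout.
#' @param plateau_frac fraction of each focus radius held flat at the peak.
#' @param noise_sd additive Gaussian pixel noise (cd/m^2), truncated so the
#'   map stays non-negative.
#' @param specular_count,specular_peak,specular_radius number, level and
#'   radius of small specular-moisture artifacts placed at random inside the
#'   tissue region.
#' @param seed RNG seed; the phantom is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(200, 300),
                         background_level = 100,
                         background_evenness = 0.98,
                         tissue_region = NULL,
                         tissue_level = 510,
                         lesion_variant = c("none", "advanced_central",
                                            "single_focus", "multifocal_diffuse"),
                         lesion_peak = NULL,
                         lesion_edge = 630,
                         lesion_foci = NULL,
                         plateau_frac = 0.6,
                         noise_sd = 2,
                         specular_count = 0,
                         specular_peak = 1300,
                         specular_radius = 1,
                         seed = 1L) {
  lesion_variant <- match.arg(lesion_variant)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L))
    stop_lum("'shape' must be c(rows, cols) with both >= 8")
  if (background_evenness <= 0 || background_evenness > 1)
    stop_lum("'background_evenness' must be in (0, 1]")
  if (noise_sd < 0) stop_lum("'noise_sd' must be >= 0")
  if (is.null(tissue_region))
    tissue_region <- list(center = (shape + 1) / 2,
                          semi = 0.35 * shape)
  if (is.null(lesion_peak))
    lesion_peak <- switch(lesion_variant, none = NA_real_,
                          advanced_central = 900, single_focus = 645,
                          multifocal_diffuse = 700)
  if (lesion_variant != "none") {
    if (!is.finite(lesion_peak) || lesion_peak <= tissue_level)
      stop_lum("'lesion_peak' must exceed 'tissue_level'")
    if (lesion_edge > lesion_peak)
      stop_lum("'lesion_edge' must not exceed 'lesion_peak'")
  }
  if (is.null(lesion_foci))
    lesion_foci <- default_foci(lesion_variant, tissue_region)
  spec <- list(shape = shape, background_level = background_level,
               background_evenness = background_evenness,
               tissue_region = tissue_region, tissue_level = tissue_level,
               lesion_variant = lesion_variant, lesion_peak = lesion_peak,
               lesion_edge = lesion_edge, lesion_foci = lesion_foci,
               plateau_frac = plateau_frac, noise_sd = noise_sd,
               specular_count = as.integer(specular_count),
               specular_peak = specular_peak,
               specular_radius = specular_radius,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Deterministic per-variant focus layouts inside the tissue ellipse.
default_foci <- function(variant, tissue_region) {
  ctr <- tissue_region$center
  semi <- tissue_region$semi
  r_unit <- min(semi)
  switch(variant,
    none = list(),
    advanced_central = list(list(center = ctr, radius = 0.70 * r_unit)),
    single_focus = list(list(center = ctr + 0.3 * semi * c(-1, 1),
                             radius = 0.15 * r_unit)),
    multifocal_diffuse = lapply(c(90, 210, 330), function(deg) {
      a <- deg * pi / 180
      list(center = ctr + 0.6 * semi * c(-cos(a), sin(a)),
           radius = 0.10 * r_unit)
    }))
}

inside_ellipse <- function(rows, cols, region) {
  ((rows - region$center[1]) / region$semi[1])^2 +
    ((cols - region$center[2]) / region$semi[2])^2 <= 1
}

#' Generate a synthetic luminance phantom with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: background with a
#' smooth left-to-right illumination gradient achieving the requested
#' evenness, an elliptical tissue plateau, lesion foci as radially symmetric
#' smooth plateaus (flat at `lesion_peak` over `plateau_frac` of the radius,
#' cosine falloff to `lesion_edge` at the boundary, tissue level outside),
#' optional specular artifacts, and additive truncated-Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return A list with
#' \describe{
#'   \item{map}{the rendered [luminance_map()]}
#'   \item{truth}{ground truth: `lesion_mask` (logical matrix), `foci`
#'     (data.frame: centre, radius, rasterised `area_px`, `peak`),
#'     `tissue_mask`, `background_mask`, and the generating `spec`}
#' }
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(lesion_variant = "single_focus",
#'                                     noise_sd = 0))
#' length(detect_foci(ph$map))  # 1
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  tissue_mask <- inside_ellipse(rows, cols, spec$tissue_region)
  for (f in spec$lesion_foci) {
    if (!inside_ellipse(f$center[1], f$center[2], spec$tissue_region))
      stop_lum("lesion focus centre lies outside the tissue region")
  }

  # background with a horizontal linear illumination gradient:
  # min/max over the frame equals the requested evenness
  grad <- if (nc > 1)
    spec$background_evenness +
      (1 - spec$background_evenness) * (cols - 1) / (nc - 1)
  else matrix(1, nr, nc)
  values <- spec$background_level * grad
  values[tissue_mask] <- spec$tissue_level

  lesion_mask <- matrix(FALSE, nr, nc)
  truth_foci <- data.frame(row = numeric(0), col = numeric(0),
                           radius = numeric(0), area_px = integer(0),
                           peak = numeric(0))
  for (f in spec$lesion_foci) {
    r <- sqrt((rows - f$center[1])^2 + (cols - f$center[2])^2)
    disk <- r <= f$radius
    rp <- spec$plateau_frac * f$radius
    s <- matrix(0, nr, nc)
    s[disk] <- ifelse(r[disk] <= rp, 1,
                      0.5 * (1 + cos(pi * (r[disk] - rp) / (f$radius - rp))))
    lum <- spec$lesion_edge + (spec$lesion_peak - spec$lesion_edge) * s
    values[disk] <- pmax(values[disk], lum[disk])
    lesion_mask <- lesion_mask | disk
    truth_foci <- rbind(truth_foci,
                        data.frame(row = f$center[1], col = f$center[2],
                                   radius = f$radius, area_px = sum(disk),
                                   peak = spec$lesion_peak))
  }

  values <- with_seed(spec$seed, {
    if (spec$specular_count > 0) {
      cand <- which(tissue_mask & !lesion_mask)
      pick <- sample(cand, min(spec$specular_count, length(cand)))
      for (p in pick) {
        pr <- ((p - 1) %% nr) + 1; pc <- ((p - 1) %/% nr) + 1
        r <- sqrt((rows - pr)^2 + (cols - pc)^2)
        values[r <= spec$specular_radius] <- spec$specular_peak
      }
    }
    if (spec$noise_sd > 0)
      values <- pmax(values + rnorm(nr * nc, 0, spec$noise_sd), 0)
    values
  })

  list(map = luminance_map(values),
       truth = list(lesion_mask = lesion_mask, foci = truth_foci,
                    tissue_mask = tissue_mask,
                    background_mask = !tissue_mask, spec = spec))
}
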