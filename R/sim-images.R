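# Ellipse semi-axes per body part, as fractions of the image half-extent:
# abdomen and cephalothorax are roundish, the leg (femur) is elongated.
part_geometry <- function(part) {
  switch(part,
    abdomen       = c(row = 0.72, col = 0.72),
    cephalothorax = c(row = 0.55, col = 0.55),
    right_leg_1   = c(row = 0.25, col = 0.85),
    stop("unknown body part: ", part))
}

#' Render a synthetic white-light / fluorescence image pair
#'
#' Builds two same-sized 12-bit rasters for one specimen body part: a
#' fluorescence image whose body-shaped region (a filled ellipse) has pixel
#' values drawn around a specimen-level emission mean (itself a truncated
#' normal around the group's configured mean and dispersion) over a dim
#' background, and a white-light image showing the same shape at a fixed
#' visibility level (the image on which areas of interest would be
#' traced). With the group's zero-inflation probability the specimen has
#' no brightly fluorescing patch; otherwise a concentric sub-ellipse
#' covering a Beta-drawn fraction of the body carries pixels around
#' `bright_patch_level`, which is what gives the percent-in-brightest
#' score its zero-inflated, group-ordered structure. Three AOI polygons
#' are placed analytically inside the body region. All pixel values are
#' integers clamped to \[0, 4095\].
#'
#' @param group group label.
#' @param part body-part label; `right_leg_1` is invalid for immatures.
#' @param config a [sim_config()].
#' @param specimen_seed integer substream seed for this render.
#' @return list with `white` and `fluor` ([gray_image]), `aois` (list of
#'   [aoi_polygon]), and `truth` (true mean emission and expected
#'   bright-area fraction).
#' @export
render_image_pair <- function(group, part, config, specimen_seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!part %in% parts_for_group(group, config$body_parts)) {
    stop("body part '", part, "' is not measured for group '", group, "'")
  }
  nr <- config$image_size[1L]
  nc <- config$image_size[2L]
  geom <- part_geometry(part)
  a <- geom[["row"]] * (nr - 1) / 2   # semi-axis along rows
  b <- geom[["col"]] * (nc - 1) / 2   # semi-axis along cols
  if (a < 6 || b < 6) {
    stop("generation error: image_size ", nr, "x", nc,
         " too small to contain the body shape for ", part)
  }
  cy <- (nr - 1) / 2
  cx <- (nc - 1) / 2
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  body <- ((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1

  br <- config$group_brightness[[group]]
  p0 <- config$zero_inflation[[group]]
  imgs <- withr::with_seed(specimen_seed, {
    spec_mean <- rtruncnorm(1L, br[["mean"]], br[["dispersion"]], 0, 4095)
    has_patch <- runif(1L) >= p0
    frac <- if (has_patch) {
      mu <- clamp(br[["mean"]] / 4095, 0.02, 0.95)
      rbeta(1L, mu * 8, (1 - mu) * 8)
    } else 0
    fl <- matrix(rtruncnorm(nr * nc, config$background_level,
                            config$noise_sd, 0, 4095), nr, nc)
    fl[body] <- rtruncnorm(sum(body), spec_mean, config$noise_sd, 0, 4095)
    if (frac > 0) {
      # concentric sub-ellipse; scaling both semi-axes by sqrt(frac) makes
      # its area frac times the body area
      patch <- ((rows - cy) / (a * sqrt(frac)))^2 +
        ((cols - cx) / (b * sqrt(frac)))^2 <= 1
      patch <- patch & body
      if (any(patch)) {
        fl[patch] <- rtruncnorm(sum(patch), config$bright_patch_level,
                                config$noise_sd, 0, 4095)
      }
    }
    wh <- matrix(rtruncnorm(nr * nc, 600, config$noise_sd, 0, 4095), nr, nc)
    wh[body] <- rtruncnorm(sum(body), 2800, config$noise_sd, 0, 4095)
    list(fl = fl, wh = wh, spec_mean = spec_mean, frac = frac)
  })
  fluor <- gray_image(clamp(round(imgs$fl), 0, 4095))
  white <- gray_image(clamp(round(imgs$wh), 0, 4095))

  # Three quadrilaterals at column offsets -b/2, 0, +b/2; half-sizes a/3 x
  # b/6 keep every vertex strictly inside the ellipse.
  aois <- lapply(seq_len(config$aois_per_part), function(k) {
    off <- (k - (config$aois_per_part + 1) / 2) * b / 2
    dr <- a / 3
    dc <- b / 6
    aoi_polygon(cbind(
      row = c(cy - dr, cy - dr, cy + dr, cy + dr),
      col = c(cx + off - dc, cx + off + dc, cx + off + dc, cx + off - dc)),
      body_part = part, aoi_index = k)
  })

  list(white = white, fluor = fluor, aois = aois,
       truth = list(group = group, body_part = part,
                    true_mean = imgs$spec_mean,
                    true_bright_fraction = imgs$frac))
}
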