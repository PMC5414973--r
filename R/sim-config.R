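#' Study group and body-part vocabularies
#'
#' The five sex/life-stage groups and three body parts measured in the
#' whole-specimen fluorescence design. Right leg 1 is never measured for
#' immatures (too small to dissect and image).
#'
#' @export
study_groups <- c("adult_female", "adult_male", "penultimate_female",
                  "penultimate_male", "immature")

#' @rdname study_groups
#' @export
study_body_parts <- c("abdomen", "cephalothorax", "right_leg_1")

#' @rdname study_groups
#' @export
filter_configs <- c("dichroic_only", "blocking")

#' Default per-group emission brightness (12-bit levels)
#'
#' Means and dispersions of the true emission level for each group, chosen
#' to reproduce the qualitative ordering of the study: females (adult and
#' penultimate) brightest, adult males dimmest, penultimate males and
#' immatures intermediate.
#'
#' @return named list, each element `c(mean, dispersion)` on the 0--4095 scale.
#' @export
default_group_brightness <- function() {
  list(
    adult_female       = c(mean = 2000, dispersion = 500),
    adult_male         = c(mean = 400,  dispersion = 250),
    penultimate_female = c(mean = 2200, dispersion = 500),
    penultimate_male   = c(mean = 1100, dispersion = 450),
    immature           = c(mean = 1500, dispersion = 450)
  )
}

default_zero_inflation <- function() {
  c(adult_female = 0.05, adult_male = 0.60, penultimate_female = 0.05,
    penultimate_male = 0.35, immature = 0.25)
}

#' Simulation configuration
#'
#' Defines a synthetic study: group sample sizes (defaulting to the
#' beam-splitter-only subset 10/5/4/9/9), body parts, AOIs per part, image
#' geometry, per-group brightness distributions, zero-inflation
#' probabilities for the percent-in-brightest score, and pixel noise.
#'
#' @param seed master seed; every specimen draws from a derived substream so
#'   results do not depend on generation order.
#' @param groups named integer vector: specimens per group. Names must be
#'   drawn from [study_groups].
#' @param body_parts body-part labels measured (immatures automatically skip
#'   `right_leg_1`).
#' @param aois_per_part number of traced areas of interest per body part.
#' @param image_size `c(rows, cols)` of rendered rasters.
#' @param group_brightness named list of `c(mean, dispersion)` per group, on
#'   the 12-bit 0--4095 scale.
#' @param zero_inflation named numeric vector: probability that a group's
#'   percent-in-brightest draw is exactly zero.
#' @param background_level mean background pixel value.
#' @param noise_sd pixel noise standard deviation.
#' @param filters filter configurations generated per specimen.
#' @param blocking_attenuation multiplicative brightness attenuation of the
#'   optional blocking filter relative to the dichroic beam splitter alone.
#' @param bright_patch_level mean pixel value inside a specimen's brightly
#'   fluorescing patch (rendered images only); sits in the bright bins so
#'   the percent-in-brightest score responds to patch area.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       groups = c(adult_female = 10L, adult_male = 5L,
                                  penultimate_female = 4L,
                                  penultimate_male = 9L, immature = 9L),
                       body_parts = study_body_parts,
                       aois_per_part = 3L,
                       image_size = c(96L, 96L),
                       group_brightness = default_group_brightness(),
                       zero_inflation = default_zero_inflation(),
                       background_level = 120,
                       noise_sd = 40,
                       filters = filter_configs,
                       blocking_attenuation = 0.4,
                       bright_patch_level = 3300) {
  if (!is_count(seed + 1)) stop("`seed` must be a single integer")
  if (is.null(names(groups)) || any(!names(groups) %in% study_groups)) {
    stop("configuration error: group labels must be among: ",
         paste(study_groups, collapse = ", "))
  }
  if (any(groups < 1)) stop("configuration error: group sizes must be >= 1")
  if (any(!body_parts %in% study_body_parts)) {
    stop("configuration error: unknown body part")
  }
  means <- vapply(group_brightness, `[`, numeric(1), 1L)
  if (any(means < 0 | means > 4095)) {
    stop("configuration error: brightness means must lie in [0, 4095]")
  }
  if (any(zero_inflation < 0 | zero_inflation > 1)) {
    stop("configuration error: zero-inflation probabilities must lie in [0, 1]")
  }
  if (any(!names(zero_inflation) %in% study_groups) ||
      any(!names(group_brightness) %in% study_groups)) {
    stop("configuration error: unknown group label in brightness/zero-inflation map")
  }
  if (!all(names(groups) %in% names(group_brightness)) ||
      !all(names(groups) %in% names(zero_inflation))) {
    stop("configuration error: every group needs a brightness and zero-inflation entry")
  }
  structure(list(
    seed = as.integer(seed), groups = groups, body_parts = body_parts,
    aois_per_part = as.integer(aois_per_part),
    image_size = as.integer(image_size),
    group_brightness = group_brightness, zero_inflation = zero_inflation,
    background_level = background_level, noise_sd = noise_sd,
    filters = filters, blocking_attenuation = blocking_attenuation,
    bright_patch_level = bright_patch_level
  ), class = "sim_config")
}

# Body parts actually measured for a group: immatures have no measurable leg.
parts_for_group <- function(group, body_parts) {
  if (group == "immature") setdiff(body_parts, "right_leg_1") else body_parts
}
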