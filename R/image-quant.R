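#' 12-bit grayscale image
#'
#' A non-empty 2-D integer raster with values in 0--4095 (4096 levels of
#' gray: 0 is black, 4095 is white). Values are carried in ordinary
#' integer storage; inputs outside the 12-bit range are rejected, never
#' silently clamped, so wrong-depth files are caught at the door.
#'
#' @param pixels numeric/integer matrix.
#' @return object of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("pixels must be a non-empty matrix")
  }
  if (any(pixels != round(pixels))) stop("pixel values must be integers")
  if (any(pixels < 0 | pixels > 4095)) {
    stop("pixel values outside the 12-bit range [0, 4095]")
  }
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels)),
                 bit_depth = 12L, max_value = 4095L),
            class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Area-of-interest polygon
#'
#' A closed polygon (implicit last-to-first edge) in 0-based pixel-center
#' (row, col) coordinates, delimiting one traced region of one body part.
#'
#' @param vertices two-column matrix of (row, col) vertices, at least 3.
#' @param body_part body-part label.
#' @param aoi_index index of this AOI within its body part (1-based).
#' @export
aoi_polygon <- function(vertices, body_part = NA_character_, aoi_index = 1L) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L) {
    stop("an AOI needs at least 3 (row, col) vertices")
  }
  colnames(vertices) <- c("row", "col")
  structure(list(vertices = vertices, body_part = body_part,
                 aoi_index = as.integer(aoi_index)),
            class = "aoi_polygon")
}

#' Ten-category brightness binning scheme
#'
#' Partitions the 4096 gray levels into ten equal categories of 409.6
#' levels each (`bin = floor(value * 10 / 4096) + 1`), grouped further into
#' dim / medium / bright classes. Which bins count as the "brightest
#' category" for the percent-area score is configurable: the whole bright
#' class (default) or the single top bin.
#'
#' @param dim_bins,medium_bins,bright_bins disjoint partition of bins 1--10.
#' @param brightest `"bright_class"` (all bright bins) or `"top_bin"`
#'   (bin 10 only).
#' @export
binning_scheme <- function(dim_bins = 1:3, medium_bins = 4:7,
                           bright_bins = 8:10,
                           brightest = c("bright_class", "top_bin")) {
  brightest <- match.arg(brightest)
  all_bins <- sort(c(dim_bins, medium_bins, bright_bins))
  if (!identical(as.integer(all_bins), 1:10)) {
    stop("dim/medium/bright must partition bins 1..10 disjointly")
  }
  structure(list(n_bins = 10L, dim_bins = as.integer(dim_bins),
                 medium_bins = as.integer(medium_bins),
                 bright_bins = as.integer(bright_bins),
                 brightest_bins = if (brightest == "top_bin") 10L
                                  else as.integer(bright_bins),
                 brightest = brightest),
            class = "binning_scheme")
}

#' Rasterize an AOI polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its center satisfies the even-odd
#' (crossing-number) rule for the polygon; pixel centers lying exactly on a
#' polygon edge count as inside. The rule is independent of vertex
#' orientation.
#'
#' @param polygon an [aoi_polygon()].
#' @param shape `c(rows, cols)` of the target image.
#' @return logical matrix of that shape.
#' @export
rasterize_aoi <- function(polygon, shape) {
  stopifnot(inherits(polygon, "aoi_polygon"), length(shape) == 2L)
  v <- polygon$vertices
  if (polygon_area(v) == 0) {
    stop("rasterization error: degenerate (zero-area) polygon")
  }
  if (any(v[, "row"] < 0 | v[, "row"] > shape[1L] - 1 |
          v[, "col"] < 0 | v[, "col"] > shape[2L] - 1)) {
    stop("rasterization error: polygon vertices outside image bounds")
  }
  mask <- matrix(FALSE, shape[1L], shape[2L])
  r0 <- max(0L, floor(min(v[, "row"])))
  r1 <- min(shape[1L] - 1L, ceiling(max(v[, "row"])))
  c0 <- max(0L, floor(min(v[, "col"])))
  c1 <- min(shape[2L] - 1L, ceiling(max(v[, "col"])))
  for (r in r0:r1) {
    for (cc in c0:c1) {
      mask[r + 1L, cc + 1L] <- point_in_polygon(r, cc, v)
    }
  }
  if (!any(mask)) {
    stop("rasterization error: polygon contains no pixel centers")
  }
  mask
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  abs(sum(v[, "row"] * v[j, "col"] - v[j, "row"] * v[, "col"])) / 2
}

# Even-odd test for one pixel center (pr, pc); on-edge points are inside.
point_in_polygon <- function(pr, pc, v) {
  n <- nrow(v)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    yi <- v[i, "row"]; xi <- v[i, "col"]
    yj <- v[j, "row"]; xj <- v[j, "col"]
    # on-segment check (collinear and within the segment's bounding box)
    cross <- (pr - yi) * (xj - xi) - (pc - xi) * (yj - yi)
    if (abs(cross) < 1e-9 &&
        pc >= min(xi, xj) - 1e-9 && pc <= max(xi, xj) + 1e-9 &&
        pr >= min(yi, yj) - 1e-9 && pr <= max(yi, yj) + 1e-9) {
      return(TRUE)
    }
    if ((yi > pr) != (yj > pr)) {
      xint <- xi + (pr - yi) * (xj - xi) / (yj - yi)
      if (pc < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Mean pixel intensity over a mask
#'
#' @param image a [gray_image()].
#' @param mask logical matrix of the same shape, at least one `TRUE`.
#' @return arithmetic mean of the masked pixel values, in \[0, 4095\].
#' @export
mean_intensity <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"))
  if (!identical(dim(mask), dim(image$pixels))) {
    stop("measurement error: mask shape differs from image shape")
  }
  if (!any(mask)) stop("measurement error: empty mask")
  mean(image$pixels[mask])
}

#' Assign a pixel value to one of the ten brightness bins
#'
#' `bin = floor(value * 10 / 4096) + 1`, so the 4096 levels split into ten
#' equal 409.6-level categories with no empty boundary class.
#'
#' @param value integer pixel value(s) in 0--4095.
#' @param scheme a [binning_scheme()] (bin rule is fixed; kept for symmetry).
#' @return bin index (1--10), vectorized.
#' @export
assign_bin <- function(value, scheme = binning_scheme()) {
  if (any(value < 0 | value > 4095)) {
    stop("domain error: pixel value outside [0, 4095]")
  }
  as.integer(floor(value * 10 / 4096) + 1)
}

#' Ten-bin brightness histogram over a mask
#'
#' @inheritParams mean_intensity
#' @param scheme a [binning_scheme()].
#' @return integer vector of ten counts summing to the mask size.
#' @export
histogram_ten_bins <- function(image, mask, scheme = binning_scheme()) {
  stopifnot(inherits(image, "gray_image"))
  if (!identical(dim(mask), dim(image$pixels))) {
    stop("measurement error: mask shape differs from image shape")
  }
  if (!any(mask)) stop("measurement error: empty mask")
  tabulate(assign_bin(image$pixels[mask], scheme), nbins = 10L)
}

#' Percent of pixels in the brightest category
#'
#' @param histogram ten nonnegative counts with positive sum.
#' @param scheme a [binning_scheme()]; its `brightest_bins` defines the
#'   brightest category.
#' @return percentage in \[0, 100\].
#' @export
percent_brightest <- function(histogram, scheme = binning_scheme()) {
  if (length(histogram) != 10L || any(histogram < 0)) {
    stop("histogram must be ten nonnegative counts")
  }
  total <- sum(histogram)
  if (total == 0) stop("measurement error: zero total count")
  100 * sum(histogram[scheme$brightest_bins]) / total
}

#' Summarize one body part from its fluorescence image and AOIs
#'
#' Applies each traced AOI to the fluorescence image, measures mean
#' intensity, the ten-bin histogram and percent-in-brightest per AOI, and
#' combines them into a single per-body-part summary. With
#' `combine_rule = "mean_of_aois"` the mean intensity and percent scores
#' are unweighted means of the per-AOI values (robust to unequal AOI
#' areas); with `"pooled"` all masked pixels are pooled first. The
#' histogram is always the pooled (summed) histogram, so its counts sum to
#' `n_pixels`.
#'
#' @param fluor fluorescence [gray_image()].
#' @param aois list of 1--3 [aoi_polygon()]s.
#' @param scheme a [binning_scheme()].
#' @param combine_rule `"mean_of_aois"` or `"pooled"`.
#' @param specimen_id,filter_config carried into the summary record.
#' @return object of class `intensity_summary`.
#' @export
summarize_body_part <- function(fluor, aois, scheme = binning_scheme(),
                                combine_rule = c("mean_of_aois", "pooled"),
                                specimen_id = NA_character_,
                                filter_config = NA_character_) {
  combine_rule <- match.arg(combine_rule)
  if (length(aois) < 1L || length(aois) > 3L) {
    stop("expected 1-3 AOIs per body part")
  }
  shape <- dim(fluor$pixels)
  per <- lapply(seq_along(aois), function(k) {
    res <- tryCatch({
      mask <- rasterize_aoi(aois[[k]], shape)
      hist <- histogram_ten_bins(fluor, mask, scheme)
      list(mean = mean_intensity(fluor, mask), hist = hist,
           pct = percent_brightest(hist, scheme), n = sum(mask))
    }, error = function(e) {
      stop("AOI ", k, ": ", conditionMessage(e), call. = FALSE)
    })
    res
  })
  hist <- Reduce(`+`, lapply(per, `[[`, "hist"))
  n_pixels <- sum(vapply(per, `[[`, numeric(1), "n"))
  if (combine_rule == "mean_of_aois") {
    m <- mean(vapply(per, `[[`, numeric(1), "mean"))
    pct <- mean(vapply(per, `[[`, numeric(1), "pct"))
  } else {
    m <- sum(vapply(per, function(x) x$mean * x$n, numeric(1))) / n_pixels
    pct <- percent_brightest(hist, scheme)
  }
  structure(list(
    specimen_id = specimen_id, body_part = aois[[1L]]$body_part,
    mean_intensity = m, histogram = hist, percent_brightest = pct,
    n_pixels = n_pixels, filter_config = filter_config,
    combine_rule = combine_rule
  ), class = "intensity_summary")
}
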