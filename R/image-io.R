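#' Read / write 12-bit images in 16-bit TIFF containers
#'
#' Images are stored as single-channel 16-bit TIFF holding 12-bit values
#' (0--4095). On read, any sample above 4095 is a hard error -- a wrong
#' bit-depth file, never silently clamped.
#'
#' @param image a [gray_image()].
#' @param path TIFF file path.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_gray_image
#' @export
read_gray_image <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (is.array(px) && length(dim(px)) == 3L) px <- px[, , 1L]
  if (any(px > 4095)) {
    stop("corrupt or wrong-depth image '", path,
         "': pixel value ", max(px), " exceeds the 12-bit maximum 4095")
  }
  gray_image(px)
}

#' Read / write AOI polygons as JSON
#'
#' One JSON array per image: each element has `body_part`, `aoi_index`, and
#' `vertices`, a list of \[row, col\] pairs in 0-based pixel-center
#' coordinates.
#'
#' @param aois list of [aoi_polygon()]s.
#' @param path JSON file path.
#' @export
write_aois <- function(aois, path) {
  payload <- lapply(aois, function(a) {
    list(body_part = a$body_part, aoi_index = a$aoi_index,
         vertices = unname(apply(a$vertices, 1L, c, simplify = FALSE)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aois
#' @export
read_aois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(a) {
    v <- do.call(rbind, lapply(a$vertices, function(p) unlist(p)))
    aoi_polygon(v, body_part = a$body_part, aoi_index = a$aoi_index)
  })
}
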