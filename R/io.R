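#' Write or read a field image as 16-bit TIFF with a JSON sidecar
#'
#' The TIFF stores intensities in \[0, 1\] at 16 bits per sample; the sidecar
#' (`<path>.json`) records pixel size, area/field indices, tendon id and any
#' provenance passed in `meta`.
#'
#' @param field a `field_image`.
#' @param path TIFF path.
#' @param meta optional named list merged into the sidecar.
#' @return `read_field_tiff()` returns a `field_image`.
#' @export
write_field_tiff <- function(field, path, meta = list()) {
  stopifnot(inherits(field, "field_image"))
  # tiff expects [row = y, col = x]
  tiff::writeTIFF(t(field$pixels), path, bits.per.sample = 16L,
                  compression = "none")
  side <- c(list(pixel_size_um = field$pixel_size,
                 area_index = field$area_index,
                 field_index = field$field_index,
                 tendon_id = field$tendon_id), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(pixels = t(m), pixel_size = side$pixel_size_um,
         area_index = as.integer(side$area_index),
         field_index = as.integer(side$field_index),
         tendon_id = side$tendon_id),
    class = "field_image")
}

#' Serialize a generator's ground truth to JSON
#'
#' The ground-truth attribute attached by the `simulate_*` generators is
#' written as plain JSON so expected downstream values can be recomputed
#' without re-simulation.
#'
#' @param x an object carrying a `ground_truth` attribute.
#' @param path JSON path.
#' @return `read_ground_truth()` returns the ground-truth list.
#' @export
write_ground_truth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("object has no ground_truth attribute", call. = FALSE)
  gt <- rapply(gt, unclass, how = "replace")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
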