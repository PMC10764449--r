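#' Detect and measure nuclei in a fluorescence field
#'
#' Segmentation pipeline: Gaussian smoothing (sigma given in um), global Otsu
#' threshold, 8-connected component labelling, area filter, and optional
#' declumping of over-large components by watershed on the distance transform.
#' Each object is measured by its intensity-free second moments: centroid,
#' pixel area, and fitted-ellipse orientation.
#'
#' @param image a `field_image` (or plain matrix indexed `[x, y]`, values in
#'   \[0, 1\], with `pixel_size` then required).
#' @param sigma_um smoothing SD in um (default 1).
#' @param min_area_um2,max_area_um2 object area filter in um^2 (defaults
#'   8-120).
#' @param declump if `TRUE` (default), components larger than
#'   `declump_area_um2` are split by distance-transform watershed before the
#'   area filter.
#' @param declump_area_um2 single-nucleus area ceiling that triggers
#'   declumping; default 110 um^2, about 1.8 times the area of the packaged
#'   20 x 4 um nucleus.
#' @param min_class_separation minimum standardized separation
#'   `(mu_fg - mu_bg) / s_within` between the Otsu classes; below it the
#'   field is treated as empty (a unimodal noise-only image always splits
#'   somewhere, at separation about 2.6).
#' @param pixel_size um per pixel, taken from the `field_image` when present.
#' @return a `nuclei_set`: data.frame with `x_px`, `y_px` (pixel centroid,
#'   origin top-left, y downward), `area_px`, `area_um2`, `orientation_deg`
#'   (degrees from +x, counterclockwise with y up, in (-90, 90]). An
#'   `all_constant` attribute flags the degenerate constant-image case (empty
#'   set with a warning rather than an error).
#' @export
detect_nuclei <- function(image, sigma_um = 1.0,
                          min_area_um2 = 8, max_area_um2 = 120,
                          declump = TRUE, declump_area_um2 = 110,
                          min_class_separation = 4,
                          pixel_size = NULL) {
  if (inherits(image, "field_image")) {
    pixel_size <- image$pixel_size
    img <- image$pixels
  } else {
    img <- image
  }
  stopifnot(is.matrix(img))
  if (is.null(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive", call. = FALSE)
  }
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      orientation_deg = numeric(0))
  class(empty) <- c("nuclei_set", "data.frame")
  if (diff(range(img)) < 1e-10) {
    warning("all-constant image: Otsu threshold undefined, returning empty set")
    attr(empty, "all_constant") <- TRUE
    return(empty)
  }
  sm <- EBImage::gblur(img, sigma = sigma_um / pixel_size)
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  mask <- sm > thr
  # Otsu always splits a unimodal (empty) field: require genuine bimodal
  # separation between the foreground and background classes before
  # accepting any objects
  mu0 <- mean(sm[!mask]); mu1 <- mean(sm[mask])
  s0 <- sd(sm[!mask]); s1 <- sd(sm[mask])
  sep <- (mu1 - mu0) / sqrt((s0^2 + s1^2) / 2)
  if (!is.finite(sep) || sep < min_class_separation) {
    attr(empty, "all_constant") <- FALSE
    return(empty)
  }
  lab <- EBImage::bwlabel(mask)
  px_area <- pixel_size^2

  if (declump) {
    counts <- tabulate(lab[lab > 0])
    big <- which(counts * px_area > declump_area_um2)
    if (length(big)) {
      big_mask <- matrix(lab %in% big, nrow(lab), ncol(lab))
      dm <- EBImage::distmap(big_mask)
      ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
      keep <- EBImage::imageData(lab)
      keep[big_mask] <- 0
      keep <- EBImage::bwlabel(keep > 0)
      ws_dat <- EBImage::imageData(ws)
      off <- max(keep)
      keep[ws_dat > 0] <- ws_dat[ws_dat > 0] + off
      lab <- keep
    }
  }
  lab <- EBImage::imageData(lab)
  ids <- which(tabulate(lab[lab > 0]) > 0)
  if (!length(ids)) return(empty)

  idx <- which(lab > 0)
  obj <- lab[idx]
  ix <- ((idx - 1) %% nrow(lab)) + 1   # x pixel index
  iy <- ((idx - 1) %/% nrow(lab)) + 1  # y pixel index (downward)
  n_px <- tapply(rep(1, length(obj)), obj, sum)
  mx <- tapply(ix, obj, mean)
  my <- tapply(iy, obj, mean)
  # central second moments in y-up coordinates for the orientation convention
  sxx <- tapply(ix, obj, var)
  syy <- tapply(iy, obj, var)
  sxy <- -(tapply(ix * iy, obj, mean) - mx * my) * n_px / pmax(n_px - 1, 1)
  theta <- fold_angle(0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi)
  area_um2 <- as.numeric(n_px) * px_area
  keep <- area_um2 >= min_area_um2 & area_um2 <= max_area_um2
  out <- data.frame(x_px = as.numeric(mx)[keep] - 0.5,
                    y_px = as.numeric(my)[keep] - 0.5,
                    area_px = as.integer(n_px)[keep],
                    area_um2 = area_um2[keep],
                    orientation_deg = as.numeric(theta)[keep])
  class(out) <- c("nuclei_set", "data.frame")
  attr(out, "all_constant") <- FALSE
  out
}

#' Cellularity fold change versus the healthy reference
#'
#' Mean nucleus count over all treated fields divided by the mean count over
#' all healthy-reference fields.
#'
#' @param treated_counts,healthy_counts numeric vectors of per-field counts
#'   (any area/field structure flattened).
#' @return the fold change (dimensionless, > 0).
#' @export
cellularity_fold_change <- function(treated_counts, healthy_counts) {
  if (!length(treated_counts) || !length(healthy_counts)) {
    stop("both count vectors must be nonempty", call. = FALSE)
  }
  h <- mean(healthy_counts)
  if (!is.finite(h) || h <= 0) {
    stop("healthy reference mean count must be positive", call. = FALSE)
  }
  mean(treated_counts) / h
}
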