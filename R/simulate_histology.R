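#' Simulate a single-channel fluorescence nuclei field
#'
#' Renders one field of the five-areas-by-four-fields tendon sampling scheme:
#' a Poisson number of elliptical nuclei, centers placed by rejection sampling
#' under a minimum spacing (falling back to unconstrained placement after
#' `placement_cap` rejections, recorded in the ground truth), orientations
#' drawn from a normal folded to (-90, 90], rendered as anti-aliased filled
#' ellipses over a constant background, plus additive Gaussian noise clipped
#' to \[0, 1\].
#'
#' Pixel convention: the image matrix is indexed `[x, y]` with x rightward and
#' y downward (origin top-left). Orientations are degrees from the +x axis
#' (the tendon longitudinal axis), counterclockwise when y points up.
#'
#' @param preset a [histology_preset()].
#' @param area_index tendon area 1-5 (area 3 is the lesion core).
#' @param field_index field 1-4 within the area.
#' @param seed integer seed.
#' @param tendon_id identifier stored on the image.
#' @return a `field_image`: list with `pixels` (matrix `[x, y]`, values in
#'   \[0, 1\]), `pixel_size`, `area_index`, `field_index`, `tendon_id`, and a
#'   `ground_truth` attribute listing every nucleus (`x_um`, `y_um` from the
#'   top-left corner, y downward; `orientation_deg`; `major_um`; `minor_um`;
#'   `forced` placement flag), the preset and the seed.
#' @export
simulate_histology_field <- function(preset, area_index = 1L, field_index = 1L,
                                     seed, tendon_id = "tendon_1") {
  stopifnot(inherits(preset, "histology_preset"))
  if (missing(seed)) stop("seed must be given", call. = FALSE)
  stopifnot(area_index %in% 1:5, field_index %in% 1:4)
  ps <- preset$pixel_size
  W <- preset$field_size[1]; H <- preset$field_size[2]
  a <- preset$nucleus_axes[1] / 2  # semi-axes, um
  b <- preset$nucleus_axes[2] / 2
  if (2 * a >= W || 2 * a >= H) {
    stop("field too small for a single nucleus", call. = FALSE)
  }
  wpx <- round(W / ps); hpx <- round(H / ps)

  gt <- with_seed(seed, {
    n <- rpois(1, preset$nuclei_per_field_mean)
    cx <- numeric(n); cy <- numeric(n); forced <- logical(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (tries in seq_len(preset$placement_cap)) {
        px <- runif(1, a, W - a); py <- runif(1, a, H - a)
        if (i == 1L ||
            min((cx[seq_len(i - 1)] - px)^2 + (cy[seq_len(i - 1)] - py)^2) >=
              preset$min_center_distance^2) {
          ok <- TRUE
          break
        }
      }
      if (!ok) forced[i] <- TRUE
      cx[i] <- px; cy[i] <- py
    }
    th <- fold_angle(rnorm(n, preset$orientation_mean, preset$orientation_sd))
    noise <- rnorm(wpx * hpx, 0, preset$noise_sd)
    list(n = n, x_um = cx, y_um = cy, orientation_deg = th, forced = forced,
         noise = noise)
  })

  img <- matrix(preset$background_level, wpx, hpx)
  amp <- preset$nucleus_intensity - preset$background_level
  apx <- a / ps; bpx <- b / ps
  for (i in seq_len(gt$n)) {
    t <- gt$orientation_deg[i] * pi / 180
    x0 <- gt$x_um[i] / ps
    yup0 <- hpx - gt$y_um[i] / ps  # renderer works in y-up coordinates
    ix0 <- max(1, floor(x0 - apx - 2)); ix1 <- min(wpx, ceiling(x0 + apx + 2))
    iy0 <- max(1, floor(hpx - yup0 - apx - 2))
    iy1 <- min(hpx, ceiling(hpx - yup0 + apx + 2))
    ixs <- ix0:ix1; iys <- iy0:iy1
    X <- matrix(ixs - 0.5, length(ixs), length(iys))
    Yup <- matrix(rep(hpx - (iys - 0.5), each = length(ixs)), length(ixs))
    dx <- X - x0; dy <- Yup - yup0
    u <- dx * cos(t) + dy * sin(t)
    v <- -dx * sin(t) + dy * cos(t)
    d <- sqrt((u / apx)^2 + (v / bpx)^2)
    # soft edge roughly one pixel wide in the minor-axis direction
    soft <- pmin(pmax((1 - d) * bpx, 0), 1)
    img[ixs, iys] <- pmax(img[ixs, iys], preset$background_level + amp * soft)
  }
  img <- pmin(pmax(img + gt$noise, 0), 1)

  field <- structure(
    list(pixels = img, pixel_size = ps, area_index = as.integer(area_index),
         field_index = as.integer(field_index), tendon_id = tendon_id),
    class = "field_image")
  attr(field, "ground_truth") <- list(
    nuclei = data.frame(x_um = gt$x_um, y_um = gt$y_um,
                        orientation_deg = gt$orientation_deg,
                        major_um = rep(2 * a, gt$n), minor_um = rep(2 * b, gt$n),
                        forced = gt$forced),
    preset = preset, seed = seed)
  field
}

#' Area of one field and of the full sampling scheme, in mm^2
#'
#' With the default 370 x 250 um field, the 5-areas-by-4-fields scheme totals
#' exactly 1.85 mm^2.
#'
#' @param preset a [histology_preset()].
#' @param n_areas,n_fields sampling scheme dimensions.
#' @return named vector with `field_mm2` and `total_mm2`.
#' @export
sampled_area <- function(preset = histology_preset(), n_areas = 5, n_fields = 4) {
  f <- prod(preset$field_size) / 1e6
  c(field_mm2 = f, total_mm2 = f * n_areas * n_fields)
}
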