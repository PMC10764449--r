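# Shared fixtures: all synthetic, built in code at test time.

# small, fast histology preset (120 x 90 um, ~12 nuclei)
small_preset <- function(nuclei_per_field_mean = 12, orientation_mean = 17.02,
                         orientation_sd = 8, min_center_distance = 21, ...) {
  histology_preset(nuclei_per_field_mean = nuclei_per_field_mean,
                   orientation_mean = orientation_mean,
                   orientation_sd = orientation_sd,
                   min_center_distance = min_center_distance,
                   field_size = c(120, 90), ...)
}

# separated-nuclei preset: spacing wide enough that nuclei can never touch
separated_preset <- function(mean_n = 10) {
  histology_preset(nuclei_per_field_mean = mean_n,
                   min_center_distance = 40,
                   field_size = c(250, 180))
}

# sinusoidal stripe pattern at a known orientation (degrees from +x,
# counterclockwise with y up), in the package's [x, y] matrix convention
make_stripes <- function(theta_deg, w = 300, h = 220, freq = 0.08) {
  th <- theta_deg * pi / 180
  x <- matrix(seq_len(w) - 0.5, w, h)
  yup <- matrix(rep(h - (seq_len(h) - 0.5), each = w), w, h)
  phase <- -x * sin(th) + yup * cos(th)
  0.5 + 0.4 * sin(2 * pi * freq * phase)
}

as_field <- function(pixels, pixel_size = 0.5, area = 1L, fieldn = 1L,
                     tendon_id = "fixture") {
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 area_index = area, field_index = fieldn,
                 tendon_id = tendon_id),
            class = "field_image")
}

# draw a filled ellipse into an [x, y] matrix (independent of the package
# renderer; used as a constructed fixture for detection tests)
draw_ellipse <- function(img, cx, cy, a, b, theta_deg = 0, value = 0.7) {
  th <- theta_deg * pi / 180
  w <- nrow(img); h <- ncol(img)
  x <- matrix(seq_len(w) - 0.5, w, h)
  yup <- matrix(rep(h - (seq_len(h) - 0.5), each = w), w, h)
  dx <- x - cx; dy <- yup - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img[inside] <- value
  img
}

# independent oracle: kappa statistics by direct summation of the defining
# formulas over the 4x4 category grid
oracle_kappas <- function(a, b, scheme = "linear") {
  n <- length(a)
  obs <- table(factor(a, levels = 0:3), factor(b, levels = 0:3)) / n
  pe_mat <- outer(rowSums(obs), colSums(obs))
  d <- abs(outer(0:3, 0:3, "-")) / 3
  w <- if (scheme == "linear") d else d^2
  po <- sum(diag(obs)); pe <- sum(diag(pe_mat))
  list(kappa = if (pe == 1) 1 else (po - pe) / (1 - pe),
       wk = if (sum(w * pe_mat) == 0) 1 else 1 - sum(w * obs) / sum(w * pe_mat))
}
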