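#' Activity-trace generator preset
#'
#' Bundles the parameters of the locomotion-index generator: a circadian
#' template of eight 3-hour levels (bin 0 starts at lights-on, bins 4-7 are
#' the dark period), a multiplicative suppression on the surgery day, and an
#' exponential post-surgery recovery.
#'
#' The expected locomotion index at minute \eqn{t} of day \eqn{d} is
#' \eqn{template[bin(t)] \times f(d)} with the injury factor
#' \deqn{f(d) = g - (g - (1 - dip)) e^{-d/\tau}, \quad d \ge 0}
#' and \eqn{f(d) = 1} before surgery, where \eqn{g} is `recovery_gain`
#' (the asymptotic activity relative to baseline) and `dip` = `dip_depth`.
#'
#' @param circadian_template eight nonnegative levels, one per 3-h bin.
#' @param dip_depth fraction in \[0, 1\]: relative activity loss on day 0.
#' @param recovery_tau recovery time constant, days (> 0).
#' @param recovery_gain asymptotic night activity relative to baseline (> 0).
#' @param noise_sd additive Gaussian noise SD, index units.
#' @param n_days_pre,n_days_post whole days simulated before / after day 0.
#' @return an object of class `activity_preset`.
#' @seealso [simulate_activity()], [injury_factor()], [study_activity_presets()]
#' @export
activity_preset <- function(circadian_template,
                            dip_depth = 0,
                            recovery_tau = 3,
                            recovery_gain = 1,
                            noise_sd = 0.05,
                            n_days_pre = 7,
                            n_days_post = 27) {
  stop_if_not_finite(circadian_template, "circadian_template")
  if (length(circadian_template) != 8L || any(circadian_template < 0)) {
    stop("circadian_template must be 8 nonnegative levels", call. = FALSE)
  }
  stop_if_not_finite(dip_depth, "dip_depth")
  if (dip_depth < 0 || dip_depth > 1) stop("dip_depth must be in [0, 1]", call. = FALSE)
  stop_if_not_finite(recovery_tau, "recovery_tau")
  if (recovery_tau <= 0) stop("recovery_tau must be > 0", call. = FALSE)
  stop_if_not_finite(recovery_gain, "recovery_gain")
  if (recovery_gain <= 0) stop("recovery_gain must be > 0", call. = FALSE)
  stop_if_not_finite(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_days_pre < 0 || n_days_post < 0 ||
      n_days_pre != round(n_days_pre) || n_days_post != round(n_days_post)) {
    stop("n_days_pre and n_days_post must be nonnegative integers", call. = FALSE)
  }
  structure(
    list(circadian_template = as.numeric(circadian_template),
         dip_depth = dip_depth, recovery_tau = recovery_tau,
         recovery_gain = recovery_gain, noise_sd = noise_sd,
         n_days_pre = as.integer(n_days_pre),
         n_days_post = as.integer(n_days_post)),
    class = "activity_preset")
}

#' Packaged activity presets for the study groups
#'
#' One preset per lesion-by-wheel group. The shared circadian template peaks
#' in the 12-15 h bin just after lights-off and has every dark-bin level above
#' every light-bin level. Group differences are carried by the surgery-day dip
#' and the recovery kinetics: bilateral-free animals recover past baseline
#' (gain > 1), blocked-wheel animals plateau below it; controls receive only a
#' mild rehousing dip. These group-level kinetics are qualitative orderings,
#' not fitted values.
#'
#' @return named list of [activity_preset()] objects with names
#'   `ctr_free`, `ctr_blocked`, `unilateral_free`, `unilateral_blocked`,
#'   `bilateral_free`, `bilateral_blocked`.
#' @export
study_activity_presets <- function() {
  template <- c(0.10, 0.07, 0.06, 0.09, 0.52, 0.42, 0.30, 0.20)
  list(
    ctr_free           = activity_preset(template, dip_depth = 0.15,
                                         recovery_tau = 2.0, recovery_gain = 1.00),
    ctr_blocked        = activity_preset(template, dip_depth = 0.15,
                                         recovery_tau = 2.0, recovery_gain = 1.00),
    unilateral_free    = activity_preset(template, dip_depth = 0.55,
                                         recovery_tau = 2.5, recovery_gain = 1.02),
    unilateral_blocked = activity_preset(template, dip_depth = 0.55,
                                         recovery_tau = 4.0, recovery_gain = 0.97),
    bilateral_free     = activity_preset(template, dip_depth = 0.65,
                                         recovery_tau = 3.0, recovery_gain = 1.12),
    bilateral_blocked  = activity_preset(template, dip_depth = 0.65,
                                         recovery_tau = 5.0, recovery_gain = 0.92))
}

#' Histology field generator preset
#'
#' Parameters of the synthetic single-channel (nuclei) fluorescence field:
#' oriented elliptical nuclei with Poisson count, folded-normal orientations,
#' and additive Gaussian camera noise. The default field is 370 x 250 um so
#' that the 5-areas-by-4-fields sampling scheme covers exactly 1.85 mm^2.
#'
#' @param nuclei_per_field_mean expected nucleus count per field.
#' @param orientation_mean mean nucleus orientation, degrees in (-90, 90].
#' @param orientation_sd orientation SD, degrees (> 0 unless exactly 0 for the
#'   degenerate no-dispersion case).
#' @param nucleus_axes full (major, minor) axis lengths, um.
#' @param min_center_distance minimum nucleus center spacing, um; placement
#'   falls back to unconstrained after `placement_cap` rejected draws (the
#'   fallback is recorded in the ground truth).
#' @param background_level,nucleus_intensity image intensities in \[0, 1\].
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param pixel_size um per pixel.
#' @param field_size (width, height) of the field, um.
#' @param placement_cap rejection-sampling cap per nucleus.
#' @return an object of class `histology_preset`.
#' @seealso [simulate_histology_field()], [study_histology_presets()]
#' @export
histology_preset <- function(nuclei_per_field_mean = 70,
                             orientation_mean = 17.02,
                             orientation_sd = 8,
                             nucleus_axes = c(20, 4),
                             min_center_distance = 21,
                             background_level = 0.08,
                             nucleus_intensity = 0.63,
                             noise_sd = 0.03,
                             pixel_size = 0.5,
                             field_size = c(370, 250),
                             placement_cap = 200L) {
  stop_if_not_finite(c(nuclei_per_field_mean, orientation_mean, orientation_sd,
                       nucleus_axes, min_center_distance, background_level,
                       nucleus_intensity, noise_sd, pixel_size, field_size),
                     "histology preset fields")
  if (nuclei_per_field_mean < 0) stop("nuclei_per_field_mean must be >= 0", call. = FALSE)
  if (orientation_sd < 0) stop("orientation_sd must be >= 0", call. = FALSE)
  if (length(nucleus_axes) != 2L || any(nucleus_axes <= 0) ||
      nucleus_axes[1] < nucleus_axes[2]) {
    stop("nucleus_axes must be positive (major, minor) lengths", call. = FALSE)
  }
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (length(field_size) != 2L || any(field_size <= 0)) {
    stop("field_size must be positive (width, height) in um", call. = FALSE)
  }
  if (any(nucleus_axes[1] >= field_size)) {
    stop("nucleus major axis must fit inside the field", call. = FALSE)
  }
  if (background_level < 0 || nucleus_intensity > 1 ||
      nucleus_intensity <= background_level) {
    stop("need 0 <= background_level < nucleus_intensity <= 1", call. = FALSE)
  }
  structure(
    list(nuclei_per_field_mean = nuclei_per_field_mean,
         orientation_mean = fold_angle(orientation_mean),
         orientation_sd = orientation_sd,
         nucleus_axes = as.numeric(nucleus_axes),
         min_center_distance = min_center_distance,
         background_level = background_level,
         nucleus_intensity = nucleus_intensity,
         noise_sd = noise_sd, pixel_size = pixel_size,
         field_size = as.numeric(field_size),
         placement_cap = as.integer(placement_cap)),
    class = "histology_preset")
}

#' Packaged histology presets for the study groups
#'
#' The CTR (healthy) preset carries the reference-study anchors: about 70 nuclei per
#' field and a 17.02 degree mean orientation with 8 degree dispersion. Injured
#' groups are ordered qualitatively (bilateral-free closest to healthy,
#' unilateral-blocked farthest): denser fields, larger mean departure from the
#' longitudinal axis, and wider orientation dispersion, with a relaxed
#' center-spacing constraint so nuclei may clump.
#'
#' @return named list of [histology_preset()] objects.
#' @export
study_histology_presets <- function() {
  list(
    ctr                = histology_preset(),
    bilateral_free     = histology_preset(nuclei_per_field_mean = 100,
                                          orientation_mean = 24,
                                          orientation_sd = 12,
                                          min_center_distance = 10),
    bilateral_blocked  = histology_preset(nuclei_per_field_mean = 120,
                                          orientation_mean = 32,
                                          orientation_sd = 16,
                                          min_center_distance = 10),
    unilateral_free    = histology_preset(nuclei_per_field_mean = 135,
                                          orientation_mean = 38,
                                          orientation_sd = 18,
                                          min_center_distance = 10),
    unilateral_blocked = histology_preset(nuclei_per_field_mean = 150,
                                          orientation_mean = 45,
                                          orientation_sd = 22,
                                          min_center_distance = 10))
}

#' Cohort design (groups, animals, tendons)
#'
#' @param groups data.frame with columns `lesion` (none / unilateral /
#'   bilateral), `wheel` (free / blocked), `n_animals`, `n_tendons`.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("lesion", "wheel", "n_animals", "n_tendons") %in% names(groups)))
  if (!all(groups$lesion %in% c("none", "unilateral", "bilateral"))) {
    stop("lesion must be none, unilateral or bilateral", call. = FALSE)
  }
  if (!all(groups$wheel %in% c("free", "blocked"))) {
    stop("wheel must be free or blocked", call. = FALSE)
  }
  if (any(groups$n_animals <= 0) || any(groups$n_tendons <= 0)) {
    stop("n_animals and n_tendons must be positive", call. = FALSE)
  }
  groups$group <- paste(ifelse(groups$lesion == "none", "ctr", groups$lesion),
                        groups$wheel, sep = "_")
  structure(list(groups = groups), class = "cohort_design")
}

#' Packaged cohort design of the reference study
#'
#' 8 control, 12 unilateral and 12 bilateral mice per wheel condition (64
#' mice), with 8 / 6 / 12 tendons per condition entering histology (52
#' tendons).
#'
#' @return a [cohort_design()].
#' @export
study_cohort_design <- function() {
  cohort_design(data.frame(
    lesion    = rep(c("none", "unilateral", "bilateral"), each = 2),
    wheel     = rep(c("free", "blocked"), 3),
    n_animals = c(8, 8, 12, 12, 12, 12),
    n_tendons = c(8, 8, 6, 6, 12, 12)))
}

#' Correlation specification for the tendon-level metric cohort
#'
#' Defines the joint (multivariate normal) distribution of the tendon-level
#' metrics used for the correlation analysis: variable names, marginal means
#' and SDs, and a correlation matrix.
#'
#' @param variables character vector of variable names.
#' @param means,sds numeric vectors, one value per variable.
#' @param rho correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite).
#' @param repair if `TRUE`, a non-PSD `rho` is repaired by clipping negative
#'   eigenvalues at zero and rescaling to unit diagonal; if `FALSE` (default)
#'   a non-PSD `rho` is an error reporting the smallest eigenvalue.
#' @return object of class `metric_correlation_spec`.
#' @export
metric_correlation_spec <- function(variables, means, sds, rho, repair = FALSE) {
  p <- length(variables)
  stopifnot(length(means) == p, length(sds) == p,
            is.matrix(rho), all(dim(rho) == p))
  stop_if_not_finite(c(means, sds, rho), "correlation spec values")
  if (any(sds <= 0)) stop("sds must be positive", call. = FALSE)
  if (max(abs(rho - t(rho))) > 1e-8) stop("rho must be symmetric", call. = FALSE)
  if (max(abs(diag(rho) - 1)) > 1e-8) stop("rho must have unit diagonal", call. = FALSE)
  ev <- eigen((rho + t(rho)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    if (!repair) {
      stop(sprintf("rho is not positive semi-definite (smallest eigenvalue %.6g)",
                   min(ev$values)), call. = FALSE)
    }
    lam <- pmax(ev$values, 0)
    rho <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- sqrt(diag(rho))
    rho <- rho / outer(d, d)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
  }
  dimnames(rho) <- list(variables, variables)
  structure(list(variables = variables,
                 means = setNames(as.numeric(means), variables),
                 sds = setNames(as.numeric(sds), variables),
                 rho = rho),
            class = "metric_correlation_spec")
}

#' Packaged correlation spec of the reference study
#'
#' Sets the activity-alignment (0.41), activity-dispersion (-0.76) and
#' cellularity-alignment (0.54) correlations; all other off-diagonals are 0.
#' Marginal means and SDs are plausible tendon-level values (normalized night
#' activity around 1, direction ratio around 1.6, dispersion around 20
#' degrees, cellularity fold change around 1.8).
#'
#' @return a [metric_correlation_spec()].
#' @export
study_correlation_spec <- function() {
  v <- c("normalized_night_activity", "cell_alignment",
         "angle_dispersion", "cellularity")
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.41
  rho[1, 3] <- rho[3, 1] <- -0.76
  rho[4, 2] <- rho[2, 4] <- 0.54
  metric_correlation_spec(v,
                          means = c(1.0, 1.6, 20, 1.8),
                          sds   = c(0.20, 0.45, 5, 0.35),
                          rho   = rho)
}

#' Write or read a preset as YAML
#'
#' Round-trip serialization for [activity_preset()], [histology_preset()] and
#' [metric_correlation_spec()] objects.
#'
#' @param preset a preset object.
#' @param path file path.
#' @return `read_preset()` returns the reconstructed preset;
#'   `write_preset()` returns `path` invisibly.
#' @export
write_preset <- function(preset, path) {
  cls <- class(preset)[1]
  x <- unclass(preset)
  if (cls == "metric_correlation_spec") x$rho <- as.data.frame(x$rho)
  yaml::write_yaml(c(list(.class = cls), x), path)
  invisible(path)
}

#' @rdname write_preset
#' @export
read_preset <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  switch(cls,
    activity_preset = do.call(activity_preset, x),
    histology_preset = do.call(histology_preset, x),
    metric_correlation_spec = {
      rho <- as.matrix(as.data.frame(x$rho))
      dimnames(rho) <- list(unlist(x$variables), unlist(x$variables))
      metric_correlation_spec(unlist(x$variables), unlist(x$means),
                              unlist(x$sds), rho)
    },
    stop("unknown preset class: ", cls, call. = FALSE))
}
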