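#' Direction ratio versus the healthy reference
#'
#' Ratio of the sample's departure from the tendon longitudinal axis to the
#' healthy reference's, after folding both directions to \[0, 90\] degrees.
#' A ratio of 1 means the same departure as healthy tissue. An alternative
#' absolute-difference mode returns `|sample - reference|` in degrees on the
#' folded scale.
#'
#' @param sample,healthy_reference `directionality_result` objects or plain
#'   direction angles in degrees.
#' @param mode `"ratio"` (default) or `"deviation"`.
#' @return the ratio (dimensionless) or absolute deviation (degrees).
#' @export
direction_ratio <- function(sample, healthy_reference, mode = c("ratio", "deviation")) {
  mode <- match.arg(mode)
  s <- if (inherits(sample, "directionality_result")) sample$direction else sample
  r <- if (inherits(healthy_reference, "directionality_result")) {
    healthy_reference$direction
  } else {
    healthy_reference
  }
  stop_if_not_finite(c(s, r), "directions")
  s <- fold_axis(s); r <- fold_axis(r)
  if (mode == "deviation") return(abs(s - r))
  if (r == 0) {
    stop("healthy reference direction is 0: ratio undefined, use mode = \"deviation\"",
         call. = FALSE)
  }
  s / r
}

#' Assemble per-tendon histomorphometric metrics from field images
#'
#' Runs nuclei detection and directionality on every field of one tendon and
#' aggregates: per-area mean counts, overall cellularity fold change versus a
#' healthy reference, and tendon-level direction/dispersion as
#' histogram-mass-weighted (goodness-weighted) means over fields. Areas with
#' no fields are flagged missing and skipped.
#'
#' @param fields list of `field_image` objects covering areas 1-5.
#' @param healthy a healthy reference: list with `mean_count` (per-field
#'   nucleus count) and `direction` (degrees), e.g. from
#'   [healthy_reference()]; or `NULL` to skip the normalized metrics.
#' @param direction_mode passed to [direction_ratio()].
#' @param ... passed to [detect_nuclei()] and [directionality()] (matched by
#'   name).
#' @return a `tendon_metrics` object: list with `tendon_id`, `per_area`
#'   (data.frame `area_index`, `n_fields`, `mean_count`), `missing_areas`,
#'   `mean_count`, `fold_change`, `direction`, `dispersion`,
#'   `direction_ratio`, `total_area_mm2`, and `fields` (per-field table).
#' @export
assemble_tendon_metrics <- function(fields, healthy = NULL,
                                    direction_mode = c("ratio", "deviation"),
                                    ...) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(length(fields) > 0,
            all(vapply(fields, inherits, logical(1), "field_image")))
  dots <- list(...)
  det_args <- dots[names(dots) %in% names(formals(detect_nuclei))]
  dir_args <- dots[names(dots) %in% names(formals(directionality))]

  per_field <- do.call(rbind, lapply(fields, function(f) {
    nuc <- do.call(detect_nuclei, c(list(image = f), det_args))
    dir <- do.call(directionality, c(list(image = f), dir_args))
    data.frame(tendon_id = f$tendon_id, area_index = f$area_index,
               field_index = f$field_index, count = nrow(nuc),
               direction = dir$direction, dispersion = dir$dispersion,
               goodness = dir$goodness, low_goodness = dir$low_goodness,
               field_mm2 = prod(dim(f$pixels)) * f$pixel_size^2 / 1e6)
  }))
  per_area <- data.frame(area_index = 1:5)
  per_area$n_fields <- vapply(1:5, function(a) sum(per_field$area_index == a),
                              numeric(1))
  per_area$mean_count <- vapply(1:5, function(a) {
    x <- per_field$count[per_field$area_index == a]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  missing_areas <- per_area$area_index[per_area$n_fields == 0]
  if (length(missing_areas)) {
    warning("areas with no fields: ", paste(missing_areas, collapse = ", "))
  }
  w <- per_field$goodness
  if (all(!is.finite(w)) || sum(w, na.rm = TRUE) <= 0) w <- rep(1, nrow(per_field))
  w[!is.finite(w)] <- 0
  direction <- circ_mean_axial(per_field$direction, w)
  dispersion <- sum(w * per_field$dispersion) / sum(w)

  out <- structure(
    list(tendon_id = per_field$tendon_id[1], per_area = per_area,
         missing_areas = missing_areas,
         mean_count = mean(per_field$count),
         direction = direction, dispersion = dispersion,
         fold_change = NA_real_, direction_ratio = NA_real_,
         direction_mode = direction_mode,
         total_area_mm2 = sum(per_field$field_mm2),
         fields = per_field),
    class = "tendon_metrics")
  if (!is.null(healthy)) {
    out$fold_change <- cellularity_fold_change(per_field$count,
                                               healthy$mean_count)
    out$direction_ratio <- direction_ratio(direction, healthy$direction,
                                           mode = direction_mode)
  }
  out
}

#' Healthy (control) reference for normalized tendon metrics
#'
#' @param mean_count mean nucleus count per field in healthy tendons.
#' @param direction healthy tissue direction, degrees.
#' @param dispersion healthy angle dispersion, degrees.
#' @return list used as the `healthy` argument of
#'   [assemble_tendon_metrics()].
#' @export
healthy_reference <- function(mean_count = 70, direction = 17.02,
                              dispersion = 8) {
  list(mean_count = mean_count, direction = direction, dispersion = dispersion)
}
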