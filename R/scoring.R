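#' Scoring rules for the six histomorphometric parameters
#'
#' Executable encoding of the ordinal 0-3 rubric. Boundary inclusivity, which
#' the source rubric wording leaves partly ambiguous, is fixed and auditable here:
#'
#' * cellularity: fold change > 3 scores 0; (2, 3\] scores 1; \[1.3, 2\]
#'   scores 2; < 1.3 scores 3 (exactly 3 scores 1; exactly 1.3 scores 2).
#' * alignment: ratio > 3 scores 0; (2.1, 3\] scores 1; ratio < 1 with
#'   dispersion < 25 percent scores 3; everything else scores 2.
#' * COL1: no expression or 0 aligned areas scores 0; 1-2 areas score 1;
#'   3-4 score 2; all 5 score 3.
#' * vascularity: plexus 0; scattered or aligned over at most one area 1;
#'   aligned over one to four areas 2; few aligned vessels as in healthy
#'   tendon 3.
#' * metaplasia (chondro and osteo share the rule): foci in all 5 areas 0;
#'   2-4 areas 1; 1 area 2; none 3.
#'
#' @return a `scoring_rules` list (versioned threshold table).
#' @seealso [write_scoring_rules()], [score_cellularity()]
#' @export
scoring_rules <- function() {
  structure(list(
    version = "1.0",
    cellularity = list(high = 3, mid = 2, low = 1.3,
                       inclusivity = "score1=(mid,high]; score2=[low,mid]"),
    alignment = list(high = 3, mid = 2.1, unity = 1, dispersion_percent = 25,
                     inclusivity = "score1=(mid,high]; score2 absorbs <=mid unless score3"),
    col1 = list(score1_areas = c(1, 2), score2_areas = c(3, 4), all_areas = 5),
    vascularity = list(levels = c("plexus", "scattered_or_aligned_le1_area",
                                  "aligned_1_to_4_areas", "few_aligned_as_healthy")),
    metaplasia = list(all_areas = 5, band1 = c(2, 4), band2 = 1)),
    class = "scoring_rules")
}

#' Serialize scoring rules to and from YAML
#'
#' @param rules a `scoring_rules` object.
#' @param path file path.
#' @return `read_scoring_rules()` returns the reconstructed rules; the
#'   round-trip is the identity.
#' @export
write_scoring_rules <- function(rules, path) {
  stopifnot(inherits(rules, "scoring_rules"))
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' @rdname write_scoring_rules
#' @export
read_scoring_rules <- function(path) {
  x <- yaml::read_yaml(path)
  x$col1$score1_areas <- as.numeric(unlist(x$col1$score1_areas))
  x$col1$score2_areas <- as.numeric(unlist(x$col1$score2_areas))
  x$metaplasia$band1 <- as.numeric(unlist(x$metaplasia$band1))
  x$vascularity$levels <- as.character(unlist(x$vascularity$levels))
  structure(x, class = "scoring_rules")
}

#' Score cellularity from the fold change
#'
#' @param fold_change cellularity fold change versus healthy (> 0).
#' @param rules a `scoring_rules` object.
#' @return integer score in 0-3 (vectorized).
#' @export
score_cellularity <- function(fold_change, rules = scoring_rules()) {
  stop_if_not_finite(fold_change, "fold_change")
  if (any(fold_change <= 0)) stop("fold_change must be positive", call. = FALSE)
  r <- rules$cellularity
  ifelse(fold_change > r$high, 0L,
    ifelse(fold_change > r$mid, 1L,
      ifelse(fold_change >= r$low, 2L, 3L)))
}

#' Score cell alignment from direction ratio and dispersion
#'
#' @param ratio direction ratio versus healthy (> 0).
#' @param dispersion_percent angle dispersion as a percentage (>= 0); the
#'   pipeline converts the fitted Gaussian SD via
#'   [dispersion_to_percent()].
#' @param rules a `scoring_rules` object.
#' @return integer score in 0-3 (vectorized).
#' @export
score_alignment <- function(ratio, dispersion_percent, rules = scoring_rules()) {
  stop_if_not_finite(ratio, "ratio")
  stop_if_not_finite(dispersion_percent, "dispersion_percent")
  if (any(ratio <= 0)) stop("ratio must be positive", call. = FALSE)
  if (any(dispersion_percent < 0)) {
    stop("dispersion_percent must be >= 0", call. = FALSE)
  }
  r <- rules$alignment
  ifelse(ratio > r$high, 0L,
    ifelse(ratio > r$mid, 1L,
      ifelse(ratio < r$unity & dispersion_percent < r$dispersion_percent,
             3L, 2L)))
}

#' Convert an angle dispersion in degrees to the rubric's percent scale
#'
#' The rubric's "dispersion < 25 percent" boundary is read as a percentage of
#' the 90-degree orientation half-range.
#'
#' @param dispersion_deg Gaussian SD in degrees.
#' @return dispersion as a percentage.
#' @export
dispersion_to_percent <- function(dispersion_deg) 100 * dispersion_deg / 90

#' Score COL1 fiber organization
#'
#' @param col1_aligned_areas number of areas (0-5) with aligned COL1 fibers;
#'   -1 encodes no COL1 expression.
#' @param rules a `scoring_rules` object.
#' @return integer score in 0-3 (vectorized).
#' @export
score_col1 <- function(col1_aligned_areas, rules = scoring_rules()) {
  a <- col1_aligned_areas
  if (any(!a %in% c(-1, 0:5))) {
    stop("col1_aligned_areas must be -1 (no expression) or 0-5", call. = FALSE)
  }
  r <- rules$col1
  ifelse(a <= 0, 0L,
    ifelse(a <= max(r$score1_areas), 1L,
      ifelse(a <= max(r$score2_areas), 2L, 3L)))
}

#' Score vascularity from its observation category
#'
#' @param category one of `"plexus"`, `"scattered_or_aligned_le1_area"`,
#'   `"aligned_1_to_4_areas"`, `"few_aligned_as_healthy"`.
#' @param rules a `scoring_rules` object.
#' @return integer score in 0-3 (vectorized).
#' @export
score_vascularity <- function(category, rules = scoring_rules()) {
  lv <- rules$vascularity$levels
  if (any(!category %in% lv)) {
    stop("unknown vascularity category: ",
         paste(setdiff(category, lv), collapse = ", "), call. = FALSE)
  }
  match(category, lv) - 1L
}

#' Score metaplasia (chondro or osteo) from the number of affected areas
#'
#' @param foci_areas number of areas (0-5) containing foci.
#' @param rules a `scoring_rules` object.
#' @return integer score in 0-3 (vectorized).
#' @export
score_metaplasia <- function(foci_areas, rules = scoring_rules()) {
  a <- foci_areas
  if (any(!a %in% 0:5)) stop("foci_areas must be in 0-5", call. = FALSE)
  r <- rules$metaplasia
  ifelse(a >= r$all_areas, 0L,
    ifelse(a >= r$band1[1], 1L,
      ifelse(a == r$band2, 2L, 3L)))
}

#' Total Histological Score card
#'
#' Sums the six ordinal sub-scores into the THS (0-18).
#'
#' @param cellularity,alignment,col1,vascularity,chondro,osteo sub-scores in
#'   0-3.
#' @return a `score_card`: list of the six sub-scores and `ths`.
#' @export
total_histological_score <- function(cellularity, alignment, col1,
                                     vascularity, chondro, osteo) {
  scores <- list(cellularity = cellularity, alignment = alignment,
                 col1 = col1, vascularity = vascularity,
                 chondro = chondro, osteo = osteo)
  missing <- names(scores)[vapply(scores, function(s) {
    length(s) != 1 || is.na(s) || !is.finite(s)
  }, logical(1))]
  if (length(missing)) {
    stop("missing sub-scores: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- names(scores)[!vapply(scores, function(s) s %in% 0:3, logical(1))]
  if (length(bad)) {
    stop("sub-scores outside 0-3: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  scores <- lapply(scores, as.integer)
  structure(c(scores, list(ths = sum(unlist(scores)))), class = "score_card")
}

#' Group THS summary
#'
#' @param cards list of `score_card` objects.
#' @param group optional group labels (one per card).
#' @return data.frame with per-group mean, SD and n of the THS.
#' @export
ths_summary <- function(cards, group = NULL) {
  ths <- vapply(cards, function(c) c$ths, numeric(1))
  if (is.null(group)) group <- rep("all", length(ths))
  out <- do.call(rbind, lapply(split(ths, group), function(x) {
    data.frame(mean_ths = mean(x), sd_ths = if (length(x) > 1) sd(x) else NA_real_,
               n = length(x))
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "mean_ths", "sd_ths", "n")]
}
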