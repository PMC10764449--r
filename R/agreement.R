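#' Two-assessor ordinal rating table
#'
#' @param assessor_a,assessor_b integer scores in 0-3, same length.
#' @param item_id optional item identifiers.
#' @param parameter parameter name (e.g. `"col1"`).
#' @return a `rating_table` data.frame with columns `item_id`, `assessor_a`,
#'   `assessor_b` and attribute `parameter`.
#' @export
rating_table <- function(assessor_a, assessor_b,
                         item_id = seq_along(assessor_a),
                         parameter = "parameter") {
  if (length(assessor_a) != length(assessor_b)) {
    stop("assessor score vectors must have equal length", call. = FALSE)
  }
  if (!length(assessor_a)) stop("empty rating table", call. = FALSE)
  if (any(!assessor_a %in% 0:3) || any(!assessor_b %in% 0:3)) {
    stop("scores must be integers in 0-3", call. = FALSE)
  }
  out <- data.frame(item_id = item_id,
                    assessor_a = as.integer(assessor_a),
                    assessor_b = as.integer(assessor_b))
  class(out) <- c("rating_table", "data.frame")
  attr(out, "parameter") <- parameter
  out
}

#' Confusion matrix of a rating table
#'
#' Counts over the fixed category set \{0, 1, 2, 3\} (unused categories keep
#' zero rows/columns).
#'
#' @param table a [rating_table()].
#' @return 4 x 4 integer matrix (rows assessor A, columns assessor B).
#' @export
confusion_matrix <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  table(factor(table$assessor_a, levels = 0:3),
        factor(table$assessor_b, levels = 0:3))
}

#' Percent agreement between two assessors
#'
#' @param table a [rating_table()].
#' @return percentage in \[0, 100\].
#' @export
percent_agreement <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  100 * mean(table$assessor_a == table$assessor_b)
}

#' Cohen's kappa for two assessors
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products over the fixed category set 0-3. The
#' degenerate single-category case (`p_e = 1`, necessarily `p_o = 1`) returns
#' exactly 1.
#'
#' @param table a [rating_table()].
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  n <- nrow(table)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  cm <- confusion_matrix(table) / n
  po <- sum(diag(cm))
  pe <- sum(rowSums(cm) * colSums(cm))
  if (abs(1 - pe) < 1e-12) {
    return(if (abs(1 - po) < 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Weighted kappa for two assessors
#'
#' Disagreement-weighted kappa `1 - sum(w * observed) / sum(w * expected)`
#' with linear weights `|i - j| / 3` (default) or quadratic
#' `((i - j) / 3)^2` on the fixed category set 0-3.
#'
#' @param table a [rating_table()].
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @return weighted kappa in \[-1, 1\].
#' @export
weighted_kappa <- function(table, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  stopifnot(inherits(table, "rating_table"))
  n <- nrow(table)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  d <- abs(outer(0:3, 0:3, "-")) / 3
  w <- if (weights == "linear") d else d^2
  cm <- confusion_matrix(table) / n
  expd <- outer(rowSums(cm), colSums(cm))
  num <- sum(w * cm)
  den <- sum(w * expd)
  if (den == 0) {
    if (num > 0) {
      stop("expected weighted disagreement is 0 but disagreement observed",
           call. = FALSE)
    }
    return(1)
  }
  1 - num / den
}

#' Full inter-assessor agreement summary
#'
#' @param table a [rating_table()].
#' @param weights weighting scheme for the weighted kappa.
#' @return an `agreement_result`: list with `parameter`,
#'   `percent_agreement`, `kappa`, `weighted_kappa`, `weights`, `n`,
#'   `confusion`.
#' @export
agreement_summary <- function(table, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  structure(
    list(parameter = attr(table, "parameter"),
         percent_agreement = percent_agreement(table),
         kappa = cohens_kappa(table),
         weighted_kappa = weighted_kappa(table, weights),
         weights = weights, n = nrow(table),
         confusion = confusion_matrix(table)),
    class = "agreement_result")
}
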