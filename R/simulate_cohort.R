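#' Simulate a tendon-level metric cohort with known correlations
#'
#' Draws `n` tendons jointly from the multivariate normal defined by a
#' [metric_correlation_spec()]. The covariance is factorized by
#' eigendecomposition (via [MASS::mvrnorm()]), which also handles singular
#' correlation matrices such as an exact rho = 1 pair.
#'
#' @param spec a [metric_correlation_spec()].
#' @param n number of tendons.
#' @param seed integer seed.
#' @return data.frame with one column per spec variable and attribute
#'   `ground_truth` (the spec, `n` and the seed).
#' @export
simulate_metric_cohort <- function(spec, n, seed) {
  stopifnot(inherits(spec, "metric_correlation_spec"), n >= 1)
  if (missing(seed)) stop("seed must be given", call. = FALSE)
  sigma <- spec$rho * outer(spec$sds, spec$sds)
  x <- with_seed(seed,
    MASS::mvrnorm(n, mu = spec$means, Sigma = sigma, tol = 1e-8))
  if (n == 1L) x <- matrix(x, nrow = 1, dimnames = list(NULL, spec$variables))
  out <- as.data.frame(x)
  names(out) <- spec$variables
  attr(out, "ground_truth") <- list(spec = spec, n = n, seed = seed)
  out
}

#' Simulate two blinded assessors rating ordinal scores
#'
#' Each assessor independently reports the true ordinal score (0-3) perturbed
#' by one step up or down with probability `confusion` (direction symmetric),
#' clipped to \[0, 3\].
#'
#' @param true_scores integer vector of true scores in 0-3.
#' @param confusion per-assessor probability of a one-step error, in
#'   \[0, 0.5\].
#' @param seed integer seed.
#' @param parameter parameter name stored on the table.
#' @return a [rating_table()] with attribute `ground_truth` (true scores,
#'   confusion, seed).
#' @export
simulate_assessors <- function(true_scores, confusion, seed,
                               parameter = "parameter") {
  if (length(true_scores) == 0) stop("empty score list", call. = FALSE)
  stopifnot(all(true_scores %in% 0:3))
  if (!is.finite(confusion) || confusion < 0 || confusion > 0.5) {
    stop("confusion must be in [0, 0.5]", call. = FALSE)
  }
  if (missing(seed)) stop("seed must be given", call. = FALSE)
  n <- length(true_scores)
  perturb <- function(x) {
    step <- sample(c(-1L, 1L), n, replace = TRUE)
    hit <- runif(n) < confusion
    pmin(pmax(x + ifelse(hit, step, 0L), 0L), 3L)
  }
  scores <- with_seed(seed, {
    a <- perturb(true_scores)
    b <- perturb(true_scores)
    list(a = a, b = b)
  })
  tab <- rating_table(scores$a, scores$b, parameter = parameter)
  attr(tab, "ground_truth") <- list(true_scores = as.integer(true_scores),
                                    confusion = confusion, seed = seed)
  tab
}
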