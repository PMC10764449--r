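#' Fold an angle into the (-90, 90] orientation range
#'
#' Orientations of undirected structures (nuclei, fibres) are defined modulo
#' 180 degrees. All orientation outputs in the package use the half-open
#' interval (-90, 90], measured in degrees from the +x axis (the tendon
#' longitudinal axis), counterclockwise when the image y axis points up.
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector folded into (-90, 90].
#' @export
#' @examples
#' fold_angle(c(90, 91, -90, 180, 197))
fold_angle <- function(theta) {
  stopifnot(is.numeric(theta))
  r <- ((theta + 90) %% 180) - 90
  # exact -90 (theta = 90 mod 180) belongs at +90 in the half-open range
  r[which(abs(r + 90) < 1e-9)] <- 90
  r
}

#' Fold an orientation to its absolute departure from the x axis, in [0, 90]
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector in [0, 90].
#' @export
fold_axis <- function(theta) abs(fold_angle(theta))

# Deterministic per-stage seed from a master seed. Stage k of a run uses
# derive_seed(master, k); the scheme is a plain affine counter kept inside
# 32-bit integer range.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  as.integer((abs(master) %% 20000000) * 100 + (stage %% 100))
}

# internal: run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  }
  invisible(x)
}

# internal: weighted circular mean of orientations (period 180 deg)
circ_mean_axial <- function(theta, w = rep(1, length(theta))) {
  stopifnot(length(theta) == length(w))
  t2 <- theta * pi / 90  # double the angle: 180-periodic -> 360-periodic
  fold_angle(atan2(sum(w * sin(t2)), sum(w * cos(t2))) * 90 / pi)
}
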