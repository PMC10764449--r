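#' Pearson correlation matrix with Fisher Z' confidence intervals
#'
#' Product-moment correlations for every variable pair, with 95 percent
#' confidence intervals from the Fisher Z' transformation,
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`, and two-tailed p values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Rows
#' are pairwise complete; `n` is reported per pair. A perfect correlation is
#' flagged degenerate and its CI collapsed to the point rather than reported
#' as infinite.
#'
#' @param data data.frame of numeric metric columns (one row per tendon).
#' @param conf_level confidence level (default 0.95).
#' @param holm if `TRUE`, append a Holm-adjusted p column (off by default:
#'   the raw matrix applies no multiplicity correction).
#' @return data.frame with columns `var1`, `var2`, `r`, `n`, `ci_low`,
#'   `ci_high`, `p_value`, `degenerate` (and `p_holm` if requested).
#' @export
pearson_matrix <- function(data, conf_level = 0.95, holm = FALSE) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  vars <- names(data)
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- do.call(rbind, lapply(pairs, function(p) {
    x <- data[[p[1]]]; y <- data[[p[2]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 4) stop(sprintf("pair %s-%s: need >= 4 complete rows", p[1], p[2]),
                    call. = FALSE)
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) {
      stop(sprintf("pair %s-%s: zero variance", p[1], p[2]), call. = FALSE)
    }
    r <- cor(x, y)
    degen <- abs(r) >= 1 - 1e-12
    if (degen) {
      ci <- c(r, r); pv <- 0
    } else {
      ci <- tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      pv <- 2 * pt(-abs(tstat), df = n - 2)
    }
    data.frame(var1 = p[1], var2 = p[2], r = r, n = n,
               ci_low = ci[1], ci_high = ci[2], p_value = pv,
               degenerate = degen)
  }))
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Fisher Z' confidence interval for a single correlation
#'
#' @param r Pearson correlation.
#' @param n sample size (> 3).
#' @param conf_level confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
fisher_ci <- function(r, n, conf_level = 0.95) {
  stopifnot(n > 3, abs(r) < 1)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Standard between/within decomposition (via [aov()]) followed by Tukey
#' honestly-significant-difference adjusted pairwise comparisons, plus a
#' D'Agostino-Pearson normality check per group (reported as `NA` for groups
#' below the omnibus validity floor of n = 8). With exactly two groups, the
#' pooled two-tailed t statistic is reported as well (`F = t^2`).
#'
#' @param values numeric response vector.
#' @param group group labels (coerced to factor).
#' @return a `group_comparison` list: `F`, `df`, `p`, `tukey` (data.frame
#'   `contrast`, `diff`, `ci_low`, `ci_high`, `p_adj`), `normality`
#'   (per-group `K2`, `p`), and `t`, `t_p` in two-group mode.
#' @export
one_way_anova_tukey <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(group) < 2)) stop("each group needs n >= 2", call. = FALSE)
  fit <- aov(values ~ group)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  normality <- do.call(rbind, lapply(levels(group), function(g) {
    x <- values[group == g]
    if (length(x) >= 8 && sd(x) > 0) {
      dp <- dagostino_pearson(x)
      data.frame(group = g, n = length(x), K2 = dp$K2, p = dp$p)
    } else {
      data.frame(group = g, n = length(x), K2 = NA_real_, p = NA_real_)
    }
  }))
  out <- list(F = s[1, "F value"], df = c(s[1, "Df"], s[2, "Df"]),
              p = s[1, "Pr(>F)"], tukey = tukey, normality = normality)
  if (nlevels(group) == 2) {
    lv <- levels(group)
    tt <- independent_t_test(values[group == lv[1]], values[group == lv[2]])
    out$t <- tt$t
    out$t_p <- tt$p
  }
  structure(out, class = "group_comparison")
}

#' Two-tailed independent t-test
#'
#' Pooled-variance Student's t by default; Welch's unequal-variance form by
#' flag. The degenerate zero-variance case returns `t = 0, p = 1` when the
#' means are equal and errors when they differ.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param welch if `TRUE`, Welch's t-test.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `welch`.
#' @export
independent_t_test <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  stop_if_not_finite(a, "a"); stop_if_not_finite(b, "b")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b), welch = welch))
    }
    stop("zero variance in both samples with unequal means", call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b), welch = welch)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' `K^2 = Z(skewness)^2 + Z(kurtosis)^2` using the standard transformed-moment
#' approximations (D'Agostino's skewness transform; Anscombe-Glynn kurtosis
#' transform), referred to a chi-square with 2 degrees of freedom.
#'
#' @param x numeric sample, n >= 8.
#' @return list with `K2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  stop_if_not_finite(x, "sample")
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson requires n >= 8", call. = FALSE)
  if (sd(x) == 0) stop("zero-variance sample", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eg2) / sqrt(vg2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  base <- (1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4)))
  crt <- sign(base) * abs(base)^(1 / 3)  # signed cube root
  z2 <- ((1 - 2 / (9 * a)) - crt) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(K2 = k2, p = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}
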