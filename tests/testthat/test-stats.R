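test_that("Fisher CI matches its step-by-step formula and classic example", {
  ci <- fisher_ci(0.5, 30)
  z <- atanh(0.5)
  expect_equal(ci, tanh(z + c(-1, 1) * 1.96 / sqrt(27)), tolerance = 2e-4)
  expect_equal(ci, c(0.1704314, 0.7289586), tolerance = 1e-6)
})

test_that("pearson_matrix handles exact linear dependence with a degenerate flag", {
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = rnorm(10))
  out <- pearson_matrix(d)
  row <- out[out$var1 == "x" & out$var2 == "y", ]
  expect_equal(row$r, 1)
  expect_true(row$degenerate)
  expect_equal(c(row$ci_low, row$ci_high), c(1, 1))
})

test_that("pearson_matrix is invariant to affine rescaling (sign flips with scale)", {
  set.seed(2)
  d <- data.frame(a = rnorm(30), b = rnorm(30))
  d$b <- d$b + 0.5 * d$a
  r0 <- pearson_matrix(d)$r
  d2 <- data.frame(a = 3 * d$a + 7, b = d$b)
  expect_equal(pearson_matrix(d2)$r, r0, tolerance = 1e-12)
  d3 <- data.frame(a = -2 * d$a, b = d$b)
  expect_equal(pearson_matrix(d3)$r, -r0, tolerance = 1e-12)
  expect_error(pearson_matrix(data.frame(a = rep(1, 10), b = rnorm(10))),
               "zero variance")
  expect_error(pearson_matrix(data.frame(a = 1:3, b = 3:1)), "4 complete")
})

test_that("pearson p-values come from the t distribution on n-2 df", {
  set.seed(4)
  d <- data.frame(x = rnorm(25), y = rnorm(25))
  out <- pearson_matrix(d)
  tstat <- out$r * sqrt((out$n - 2) / (1 - out$r^2))
  expect_equal(out$p_value, 2 * pt(-abs(tstat), out$n - 2), tolerance = 1e-12)
  withholm <- pearson_matrix(cbind(d, z = rnorm(25)), holm = TRUE)
  expect_true("p_holm" %in% names(withholm))
  expect_true(all(withholm$p_holm >= withholm$p_value))
})

test_that("identical groups give F = 0 and Tukey p of 1", {
  g <- rep(c("a", "b", "c"), each = 5)
  v <- rep(c(1, 2, 3, 4, 5), 3)
  res <- one_way_anova_tukey(v, g)
  expect_equal(res$F, 0)
  expect_equal(res$tukey$p_adj, rep(1, 3), tolerance = 1e-12)
})

test_that("two-group ANOVA is the squared pooled t-test", {
  set.seed(6)
  a <- rnorm(8, 1); b <- rnorm(10, 2)
  res <- one_way_anova_tukey(c(a, b), rep(c("a", "b"), c(8, 10)))
  tt <- independent_t_test(a, b)
  expect_equal(res$F, tt$t^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p, tolerance = 1e-10)
})

test_that("ANOVA and Tukey match a manual decomposition oracle", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(3:4, 1)
    ns <- sample(4:8, k, replace = TRUE)
    v <- unlist(lapply(seq_len(k), function(i) rnorm(ns[i], mean = i)))
    g <- factor(rep(seq_len(k), ns))
    res <- one_way_anova_tukey(v, g)
    # manual sums of squares
    gm <- mean(v)
    means <- tapply(v, g, mean)
    ssb <- sum(ns * (means - gm)^2)
    ssw <- sum((v - means[g])^2)
    dfb <- k - 1; dfw <- length(v) - k
    f_manual <- (ssb / dfb) / (ssw / dfw)
    expect_equal(res$F, f_manual, tolerance = 1e-8)
    # manual Tukey adjusted p via the studentized range distribution
    mse <- ssw / dfw
    pair <- utils::combn(seq_len(k), 2)
    p_manual <- apply(pair, 2, function(ij) {
      se <- sqrt(mse / 2 * (1 / ns[ij[1]] + 1 / ns[ij[2]]))
      q <- abs(means[ij[2]] - means[ij[1]]) / se
      stats::ptukey(q, k, dfw, lower.tail = FALSE)
    })
    got <- res$tukey$p_adj[order(res$tukey$contrast)]
    lab <- apply(pair, 2, function(ij) paste0(ij[2], "-", ij[1]))
    expect_equal(got, p_manual[order(lab)], tolerance = 1e-6)
  }
})

test_that("independent t-test matches a textbook pooled computation", {
  a <- c(14.1, 15.2, 13.8, 16.0, 14.9)
  b <- c(12.9, 13.1, 12.2, 13.8)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p_manual <- 2 * pt(-abs(t_manual), na + nb - 2)
  res <- independent_t_test(a, b)
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$p, p_manual, tolerance = 1e-10)
  expect_equal(res$df, na + nb - 2)
  welch <- independent_t_test(a, b, welch = TRUE)
  expect_false(isTRUE(all.equal(welch$df, res$df)))
})

test_that("t-test degenerate cases behave as specified", {
  x <- c(1, 2, 3)
  same <- independent_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- independent_t_test(x, x + 10)
  expect_lt(shifted$p, 0.01)
  flat_eq <- independent_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(flat_eq$t, 0)
  expect_equal(flat_eq$p, 1)
  expect_error(independent_t_test(c(2, 2, 2), c(3, 3)), "zero variance")
})

test_that("D'Agostino-Pearson reproduces frozen reference values", {
  # expected values computed independently with scipy.stats.normaltest
  set.seed(42); x <- round(rnorm(50), 6)
  set.seed(7); y <- round(rexp(60), 6)
  dx <- dagostino_pearson(x)
  dy <- dagostino_pearson(y)
  expect_equal(dx$K2, 0.6863999832, tolerance = 1e-9)
  expect_equal(dx$p, 0.7094963041, tolerance = 1e-9)
  expect_equal(dy$K2, 31.3885797861, tolerance = 1e-9)
  expect_equal(dy$p, 1.527764809e-07, tolerance = 1e-6)
})

test_that("D'Agostino-Pearson calibrates on normal data and flags skewed data", {
  set.seed(11)
  expect_gt(dagostino_pearson(rnorm(5000))$p, 0.001)
  set.seed(12)
  expect_lt(dagostino_pearson(rexp(500))$p, 0.01)
  expect_error(dagostino_pearson(rep(1, 20)), "zero-variance")
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})
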