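test_that("percent agreement counts identical pairs", {
  expect_equal(percent_agreement(rating_table(c(0, 1, 2, 3), c(0, 1, 2, 3))), 100)
  expect_equal(percent_agreement(rating_table(c(0, 0, 1, 1), c(0, 1, 1, 1))), 75)
  expect_equal(percent_agreement(rating_table(c(0, 1), c(1, 0))), 0)
  expect_error(rating_table(integer(0), integer(0)), "empty")
  expect_error(rating_table(c(0, 1), c(0, 4)), "0-3")
})

test_that("Cohen's kappa matches hand-computed marginals", {
  t1 <- rating_table(c(0, 0, 1, 1), c(0, 1, 1, 1))
  # p_o = 0.75; p_e = 0.5*0.25 + 0.5*0.75 = 0.5; kappa = 0.5
  expect_equal(cohens_kappa(t1), 0.5)
  expect_equal(cohens_kappa(rating_table(c(0, 1, 2, 3), c(0, 1, 2, 3))), 1)
  # degenerate single-category table
  expect_equal(cohens_kappa(rating_table(rep(2, 5), rep(2, 5))), 1)
})

test_that("independent assessors score chance-level kappa", {
  set.seed(99)
  a <- sample(0:3, 1e4, TRUE)
  b <- sample(0:3, 1e4, TRUE)
  expect_lt(abs(cohens_kappa(rating_table(a, b))), 0.05)
})

test_that("kappa and weighted kappa match exhaustive enumeration on 3-item tables", {
  grid <- as.matrix(expand.grid(a1 = 0:3, a2 = 0:3, a3 = 0:3,
                                b1 = 0:3, b2 = 0:3, b3 = 0:3))
  got <- matrix(NA_real_, nrow(grid), 3)
  want <- matrix(NA_real_, nrow(grid), 3)
  for (i in seq_len(nrow(grid))) {
    a <- grid[i, 1:3]; b <- grid[i, 4:6]
    tab <- rating_table(a, b)
    orl <- oracle_kappas(a, b, "linear")
    orq <- oracle_kappas(a, b, "quadratic")
    got[i, ] <- c(cohens_kappa(tab), weighted_kappa(tab, "linear"),
                  weighted_kappa(tab, "quadratic"))
    want[i, ] <- c(orl$kappa, orl$wk, orq$wk)
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("quadratic weighting is no harsher than linear for one-step disagreements", {
  set.seed(5)
  for (i in 1:50) {
    a <- sample(0:3, 8, TRUE)
    shift <- sample(c(-1L, 0L, 1L), 8, TRUE)
    b <- pmin(pmax(a + shift, 0L), 3L)
    tab <- rating_table(a, b)
    expect_gte(weighted_kappa(tab, "quadratic") + 1e-12,
               weighted_kappa(tab, "linear"))
  }
})

test_that("results are invariant to item order", {
  set.seed(8)
  a <- sample(0:3, 40, TRUE)
  b <- pmin(pmax(a + sample(c(-1L, 0L, 1L), 40, TRUE), 0L), 3L)
  perm <- sample(40)
  t1 <- rating_table(a, b); t2 <- rating_table(a[perm], b[perm])
  expect_equal(percent_agreement(t1), percent_agreement(t2))
  expect_equal(cohens_kappa(t1), cohens_kappa(t2))
  expect_equal(weighted_kappa(t1), weighted_kappa(t2))
})

test_that("kappa decreases strictly with assessor confusion", {
  truth <- rep(0:3, length.out = 500)
  kappas <- vapply(c(0, 0.1, 0.3), function(cf) {
    cohens_kappa(simulate_assessors(truth, cf, seed = 42))
  }, numeric(1))
  expect_equal(kappas[1], 1)
  expect_true(all(diff(kappas) < 0))
})

test_that("assessor simulation honors its degenerate limits", {
  truth <- rep(0:3, 10)
  clean <- simulate_assessors(truth, 0, seed = 3)
  expect_equal(clean$assessor_a, truth)
  expect_equal(clean$assessor_b, truth)
  noisy <- simulate_assessors(rep(1:2, 500), 0.5, seed = 3)
  expect_lt(percent_agreement(noisy), 100)
  expect_error(simulate_assessors(integer(0), 0.1, seed = 1), "empty")
  expect_error(simulate_assessors(0:3, 0.7, seed = 1), "confusion")
})

test_that("kappa agrees with e1071's independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (i in 1:20) {
    a <- sample(0:3, 30, TRUE)
    b <- pmin(pmax(a + sample(c(-1L, 0L, 1L), 30, TRUE), 0L), 3L)
    ours <- cohens_kappa(rating_table(a, b))
    ref <- e1071::classAgreement(table(factor(a, levels = 0:3),
                                       factor(b, levels = 0:3)))$kappa
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})
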