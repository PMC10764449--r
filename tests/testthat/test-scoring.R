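test_that("every rubric cell maps to its score", {
  # cellularity
  expect_identical(score_cellularity(1.2), 3L)
  expect_identical(score_cellularity(3.5), 0L)
  expect_identical(score_cellularity(2.5), 1L)
  expect_identical(score_cellularity(1.3), 2L)  # strict '<1.3' reading
  expect_identical(score_cellularity(3), 1L)    # score 1 band is (2, 3]
  # alignment
  expect_identical(score_alignment(4, 10), 0L)
  expect_identical(score_alignment(0.9, 20), 3L)
  expect_identical(score_alignment(0.9, 30), 2L)
  expect_identical(score_alignment(2.5, 10), 1L)
  expect_identical(score_alignment(2.05, 10), 2L)  # (2, 2.1] absorbed by score 2
  # COL1
  expect_identical(score_col1(5), 3L)
  expect_identical(score_col1(2), 1L)
  expect_identical(score_col1(3), 2L)
  expect_identical(score_col1(c(-1, 0)), c(0L, 0L))
  # vascularity
  expect_identical(score_vascularity("plexus"), 0L)
  expect_identical(score_vascularity("few_aligned_as_healthy"), 3L)
  expect_identical(score_vascularity("aligned_1_to_4_areas"), 2L)
  # metaplasia
  expect_identical(score_metaplasia(0), 3L)
  expect_identical(score_metaplasia(5), 0L)
  expect_identical(score_metaplasia(1), 2L)
  expect_identical(score_metaplasia(3), 1L)
})

test_that("scoring is total over a randomized sweep of admissible inputs", {
  set.seed(1)
  n <- 1e5
  fc <- exp(runif(n, log(0.05), log(20)))
  sc <- score_cellularity(fc)
  expect_true(all(sc %in% 0:3))
  ratio <- exp(runif(n, log(0.05), log(20)))
  disp <- runif(n, 0, 100)
  sa <- score_alignment(ratio, disp)
  expect_true(all(sa %in% 0:3))
  expect_true(all(score_col1(sample(c(-1, 0:5), n, TRUE)) %in% 0:3))
  expect_true(all(score_metaplasia(sample(0:5, n, TRUE)) %in% 0:3))
  lv <- scoring_rules()$vascularity$levels
  expect_true(all(score_vascularity(sample(lv, n, TRUE)) %in% 0:3))
})

test_that("scores are monotone in their driving quantity", {
  fc <- seq(1, 6, by = 0.01)
  expect_true(all(diff(score_cellularity(fc)) <= 0))
  expect_true(all(diff(score_metaplasia(0:5)) <= 0))
  for (disp in c(10, 40)) {
    ratio <- seq(0.2, 5, by = 0.01)
    expect_true(all(diff(score_alignment(ratio, disp)) <= 0))
  }
})

test_that("bisection over the rule table recovers every stated threshold", {
  find_boundary <- function(f, lo, hi, tol = 1e-9) {
    # f must change value between lo and hi; bisect to the jump point
    flo <- f(lo)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) == flo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(find_boundary(score_cellularity, 0.5, 1.8), 1.3, tolerance = 1e-6)
  expect_equal(find_boundary(score_cellularity, 1.8, 2.8), 2.0, tolerance = 1e-6)
  expect_equal(find_boundary(score_cellularity, 2.5, 3.8), 3.0, tolerance = 1e-6)
  al <- function(r) score_alignment(r, 10)
  expect_equal(find_boundary(al, 2.5, 3.9), 3.0, tolerance = 1e-6)
  expect_equal(find_boundary(al, 1.5, 2.9), 2.1, tolerance = 1e-6)
  expect_equal(find_boundary(al, 0.5, 1.5), 1.0, tolerance = 1e-6)
  dd <- function(d) score_alignment(0.8, d)
  expect_equal(find_boundary(dd, 10, 40), 25, tolerance = 1e-6)
})

test_that("scoring rules round-trip through YAML identically", {
  rules <- scoring_rules()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scoring_rules(rules, path)
  back <- read_scoring_rules(path)
  expect_equal(back, rules)
  # the packaged rule file matches the in-code rules
  pkg_file <- system.file("extdata", "scoring_rules.yaml",
                          package = "tendonwatch")
  expect_true(nzchar(pkg_file))
  expect_equal(read_scoring_rules(pkg_file), rules)
})

test_that("THS is the exact sum of the six sub-scores with strict guards", {
  expect_equal(total_histological_score(3, 3, 3, 3, 3, 3)$ths, 18)
  expect_equal(total_histological_score(0, 0, 0, 0, 0, 0)$ths, 0)
  expect_equal(total_histological_score(3, 2, 1, 2, 3, 3)$ths, 14)
  expect_error(total_histological_score(3, NA, 1, 2, 3, 3), "alignment")
  expect_error(total_histological_score(3, 2, 1, 2, 3, 5), "osteo")
  cards <- list(total_histological_score(3, 3, 3, 3, 3, 3),
                total_histological_score(2, 2, 2, 2, 1, 3))
  s <- ths_summary(cards, c("ctr", "bilateral_free"))
  expect_equal(s$mean_ths[s$group == "ctr"], 18)
  expect_equal(s$mean_ths[s$group == "bilateral_free"], 12)
})
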