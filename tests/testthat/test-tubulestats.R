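test_that("oblique sections convert to tubule equivalents by the floor rule", {
  expect_equal(oblique_equivalents(50, 50), 1L)
  expect_equal(oblique_equivalents(50, 175), 3L)
  expect_equal(oblique_equivalents(50, 10), 1L)   # observed => at least one
  expect_equal(oblique_equivalents(50, c(50, 175, 10)), c(1L, 3L, 1L))
  expect_error(oblique_equivalents(0, 10), "> 0")
  expect_error(oblique_equivalents(50, -1), "> 0")
})

test_that("per-tubule means average circular sections, optionally weighted", {
  tab <- function(pos, shape = "circular", len = NA_real_) {
    data.frame(tubule_id = seq_along(pos), shape = shape,
               positives = pos, oblique_length = len)
  }
  expect_warning(expect_equal(mean_positive_per_tubule(tab(c(2, 2, 2))), 2),
                 ">= 40")
  expect_warning(expect_equal(mean_positive_per_tubule(tab(c(0, 1, 2, 3))), 1.5),
                 ">= 40")
  # oblique contribution weighted by diameter equivalents:
  # circular {1, 1} plus an oblique of length 2 diameters carrying 4 cells
  mixed <- rbind(tab(c(1, 1)),
                 tab(4, shape = "oblique", len = 2))
  expect_warning(expect_equal(
    mean_positive_per_tubule(mixed, include_oblique = TRUE), 1.5), ">= 40")
  expect_warning(expect_equal(mean_positive_per_tubule(mixed), 1), ">= 40")

  big <- generate_tubule_table(10000, 0, positive_rate = 1.5, seed = 9)
  expect_lte(abs(mean_positive_per_tubule(big) - 1.5), 3 * sqrt(1.5 / 10000))
  empty <- data.frame(tubule_id = integer(0), shape = character(0),
                      positives = integer(0), oblique_length = numeric(0))
  expect_error(mean_positive_per_tubule(empty), "empty")
  expect_error(mean_positive_per_tubule(tab(3, shape = "oblique", len = 1)),
               "no circular")
})

test_that("the unpaired t-test matches the pooled-variance closed form", {
  res <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0213, tolerance = 1e-2)
  # symmetry: swapping groups flips the sign, p unchanged
  swapped <- unpaired_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p, res$p)
  # degenerate cases
  same <- unpaired_t_test(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
  expect_error(unpaired_t_test(c(2, 2), c(3, 3)), "zero pooled variance")
})

test_that("frequency pooling sums counts and reproduces reference percentages", {
  wt5 <- data.frame(positives = c(11, 0, 1), total = c(121, 93, 104))
  p5 <- pool_frequencies(wt5)
  expect_equal(p5$positives, 12)
  expect_equal(p5$total, 318)
  expect_equal(p5$display, 3.77)

  ko7 <- data.frame(positives = c(25, 14, 37, 12, 35),
                    total = c(99, 137, 110, 97, 232))
  expect_equal(pool_frequencies(ko7)$display, 18.22)

  one <- pool_frequencies(data.frame(positives = 3, total = 50))
  expect_equal(one$percentage, 6)

  freqs <- caspase3_frequencies()
  expect_error(pool_frequencies(freqs), "mix")
  expect_equal(pool_frequencies(freqs, allow_mixed = TRUE)$total,
               sum(freqs$total))
  expect_error(pool_frequencies(data.frame(positives = 5, total = 4)),
               "positives <= total")
})

test_that("2x2 chi-square matches the direct formula and its symmetries", {
  eq <- chi_square_2x2(20, 80, 10, 40)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)

  set.seed(13)
  for (i in 1:10) {
    cnt <- sample(1:200, 4)
    res <- chi_square_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    O <- matrix(cnt, 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(res$statistic, sum((O - E)^2 / E))
    expect_equal(res$df, 1)
    # invariant to swapping the groups, and to swapping both columns
    expect_equal(chi_square_2x2(cnt[3], cnt[4], cnt[1], cnt[2])$statistic,
                 res$statistic)
    expect_equal(chi_square_2x2(cnt[2], cnt[1], cnt[4], cnt[3])$statistic,
                 res$statistic)
  }
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
  expect_error(chi_square_2x2(-1, 2, 3, 4), ">= 0")
})

test_that("chi-square calibration: type-I error near nominal under the null", {
  set.seed(14)
  n_sim <- 2000; n <- 500; p0 <- 0.3
  pos1 <- rbinom(n_sim, n, p0)
  pos2 <- rbinom(n_sim, n, p0)
  pvals <- vapply(seq_len(n_sim), function(i)
    chi_square_2x2(pos1[i], n - pos1[i], pos2[i], n - pos2[i])$p, 1.0)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("goodness of fit uses the expected counts as given", {
  same <- chi_square_gof(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  cross <- mendelian_cross_counts()
  res <- chi_square_gof(cross$observed, cross$expected)
  expect_equal(res$statistic, 1203 / 15.5)
  expect_equal(res$df, 3)
  expect_lt(res$p, 1e-15)

  # scaling all counts by k scales the statistic by k
  res2 <- chi_square_gof(2 * cross$observed, 2 * cross$expected)
  expect_equal(res2$statistic, 2 * res$statistic)

  expect_error(chi_square_gof(c(1, 2), c(1, 2, 3)), "same length")
  expect_error(chi_square_gof(c(1, 2), c(1, 0)), "> 0")
  expect_error(chi_square_gof(5, 5), "at least 2")
})

test_that("tubule and frequency tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  tt <- generate_tubule_table(25, 0.3, 1.2, seed = 15)
  p1 <- file.path(dir, "tubules.csv")
  write_tubule_table(tt, p1)
  back <- read_tubule_table(p1)
  expect_s3_class(back, "tubule_count_table")
  expect_equal(back$positives, tt$positives)
  p2 <- file.path(dir, "freqs.csv")
  utils::write.csv(caspase3_frequencies(), p2, row.names = FALSE)
  expect_equal(read_frequency_table(p2), caspase3_frequencies())
})
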