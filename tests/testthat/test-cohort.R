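test_that("odds ratios follow the cross-product formula", {
  expect_equal(round(odds_ratio(82, 1, 50, 16), 2), 26.24)
  expect_equal(odds_ratio(10, 10, 10, 10), 1.0)
  expect_equal(round(odds_ratio(57, 26, 63, 10), 3), 0.348)
  # inversion identity, exactly
  withr::with_seed(2, {
    for (i in 1:20) {
      t <- sample(1:50, 4, replace = TRUE)
      expect_equal(odds_ratio(t[1], t[2], t[3], t[4]),
                   1 / odds_ratio(t[3], t[4], t[1], t[2]),
                   tolerance = 1e-15)
    }
  })
  expect_warning(or <- odds_ratio(5, 0, 3, 2), class = "mtduplex_undefined_or")
  expect_true(is.na(or))
  expect_error(odds_ratio(-1, 1, 1, 1), class = "mtduplex_domain_error")
})

test_that("Fisher two-sided p equals full hypergeometric enumeration", {
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 1 / 126, tolerance = 1e-12)

  withr::with_seed(8, {
    for (i in 1:40) {
      t <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
      p <- fisher_exact_two_sided(t[1], t[2], t[3], t[4])
      expect_equal(p, fisher_oracle(t[1], t[2], t[3], t[4]),
                   tolerance = 1e-9)
      # and agrees with the reference implementation
      expect_equal(p, stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-9)
      # symmetric under swapping rows and swapping columns
      expect_equal(p, fisher_exact_two_sided(t[3], t[4], t[1], t[2]),
                   tolerance = 1e-12)
      expect_equal(p, fisher_exact_two_sided(t[2], t[1], t[4], t[3]),
                   tolerance = 1e-12)
    }
  })
  # degenerate margins
  expect_equal(fisher_exact_two_sided(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_two_sided(2, 3, 0, 0), 1)
})

test_that("compare_groups reproduces the printed cohort odds ratios", {
  cohort <- cohort_from_table8()
  pairs <- list(c("Young-NL", "Old-NL"), c("Young-NL", "Old-AMD"),
                c("Old-NL", "Old-AMD"))
  cmp <- compare_groups(cohort, pairs)
  or_of <- function(pos, g1, g2) {
    cmp$odds_ratio[cmp$position == pos & cmp$group1 == g1 & cmp$group2 == g2]
  }
  expect_equal(round(or_of(4104, "Young-NL", "Old-NL"), 2), 26.24)
  expect_equal(round(or_of(4104, "Young-NL", "Old-AMD"), 2), 26.84)
  expect_equal(round(or_of(5320, "Young-NL", "Old-NL"), 3), 4.588)
  expect_equal(round(or_of(13095, "Old-NL", "Old-AMD"), 3), 0.439)
  expect_equal(round(or_of(13105, "Young-NL", "Old-AMD"), 3), 0.348)
  expect_equal(round(or_of(13105, "Old-NL", "Old-AMD"), 3), 0.365)
  expect_true(all(cmp$p_two_sided > 0 & cmp$p_two_sided <= 1))

  # a SNP absent everywhere gives an undefined odds ratio, not an error
  absent <- compare_groups(cohort, pairs,
                           snps = tibble::tibble(position = 4556L, ref = "C",
                                                 alt = "T"))
  expect_true(all(is.na(absent$odds_ratio)))
  expect_error(compare_groups(cohort, list(c("Young-NL", "Middle"))),
               class = "mtduplex_lookup_error")
  # optional BH adjustment adds a column without changing raw p-values
  adj <- compare_groups(cohort, pairs, adjust = "BH")
  expect_true(all(adj$p_adjusted >= adj$p_two_sided - 1e-12))
})

test_that("the paired tissue t-test matches the closed-form t distribution", {
  got <- tissue_count_ttest(c(35, 135, 165), c(9, 8, 3))
  d <- c(35, 135, 165) - c(9, 8, 3)
  tstat <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(got$statistic, tstat, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(tstat), df = 2), tolerance = 1e-12)
  # blood exceeds retina in the study's direction
  expect_gt(got$estimate, 0)

  expect_error(tissue_count_ttest(c(1, 2, 3), c(1, 2, 3)),
               class = "mtduplex_undefined_test")
  expect_error(tissue_count_ttest(1, 2), class = "mtduplex_undefined_test")
})
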