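het_fixture <- as_heteroplasmy_table()

test_that("tissue counts conserve rows and compute shares", {
  per_sample <- tissue_counts(het_fixture, by = "sample")
  expect_equal(sum(per_sample$n), nrow(het_fixture))
  per_tissue <- tissue_counts(het_fixture, by = "tissue")
  expect_equal(sum(per_tissue$share_pct), 100, tolerance = 0.1)
  # verbatim fixture totals (the printed row list; see fixture README)
  expect_equal(per_tissue$n[per_tissue$tissue == "blood"], 337L)
  expect_equal(per_tissue$n[per_tissue$tissue == "rpe_choroid"], 45L)
  expect_equal(per_tissue$n[per_tissue$tissue == "retina"], 20L)

  empty <- het_fixture[0, ]
  expect_equal(nrow(tissue_counts(empty)), 0L)
})

test_that("planted 10:2:1 tissue imbalance yields a 10/13 blood share", {
  tab <- tibble::tibble(
    position = rep(1:13, 3), ref = "C", alt = "T",
    subject = rep(c("S1", "S2", "S3"), each = 13),
    tissue = rep(c(rep("blood", 10), rep("rpe_choroid", 2), "retina"), 3),
    freq = 0.05
  )
  counts <- tissue_counts(tab, by = "sample")
  blood <- counts[counts$tissue == "blood", ]
  expect_equal(blood$share_pct, rep(100 * 10 / 13, 3))
})

test_that("hot-spots require recurrence across subjects", {
  hs <- detect_hotspots(het_fixture, min_subjects = 2)
  r2523 <- hs[hs$position == 2523, ]
  expect_equal(r2523$n_subjects, 3L)
  expect_false(813 %in% hs$position)     # single-subject SNP
  expect_false(any(duplicated(hs[, c("position", "alt")])))
  expect_equal(hs$position, sort(hs$position))
  # monotone in min_subjects
  hs3 <- detect_hotspots(het_fixture, min_subjects = 3)
  expect_true(all(paste(hs3$position, hs3$alt) %in% paste(hs$position, hs$alt)))
  expect_true(all(hs3$n_subjects == 3L))
  # empty input
  expect_equal(nrow(detect_hotspots(het_fixture[0, ])), 0L)
})

test_that("the poly-C preset drops the 302-316 tract from hot-spots", {
  hs <- detect_hotspots(het_fixture, excluded_regions = polyc_region())
  expect_false(any(hs$position %in% 302:316))
  # 309C>T and 310T>C recur across subjects, so they appear without the preset
  hs_all <- detect_hotspots(het_fixture)
  expect_true(all(c(309, 310) %in% hs_all$position))
})

test_that("blood-only filtering reproduces the printed 10-SNP list", {
  bo <- blood_only_snps(het_fixture)
  expect_equal(bo$position,
               c(1292L, 1619L, 2143L, 2162L, 6366L, 8021L, 8065L, 8701L,
                 8718L, 13386L))
  # none of them is ever seen outside blood
  nonblood <- het_fixture[het_fixture$tissue != "blood", ]
  expect_length(intersect(paste(bo$position, bo$alt),
                          paste(nonblood$position, nonblood$alt)), 0L)
  # no blood rows at all -> empty result
  expect_equal(nrow(blood_only_snps(nonblood)), 0L)
})

test_that("blood-only filter distinguishes all-blood from blood-plus-retina SNPs", {
  tab <- tibble::tibble(
    position = c(rep(100L, 3), rep(200L, 4)),
    ref = "C", alt = "T",
    subject = c("S1", "S2", "S3", "S1", "S2", "S3", "S1"),
    tissue = c(rep("blood", 6), "retina"),
    freq = 0.05
  )
  expect_equal(blood_only_snps(tab)$position, 100L)
  # without the all-subjects rule a subject-private blood SNP also qualifies
  tab2 <- dplyr::bind_rows(tab, tibble::tibble(
    position = 300L, ref = "G", alt = "A", subject = "S1",
    tissue = "blood", freq = 0.02))
  expect_equal(blood_only_snps(tab2, require_all_subjects = FALSE)$position,
               c(100L, 300L))
})

test_that("frequency bands are half-open and conserve the row count", {
  bands <- maf_band_histogram(het_fixture, c(0.30, 0.50))
  expect_equal(sum(bands$n), nrow(het_fixture))
  expect_equal(bands$n[bands$band_lo == 0.30], 0L)

  # boundary convention: a value at the lower edge belongs to the band
  one <- tibble::tibble(position = 1L, ref = "C", alt = "T", subject = "S1",
                        tissue = "blood", freq = 0.30)
  b1 <- maf_band_histogram(one, c(0.30, 0.50))
  expect_equal(b1$n[b1$band_lo == 0.30], 1L)

  # brute-force binning oracle on uniform synthetic frequencies
  withr::with_seed(5, {
    tab <- tibble::tibble(position = 1:500, ref = "C", alt = "T",
                          subject = "S1", tissue = "blood",
                          freq = runif(500, 0.001, 1))
    edges <- c(0.1, 0.25, 0.5, 0.9)
    got <- maf_band_histogram(tab, edges)
    full <- c(0, edges, 1.01)
    want <- sapply(seq_len(length(full) - 1), function(i) {
      sum(tab$freq >= full[i] & tab$freq < full[i + 1])
    })
    expect_equal(got$n, want)
  })
  expect_error(maf_band_histogram(het_fixture, c(0.5, 0.3)),
               class = "mtduplex_domain_error")
})

test_that("spectrum and burden plots build", {
  expect_s3_class(plot_maf_spectrum(het_fixture), "ggplot")
  expect_s3_class(plot_tissue_counts(het_fixture), "ggplot")
})
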