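test_that("binomial_tail matches direct pmf summation", {
  expect_equal(binomial_tail(0, 1000, 0.001), 1.0)
  expect_equal(binomial_tail(5, 100, 0.003),
               binom_tail_oracle(5, 100, 0.001), tolerance = 1e-12)
  # randomised oracle equivalence for depths up to 10,000
  withr::with_seed(31, {
    for (i in 1:50) {
      depth <- sample(10:10000, 1)
      err <- runif(1, 1e-4, 0.01)
      alt <- rbinom(1, depth, min(0.05, 10 * err))
      got_log <- binomial_tail(alt, depth, err, log_p = TRUE)
      want_log <- binom_tail_oracle(alt, depth, err / 3, log = TRUE)
      expect_equal(exp(got_log - want_log), 1, tolerance = 1e-9)
    }
  })
  expect_error(binomial_tail(11, 10, 0.001), class = "mtduplex_domain_error")
})

test_that("extreme counts saturate the Phred scale", {
  # 300 alt at 30,000x under a 0.1% error model: normal bound puts the
  # tail far below 1e-100, so the Phred-scaled quality caps at 100
  log_tail <- binomial_tail(300, 30000, 0.001, log_p = TRUE)
  expect_lt(log_tail / log(10), -100)
  z <- (300 - 30000 * 0.001 / 3) / sqrt(30000 * (0.001 / 3))
  expect_gt(z, 20)  # the normal approximation agrees this is absurdly extreme
})

test_that("qual is non-decreasing in alt_count at fixed depth", {
  quals <- -10 * binomial_tail(0:50, 5000, 0.001, log_p = TRUE) / log(10)
  expect_true(all(diff(quals) >= 0))
})

test_that("call_pool_variants finds a PASS variant at 1% and flags 0.01%", {
  ref <- toy_reference(50)
  base <- ref_base(ref, 25)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  mk_pileup <- function(alt_count, depth = 30000L) {
    counts <- matrix(0L, 50, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    refs <- ref_base(ref, 1:50)
    counts[cbind(1:50, match(refs, colnames(counts)))] <- depth
    counts[25, match(base, colnames(counts))] <- depth - alt_count
    counts[25, match(alt, colnames(counts))] <- alt_count
    tibble::tibble(pool = "A", position = 1:50, ref = refs,
                   n_a = counts[, "A"], n_c = counts[, "C"],
                   n_g = counts[, "G"], n_t = counts[, "T"])
  }

  calls <- call_pool_variants(mk_pileup(300L), ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$filter, "PASS")
  expect_equal(calls$frequency, 0.01)
  expect_equal(calls$qual, 100)

  # 3 of 30,000 (0.01%) is far below the floor: no PASS call anywhere
  low <- call_pool_variants(mk_pileup(3L), ref)
  expect_false(any(low$filter == "PASS"))

  # between min_maf/2 and min_maf: emitted but flagged low_maf
  sub <- call_pool_variants(mk_pileup(200L), ref)
  expect_equal(sub$filter, "low_maf")

  # pure reference pileup yields no calls
  none <- call_pool_variants(mk_pileup(0L), ref)
  expect_equal(nrow(none), 0L)

  # shallow depth trips the depth filter even at high frequency
  shallow <- call_pool_variants(mk_pileup(50L, depth = 500L), ref)
  expect_equal(shallow$filter, "low_depth")

  outside <- dplyr::mutate(mk_pileup(300L), position = position + 100L)
  expect_error(call_pool_variants(outside, ref),
               class = "mtduplex_domain_error")
})

test_that("every PASS call satisfies all thresholds on simulated pileups", {
  ref <- toy_reference(400)
  panel <- design_panel(ref, 2, 5)
  tree <- load_haplotree()
  prof <- simulate_subject(tree, "H2a2a1")
  events <- heteroplasmy_events(c(40, 90, 140, 190), c(0.006, 0.011, 0.03, 0.3),
                                ref)
  tt <- plant_events(prof, "blood", events)
  cfg <- caller_config()
  for (seed in 1:5) {
    pu <- simulate_strand_pileups(
      tt, panel, sim_config(depth_mean = 5000, depth_min = 800,
                            depth_max = 20000), seed = seed)
    calls <- call_pool_variants(pu, ref, cfg)
    pass <- calls[calls$filter == "PASS", ]
    expect_true(all(pass$frequency >= cfg$min_maf))
    expect_true(all(pass$depth >= cfg$min_depth))
    expect_true(all(pass$qual >= cfg$min_qual))
    # emitted records never fall below the half-floor reporting threshold
    expect_true(all(calls$frequency >= cfg$min_maf / 2))
    expect_equal(calls$frequency, calls$alt_count / calls$depth)
  }
})

test_that("multi-allelic sites yield one record per alternate base", {
  ref <- mt_reference("AAAA")
  pu <- tibble::tibble(pool = "B", position = 1:4, ref = "A",
                       n_a = c(9000L, 10000L, 10000L, 10000L),
                       n_c = c(500L, 0L, 0L, 0L),
                       n_g = c(500L, 0L, 0L, 0L),
                       n_t = 0L)
  calls <- call_pool_variants(pu, ref)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$alt, c("C", "G"))
  expect_true(all(calls$filter == "PASS"))
})
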