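test_that("simulate_subject carries the root-to-haplogroup germline union", {
  tree <- load_haplotree()
  expect_equal(nrow(simulate_subject(tree, "I1a1b")$germline), 30L)
  expect_equal(nrow(simulate_subject(tree, "U2e2a1")$germline), 32L)
  expect_equal(nrow(simulate_subject(tree, "H2a2a1")$germline), 0L)
  expect_error(simulate_subject(tree, "nope"), class = "mtduplex_lookup_error")
})

test_that("plant_events validates event lists", {
  tree <- load_haplotree()
  prof <- simulate_subject(tree, "H7b")
  ref <- toy_reference(100)

  ok <- heteroplasmy_events(10, 0.089, ref)
  tt <- plant_events(prof, "blood", ok)
  expect_s3_class(tt, "tissue_truth")
  expect_equal(tt$events$kind, "true_heteroplasmy")

  expect_equal(nrow(plant_events(prof, "retina")$events), 0L)

  dup <- dplyr::bind_rows(ok, ok)
  expect_error(plant_events(prof, "blood", dup),
               class = "mtduplex_validation_error")

  art <- dplyr::mutate(ok, kind = "single_strand_artifact")
  expect_error(plant_events(prof, "blood", art),
               class = "mtduplex_validation_error")  # artifact needs a pool
  art$artifact_pool <- "A"
  expect_equal(plant_events(prof, "blood", art)$events$artifact_pool, "A")
})

test_that("pileup counts conserve depth and respect the configured range", {
  ref <- toy_reference(300)
  panel <- design_panel(ref, n_pairs = 3, min_overlap = 5)
  tree <- load_haplotree()
  prof <- simulate_subject(tree, "H2a2a1")
  tt <- plant_events(prof, "blood",
                     heteroplasmy_events(c(50, 150), c(0.05, 0.30), ref))
  cfg <- sim_config(depth_mean = 5000, depth_min = 1000, depth_max = 20000)
  pu <- simulate_strand_pileups(tt, panel, cfg, seed = 3)
  depth <- pu$n_a + pu$n_c + pu$n_g + pu$n_t
  expect_true(all(depth >= 1000 & depth <= 20000))
  expect_equal(nrow(pu), 2L * 300L)
  # same seed twice gives identical pileups
  expect_identical(pu, simulate_strand_pileups(tt, panel, cfg, seed = 3))
  # depth model hits the configured mean
  big <- simulate_strand_pileups(tt, design_panel(ref, 1, 0),
                                 sim_config(), seed = 9)
  d <- big$n_a + big$n_c + big$n_g + big$n_t
  expect_lt(abs(mean(d) - 30000) / 30000, 0.25)
})

test_that("planted alt counts follow binomial moments at 1% MAF", {
  ref <- toy_reference(40)
  panel <- design_panel(ref, 1, 0)
  tree <- load_haplotree()
  prof <- simulate_subject(tree, "H2a2a1")
  tt <- plant_events(prof, "blood", heteroplasmy_events(20, 0.01, ref))
  cfg <- sim_config(depth_mean = 30000, depth_min = 30000, depth_max = 30000)
  alt_col <- paste0("n_", tolower(tt$events$alt))
  counts <- sapply(1:100, function(s) {
    pu <- simulate_strand_pileups(tt, panel, cfg, seed = s)
    pu[[alt_col]][pu$position == 20]   # both pools
  })
  # the alt rate is the planted MAF plus the error channel
  p_alt <- 0.01 + 0.99 * 0.001 / 3
  se <- sqrt(30000 * p_alt * (1 - p_alt)) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 30000 * p_alt), 4 * se)
})

test_that("maf = 0 everywhere with zero error leaves pure reference pileups", {
  ref <- toy_reference(120)
  panel <- design_panel(ref, 2, 4)
  tree <- load_haplotree()
  tt <- plant_events(simulate_subject(tree, "H2a2a1"), "blood")
  cfg <- sim_config(depth_mean = 2000, depth_min = 1000, depth_max = 4000,
                    base_error_rate = 0)
  pu <- simulate_strand_pileups(tt, panel, cfg, seed = 5)
  counts <- as.matrix(pu[, c("n_a", "n_c", "n_g", "n_t")])
  nonref <- rowSums(counts) - counts[cbind(seq_len(nrow(pu)),
                                           match(pu$ref, c("A", "C", "G", "T")))]
  expect_true(all(nonref == 0))
})

test_that("germline variants propagate near fixation and artifacts stay strand-asymmetric", {
  ref <- toy_reference(500)
  panel <- design_panel(ref, 2, 10)
  tree <- load_haplotree()
  prof <- simulate_subject(tree, "H7b")  # positions 263, 4793, 5348 out of range
  prof$germline <- heteroplasmy_events(c(100, 200), c(0.995, 0.995), ref)[, 1:4] |>
    dplyr::mutate(maf = 0.995)
  art <- heteroplasmy_events(350, 0.08, ref, kind = "single_strand_artifact",
                             artifact_pool = "A")
  for (tissue in c("blood", "retina", "rpe_choroid")) {
    tt <- plant_events(prof, tissue, art)
    pu <- simulate_strand_pileups(tt, panel, sim_config(), seed = 21)
    counts <- as.matrix(pu[, c("n_a", "n_c", "n_g", "n_t")])
    depth <- rowSums(counts)
    freq_of <- function(pos, alt, pool) {
      i <- which(pu$position == pos & pu$pool == pool)
      counts[i, match(alt, c("A", "C", "G", "T"))] / depth[i]
    }
    for (g in seq_len(2)) {
      for (pool in c("A", "B")) {
        f <- freq_of(prof$germline$position[g], prof$germline$alt[g], pool)
        expect_gt(f, 0.99 - 3 * sqrt(0.995 * 0.005 / 1000))
      }
    }
    expect_gt(freq_of(350, art$alt, "A"), 0.05)
    expect_lt(freq_of(350, art$alt, "B"), 0.005)  # ~ error/3 only
  }
})

test_that("cohort presence draws respect degenerate and binomial probabilities", {
  sizes <- c("Young" = 83L, "OldNL" = 66L, "AMD" = 73L)
  probs <- tibble::tibble(
    group = c("Young", "OldNL", "AMD"), position = 4104L, ref = "A", alt = "G",
    prob = c(0.988, 0.758, 0.753)
  )
  cp <- simulate_cohort_presence(sizes, probs, seed = 1)
  expect_s3_class(cp, "cohort_presence")
  young <- cp$carriers$carriers[cp$carriers$group == "Young"]
  # binomial 99% interval around 82
  expect_true(young >= qbinom(0.005, 83, 0.988) &&
                young <= qbinom(0.995, 83, 0.988))
  # deterministic per seed
  cp2 <- simulate_cohort_presence(sizes, probs, seed = 1)
  expect_identical(cp$carriers, cp2$carriers)

  zero <- simulate_cohort_presence(sizes, dplyr::mutate(probs, prob = 0), seed = 2)
  expect_true(all(zero$carriers$carriers == 0L))
  one <- simulate_cohort_presence(sizes, dplyr::mutate(probs, prob = 1), seed = 2)
  expect_equal(one$carriers$carriers, unname(sizes[one$carriers$group]))

  expect_error(simulate_cohort_presence(sizes, dplyr::mutate(probs, group = "X")),
               class = "mtduplex_lookup_error")
})
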