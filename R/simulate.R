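# Strand-resolved pileup simulator.
#
# The generator reproduces the statistical structure the downstream analysis
# assumes: two pools sequencing the two strands independently, per-position
# depth in [depth_min, depth_max] with a log-uniform body tilted so the mean
# matches depth_mean, a uniform substitution error spread over the three
# non-reference bases, germline homoplasmies propagated identically to every
# tissue of a subject, planted low-frequency heteroplasmies appearing on
# both strands, and deamination-like single-strand artifacts appearing in
# one pool only.

#' Simulation configuration
#'
#' @param depth_mean Target mean per-position, per-pool sequencing depth
#'   (default 30,000).
#' @param depth_min,depth_max Depth range (defaults 1,000 and 100,000).
#' @param base_error_rate Per-base substitution error rate (default 0.001,
#'   i.e. 0.1%); split evenly across the three non-reference bases.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(depth_mean = 30000, depth_min = 1000,
                       depth_max = 100000, base_error_rate = 0.001) {
  assert_scalar_number(depth_min, "depth_min", lower = 1)
  assert_scalar_number(depth_mean, "depth_mean", lower = depth_min)
  assert_scalar_number(depth_max, "depth_max", lower = depth_mean)
  assert_scalar_number(base_error_rate, "base_error_rate", lower = 0,
                       upper = 0.05 - 1e-12)
  out <- structure(list(depth_mean = depth_mean, depth_min = depth_min,
                        depth_max = depth_max,
                        base_error_rate = base_error_rate),
                   class = "sim_config")
  attr(out, "depth_exponent") <- depth_exponent(out)
  out
}

# Depth model: d = depth_min * (depth_max/depth_min)^(u^g), u ~ U(0,1).
# g = 1 is log-uniform; g is solved once so that E[d] = depth_mean, keeping
# every draw inside [depth_min, depth_max] without truncation.
depth_exponent <- function(config) {
  r <- config$depth_max / config$depth_min
  if (r == 1) return(1)
  target <- config$depth_mean / config$depth_min
  mean_for <- function(g) {
    u <- (seq_len(2048) - 0.5) / 2048
    mean(r^(u^g))
  }
  uniroot(function(g) mean_for(g) - target, c(0.02, 50), tol = 1e-10)$root
}

draw_depths <- function(n, config, exponent = depth_exponent(config)) {
  u <- runif(n)
  as.integer(round(config$depth_min *
                     (config$depth_max / config$depth_min)^(u^exponent)))
}

#' Simulate a subject's germline profile from the haplogroup tree
#'
#' The subject's germline homoplasmies are the union of defining SNPs on
#' the root-to-haplogroup path, fixed near 100% allele frequency and shared
#' identically by every tissue of the subject.
#'
#' @param tree An `mt_haplotree`.
#' @param haplogroup Label of a node in `tree`.
#' @param subject_id Identifier (defaults to the haplogroup label).
#' @param germline_maf Allele frequency of germline variants (default
#'   0.995, matching near-fixed homoplasmy).
#' @return A list of class `subject_profile`: `subject_id`, `haplogroup`,
#'   `germline` (tibble `position`, `ref`, `alt`, `maf`).
#' @export
simulate_subject <- function(tree, haplogroup, subject_id = haplogroup,
                             germline_maf = 0.995) {
  snps <- haplogroup_snps(tree, haplogroup)
  structure(
    list(subject_id = subject_id, haplogroup = haplogroup,
         germline = dplyr::mutate(snps, maf = germline_maf)),
    class = "subject_profile"
  )
}

#' Plant heteroplasmy and artifact events in one tissue
#'
#' @param profile A `subject_profile`.
#' @param tissue One of `"blood"`, `"retina"`, `"rpe_choroid"`.
#' @param events Tibble with columns `position`, `ref`, `alt`, `maf`,
#'   `kind` (`"true_heteroplasmy"` or `"single_strand_artifact"`) and
#'   `artifact_pool` (`"A"`/`"B"` for artifacts, `NA` otherwise). May be
#'   empty for a germline-only tissue.
#' @return A list of class `tissue_truth` retaining the profile, tissue and
#'   event list for later recovery scoring.
#' @export
plant_events <- function(profile, tissue = c("blood", "retina", "rpe_choroid"),
                         events = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  tissue <- match.arg(tissue)
  events <- events %||% tibble(position = integer(), ref = character(),
                               alt = character(), maf = numeric(),
                               kind = character(), artifact_pool = character())
  events <- as_tibble(events)
  if (nrow(events) > 0) {
    assert_bases(events$ref, "ref"); assert_bases(events$alt, "alt")
    if (any(events$ref == events$alt)) {
      abort("event ref and alt must differ", class = "mtduplex_validation_error")
    }
    if (any(events$maf <= 0 | events$maf >= 1)) {
      abort("event maf must be in (0, 1)", class = "mtduplex_validation_error")
    }
    if (any(!events$kind %in% c("true_heteroplasmy", "single_strand_artifact"))) {
      abort("unknown event kind", class = "mtduplex_validation_error")
    }
    art <- events$kind == "single_strand_artifact"
    if (any(art & !events$artifact_pool %in% c("A", "B")) ||
        any(!art & !is.na(events$artifact_pool))) {
      abort("artifact_pool must be A/B for artifacts and NA otherwise",
            class = "mtduplex_validation_error")
    }
    if (anyDuplicated(events[, c("position", "alt")])) {
      abort("duplicate (position, alt) events", class = "mtduplex_validation_error")
    }
  }
  structure(list(profile = profile, tissue = tissue, events = events),
            class = "tissue_truth")
}

#' Convenience constructor for heteroplasmy / artifact event rows
#'
#' @param position,maf Vectors of positions and allele fractions.
#' @param reference An [mt_reference()] used to look up reference bases.
#' @param alt Alternate bases; default picks the transition partner of each
#'   reference base (the dominant substitution class in mtDNA heteroplasmy).
#' @param kind `"true_heteroplasmy"` or `"single_strand_artifact"`.
#' @param artifact_pool Pool carrying the artifact (`"A"`/`"B"`), for
#'   artifact events.
#' @return Event tibble suitable for [plant_events()].
#' @export
heteroplasmy_events <- function(position, maf, reference, alt = NULL,
                                kind = "true_heteroplasmy",
                                artifact_pool = NA_character_) {
  ref <- ref_base(reference, position)
  alt <- alt %||% transition_partner(ref)
  tibble(position = as.integer(position), ref = ref, alt = alt,
         maf = maf, kind = kind, artifact_pool = artifact_pool)
}

transition_partner <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[base]
}

#' Simulate strand-resolved pileups for one tissue sample
#'
#' Each pool draws per-position depths independently, then base counts:
#' event alternate alleles are binomial at the event MAF plus the error
#' channel, `maf + (1 - maf) * base_error_rate / 3` (both pools for true
#' heteroplasmies and germline variants; only the artifact pool for
#' single-strand artifacts), every other non-reference base is binomial at
#' `base_error_rate / 3`, and the reference base takes the remainder so
#' counts always sum to the drawn depth.
#'
#' @param truth A `tissue_truth` from [plant_events()].
#' @param panel An `mt_panel`; every position must be covered by each pool.
#' @param config A [sim_config()].
#' @param seed Integer seed; fixed seeds give identical pileups.
#' @return Tibble with columns `pool`, `position`, `ref`, `n_a`, `n_c`,
#'   `n_g`, `n_t` (both pools stacked), of class `mt_pileup`.
#' @export
simulate_strand_pileups <- function(truth, panel, config = sim_config(),
                                    seed = NULL) {
  stopifnot(inherits(truth, "tissue_truth"), inherits(panel, "mt_panel"),
            inherits(config, "sim_config"))
  reference <- attr(panel, "reference")
  L <- reference$length
  events <- dplyr::bind_rows(
    dplyr::mutate(truth$profile$germline, kind = "true_heteroplasmy",
                  artifact_pool = NA_character_),
    truth$events
  )
  if (nrow(events) > 0 && any(events$position < 1L | events$position > L)) {
    abort("event positions outside the reference",
          class = "mtduplex_validation_error")
  }
  if (!isTRUE(attr(panel, "coverage_complete"))) {
    cov <- coverage_profile(panel)
    if (any(cov$coverage < 1L)) {
      abort("panel does not cover every position in both pools",
            class = "mtduplex_config_error")
    }
  }
  if (!is.null(seed)) withr::local_seed(seed)
  exponent <- attr(config, "depth_exponent") %||% depth_exponent(config)
  ref_all <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]

  one_pool <- function(pool) {
    depth <- draw_depths(L, config, exponent)
    counts <- matrix(0L, nrow = L, ncol = 4L,
                     dimnames = list(NULL, DNA_BASES))
    err3 <- config$base_error_rate / 3
    # error counts for every non-reference base
    for (b in DNA_BASES) {
      idx <- which(ref_all != b)
      counts[idx, b] <- rbinom(length(idx), depth[idx], err3)
    }
    # event alt counts override the error draw at the event's alt base
    ev <- events
    if (nrow(ev) > 0) {
      active <- ev$kind == "true_heteroplasmy" |
        (ev$kind == "single_strand_artifact" & ev$artifact_pool == pool)
      ev <- ev[active, , drop = FALSE]
    }
    if (nrow(ev) > 0) {
      j <- match(ev$alt, DNA_BASES)
      # the error channel also feeds the event's alternate base: reads are
      # alt if drawn from the variant fraction or mis-read towards it
      p_alt <- ev$maf + (1 - ev$maf) * err3
      counts[cbind(ev$position, j)] <-
        rbinom(nrow(ev), depth[ev$position], p_alt)
    }
    # reference base takes the remainder (clamped at zero)
    nonref <- rowSums(counts)
    ref_idx <- cbind(seq_len(L), match(ref_all, DNA_BASES))
    counts[ref_idx] <- pmax(0L, depth - as.integer(nonref))
    tibble(pool = pool, position = seq_len(L), ref = ref_all,
           n_a = counts[, "A"], n_c = counts[, "C"],
           n_g = counts[, "G"], n_t = counts[, "T"])
  }

  out <- dplyr::bind_rows(one_pool("A"), one_pool("B"))
  structure(out, class = c("mt_pileup", class(out)),
            subject_id = truth$profile$subject_id, tissue = truth$tissue)
}

#' Simulate cohort carrier/non-carrier presence
#'
#' Carrier counts per group and SNP are independent binomial draws at the
#' supplied carrier probabilities, mirroring how hot-spot presence is
#' tallied in blood across subject groups.
#'
#' @param group_sizes Named integer vector, e.g.
#'   `c("Young-NL" = 83, "Old-NL" = 66, "Old-AMD" = 73)`.
#' @param carrier_prob Tibble with columns `group`, `position`, `ref`,
#'   `alt`, `prob`.
#' @param seed Integer seed.
#' @return A `cohort_presence` object: list with `groups` (tibble `group`,
#'   `n`) and `carriers` (tibble `group`, `position`, `ref`, `alt`,
#'   `carriers`).
#' @export
simulate_cohort_presence <- function(group_sizes, carrier_prob, seed = NULL) {
  carrier_prob <- as_tibble(carrier_prob)
  if (any(!carrier_prob$group %in% names(group_sizes))) {
    abort("carrier_prob refers to unknown groups", class = "mtduplex_lookup_error")
  }
  if (any(carrier_prob$prob < 0 | carrier_prob$prob > 1)) {
    abort("carrier probabilities must be in [0, 1]",
          class = "mtduplex_validation_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n <- unname(group_sizes[carrier_prob$group])
  carriers <- rbinom(nrow(carrier_prob), n, carrier_prob$prob)
  cohort_presence(
    groups = tibble(group = names(group_sizes), n = as.integer(group_sizes)),
    carriers = dplyr::mutate(
      dplyr::select(carrier_prob, -"prob"), carriers = as.integer(carriers))
  )
}

#' Construct a cohort presence object
#'
#' @param groups Tibble `group`, `n`.
#' @param carriers Tibble `group`, `position`, `ref`, `alt`, `carriers`.
#' @return A list of class `cohort_presence`.
#' @export
cohort_presence <- function(groups, carriers) {
  groups <- as_tibble(groups); carriers <- as_tibble(carriers)
  n_of <- setNames(groups$n, groups$group)
  if (any(carriers$carriers < 0) ||
      any(carriers$carriers > n_of[carriers$group])) {
    abort("carrier counts must lie in [0, group size]",
          class = "mtduplex_validation_error")
  }
  structure(list(groups = groups, carriers = carriers),
            class = "cohort_presence")
}
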