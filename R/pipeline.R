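# End-to-end pipeline composition and the fixture-based reproduction path.

#' Pipeline configuration
#'
#' Collects every stage's tunable parameters in one validated, YAML
#' round-trippable object.
#'
#' @param reference_path FASTA path; `NULL` uses the packaged synthetic
#'   reference.
#' @param n_pairs,min_overlap Panel parameters (see [design_panel()]).
#' @param caller A [caller_config()].
#' @param sim A [sim_config()].
#' @param require_pass,combine Concordance options (see [concord()]).
#' @param zygosity A [zygosity_thresholds()].
#' @param min_subjects,exclude_polyc Hot-spot options.
#' @param subjects Named character vector mapping subject id to haplogroup
#'   label; defaults to the three study subjects.
#' @param het_per_tissue Named integer vector: true heteroplasmies planted
#'   per tissue. The default (blood 10, RPE+choroid 2, retina 1) imposes
#'   the blood-dominant tissue imbalance; tissue differences are planted,
#'   not emergent.
#' @param artifacts_per_tissue Single-strand artifacts planted per tissue
#'   (default 2).
#' @param maf_range Planted heteroplasmy frequency range (default 1-40%).
#' @param seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_path = NULL, n_pairs = 171,
                            min_overlap = 20,
                            caller = caller_config(), sim = sim_config(),
                            require_pass = TRUE,
                            combine = c("weighted", "min"),
                            zygosity = zygosity_thresholds(),
                            min_subjects = 2, exclude_polyc = FALSE,
                            subjects = c(S1 = "I1a1b", S2 = "H7b",
                                         S3 = "U2e2a1"),
                            het_per_tissue = c(blood = 10L, rpe_choroid = 2L,
                                               retina = 1L),
                            artifacts_per_tissue = 2L,
                            maf_range = c(0.01, 0.40),
                            seed = 1L) {
  combine <- match.arg(combine)
  stopifnot(inherits(caller, "caller_config"), inherits(sim, "sim_config"),
            inherits(zygosity, "zygosity_thresholds"))
  assert_scalar_number(seed, "seed")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be increasing fractions in (0, 1)",
          class = "mtduplex_config_error")
  }
  structure(
    list(reference_path = reference_path, n_pairs = as.integer(n_pairs),
         min_overlap = as.integer(min_overlap), caller = caller, sim = sim,
         require_pass = isTRUE(require_pass), combine = combine,
         zygosity = zygosity, min_subjects = as.integer(min_subjects),
         exclude_polyc = isTRUE(exclude_polyc),
         subjects = subjects,
         het_per_tissue = c(blood = as.integer(het_per_tissue[["blood"]]),
                            rpe_choroid = as.integer(het_per_tissue[["rpe_choroid"]]),
                            retina = as.integer(het_per_tissue[["retina"]])),
         artifacts_per_tissue = as.integer(artifacts_per_tissue),
         maf_range = as.numeric(maf_range), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Save / load a pipeline configuration as YAML
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly; `load_config()` returns the config.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- list(
    reference_path = config$reference_path,
    n_pairs = config$n_pairs, min_overlap = config$min_overlap,
    caller = unclass(config$caller), sim = unclass(config$sim),
    require_pass = config$require_pass, combine = config$combine,
    zygosity = unclass(config$zygosity),
    min_subjects = config$min_subjects, exclude_polyc = config$exclude_polyc,
    subjects = as.list(config$subjects),
    het_per_tissue = as.list(config$het_per_tissue),
    artifacts_per_tissue = config$artifacts_per_tissue,
    maf_range = config$maf_range, seed = config$seed
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    reference_path = y$reference_path, n_pairs = y$n_pairs,
    min_overlap = y$min_overlap,
    caller = do.call(caller_config, y$caller),
    sim = do.call(sim_config, y$sim),
    require_pass = y$require_pass, combine = y$combine,
    zygosity = do.call(zygosity_thresholds, y$zygosity),
    min_subjects = y$min_subjects, exclude_polyc = y$exclude_polyc,
    subjects = unlist(y$subjects),
    het_per_tissue = unlist(y$het_per_tissue),
    artifacts_per_tissue = y$artifacts_per_tissue,
    maf_range = unlist(y$maf_range), seed = y$seed
  )
}

TISSUES <- c("blood", "rpe_choroid", "retina")

#' Run the simulation pipeline end to end
#'
#' For each configured subject and tissue: plant events, simulate strand
#' pileups, call each pool, apply both-strand concordance and classify the
#' true variants; then aggregate heteroplasmies across samples into tissue
#' counts, hot-spots, the blood-only list and the transition/transversion
#' summary. Fully reproducible from the config's seed.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, per-sample VCFs and
#'   aggregate TSVs are written there.
#' @return A result bundle (list): `truth`, `per_sample`, `haplogroups`,
#'   `heteroplasmy_table`, `tissue_counts`, `hotspots`, `blood_only`,
#'   `tstv`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  reference <- if (is.null(config$reference_path)) {
    load_reference(mtdna_reference_path())
  } else {
    load_reference(config$reference_path)
  }
  panel <- design_panel(reference, config$n_pairs, config$min_overlap)
  tree <- load_haplotree()
  log <- character()
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log <<- c(log, line)
    line
  }
  say("init", sprintf("seed=%d subjects=%d", config$seed,
                      length(config$subjects)))

  sample_idx <- 0L
  per_sample <- list()
  truth <- list()
  het_rows <- list()
  hom_rows <- list()
  haplogroups <- list()

  for (sid in names(config$subjects)) {
    profile <- simulate_subject(tree, config$subjects[[sid]], subject_id = sid)
    for (tissue in TISSUES) {
      sample_idx <- sample_idx + 1L
      sample_seed <- (config$seed + 7919L * sample_idx) %% .Machine$integer.max
      events <- withr::with_seed(sample_seed, random_events(
        reference, profile,
        n_het = config$het_per_tissue[[tissue]],
        n_artifacts = config$artifacts_per_tissue,
        maf_range = config$maf_range))
      tt <- plant_events(profile, tissue, events)
      pileups <- simulate_strand_pileups(tt, panel, config$sim,
                                         seed = sample_seed + 1L)
      calls <- call_pool_variants(pileups, reference, config$caller)
      conc <- concord(calls[calls$pool == "A", ], calls[calls$pool == "B", ],
                      require_pass = config$require_pass,
                      combine = config$combine)
      classified <- classify_variants(tidy(conc), tree = tree,
                                      thresholds = config$zygosity)
      say(ifelse(TRUE, "sample", "sample"),
          sprintf("%s/%s: %d true variants, %d artifacts", sid, tissue,
                  nrow(conc$true_variants), nrow(conc$artifacts)))
      key <- sprintf("%s_%s", sid, tissue)
      truth[[key]] <- tt
      per_sample[[key]] <- list(concordance = conc, classified = classified)
      het <- classified[classified$zygosity == "heteroplasmy", ]
      if (nrow(het) > 0L) {
        het_rows[[key]] <- tibble(position = het$position, ref = het$ref,
                                  alt = het$alt, subject = sid,
                                  tissue = tissue,
                                  freq = het$combined_freq)
      }
      hom <- classified[classified$zygosity == "homoplasmy", ]
      hom_rows[[key]] <- tibble(position = hom$position, ref = hom$ref,
                                alt = hom$alt, subject = sid, tissue = tissue,
                                freq = hom$combined_freq)
      haplogroups[[key]] <- tibble(subject = sid, tissue = tissue,
                                   haplogroup = attr(classified, "haplogroup"))
      if (!is.null(output_dir)) {
        dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
        write_variants_vcf(classified, reference,
                           file.path(output_dir, paste0(key, ".vcf")))
      }
    }
  }

  het_table <- dplyr::bind_rows(het_rows)
  excl <- if (config$exclude_polyc) polyc_region() else NULL
  bundle <- list(
    config = config,
    truth = truth,
    per_sample = per_sample,
    haplogroups = dplyr::bind_rows(haplogroups),
    homoplasmy_table = dplyr::bind_rows(hom_rows),
    heteroplasmy_table = het_table,
    tissue_counts = if (nrow(het_table)) tissue_counts(het_table) else NULL,
    hotspots = if (nrow(het_table))
      detect_hotspots(het_table, config$min_subjects, excl) else NULL,
    blood_only = if (nrow(het_table)) blood_only_snps(het_table) else NULL,
    tstv = if (nrow(het_table))
      tstv_summary(het_table, .data$subject, .data$tissue) else NULL,
    log = log
  )
  if (!is.null(output_dir)) {
    readr::write_tsv(het_table, file.path(output_dir, "heteroplasmy_table.tsv"))
    readr::write_tsv(bundle$haplogroups, file.path(output_dir, "haplogroups.tsv"))
    writeLines(log, file.path(output_dir, "pipeline.log"))
  }
  bundle
}

# Draw random planted events for one tissue: true heteroplasmies on both
# strands plus deamination-like single-strand artifacts (C>T / G>A on one
# pool only), avoiding germline positions and duplicates.
random_events <- function(reference, profile, n_het, n_artifacts, maf_range) {
  taken <- profile$germline$position
  ref_all <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  free <- setdiff(seq_len(reference$length), taken)
  het_pos <- sort(sample(free, n_het))
  free <- setdiff(free, het_pos)
  # artifacts are C>T or G>A, so draw from C/G sites
  cg <- free[ref_all[free] %in% c("C", "G")]
  art_pos <- sort(sample(cg, n_artifacts))
  het <- heteroplasmy_events(het_pos,
                             maf = runif(n_het, maf_range[1], maf_range[2]),
                             reference = reference)
  art_ref <- ref_all[art_pos]
  art <- tibble(position = as.integer(art_pos), ref = art_ref,
                alt = ifelse(art_ref == "C", "T", "A"),
                maf = runif(n_artifacts, 0.01, 0.10),
                kind = "single_strand_artifact",
                artifact_pool = sample(c("A", "B"), n_artifacts,
                                       replace = TRUE))
  dplyr::bind_rows(het, art)
}

#' Reproduce the study's aggregate results from the packaged tables
#'
#' Runs the aggregation and statistics stages directly on the transcribed
#' study tables (no simulation): per-tissue heteroplasmy counts and
#' shares, transition/transversion partition, blood-only SNPs, frequency
#' bands, hot-spot detection, per-subject haplogroup assignment from the
#' homoplasmy sets, and cohort odds ratios with Fisher exact tests.
#'
#' @return A list of tibbles: `tissue_counts`, `tissue_totals`,
#'   `total_snp_share`, `tstv`, `blood_only`, `maf_bands`, `hotspots`,
#'   `haplogroups`, `cohort_comparisons`.
#' @export
reproduce_study <- function() {
  het <- as_heteroplasmy_table()
  hom <- as_homoplasmy_table()
  tree <- load_haplotree()

  # the fixture carries the table's printed Total row; shares use it as
  # printed (it differs from the subject-row column sums by 2, a documented
  # inconsistency of the source table)
  t2 <- load_fixture("table2")
  totals2 <- unlist(t2[t2$subject == "Total", c("blood", "rpe_choroid", "retina")])
  total_snp_share <- tibble(tissue = names(totals2),
                            n = as.integer(totals2),
                            share_pct = 100 * as.numeric(totals2) / sum(totals2))

  haplogroups <- hom |>
    dplyr::distinct(.data$subject, .data$position, .data$ref, .data$alt) |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(~assign_haplogroup(.x, tree)) |>
    dplyr::ungroup()

  pairs <- list(c("Young-NL", "Old-NL"), c("Young-NL", "Old-AMD"),
                c("Old-NL", "Old-AMD"))
  list(
    tissue_counts = tissue_counts(het, by = "sample"),
    tissue_totals = tissue_counts(het, by = "tissue"),
    total_snp_share = total_snp_share,
    tstv = tstv_summary(het, .data$subject, .data$tissue),
    blood_only = blood_only_snps(het),
    maf_bands = maf_band_histogram(het, c(0.30, 0.50)),
    hotspots = detect_hotspots(het, min_subjects = 2),
    haplogroups = haplogroups,
    cohort_comparisons = compare_groups(cohort_from_table8(), pairs)
  )
}
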