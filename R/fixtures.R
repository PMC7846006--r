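# Packaged transcriptions of the study's printed tables.
#
# The fixtures are shipped verbatim from the printed tables, including
# their internal inconsistencies (documented in the fixture README); the
# loader verifies file checksums against the packaged manifest.

FIXTURE_FILES <- c(
  table2 = "table2_total_snps.tsv",
  table3 = "table3_homoplasmy.tsv",
  table5 = "table5_heteroplasmy.tsv",
  table7 = "table7_annotations.tsv",
  table8 = "table8_cohort.tsv"
)

fixture_path <- function(file) {
  system.file("extdata", file, package = "mtduplex", mustWork = TRUE)
}

check_fixture_integrity <- function(file) {
  manifest <- readr::read_tsv(fixture_path("fixture_checksums.tsv"),
                              show_col_types = FALSE, col_types = "cc")
  expected <- manifest$md5[manifest$file == file]
  actual <- unname(tools::md5sum(fixture_path(file)))
  if (length(expected) != 1L || expected != actual) {
    abort(sprintf("fixture checksum mismatch for %s", file),
          class = "mtduplex_integrity_error")
  }
  invisible(TRUE)
}

#' Load a packaged study table
#'
#' Returns the transcribed tables as tibbles. Frequency columns are
#' converted from printed percentages to fractions; everything else is
#' verbatim.
#'
#' * `table2` — total SNP counts per subject and tissue.
#' * `table3` — germline homoplasmy SNPs with per-sample frequencies.
#' * `table5` — heteroplasmy SNPs with per-sample frequencies.
#' * `table7` — hot-spot annotations (locus, amino-acid change, rs id,
#'   pathogenicity notes).
#' * `table8` — hot-spot carrier counts in the 222-subject blood cohort
#'   (Young-NL n=83, Old-NL n=66, Old-AMD n=73).
#'
#' @param name One of `"table2"`, `"table3"`, `"table5"`, `"table7"`,
#'   `"table8"`.
#' @return A tibble.
#' @examples
#' load_fixture("table8")
#' @export
load_fixture <- function(name = c("table2", "table3", "table5", "table7",
                                  "table8")) {
  name <- match.arg(name)
  file <- FIXTURE_FILES[[name]]
  check_fixture_integrity(file)
  df <- readr::read_tsv(fixture_path(file), show_col_types = FALSE,
                        na = "NA")
  freq_cols <- grep("^s[123]_", names(df), value = TRUE)
  for (col in freq_cols) df[[col]] <- df[[col]] / 100
  as_tibble(df)
}

SAMPLE_COLS <- c("s1_blood", "s1_rpe_choroid", "s1_retina",
                 "s2_blood", "s2_rpe_choroid", "s2_retina",
                 "s3_blood", "s3_rpe_choroid", "s3_retina")

wide_to_long <- function(wide) {
  wide |>
    tidyr::pivot_longer(dplyr::all_of(SAMPLE_COLS), names_to = "sample",
                        values_to = "freq") |>
    dplyr::filter(!is.na(.data$freq)) |>
    tidyr::separate_wider_regex(
      "sample", c(subject = "s[123]", "_", tissue = ".*")) |>
    dplyr::mutate(subject = toupper(.data$subject)) |>
    dplyr::select("position", "ref", "alt", "subject", "tissue", "freq")
}

#' Long per-sample heteroplasmy table from the packaged fixture
#'
#' @param table5 The wide fixture (default: `load_fixture("table5")`).
#' @return Long tibble (`position`, `ref`, `alt`, `subject`, `tissue`,
#'   `freq`), one row per SNP observed in a sample.
#' @export
as_heteroplasmy_table <- function(table5 = load_fixture("table5")) {
  wide_to_long(table5)
}

#' Long per-sample homoplasmy table from the packaged fixture
#'
#' @param table3 The wide fixture (default: `load_fixture("table3")`).
#' @return Long tibble (`position`, `ref`, `alt`, `subject`, `tissue`,
#'   `freq`).
#' @export
as_homoplasmy_table <- function(table3 = load_fixture("table3")) {
  wide_to_long(dplyr::select(table3, -dplyr::any_of("note")))
}

#' Known-SNP annotation keys
#'
#' The packaged stand-in for external variant databases: the union of the
#' annotated hot-spot SNPs and the germline homoplasmy SNPs. "Unique"
#' classifications are relative to this set.
#'
#' @return Tibble (`position`, `ref`, `alt`).
#' @export
annotation_keys <- function() {
  dplyr::distinct(
    dplyr::bind_rows(
      dplyr::select(load_fixture("table7"), "position", "ref", "alt"),
      dplyr::select(load_fixture("table3"), "position", "ref", "alt")
    ),
    .data$position, .data$ref, .data$alt
  )
}

#' Cohort presence object from the packaged carrier-count table
#'
#' @param table8 The fixture (default `load_fixture("table8")`).
#' @return A `cohort_presence` with groups Young-NL (n=83), Old-NL (n=66)
#'   and Old-AMD (n=73).
#' @export
cohort_from_table8 <- function(table8 = load_fixture("table8")) {
  groups <- tibble(group = c("Young-NL", "Old-NL", "Old-AMD"),
                   n = c(83L, 66L, 73L))
  carriers <- dplyr::bind_rows(
    dplyr::transmute(table8, group = "Young-NL", .data$position, .data$ref,
                     .data$alt, carriers = .data$young_nl_carriers),
    dplyr::transmute(table8, group = "Old-NL", .data$position, .data$ref,
                     .data$alt, carriers = .data$old_nl_carriers),
    dplyr::transmute(table8, group = "Old-AMD", .data$position, .data$ref,
                     .data$alt, carriers = .data$old_amd_carriers)
  )
  cohort_presence(groups, carriers)
}
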