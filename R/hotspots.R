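# Cross-sample aggregation: tissue counts, hot-spots, blood-only SNPs,
# frequency-band histograms.
#
# All operations work on a long "heteroplasmy table": one row per
# (SNP, subject, tissue) with a positive combined frequency.

validate_het_table <- function(table) {
  table <- as_tibble(table)
  needed <- c("position", "ref", "alt", "subject", "tissue", "freq")
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    abort(sprintf("heteroplasmy table lacks columns: %s",
                  paste(missing, collapse = ", ")),
          class = "mtduplex_validation_error")
  }
  if (any(!table$tissue %in% c("blood", "retina", "rpe_choroid"))) {
    abort("tissue must be blood, retina or rpe_choroid",
          class = "mtduplex_validation_error")
  }
  table
}

#' Heteroplasmy counts per sample or per tissue
#'
#' @param table Long heteroplasmy table (`position`, `ref`, `alt`,
#'   `subject`, `tissue`, `freq`).
#' @param by `"sample"` (default): counts per (subject, tissue) with each
#'   subject's tissue shares; `"tissue"`: totals per tissue across subjects
#'   with overall shares.
#' @return A tibble of counts `n` and percentage shares `share_pct`
#'   (shares sum to 100 within a subject, or overall for `by = "tissue"`).
#' @export
tissue_counts <- function(table, by = c("sample", "tissue")) {
  by <- match.arg(by)
  table <- validate_het_table(table)
  if (by == "sample") {
    table |>
      dplyr::count(.data$subject, .data$tissue) |>
      dplyr::group_by(.data$subject) |>
      dplyr::mutate(share_pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  } else {
    table |>
      dplyr::count(.data$tissue) |>
      dplyr::mutate(share_pct = 100 * .data$n / sum(.data$n))
  }
}

#' Detect recurrence hot-spots
#'
#' A hot-spot is a heteroplasmy SNP observed in at least `min_subjects`
#' distinct subjects, in any tissue (a subject counts once however many of
#' its tissues carry the SNP). Optionally excludes positions inside given
#' regions; [polyc_region()] is a documented preset for the homopolymeric
#' C-tract at 302-316, whose calls are unstable in amplicon data.
#'
#' @param table Long heteroplasmy table.
#' @param min_subjects Minimum number of distinct subjects (default 2).
#' @param excluded_regions Optional tibble of intervals (`start`, `end`),
#'   1-based inclusive.
#' @return Tibble sorted by position: `position`, `ref`, `alt`,
#'   `n_subjects` and a nested `samples` list-column of per-sample
#'   frequencies.
#' @export
detect_hotspots <- function(table, min_subjects = 2, excluded_regions = NULL) {
  assert_scalar_number(min_subjects, "min_subjects", lower = 1)
  table <- validate_het_table(table)
  if (!is.null(excluded_regions) && nrow(excluded_regions) > 0) {
    excl <- vapply(table$position, function(p) {
      any(p >= excluded_regions$start & p <= excluded_regions$end)
    }, logical(1))
    table <- table[!excl, , drop = FALSE]
  }
  table |>
    dplyr::group_by(.data$position, .data$ref, .data$alt) |>
    dplyr::summarise(
      n_subjects = dplyr::n_distinct(.data$subject),
      samples = list(dplyr::pick("subject", "tissue", "freq")),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_subjects >= min_subjects) |>
    dplyr::arrange(.data$position, .data$alt)
}

#' Poly-C tract exclusion preset
#'
#' @return One-row tibble covering positions 302-316.
#' @export
polyc_region <- function() tibble(start = 302L, end = 316L)

#' Blood-only heteroplasmy SNPs
#'
#' SNPs present in blood and absent from every retina and RPE+choroid
#' sample. With `require_all_subjects = TRUE` (default) the SNP must be
#' present in the blood of every subject in the table; this is the rule
#' that reproduces the reported blood-only list, whereas the looser
#' "any blood, no other tissue" reading admits many more SNPs.
#'
#' @param table Long heteroplasmy table.
#' @param require_all_subjects Require presence in every subject's blood.
#' @return Tibble of SNP keys (`position`, `ref`, `alt`), sorted by
#'   position.
#' @export
blood_only_snps <- function(table, require_all_subjects = TRUE) {
  table <- validate_het_table(table)
  n_subjects <- dplyr::n_distinct(table$subject)
  table |>
    dplyr::group_by(.data$position, .data$ref, .data$alt) |>
    dplyr::summarise(
      n_blood_subjects = dplyr::n_distinct(.data$subject[.data$tissue == "blood"]),
      n_nonblood = sum(.data$tissue != "blood"),
      .groups = "drop"
    ) |>
    dplyr::filter(
      .data$n_nonblood == 0L,
      if (require_all_subjects) .data$n_blood_subjects == n_subjects
      else .data$n_blood_subjects >= 1L
    ) |>
    dplyr::select("position", "ref", "alt") |>
    dplyr::arrange(.data$position, .data$alt)
}

#' Histogram of heteroplasmy frequencies in bands
#'
#' Bands are half-open `[lo, hi)` between consecutive edges, with implicit
#' underflow `[0, first)` and overflow `[last, 1]` bands so the counts
#' always sum to the table size.
#'
#' @param table Long heteroplasmy table.
#' @param band_edges Strictly increasing fractions in (0, 1].
#' @return Tibble `band_lo`, `band_hi`, `n`.
#' @export
maf_band_histogram <- function(table, band_edges) {
  table <- validate_het_table(table)
  if (length(band_edges) < 1 || any(diff(band_edges) <= 0) ||
      any(band_edges <= 0 | band_edges > 1)) {
    abort("band_edges must be strictly increasing fractions in (0, 1]",
          class = "mtduplex_domain_error")
  }
  edges <- unique(c(0, band_edges, 1 + 1e-9))
  idx <- findInterval(table$freq, edges, rightmost.closed = FALSE)
  n <- tabulate(idx, nbins = length(edges) - 1L)
  tibble(band_lo = edges[-length(edges)],
         band_hi = pmin(edges[-1], 1),
         n = n)
}

#' Frequency spectrum plot
#'
#' @param table Long heteroplasmy table.
#' @param binwidth Histogram bin width on the frequency axis (default 0.02).
#' @return A ggplot.
#' @export
plot_maf_spectrum <- function(table, binwidth = 0.02) {
  table <- validate_het_table(table)
  ggplot2::ggplot(table, ggplot2::aes(.data$freq)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "heteroplasmy frequency", y = "SNPs") +
    ggplot2::theme_minimal()
}

#' Per-sample heteroplasmy burden plot
#'
#' @param table Long heteroplasmy table.
#' @return A ggplot of SNP counts per subject and tissue.
#' @export
plot_tissue_counts <- function(table) {
  counts <- tissue_counts(table, by = "sample")
  ggplot2::ggplot(counts, ggplot2::aes(.data$tissue, .data$n,
                                       fill = .data$tissue)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~subject) +
    ggplot2::labs(x = NULL, y = "heteroplasmy SNPs") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
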