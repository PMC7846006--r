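# Variant classification: zygosity, category, substitution class.

#' Transition or transversion?
#'
#' Transitions stay within the purines (A, G) or within the pyrimidines
#' (C, T) and are the signature of replication error; transversions cross
#' between the two classes and are associated with oxidative damage.
#'
#' @param ref,alt Character vectors of bases; `ref[i] != alt[i]`.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("C", "T")  # transition
#' classify_substitution("A", "C")  # transversion
#' @export
classify_substitution <- function(ref, alt) {
  assert_bases(ref, "ref"); assert_bases(alt, "alt")
  if (any(ref == alt)) {
    abort("ref and alt must differ", class = "mtduplex_domain_error")
  }
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[ref] == purine[alt], "transition", "transversion"))
}

#' Zygosity thresholds
#'
#' @param homoplasmy_min Combined frequency at or above which a variant is
#'   homoplasmic (default 0.85; observed homoplasmies sit at or above ~0.90
#'   and heteroplasmies at or below ~0.60, and 85-90% is the heteroplasmy
#'   burden at which cellular pathogenicity is reached, so 0.85 separates
#'   the two cleanly).
#' @param low_frequency_max Reporting flag threshold for "low-frequency"
#'   heteroplasmy (default 0.40).
#' @return A list of class `zygosity_thresholds`.
#' @export
zygosity_thresholds <- function(homoplasmy_min = 0.85, low_frequency_max = 0.40) {
  assert_scalar_number(low_frequency_max, "low_frequency_max", lower = 1e-12)
  assert_scalar_number(homoplasmy_min, "homoplasmy_min",
                       lower = low_frequency_max + 1e-12, upper = 1)
  structure(list(homoplasmy_min = homoplasmy_min,
                 low_frequency_max = low_frequency_max),
            class = "zygosity_thresholds")
}

#' Homoplasmy or heteroplasmy from combined frequency
#'
#' @param combined_freq Numeric vector of combined allele frequencies in
#'   (0, 1].
#' @param thresholds A [zygosity_thresholds()].
#' @return Character vector, `"homoplasmy"` or `"heteroplasmy"`.
#' @examples
#' classify_zygosity(c(0.9953, 0.6043, 0.85))
#' @export
classify_zygosity <- function(combined_freq, thresholds = zygosity_thresholds()) {
  if (any(combined_freq <= 0 | combined_freq > 1)) {
    abort("combined_freq must be in (0, 1]", class = "mtduplex_domain_error")
  }
  ifelse(combined_freq >= thresholds$homoplasmy_min, "homoplasmy",
         "heteroplasmy")
}

#' Categorise variants as haplogroup-defining, private or unique
#'
#' A variant on the assigned haplogroup's root-to-node path is
#' haplogroup-defining; otherwise a variant known to the packaged
#' annotation set is private; anything else is unique. "Unique" is
#' relative to the packaged annotation set (no network lookups).
#'
#' @param variants Data frame with `position`, `ref`, `alt`.
#' @param haplogroup_path_snps Tibble of defining SNPs on the assigned
#'   haplogroup's path (see [haplogroup_snps()]).
#' @param annotation_db Tibble of known SNP keys (`position`, `ref`,
#'   `alt`); default [annotation_keys()].
#' @return Character vector of categories, one per variant row.
#' @export
categorize_variant <- function(variants, haplogroup_path_snps,
                               annotation_db = annotation_keys()) {
  key <- function(df) snp_label(df$position, df$ref, df$alt)
  v <- key(as_tibble(variants))
  on_path <- v %in% key(as_tibble(haplogroup_path_snps))
  known <- v %in% key(as_tibble(annotation_db))
  dplyr::case_when(on_path ~ "haplogroup_defining",
                   known ~ "private",
                   TRUE ~ "unique")
}

#' Classify a sample's true variants
#'
#' Assigns zygosity, haplogroup (from the sample's homoplasmies), category
#' and substitution class in one pass.
#'
#' @param true_variants Tibble from [concord()] (`tidy()` of the
#'   concordance object): `position`, `ref`, `alt`, `combined_freq`, plus
#'   any frequency/depth columns, which are carried through.
#' @param tree An `mt_haplotree` (default: packaged mini-tree).
#' @param annotation_db Known-SNP keys; default [annotation_keys()].
#' @param thresholds A [zygosity_thresholds()].
#' @return A tibble of class `mt_classified`: input columns plus
#'   `zygosity`, `category`, `mutation_class`, `low_frequency_flag`, with
#'   the assigned haplogroup in attribute `haplogroup` (also a column).
#' @export
classify_variants <- function(true_variants, tree = load_haplotree(),
                              annotation_db = annotation_keys(),
                              thresholds = zygosity_thresholds()) {
  v <- as_tibble(true_variants)
  v$zygosity <- classify_zygosity(v$combined_freq, thresholds)
  hom <- v[v$zygosity == "homoplasmy", c("position", "ref", "alt")]
  hg <- assign_haplogroup(hom, tree)
  path_snps <- haplogroup_snps(tree, hg$haplogroup)
  v$category <- categorize_variant(v, path_snps, annotation_db)
  v$mutation_class <- classify_substitution(v$ref, v$alt)
  v$low_frequency_flag <- v$combined_freq < thresholds$low_frequency_max
  v$haplogroup <- hg$haplogroup
  structure(v, class = c("mt_classified", class(v)),
            haplogroup = hg$haplogroup, haplogroup_score = hg$score)
}

#' Transition/transversion counts per group
#'
#' @param variants Data frame with `ref` and `alt` columns (heteroplasmy
#'   rows only; filter upstream) plus any grouping columns.
#' @param ... Grouping columns (tidy-select), e.g. `subject, tissue`.
#' @return Tibble with the grouping columns, `n_transition`,
#'   `n_transversion`, `n` and `prop_transversion`.
#' @export
tstv_summary <- function(variants, ...) {
  v <- as_tibble(variants)
  v$mutation_class <- classify_substitution(v$ref, v$alt)
  v |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n_transition = sum(.data$mutation_class == "transition"),
      n_transversion = sum(.data$mutation_class == "transversion"),
      n = dplyr::n(),
      prop_transversion = .data$n_transversion / .data$n,
      .groups = "drop"
    )
}
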