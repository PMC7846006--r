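# Cohort statistics on hot-spot carrier status.

#' Cross-product odds ratio of a 2x2 table
#'
#' For a table (a = group-1 carriers, b = group-1 non-carriers, c = group-2
#' carriers, d = group-2 non-carriers) the odds ratio is `(a d) / (b c)`.
#' Zero cross-cells (`b == 0` or `c == 0`) make the ratio undefined; no
#' continuity correction is applied — the result is `NA` with a classed
#' warning (`mtduplex_undefined_or`).
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorised).
#' @return Numeric vector of odds ratios, unrounded.
#' @examples
#' odds_ratio(82, 1, 50, 16)  # 26.24
#' @export
odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    abort("cell counts must be non-negative", class = "mtduplex_domain_error")
  }
  undefined <- b == 0 | c == 0
  out <- ifelse(undefined, NA_real_, (a * d) / (b * c))
  if (any(undefined)) {
    warn("odds ratio undefined for tables with zero cross-cells (no continuity correction applied)",
         class = "mtduplex_undefined_or")
  }
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: the p-value is the sum of hypergeometric
#' probabilities, over all tables with the observed margins, whose point
#' probability does not exceed that of the observed table. Probabilities
#' are computed in log space.
#'
#' @inheritParams odds_ratio
#' @return Two-sided p-value in (0, 1]. Degenerate margins give 1.
#' @examples
#' fisher_exact_two_sided(5, 0, 0, 5)  # 1/126
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    abort("cell counts must be non-negative", class = "mtduplex_domain_error")
  }
  mapply(function(a, b, c, d) {
    m <- a + b            # row 1 total
    n <- c + d            # row 2 total
    k <- a + c            # column 1 total
    if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
    support <- max(0L, k - n):min(k, m)
    logp <- dhyper(support, m, n, k, log = TRUE)
    log_obs <- dhyper(a, m, n, k, log = TRUE)
    # relative tolerance guards against ties lost to rounding
    p <- sum(exp(logp[logp <= log_obs + 1e-7]))
    min(1, p)
  }, a, b, c, d)
}

#' Pairwise group comparisons of hot-spot carrier status
#'
#' Builds the carrier/non-carrier 2x2 table for every SNP and group pair
#' and reports the cross-product odds ratio and the two-sided Fisher exact
#' p-value. Carrier status is presence/absence of the heteroplasmy, not
#' its frequency. No multiple-testing correction is applied by default;
#' `adjust = "BH"` adds a Benjamini-Hochberg adjusted column.
#'
#' @param cohort A `cohort_presence` object.
#' @param group_pairs List of length-2 character vectors of group labels,
#'   e.g. `list(c("Young-NL", "Old-NL"))`.
#' @param snps Optional tibble (`position`, `ref`, `alt`) restricting the
#'   SNPs compared; default: every SNP in the cohort.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble: `position`, `ref`, `alt`, `group1`, `group2`, cell
#'   counts `a`, `b`, `c`, `d`, `odds_ratio`, `p_two_sided` (and
#'   `p_adjusted` if requested).
#' @export
compare_groups <- function(cohort, group_pairs, snps = NULL,
                           adjust = c("none", "BH")) {
  stopifnot(inherits(cohort, "cohort_presence"))
  adjust <- match.arg(adjust)
  n_of <- setNames(cohort$groups$n, cohort$groups$group)
  all_groups <- unlist(group_pairs)
  if (any(!all_groups %in% names(n_of))) {
    abort(sprintf("unknown group(s): %s",
                  paste(setdiff(all_groups, names(n_of)), collapse = ", ")),
          class = "mtduplex_lookup_error")
  }
  snps <- as_tibble(snps %||%
                      dplyr::distinct(cohort$carriers, .data$position,
                                      .data$ref, .data$alt))
  carriers_of <- function(group, snp_row) {
    hit <- cohort$carriers[cohort$carriers$group == group &
                             cohort$carriers$position == snp_row$position &
                             cohort$carriers$ref == snp_row$ref &
                             cohort$carriers$alt == snp_row$alt, ]
    if (nrow(hit) == 0L) 0L else hit$carriers[1]
  }
  out <- purrr::map_dfr(seq_len(nrow(snps)), function(i) {
    snp <- snps[i, ]
    purrr::map_dfr(group_pairs, function(pair) {
      g1 <- pair[1]; g2 <- pair[2]
      a <- carriers_of(g1, snp); b <- n_of[[g1]] - a
      c <- carriers_of(g2, snp); d <- n_of[[g2]] - c
      or <- withCallingHandlers(
        odds_ratio(a, b, c, d),
        mtduplex_undefined_or = function(w) invokeRestart("muffleWarning")
      )
      tibble(position = snp$position, ref = snp$ref, alt = snp$alt,
             group1 = g1, group2 = g2, a = a, b = b, c = c, d = d,
             odds_ratio = or,
             p_two_sided = fisher_exact_two_sided(a, b, c, d))
    })
  })
  if (adjust == "BH") out$p_adjusted <- p.adjust(out$p_two_sided, "BH")
  out
}

#' Paired two-tailed t-test on per-subject tissue counts
#'
#' @param counts_x,counts_y Equal-length paired vectors of per-subject
#'   counts (n >= 2).
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p_value`.
#' @export
tissue_count_ttest <- function(counts_x, counts_y) {
  if (length(counts_x) != length(counts_y) || length(counts_x) < 2) {
    abort("need equal-length paired vectors with n >= 2",
          class = "mtduplex_undefined_test")
  }
  if (stats::sd(counts_x - counts_y) == 0) {
    abort("zero variance of paired differences: t-test undefined",
          class = "mtduplex_undefined_test")
  }
  fit <- t.test(counts_x, counts_y, paired = TRUE)
  tibble(estimate = unname(fit$estimate), statistic = unname(fit$statistic),
         df = unname(fit$parameter), p_value = fit$p.value)
}
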