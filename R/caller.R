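# Per-pool variant calling from strand pileups.
#
# The caller is intentionally minimal: each candidate (position, alt) is
# tested against a uniform sequencing-error model with a one-sided binomial
# tail, and the Phred-scaled quality is capped at 100. The acceptance
# surface downstream depends only on frequencies well above the error
# floor, not on caller subtleties.

#' One-sided binomial tail probability under the error model
#'
#' `P[X >= alt_count]` for `X ~ Binomial(depth, error_rate / 3)`: the
#' probability that sequencing error alone, spread uniformly over the three
#' non-reference bases, produces at least the observed count of one
#' specific alternate base.
#'
#' @param alt_count Observed alternate-base count(s).
#' @param depth Total depth(s).
#' @param error_rate Per-base substitution error rate (all three
#'   non-reference bases combined).
#' @param log_p Return the natural-log tail probability (used to compute
#'   Phred scores without underflow).
#' @return Numeric vector of tail probabilities in (0, 1] (or their logs).
#' @examples
#' binomial_tail(0, 1000, 0.001)    # 1
#' binomial_tail(5, 100, 0.003)
#' @export
binomial_tail <- function(alt_count, depth, error_rate, log_p = FALSE) {
  if (any(alt_count < 0) || any(alt_count > depth)) {
    abort("alt_count must lie in [0, depth]", class = "mtduplex_domain_error")
  }
  pbinom(alt_count - 1, depth, error_rate / 3, lower.tail = FALSE,
         log.p = log_p)
}

#' Caller thresholds
#'
#' @param min_maf Minimum allele frequency for a PASS call (default 0.01,
#'   the 1% detection floor). Candidates down to `min_maf / 2` are emitted
#'   with a `low_maf` filter flag so the concordance stage can explain
#'   rejections.
#' @param min_depth Minimum depth for PASS (default 1000).
#' @param min_qual Minimum Phred-scaled quality for PASS (default 30).
#' @param error_rate Assumed per-base error rate for the noise model
#'   (default 0.001).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(min_maf = 0.01, min_depth = 1000, min_qual = 30,
                          error_rate = 0.001) {
  assert_scalar_number(min_maf, "min_maf", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(min_depth, "min_depth", lower = 1)
  assert_scalar_number(min_qual, "min_qual", lower = 0, upper = 100)
  assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 1)
  structure(list(min_maf = min_maf, min_depth = min_depth,
                 min_qual = min_qual, error_rate = error_rate),
            class = "caller_config")
}

#' Call candidate variants in one pool
#'
#' Emits one record per (position, alternate base) with a positive count
#' and frequency of at least `min_maf / 2`. Quality is
#' `min(100, -10 log10 P[X >= alt_count])` under the binomial error model.
#' A call PASSes iff frequency `>= min_maf`, depth `>= min_depth` and
#' quality `>= min_qual`; sub-threshold records carry `low_maf`,
#' `low_depth` or `low_qual` filter flags instead of being dropped.
#'
#' @param pileup An `mt_pileup` tibble (one or both pools; each pool is
#'   called independently).
#' @param reference The [mt_reference()] the pileup was built against.
#' @param config A [caller_config()].
#' @return Tibble of class `mt_calls`: `pool`, `position`, `ref`, `alt`,
#'   `alt_count`, `depth`, `frequency`, `qual`, `filter`.
#' @export
call_pool_variants <- function(pileup, reference, config = caller_config()) {
  stopifnot(inherits(reference, "mt_reference"), inherits(config, "caller_config"))
  pileup <- as_tibble(pileup)
  if (any(pileup$position < 1L | pileup$position > reference$length)) {
    abort("pileup positions outside the reference",
          class = "mtduplex_domain_error")
  }
  counts <- as.matrix(pileup[, c("n_a", "n_c", "n_g", "n_t")])
  colnames(counts) <- DNA_BASES
  depth <- rowSums(counts)
  ref <- pileup$ref

  rows <- list()
  for (b in DNA_BASES) {
    cnt <- counts[, b]
    keep <- ref != b & cnt > 0L & depth > 0L & cnt / depth >= config$min_maf / 2
    if (!any(keep)) next
    rows[[b]] <- tibble(
      pool = pileup$pool[keep], position = pileup$position[keep],
      ref = ref[keep], alt = b,
      alt_count = as.integer(cnt[keep]), depth = as.integer(depth[keep])
    )
  }
  if (length(rows) == 0L) {
    return(empty_calls())
  }
  out <- dplyr::bind_rows(rows)
  out$frequency <- out$alt_count / out$depth
  log_tail <- binomial_tail(out$alt_count, out$depth, config$error_rate,
                            log_p = TRUE)
  out$qual <- pmin(100, -10 * log_tail / log(10))
  out$filter <- dplyr::case_when(
    out$frequency < config$min_maf ~ "low_maf",
    out$depth < config$min_depth ~ "low_depth",
    out$qual < config$min_qual ~ "low_qual",
    TRUE ~ "PASS"
  )
  out <- dplyr::arrange(out, .data$pool, .data$position, .data$alt)
  structure(out, class = c("mt_calls", class(out)))
}

empty_calls <- function() {
  out <- tibble(pool = character(), position = integer(), ref = character(),
                alt = character(), alt_count = integer(), depth = integer(),
                frequency = numeric(), qual = numeric(), filter = character())
  structure(out, class = c("mt_calls", class(out)))
}
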