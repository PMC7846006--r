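# Both-strand concordance: the core filtering rule.
#
# A variant seen independently in both pools (both strands) is a true
# variant; a variant seen in only one pool is treated as a DNA modification
# artifact. Combined frequency is the depth-weighted mean of the two pool
# frequencies (the variance-minimising combination); `combine = "min"` is
# available as a conservative alternative.

#' Intersect per-pool calls into true variants and artifacts
#'
#' @param calls_a,calls_b `mt_calls` tibbles for pools A and B (a single
#'   stacked tibble may be passed as `calls_a` with `calls_b = NULL`).
#' @param require_pass If `TRUE` (default) a true variant needs a PASS call
#'   in both pools. If `FALSE` (lenient), a PASS call in one pool plus any
#'   emitted sub-threshold record (frequency `>= min_maf/2`) in the other
#'   suffices.
#' @param combine `"weighted"` (depth-weighted mean, default) or `"min"`.
#' @return Object of class `mtduplex_concordance`: a list with
#'   `true_variants` (tibble `position`, `ref`, `alt`, `freq_a`, `freq_b`,
#'   `depth_a`, `depth_b`, `combined_freq`) and `artifacts` (tibble
#'   `position`, `ref`, `alt`, `pool_seen`, `frequency`, `reason`). Every
#'   distinct (position, ref, alt) key across both pools lands in exactly
#'   one of the two tables.
#' @examples
#' a <- tibble::tibble(pool = "A", position = 1120L, ref = "C", alt = "T",
#'                     alt_count = 2700L, depth = 30000L, frequency = 0.090,
#'                     qual = 100, filter = "PASS")
#' b <- dplyr::mutate(a, pool = "B", frequency = 0.088)
#' concord(a, b)
#' @export
concord <- function(calls_a, calls_b = NULL, require_pass = TRUE,
                    combine = c("weighted", "min")) {
  combine <- match.arg(combine)
  calls <- dplyr::bind_rows(as_tibble(calls_a), as_tibble(calls_b))
  if (nrow(calls) == 0L) {
    return(new_concordance(empty_true_variants(), empty_artifacts()))
  }
  if (!all(calls$pool %in% c("A", "B"))) {
    abort("calls must come from pools A and B", class = "mtduplex_domain_error")
  }
  ref_check <- dplyr::distinct(calls, .data$position, .data$ref)
  if (anyDuplicated(ref_check$position)) {
    abort("conflicting reference alleles at the same position across pools",
          class = "mtduplex_data_error")
  }

  per_pool <- function(p) {
    df <- calls[calls$pool == p, ]
    dplyr::select(df, "position", "ref", "alt",
                  frequency = "frequency", depth = "depth", filter = "filter")
  }
  a <- per_pool("A"); b <- per_pool("B")
  merged <- dplyr::full_join(a, b, by = c("position", "ref", "alt"),
                             suffix = c("_a", "_b"))

  seen_a <- !is.na(merged$frequency_a)
  seen_b <- !is.na(merged$frequency_b)
  if (require_pass) {
    ok <- seen_a & seen_b &
      merged$filter_a == "PASS" & merged$filter_b == "PASS"
    reason_both <- "not PASS in both pools"
  } else {
    ok <- seen_a & seen_b &
      (merged$filter_a == "PASS" | merged$filter_b == "PASS")
    reason_both <- "no PASS call in either pool"
  }
  ok[is.na(ok)] <- FALSE

  tv <- merged[ok, ]
  combined <- if (combine == "weighted") {
    (tv$frequency_a * tv$depth_a + tv$frequency_b * tv$depth_b) /
      (tv$depth_a + tv$depth_b)
  } else {
    pmin(tv$frequency_a, tv$frequency_b)
  }
  true_variants <- tibble(
    position = tv$position, ref = tv$ref, alt = tv$alt,
    freq_a = tv$frequency_a, freq_b = tv$frequency_b,
    depth_a = tv$depth_a, depth_b = tv$depth_b, combined_freq = combined
  )
  true_variants <- dplyr::arrange(true_variants, .data$position, .data$alt)

  rej <- merged[!ok, ]
  if (nrow(rej) > 0L) {
    single_a <- !is.na(rej$frequency_a) & is.na(rej$frequency_b)
    single_b <- is.na(rej$frequency_a) & !is.na(rej$frequency_b)
    pool_seen <- ifelse(single_a, "A",
                 ifelse(single_b, "B",
                        # seen in both but not qualifying: report the better pool
                        ifelse(rej$frequency_a >= rej$frequency_b, "A", "B")))
    frequency <- ifelse(pool_seen == "A", rej$frequency_a, rej$frequency_b)
    reason <- ifelse(single_a | single_b, "present in one pool only",
                     reason_both)
    artifacts <- tibble(position = rej$position, ref = rej$ref, alt = rej$alt,
                        pool_seen = pool_seen, frequency = frequency,
                        reason = reason)
    artifacts <- dplyr::arrange(artifacts, .data$position, .data$alt)
  } else {
    artifacts <- empty_artifacts()
  }
  new_concordance(true_variants, artifacts)
}

empty_true_variants <- function() {
  tibble(position = integer(), ref = character(), alt = character(),
         freq_a = numeric(), freq_b = numeric(), depth_a = integer(),
         depth_b = integer(), combined_freq = numeric())
}

empty_artifacts <- function() {
  tibble(position = integer(), ref = character(), alt = character(),
         pool_seen = character(), frequency = numeric(), reason = character())
}

new_concordance <- function(true_variants, artifacts) {
  structure(list(true_variants = true_variants, artifacts = artifacts),
            class = "mtduplex_concordance")
}

#' @export
print.mtduplex_concordance <- function(x, ...) {
  cat(sprintf("<mtduplex_concordance> %d true variant(s), %d artifact(s)\n",
              nrow(x$true_variants), nrow(x$artifacts)))
  invisible(x)
}

#' Tidy a concordance result
#'
#' @param x An `mtduplex_concordance`.
#' @param which `"true_variants"` (default) or `"artifacts"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy mtduplex_concordance
#' @export
tidy.mtduplex_concordance <- function(x, which = c("true_variants", "artifacts"),
                                      ...) {
  which <- match.arg(which)
  x[[which]]
}

#' One-row summary of a concordance result
#'
#' @param x An `mtduplex_concordance`.
#' @param ... Unused.
#' @method glance mtduplex_concordance
#' @export
glance.mtduplex_concordance <- function(x, ...) {
  tibble(
    n_true = nrow(x$true_variants),
    n_artifacts = nrow(x$artifacts),
    n_keys = nrow(x$true_variants) + nrow(x$artifacts),
    median_true_freq = stats::median(x$true_variants$combined_freq)
  )
}

#' Pool-frequency concordance plot
#'
#' Scatter of pool-A versus pool-B frequency for true variants, with
#' single-pool artifacts shown along the axes.
#'
#' @param object An `mtduplex_concordance`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mtduplex_concordance
#' @export
autoplot.mtduplex_concordance <- function(object, ...) {
  tv <- dplyr::mutate(object$true_variants, status = "true variant")
  ar <- object$artifacts
  ar_pts <- tibble(
    freq_a = ifelse(ar$pool_seen == "A", ar$frequency, 0),
    freq_b = ifelse(ar$pool_seen == "B", ar$frequency, 0),
    status = "artifact"
  )
  df <- dplyr::bind_rows(tv[, c("freq_a", "freq_b")] |>
                           dplyr::mutate(status = "true variant"), ar_pts)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_a, .data$freq_b,
                                   colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_sqrt() + ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "pool A frequency", y = "pool B frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
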