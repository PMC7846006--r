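# Shared builders for tests: tiny references, hand-made call tables, and
# brute-force oracles kept deliberately independent of the implementation.

toy_reference <- function(n = 100, seed = 7) {
  withr::with_seed(seed, {
    mt_reference(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                       collapse = ""), name = "toy")
  })
}

make_calls <- function(pool, position, ref, alt, frequency, depth = 30000L,
                       filter = "PASS", qual = 100) {
  tibble::tibble(
    pool = pool, position = as.integer(position), ref = ref, alt = alt,
    alt_count = as.integer(round(frequency * depth)), depth = as.integer(depth),
    frequency = frequency, qual = qual, filter = filter
  )
}

# manual panel construction (bypasses design_panel) for oracle checks
manual_panel <- function(amplicons, reference) {
  structure(amplicons, class = c("mt_panel", class(amplicons)),
            reference = reference)
}

# brute-force per-position interval-stabbing coverage count
brute_force_coverage <- function(amplicons, L) {
  sapply(seq_len(L), function(p) {
    sum(mapply(function(s, e) {
      if (e >= s) p >= s && p <= e else p >= s || p <= e
    }, amplicons$start, amplicons$end))
  })
}

# direct pmf summation for the binomial upper tail, written without pbinom;
# summed in log space so deep tails stay representable
binom_tail_oracle <- function(alt, depth, p, log = FALSE) {
  if (alt == 0) return(if (log) 0 else 1)
  k <- alt:depth
  terms <- lchoose(depth, k) + k * base::log(p) + (depth - k) * log1p(-p)
  m <- max(terms)
  out <- m + base::log(sum(exp(terms - m)))
  if (log) out else exp(out)
}

# full hypergeometric enumeration for the two-sided Fisher p-value,
# computed from factorials only
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  log_obs <- lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k)
  sum(exp(logp[logp <= log_obs + 1e-7]))
}

default_study_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) {
      ref <- load_reference(mtdna_reference_path())
      panel <<- design_panel(ref)
    }
    panel
  }
})
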