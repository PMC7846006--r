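# Readers/writers for pileups and VCF 4.2 output.

#' Write / read strand pileups as TSV
#'
#' @param pileup An `mt_pileup` tibble.
#' @param path File path.
#' @return `path` invisibly; the reader returns the pileup tibble.
#' @export
write_pileup_tsv <- function(pileup, path) {
  readr::write_tsv(as_tibble(pileup), path)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, col_types = "ciciiii")
  structure(as_tibble(df), class = c("mt_pileup", class(df)))
}

vcf_header <- function(reference, info_lines) {
  c("##fileformat=VCFv4.2",
    "##source=mtduplex",
    sprintf("##contig=<ID=%s,length=%d>", reference$name, reference$length),
    info_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
}

#' Write classified (or true) variants as VCF 4.2
#'
#' INFO carries the combined and per-pool frequencies and depths (`AF`,
#' `AF_A`, `AF_B`, `DP_A`, `DP_B`) and, when present, the classification
#' fields `ZYG`, `CAT`, `CLASS` and `LOWFREQ`. Input must be sorted by
#' position.
#'
#' @param variants Tibble from [concord()]/[classify_variants()].
#' @param reference The [mt_reference()] naming the contig.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, reference, path) {
  v <- as_tibble(variants)
  if (is.unsorted(v$position)) {
    abort("variants must be sorted by position",
          class = "mtduplex_validation_error")
  }
  info_defs <- c(
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Combined allele frequency">',
    '##INFO=<ID=AF_A,Number=1,Type=Float,Description="Pool A allele frequency">',
    '##INFO=<ID=AF_B,Number=1,Type=Float,Description="Pool B allele frequency">',
    '##INFO=<ID=DP_A,Number=1,Type=Integer,Description="Pool A depth">',
    '##INFO=<ID=DP_B,Number=1,Type=Integer,Description="Pool B depth">',
    '##INFO=<ID=ZYG,Number=1,Type=String,Description="homoplasmy or heteroplasmy">',
    '##INFO=<ID=CAT,Number=1,Type=String,Description="haplogroup_defining, private or unique">',
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="transition or transversion">',
    '##INFO=<ID=LOWFREQ,Number=0,Type=Flag,Description="Combined frequency below the low-frequency threshold">'
  )
  fmt_num <- function(x) formatC(x, digits = 10, format = "g")
  has_pools <- "freq_a" %in% names(v)
  has_class <- "zygosity" %in% names(v)
  info <- vapply(seq_len(nrow(v)), function(i) {
    fields <- c(sprintf("AF=%s", fmt_num(v$combined_freq[i])))
    if (has_pools) {
      fields <- c(fields,
                  sprintf("AF_A=%s", fmt_num(v$freq_a[i])),
                  sprintf("AF_B=%s", fmt_num(v$freq_b[i])),
                  sprintf("DP_A=%d", v$depth_a[i]),
                  sprintf("DP_B=%d", v$depth_b[i]))
    }
    if (has_class) {
      fields <- c(fields,
                  sprintf("ZYG=%s", v$zygosity[i]),
                  sprintf("CAT=%s", v$category[i]),
                  sprintf("CLASS=%s", v$mutation_class[i]),
                  if (isTRUE(v$low_frequency_flag[i])) "LOWFREQ")
    }
    paste(fields, collapse = ";")
  }, character(1))
  body <- if (nrow(v) == 0L) character() else
    paste(reference$name, v$position, ".", v$ref, v$alt, "100", "PASS", info,
          sep = "\t")
  writeLines(c(vcf_header(reference, info_defs), body), path)
  invisible(path)
}

#' Read back a variants VCF written by [write_variants_vcf()]
#'
#' @param path VCF path.
#' @return Tibble with the positions, alleles and INFO fields restored.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(tibble(position = integer(), ref = character(), alt = character(),
                  combined_freq = numeric()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  info <- vapply(parts, `[[`, "", 8L)
  out <- tibble(
    position = as.integer(vapply(parts, `[[`, "", 2L)),
    ref = vapply(parts, `[[`, "", 4L),
    alt = vapply(parts, `[[`, "", 5L),
    combined_freq = as.numeric(info_field(info, "AF")),
    freq_a = as.numeric(info_field(info, "AF_A")),
    freq_b = as.numeric(info_field(info, "AF_B")),
    depth_a = as.integer(info_field(info, "DP_A")),
    depth_b = as.integer(info_field(info, "DP_B")),
    zygosity = info_field(info, "ZYG"),
    category = info_field(info, "CAT"),
    mutation_class = info_field(info, "CLASS"),
    low_frequency_flag = grepl("(^|;)LOWFREQ($|;)", info)
  )
  keep <- !vapply(out, function(col) all(is.na(col)), logical(1))
  keep["low_frequency_flag"] <- !all(is.na(out$zygosity))
  out[, keep, drop = FALSE]
}

#' Write per-pool calls as VCF 4.2
#'
#' One record per call with INFO `DP`, `AF`, `POOL` and the caller's
#' FILTER value.
#'
#' @param calls An `mt_calls` tibble.
#' @param reference The [mt_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, reference, path) {
  calls <- dplyr::arrange(as_tibble(calls), .data$position, .data$pool,
                          .data$alt)
  info_defs <- c(
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Pool depth">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Pool allele frequency">',
    '##INFO=<ID=POOL,Number=1,Type=String,Description="Primer pool (strand)">',
    '##FILTER=<ID=low_maf,Description="Frequency below min_maf">',
    '##FILTER=<ID=low_depth,Description="Depth below min_depth">',
    '##FILTER=<ID=low_qual,Description="Quality below min_qual">'
  )
  body <- if (nrow(calls) == 0L) character() else
    paste(reference$name, calls$position, ".", calls$ref, calls$alt,
          formatC(calls$qual, digits = 6, format = "g"), calls$filter,
          sprintf("DP=%d;AF=%s;POOL=%s", calls$depth,
                  formatC(calls$frequency, digits = 10, format = "g"),
                  calls$pool),
          sep = "\t")
  writeLines(c(vcf_header(reference, info_defs), body), path)
  invisible(path)
}
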