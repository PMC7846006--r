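# Circular mitochondrial reference and the two-pool amplicon panel.

#' Construct a circular mitochondrial reference
#'
#' The reference is the coordinate frame for every other record in the
#' package: positions are 1-based and inclusive, following the rCRS
#' convention in which variants are written `m.<pos><ref>><alt>`, and the
#' molecule is circular so intervals may wrap through the origin.
#'
#' @param sequence Single character string of A/C/G/T bases.
#' @param name Sequence name used in output files (default `"MT"`).
#' @return An object of class `mt_reference` with fields `name`, `sequence`,
#'   `length` and `circular` (always `TRUE`).
#' @examples
#' ref <- mt_reference("ACGTACGT", name = "toy")
#' ref$length
#' @export
mt_reference <- function(sequence, name = "MT") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty string",
          class = "mtduplex_format_error")
  }
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- !bases %in% DNA_BASES
  if (any(bad)) {
    abort(sprintf("reference contains non-ACGT characters: %s",
                  paste(unique(bases[bad]), collapse = ", ")),
          class = "mtduplex_format_error")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         circular = TRUE),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf("<mt_reference> %s: %d bp, circular\n", x$name, x$length))
  invisible(x)
}

#' Load a mitochondrial reference from a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return An [mt_reference()] object.
#' @examples
#' ref <- load_reference(mtdna_reference_path())
#' ref$length  # 16569
#' @export
load_reference <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    abort(sprintf("expected exactly one FASTA record, found %d", length(set)),
          class = "mtduplex_format_error")
  }
  if (Biostrings::width(set)[1] == 0L) {
    abort("FASTA record has an empty sequence", class = "mtduplex_format_error")
  }
  name <- sub("\\s.*$", "", names(set)[1])
  seq <- as.character(set[[1]])
  if (grepl("[^ACGTacgt]", seq)) {
    abort("reference contains ambiguity codes or non-ACGT characters",
          class = "mtduplex_format_error")
  }
  mt_reference(seq, name = name)
}

#' Path to the packaged synthetic rCRS-like reference
#'
#' The packaged reference is a synthetic 16,569-bp stand-in for the human
#' mitochondrial genome: it has the rCRS length and carries the documented
#' reference base at every position used by the packaged study tables, with
#' pseudo-random bases elsewhere. A real rCRS FASTA can be supplied to
#' [load_reference()] instead.
#'
#' @return File path to the FASTA shipped with the package.
#' @export
mtdna_reference_path <- function() {
  system.file("extdata", "mt_reference_synthetic.fasta", package = "mtduplex",
              mustWork = TRUE)
}

#' Reference bases at given positions
#'
#' @param reference An [mt_reference()].
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of bases.
#' @export
ref_base <- function(reference, positions) {
  stopifnot(inherits(reference, "mt_reference"))
  if (any(positions < 1L | positions > reference$length)) {
    abort("positions outside the reference", class = "mtduplex_domain_error")
  }
  strsplit(reference$sequence, "", fixed = TRUE)[[1]][positions]
}

# Panel design ------------------------------------------------------------

#' Design a two-pool overlapping amplicon panel
#'
#' Tiles the circular reference with `n_pairs` amplicons per pool so that
#' consecutive amplicons overlap by at least `min_overlap` bases and every
#' position is covered by each pool. The two pools (A and B) target the two
#' strands; pool B's tiling is phase-shifted by half a tile so that pool
#' boundaries do not coincide. Amplicons whose `end` is less than their
#' `start` wrap through the origin.
#'
#' @param reference An [mt_reference()].
#' @param n_pairs Number of primer pairs (amplicons) per pool; default 171,
#'   the panel size used for whole-mtDNA interrogation.
#' @param min_overlap Minimum overlap in bases between consecutive amplicons
#'   within a pool (default 20).
#' @return A tibble of class `mt_panel` with columns `amplicon_id`, `start`,
#'   `end`, `pool` (1-based inclusive coordinates) and the reference stored
#'   in attribute `reference`.
#' @examples
#' ref <- load_reference(mtdna_reference_path())
#' panel <- design_panel(ref)
#' nrow(panel)  # 2 pools x 171 amplicons
#' @export
design_panel <- function(reference, n_pairs = 171, min_overlap = 20) {
  stopifnot(inherits(reference, "mt_reference"))
  assert_scalar_number(n_pairs, "n_pairs", lower = 1)
  assert_scalar_number(min_overlap, "min_overlap", lower = 0)
  n_pairs <- as.integer(n_pairs)
  min_overlap <- as.integer(min_overlap)
  L <- reference$length
  step <- L / n_pairs
  amp_len <- as.integer(ceiling(step)) + min_overlap
  if (amp_len > L) {
    abort(sprintf(
      "infeasible tiling: amplicon length %d exceeds reference length %d",
      amp_len, L), class = "mtduplex_config_error")
  }

  tile <- function(pool, offset) {
    start <- (as.integer(floor((seq_len(n_pairs) - 1L) * step)) + offset) %% L + 1L
    end <- (start + amp_len - 2L) %% L + 1L
    tibble(
      amplicon_id = sprintf("%s%03d", pool, seq_len(n_pairs)),
      start = start, end = end, pool = pool
    )
  }

  out <- dplyr::bind_rows(
    tile("A", 0L),
    tile("B", as.integer(floor(step / 2)))
  )
  # the tiling construction guarantees full per-pool coverage
  structure(out, class = c("mt_panel", class(out)), reference = reference,
            coverage_complete = TRUE)
}

#' Positions covered by an amplicon on a circular reference
#'
#' @param start,end 1-based inclusive endpoints; `end < start` wraps through
#'   the origin.
#' @param L Reference length.
#' @return Integer vector of covered positions.
#' @export
amplicon_positions <- function(start, end, L) {
  if (end >= start) seq.int(start, end) else c(seq.int(start, L), seq.int(1L, end))
}

#' Per-position, per-pool coverage of a panel
#'
#' @param panel An `mt_panel` from [design_panel()].
#' @return Tibble with columns `pool`, `position`, `coverage` (one row per
#'   pool and reference position).
#' @export
coverage_profile <- function(panel) {
  stopifnot(inherits(panel, "mt_panel"))
  L <- attr(panel, "reference")$length
  per_pool <- function(df) {
    # difference-array accumulation; wrap handled by splitting the interval
    d <- integer(L + 1L)
    for (i in seq_len(nrow(df))) {
      s <- df$start[i]; e <- df$end[i]
      if (e >= s) {
        d[s] <- d[s] + 1L
        d[e + 1L] <- d[e + 1L] - 1L
      } else {
        d[s] <- d[s] + 1L          # s..L
        d[1L] <- d[1L] + 1L        # 1..e
        d[e + 1L] <- d[e + 1L] - 1L
      }
    }
    cumsum(d[seq_len(L)])
  }
  panel <- as_tibble(panel)
  dplyr::bind_rows(lapply(split(panel, panel$pool), function(df) {
    tibble(pool = df$pool[1], position = seq_len(L), coverage = per_pool(df))
  }))
}

#' Write / read a panel as BED-like TSV
#'
#' Coordinates are written 1-based inclusive (documented in the header
#' comment), with columns `amplicon_id`, `start`, `end`, `pool`.
#'
#' @param panel An `mt_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "mt_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# amplicon panel; coordinates are 1-based inclusive; end < start wraps the origin", con)
  writeLines(paste(c("amplicon_id", "start", "end", "pool"), collapse = "\t"), con)
  apply(as_tibble(panel), 1L, function(r) {
    writeLines(paste(r[["amplicon_id"]], r[["start"]], r[["end"]], r[["pool"]],
                     sep = "\t"), con)
  })
  invisible(path)
}

#' @rdname write_panel_tsv
#' @param reference The [mt_reference()] the panel was designed against.
#' @export
read_panel_tsv <- function(path, reference) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = "ciic")
  structure(as_tibble(df), class = c("mt_panel", class(df)),
            reference = reference)
}
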