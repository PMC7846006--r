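# Simplified haplogroup tree and assignment scoring.
#
# The packaged mini-tree encodes root-to-leaf paths whose defining SNPs are
# the germline homoplasmy sets of the three study subjects (haplogroups
# I1a1b, H7b and U2e2a1) plus a few decoy branches. It is not a full
# phylogeny: assignment against it is a deliberately simple symmetric match
# score, not a reimplementation of full tree-walking classifiers.

#' Load a haplogroup mini-tree
#'
#' @param path TSV with columns `label`, `parent` (NA for the root) and
#'   `snps` (comma-separated `<pos><ref>><alt>` tokens, NA for none).
#'   Defaults to the packaged mini-tree.
#' @return A tibble of class `mt_haplotree` with columns `label`, `parent`
#'   and a list-column `snps` of tibbles (`position`, `ref`, `alt`).
#' @examples
#' tree <- load_haplotree()
#' tree$label
#' @export
load_haplotree <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mini_haplotree.tsv",
                                package = "mtduplex", mustWork = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE, col_types = "ccc")
  df$snps <- lapply(df$snps, function(s) {
    if (is.na(s) || s == "") return(tibble(position = integer(),
                                           ref = character(),
                                           alt = character()))
    parse_snp_tokens(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  roots <- df$label[is.na(df$parent)]
  if (length(roots) != 1L) {
    abort("haplotree must have exactly one root", class = "mtduplex_config_error")
  }
  known <- df$parent %in% c(NA, df$label)
  if (!all(known)) {
    abort("haplotree has parents that are not nodes",
          class = "mtduplex_config_error")
  }
  out <- structure(as_tibble(df), class = c("mt_haplotree", class(df)))
  # acyclicity: walking to the root must terminate for every node
  for (lab in out$label) haplogroup_path(out, lab)
  out
}

parse_snp_tokens <- function(tokens) {
  m <- regmatches(tokens, regexec("^(\\d+)([ACGT])>([ACGT])$", tokens))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    abort(sprintf("malformed SNP token: %s", paste(tokens[bad], collapse = ", ")),
          class = "mtduplex_format_error")
  }
  tibble(
    position = as.integer(vapply(m, `[[`, "", 2L)),
    ref = vapply(m, `[[`, "", 3L),
    alt = vapply(m, `[[`, "", 4L)
  )
}

#' Root-to-node path labels
#'
#' @param tree An `mt_haplotree`.
#' @param label Haplogroup label present in the tree.
#' @return Character vector of labels from the root down to `label`.
#' @export
haplogroup_path <- function(tree, label) {
  if (!label %in% tree$label) {
    abort(sprintf("unknown haplogroup '%s'", label),
          class = "mtduplex_lookup_error")
  }
  parent <- setNames(tree$parent, tree$label)
  path <- character()
  cur <- label
  for (i in seq_len(nrow(tree) + 1L)) {
    path <- c(cur, path)
    cur <- parent[[cur]]
    if (is.na(cur)) return(path)
  }
  abort("haplotree contains a cycle", class = "mtduplex_config_error")
}

#' Defining SNPs accumulated along a root-to-node path
#'
#' @inheritParams haplogroup_path
#' @return Tibble (`position`, `ref`, `alt`), one row per distinct SNP on
#'   the path.
#' @export
haplogroup_snps <- function(tree, label) {
  labs <- haplogroup_path(tree, label)
  snps <- dplyr::bind_rows(tree$snps[match(labs, tree$label)])
  dplyr::distinct(snps, .data$position, .data$ref, .data$alt)
}

#' Assign a haplogroup from a homoplasmy SNP set
#'
#' Scores every tree node with a symmetric (Kulczynski-style) match
#' fraction, `(matched/expected + matched/observed) / 2`, where `expected`
#' is the number of defining SNPs on the root-to-node path and `observed`
#' the size of the supplied homoplasmy set; the best-scoring node wins,
#' with ties broken toward the shallowest node and then lexicographically.
#' An empty homoplasmy set returns the root (the reference haplogroup).
#'
#' @param homoplasmies Data frame with columns `position`, `ref`, `alt`:
#'   the sample's homoplasmic (near-fixed) variants.
#' @param tree An `mt_haplotree` (default: the packaged mini-tree).
#' @return One-row tibble: `haplogroup`, `score`, `n_matched`, `n_expected`,
#'   `n_observed`.
#' @examples
#' tree <- load_haplotree()
#' assign_haplogroup(haplogroup_snps(tree, "H7b"), tree)
#' @export
assign_haplogroup <- function(homoplasmies, tree = load_haplotree()) {
  stopifnot(inherits(tree, "mt_haplotree"))
  if (nrow(tree) == 0L) {
    abort("empty haplotree", class = "mtduplex_config_error")
  }
  root <- tree$label[is.na(tree$parent)]
  obs <- dplyr::distinct(as_tibble(homoplasmies), .data$position, .data$ref,
                         .data$alt)
  obs_keys <- snp_label(obs$position, obs$ref, obs$alt)
  if (length(obs_keys) == 0L) {
    return(tibble(haplogroup = root, score = 1, n_matched = 0L,
                  n_expected = 0L, n_observed = 0L))
  }
  scored <- purrr::map_dfr(tree$label, function(lab) {
    path <- haplogroup_snps(tree, lab)
    exp_keys <- snp_label(path$position, path$ref, path$alt)
    m <- sum(exp_keys %in% obs_keys)
    score <- if (length(exp_keys) == 0L) 0 else
      (m / length(exp_keys) + m / length(obs_keys)) / 2
    tibble(haplogroup = lab, score = score, n_matched = m,
           n_expected = length(exp_keys), n_observed = length(obs_keys),
           depth = length(haplogroup_path(tree, lab)))
  })
  best <- scored[order(-scored$score, scored$depth, scored$haplogroup), ]
  dplyr::select(best[1, ], -"depth")
}
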