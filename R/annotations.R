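# GO annotations and the labeled cross-species pair datasets.

#' Experimental GO evidence codes
#'
#' The evidence codes treated as experimental when deciding functional
#' relatedness: EXP, IDA, IPI, IMP, IGI, IEP.
#'
#' @return Character vector of evidence codes.
#' @export
evidence_experimental <- function() c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Construct an annotation set
#'
#' An annotation set is a tibble of protein/GO-term records with columns
#' `protein`, `term`, `evidence` and `aspect` (`P` = biological process,
#' `F` = molecular function, `C` = cellular component). Duplicate records
#' are stored once.
#'
#' @param records Data frame with those four columns.
#' @return A tibble of class `annotation_set`.
#' @export
annotation_set <- function(records) {
  records <- as_tibble(records)
  need <- c("protein", "term", "evidence", "aspect")
  if (!all(need %in% names(records))) {
    if (ncol(records) >= 4L) names(records)[1:4] <- need
    else abort("annotation records need columns protein, term, evidence, aspect")
  }
  records <- distinct(records[, need])
  class(records) <- c("annotation_set", class(records))
  records
}

#' Read GO annotations from a GAF 2.x file
#'
#' Reads the standard Gene Association File layout: `!`-prefixed comment
#' lines are skipped, the DB object symbol (column 3) becomes the protein ID,
#' the GO ID (column 5), evidence code (column 7) and aspect (column 9) are
#' kept, and records whose qualifier (column 4) contains `NOT` are excluded.
#'
#' @param path Path to the GAF file.
#' @return An [annotation_set()].
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GAF file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warn(sprintf("GAF file '%s' has no records", path))
    return(annotation_set(tibble(protein = character(), term = character(),
                                 evidence = character(), aspect = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 9L)
  if (length(short) > 0L) {
    abort(sprintf("GAF '%s': line %d has fewer than 9 columns", path, lineno[short[1L]]))
  }
  go_id <- vapply(parts, `[[`, "", 5L)
  bad <- which(!startsWith(go_id, "GO:"))
  if (length(bad) > 0L) {
    abort(sprintf("GAF '%s': line %d has malformed GO ID '%s'",
                  path, lineno[bad[1L]], go_id[bad[1L]]))
  }
  qualifier <- vapply(parts, `[[`, "", 4L)
  not_rec <- grepl("(^|\\|)NOT(\\||$)", qualifier)
  tib <- tibble(
    protein  = vapply(parts, `[[`, "", 3L),
    term     = go_id,
    evidence = vapply(parts, `[[`, "", 7L),
    aspect   = vapply(parts, `[[`, "", 9L)
  )
  annotation_set(tib[!not_rec, ])
}

#' Read annotations from a simple 4-column TSV
#'
#' Column order `protein`, `term`, `evidence`, `aspect`; `#` comments
#' skipped; no header.
#'
#' @param path Path to the TSV.
#' @return An [annotation_set()].
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  df <- readr::read_tsv(path, col_names = c("protein", "term", "evidence", "aspect"),
                        comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  annotation_set(df)
}

#' Filter annotations by evidence code and aspect
#'
#' Keeps records whose evidence code is in `evidence` and whose aspect
#' equals `aspect`. The defaults select experimentally supported
#' biological-process annotations, the view under which functional
#' relatedness is defined.
#'
#' @param annotations An [annotation_set()].
#' @param evidence Evidence codes to keep.
#' @param aspect Single aspect to keep (`"P"`, `"F"` or `"C"`), or `NULL`
#'   to keep all aspects.
#' @return The filtered `annotation_set`.
#' @export
filter_annotations <- function(annotations, evidence = evidence_experimental(),
                               aspect = "P") {
  out <- dplyr::filter(annotations, .data$evidence %in% !!evidence)
  if (!is.null(aspect)) out <- dplyr::filter(out, .data$aspect %in% !!aspect)
  if (nrow(out) == 0L) inform("filter_annotations: no records left after filtering")
  annotation_set(out)
}

#' Keep only rare GO terms
#'
#' Removes every record whose GO term annotates more than `rarity` distinct
#' proteins within `annotations` (both species combined). The bound is
#' inclusive: a term annotating exactly `rarity` proteins is kept.
#' `rarity = "ALL"` (or `Inf`) is the identity.
#'
#' @param annotations An [annotation_set()].
#' @param rarity Positive integer threshold, or `"ALL"`/`Inf` for no filter.
#' @return The filtered `annotation_set`.
#' @export
apply_rarity <- function(annotations, rarity) {
  if (identical(rarity, "ALL") || is.infinite(rarity)) return(annotations)
  rarity <- as.numeric(rarity)
  if (is.na(rarity) || rarity < 1) abort("`rarity` must be >= 1, 'ALL' or Inf")
  freq <- annotations |>
    distinct(.data$term, .data$protein) |>
    count(.data$term, name = "n_proteins")
  keep_terms <- freq$term[freq$n_proteins <= rarity]
  annotation_set(dplyr::filter(annotations, .data$term %in% keep_terms))
}

#' Restrict annotations to proteins present in the networks
#'
#' @param annotations An [annotation_set()].
#' @param net1,net2 The two [ppi_network()] objects.
#' @return The restricted `annotation_set`.
#' @export
restrict_to_networks <- function(annotations, net1, net2) {
  annotation_set(dplyr::filter(annotations,
                               .data$protein %in% c(net1$nodes, net2$nodes)))
}

terms_by_protein <- function(annotations, proteins) {
  annotations |>
    dplyr::filter(.data$protein %in% proteins) |>
    distinct(.data$protein, .data$term)
}

#' Label cross-species pairs as functionally related or unrelated
#'
#' A pair (u in network 1, v in network 2) is *functionally related*
#' (label 1) when u and v share at least `k` GO terms in the qualifying
#' `filtered` view (experimental evidence, chosen aspect, rarity-filtered),
#' and *functionally unrelated* (label 0) when they share no GO terms of any
#' kind in the `unfiltered` set. Pairs sharing only non-qualifying terms get
#' neither label and are omitted. Only proteins that are network nodes are
#' considered.
#'
#' @param filtered Qualifying [annotation_set()] (see [filter_annotations()],
#'   [apply_rarity()]).
#' @param unfiltered The full `annotation_set`, all aspects and evidence.
#' @param net1,net2 The two [ppi_network()]s.
#' @param k Minimum number of shared qualifying terms for a positive.
#' @return A tibble of class `labeled_pairs` with columns `node1`, `node2`,
#'   `label` (1 related / 0 unrelated) and a `config` attribute.
#' @export
label_pairs <- function(filtered, unfiltered, net1, net2, k = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("`k` must be an integer >= 1")
  t1 <- terms_by_protein(filtered, net1$nodes)
  t2 <- terms_by_protein(filtered, net2$nodes)
  positives <- inner_join(t1, t2, by = "term", relationship = "many-to-many") |>
    count(node1 = .data$protein.x, node2 = .data$protein.y, name = "shared") |>
    dplyr::filter(.data$shared >= k) |>
    select("node1", "node2")

  u1 <- terms_by_protein(unfiltered, net1$nodes)
  u2 <- terms_by_protein(unfiltered, net2$nodes)
  sharing_any <- inner_join(u1, u2, by = "term", relationship = "many-to-many") |>
    distinct(node1 = .data$protein.x, node2 = .data$protein.y)
  negatives <- tidyr::expand_grid(node1 = net1$nodes, node2 = net2$nodes) |>
    anti_join(sharing_any, by = c("node1", "node2"))

  out <- bind_rows(
    mutate(positives, label = 1L),
    mutate(negatives, label = 0L)
  )
  if (sum(out$label) == 0L) warn("label_pairs: no functionally related pairs found")
  attr(out, "config") <- list(k = k)
  class(out) <- c("labeled_pairs", class(out))
  out
}

#' Build a ground truth-rarity dataset in one call
#'
#' Convenience wrapper: evidence/aspect filter, restriction to network
#' proteins, rarity filter, then pair labeling. The returned object also
#' carries the "relevant" annotation view (the qualifying protein-term
#' records), which downstream functional prediction uses.
#'
#' @param annotations Full [annotation_set()].
#' @param net1,net2 The two [ppi_network()]s.
#' @param k Shared-term threshold (1, 2, 3, ...).
#' @param rarity Rarity threshold (`"ALL"`, or a positive integer such as
#'   50 or 25).
#' @param evidence,aspect Passed to [filter_annotations()].
#' @return A list of class `ground_truth` with elements `pairs`
#'   (`labeled_pairs`), `relevant` (`annotation_set`) and `config`.
#' @export
build_ground_truth <- function(annotations, net1, net2, k = 1L, rarity = "ALL",
                               evidence = evidence_experimental(), aspect = "P") {
  qualifying <- annotations |>
    filter_annotations(evidence = evidence, aspect = aspect) |>
    restrict_to_networks(net1, net2) |>
    apply_rarity(rarity)
  pairs <- label_pairs(qualifying, annotations, net1, net2, k = k)
  cfg <- list(k = as.integer(k), rarity = rarity, evidence = evidence, aspect = aspect)
  attr(pairs, "config") <- cfg
  structure(list(pairs = pairs, relevant = qualifying, config = cfg),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth k=%s rarity=%s: %d positive / %d negative pairs, %d relevant terms>\n",
              x$config$k, as.character(x$config$rarity),
              sum(x$pairs$label == 1L), sum(x$pairs$label == 0L),
              dplyr::n_distinct(x$relevant$term)))
  invisible(x)
}

#' Write labeled pairs to TSV
#'
#' Three columns: `node1`, `node2`, `label` (1 related, 0 unrelated).
#'
#' @param pairs A `labeled_pairs` tibble.
#' @param path Output path.
#' @export
write_labeled_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("node1", "node2", "label")], path, col_names = FALSE)
  invisible(path)
}
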