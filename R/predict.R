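# Cross-species GO-term transfer by hypergeometric enrichment, precision/
# recall evaluation, and the consensus (prediction-overlap) ensemble.

#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of seeing `P_size` or more successes when `O_size` pairs are
#' drawn without replacement from a population of `M_size` pairs containing
#' `N_size` successes. `M` is the set of cross-species pairs in which both
#' proteins carry at least `k` relevant GO terms; `N` those of `M` sharing
#' the term under test; `O` the alignment's pairs within `M`; `P` those of
#' `O` sharing the term. `P_size = 0` gives exactly 1.
#'
#' @param M_size,N_size,O_size,P_size The four counts (`P <= O <= M`,
#'   `P <= N <= M`).
#' @return The upper-tail p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(M_size, N_size, O_size, P_size) {
  ok <- all(c(M_size, N_size, O_size, P_size) >= 0) &&
    P_size <= O_size && O_size <= M_size && P_size <= N_size && N_size <= M_size
  if (!ok) abort("invalid enrichment counts: need 0 <= P <= O <= M and P <= N <= M")
  phyper(P_size - 1, N_size, M_size - N_size, O_size, lower.tail = FALSE)
}

aligned_proteins <- function(alignment) {
  unique(c(alignment$node1, alignment$node2))
}

#' Predict GO annotations from an alignment
#'
#' For the ground truth-rarity dataset at hand, a protein is *eligible* when
#' it carries at least `k` relevant GO terms. For every relevant term `g`
#' the alignment's enrichment in `g` is tested with
#' [hypergeom_upper_tail()]; if `g` is enriched (`p < alpha`), every
#' eligible aligned protein with an alignment partner annotated by `g`
#' is predicted to carry `g`. A protein's own annotation is hidden during
#' transfer: it never triggers its own prediction — the term must arrive
#' from a partner across the alignment.
#'
#' @param alignment An `alignment` tibble (`node1` from network 1, `node2`
#'   from network 2).
#' @param ground_truth A [build_ground_truth()] object supplying the
#'   relevant annotation view and `k`.
#' @param net1,net2 The two [ppi_network()]s (define the two protein sets).
#' @param alpha Enrichment significance level (raw, uncorrected).
#' @return A tibble of class `prediction_set`: `protein`, `term`,
#'   `p_value`, with a `provenance` attribute.
#' @export
predict_annotations <- function(alignment, ground_truth, net1, net2, alpha = 0.05) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  if (nrow(alignment) == 0L) abort("empty alignment")
  k <- ground_truth$config$k
  if (k < 1L) abort("`k` must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  rel <- ground_truth$relevant
  pt <- distinct(rel, .data$protein, .data$term)
  n_terms <- count(pt, .data$protein, name = "n_terms")
  eligible <- n_terms$protein[n_terms$n_terms >= k]
  elig1 <- intersect(eligible, net1$nodes)
  elig2 <- intersect(eligible, net2$nodes)
  M_size <- length(elig1) * length(elig2)
  al <- alignment[alignment$node1 %in% elig1 & alignment$node2 %in% elig2, ]
  O_size <- nrow(al)
  terms <- unique(pt$term)
  has_term <- split(pt$protein, pt$term)

  res <- purrr::map_dfr(terms, function(g) {
    pg <- has_term[[g]]
    N_size <- sum(elig1 %in% pg) * sum(elig2 %in% pg)
    P_size <- sum(al$node1 %in% pg & al$node2 %in% pg)
    tibble(term = g,
           p_value = hypergeom_upper_tail(M_size, N_size, O_size, P_size))
  })
  enriched <- res[res$p_value < alpha, ]
  if (nrow(enriched) == 0L) {
    inform("no GO term enriched in the alignment; empty prediction set")
    preds <- tibble(protein = character(), term = character(), p_value = numeric())
  } else {
    # transfer g to u when an aligned partner of u carries g
    both_dir <- bind_rows(
      tibble(protein = alignment$node1, partner = alignment$node2),
      tibble(protein = alignment$node2, partner = alignment$node1)
    )
    both_dir <- both_dir[both_dir$protein %in% eligible, ]
    partner_terms <- inner_join(both_dir, pt, by = c(partner = "protein"),
                                relationship = "many-to-many")
    preds <- partner_terms |>
      inner_join(enriched, by = "term") |>
      distinct(.data$protein, .data$term, .data$p_value)
  }
  attr(preds, "provenance") <- list(
    k = k, rarity = ground_truth$config$rarity, alpha = alpha, source = "single"
  )
  attr(preds, "enrichment") <- res
  class(preds) <- c("prediction_set", class(preds))
  preds
}

#' Ground-truth protein-term associations
#'
#' The distinct (protein, term) records of a ground truth-rarity dataset's
#' relevant annotation view: the truth set that [precision_recall()]
#' scores against.
#'
#' @param ground_truth A [build_ground_truth()] object.
#' @return A tibble with columns `protein`, `term`.
#' @export
truth_associations <- function(ground_truth) {
  distinct(ground_truth$relevant, .data$protein, .data$term)
}

#' Precision and recall of predicted annotations
#'
#' Precision is the fraction of predicted (protein, term) associations
#' present in the ground truth-rarity dataset; an empty prediction set
#' scores precision 1 (reported with a message). Recall is the fraction of
#' the ground-truth associations (whose proteins are network nodes — the
#' evaluation scope) that are predicted. When `alignment` is supplied, the
#' attainable-recall ceiling — the fraction of ground-truth associations
#' that any transfer across this alignment could reach — is reported too.
#'
#' @param predictions A `prediction_set`.
#' @param ground_truth A [build_ground_truth()] object (its relevant view
#'   is the truth).
#' @param alignment Optional `alignment` used for the recall ceiling.
#' @return One-row tibble: `precision`, `recall`, `n_predictions`,
#'   `n_truth`, and `recall_ceiling` if `alignment` was given.
#' @export
precision_recall <- function(predictions, ground_truth, alignment = NULL) {
  truth <- truth_associations(ground_truth)
  if (nrow(truth) == 0L) abort("empty ground truth")
  n_pred <- nrow(predictions)
  hits <- inner_join(as_tibble(predictions)[, c("protein", "term")], truth,
                     by = c("protein", "term"))
  precision <- if (n_pred == 0L) {
    inform("empty prediction set: precision reported as 1")
    1
  } else nrow(hits) / n_pred
  out <- tibble(precision = precision,
                recall = nrow(hits) / nrow(truth),
                n_predictions = n_pred, n_truth = nrow(truth))
  if (!is.null(alignment)) {
    both_dir <- bind_rows(
      tibble(protein = alignment$node1, partner = alignment$node2),
      tibble(protein = alignment$node2, partner = alignment$node1)
    )
    reachable <- inner_join(both_dir, truth, by = c(partner = "protein"),
                            relationship = "many-to-many") |>
      distinct(.data$protein, .data$term)
    out$recall_ceiling <- nrow(inner_join(truth, reachable,
                                          by = c("protein", "term"))) / nrow(truth)
  }
  out
}

check_same_provenance <- function(p1, p2) {
  a <- attr(p1, "provenance"); b <- attr(p2, "provenance")
  if (!is.null(a) && !is.null(b) &&
      (!identical(a$k, b$k) || !identical(a$rarity, b$rarity))) {
    abort("prediction sets come from different ground truth-rarity datasets")
  }
  a
}

#' Consensus (overlap) of two prediction sets
#'
#' Intersects two prediction sets on (protein, term): the high-precision
#' consensus of two feature pipelines run on the same ground truth-rarity
#' dataset. Disagreeing provenance is an error.
#'
#' @param p1,p2 `prediction_set` tibbles.
#' @return A `prediction_set` whose provenance is marked `"consensus"`;
#'   p-values are taken from `p1`.
#' @export
intersect_predictions <- function(p1, p2) {
  prov <- check_same_provenance(p1, p2)
  out <- semi_join(as_tibble(p1), as_tibble(p2)[, c("protein", "term")],
                   by = c("protein", "term"))
  if (nrow(out) == 0L) warn("prediction sets are disjoint: empty consensus")
  prov$source <- "consensus"
  attr(out, "provenance") <- prov
  class(out) <- c("prediction_set", class(out))
  out
}

#' Set difference of two prediction sets
#'
#' Predictions made by `p1` but not by `p2` (same provenance required).
#'
#' @param p1,p2 `prediction_set` tibbles.
#' @return A `prediction_set`.
#' @export
difference_predictions <- function(p1, p2) {
  prov <- check_same_provenance(p1, p2)
  out <- anti_join(as_tibble(p1), as_tibble(p2)[, c("protein", "term")],
                   by = c("protein", "term"))
  prov$source <- "difference"
  attr(out, "provenance") <- prov
  class(out) <- c("prediction_set", class(out))
  out
}

#' Write predictions as TSV
#'
#' Columns `protein`, `term`, `p_value`.
#'
#' @param predictions A `prediction_set`.
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(as_tibble(predictions)[, c("protein", "term", "p_value")],
                   path, col_names = FALSE)
  invisible(path)
}
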