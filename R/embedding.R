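# Skip-gram embeddings over walk corpora, and pair-feature construction
# from node vectors (orbit signatures or embeddings).

#' Train node embeddings from a walk corpus
#'
#' Fits skip-gram with negative sampling over the walks (each walk is a
#' "sentence" of node IDs), using a dynamic context window of size
#' `params$window` and `params$negative` negative samples per pair.
#' Training is single-threaded and deterministic given `params$seed`.
#'
#' @param walks List of character vectors from [generate_walks()] or
#'   [generate_metapath_walks()].
#' @param params A [walk_params()].
#' @return A tibble of class `embedding_matrix`: column `node` plus
#'   `dim1` ... `dim<d>` coordinates, one row per node seen in the corpus.
#' @export
train_embedding <- function(walks, params = walk_params()) {
  if (length(walks) == 0L) abort("empty walk corpus")
  if (params$dim <= 0L) abort("embedding dimension must be positive")
  vocab <- sort(unique(unlist(walks, use.names = FALSE)))
  corpus <- lapply(walks, function(w) match(w, vocab) - 1L)
  emb <- sgns_train(corpus, length(vocab), params$dim, params$window,
                    params$epochs, params$negative, params$alpha, params$seed)
  out <- as_tibble(as.data.frame(emb))
  names(out) <- paste0("dim", seq_len(params$dim))
  out <- dplyr::bind_cols(tibble(node = vocab), out)
  class(out) <- c("embedding_matrix", class(out))
  out
}

#' Combine two node embeddings into a pair feature
#'
#' @param e1,e2 Numeric vectors of equal length.
#' @param mode `"concat"` (ordered concatenation, default) or `"hadamard"`
#'   (elementwise product).
#' @return Numeric vector (length `2d` for concat, `d` for hadamard).
#' @export
pair_feature_embedding <- function(e1, e2, mode = c("concat", "hadamard")) {
  mode <- match.arg(mode)
  if (length(e1) != length(e2)) abort("embedding dimensions differ")
  if (mode == "concat") c(as.numeric(e1), as.numeric(e2))
  else as.numeric(e1) * as.numeric(e2)
}

#' Write an embedding matrix as TSV
#'
#' @param embedding Result of [train_embedding()].
#' @param path Output path.
#' @export
write_embedding <- function(embedding, path) {
  readr::write_tsv(embedding, path, col_names = FALSE)
  invisible(path)
}

# Look up per-node feature rows for the two sides of a pair table and
# bind them into one numeric feature block. `lookup1`/`lookup2` are
# tibbles with a `node` column; missing nodes get zero vectors.
lookup_block <- function(nodes, lookup, prefix) {
  feat_cols <- setdiff(names(lookup), "node")
  idx <- match(nodes, lookup$node)
  block <- as.matrix(lookup[feat_cols])[idx, , drop = FALSE]
  n_missing <- sum(is.na(idx))
  if (n_missing > 0L) {
    block[is.na(idx), ] <- 0
    inform(sprintf("%d node(s) without feature rows; zero vectors used", n_missing))
  }
  colnames(block) <- paste0(prefix, "_", feat_cols)
  block
}

#' Build a pair-feature table from graphlet orbit signatures
#'
#' For each `(node1, node2)` pair, concatenates the two nodes' 15 orbit
#' counts (network-1 node first), each coordinate transformed as
#' `log(count + 1)`. In integrated mode (`orbits2 = NULL`) a single orbit
#' table over the namespaced integrated network is used and `species` must
#' give the two tags so raw pair IDs can be mapped; in isolated mode two
#' per-network orbit tables are given.
#'
#' @param pairs Data frame with columns `node1`, `node2` (raw IDs).
#' @param orbits1 [count_orbits()] table (integrated network, or network 1).
#' @param orbits2 Optional orbit table for network 2 (isolated mode).
#' @param species Character(2) of species tags; required in integrated mode.
#' @return A tibble: `node1`, `node2`, then 30 numeric feature columns.
#' @export
graphlet_pair_features <- function(pairs, orbits1, orbits2 = NULL, species = NULL) {
  pairs <- as_tibble(pairs)[, c("node1", "node2")]
  if (is.null(orbits2)) {
    if (is.null(species) || length(species) != 2L) {
      abort("integrated mode needs `species = c(tag1, tag2)`")
    }
    b1 <- lookup_block(namespaced(species[1], pairs$node1), orbits1, "n1")
    b2 <- lookup_block(namespaced(species[2], pairs$node2), orbits1, "n2")
  } else {
    b1 <- lookup_block(pairs$node1, orbits1, "n1")
    b2 <- lookup_block(pairs$node2, orbits2, "n2")
  }
  feats <- log(cbind(b1, b2) + 1)
  dplyr::bind_cols(pairs, as_tibble(as.data.frame(feats)))
}

#' Build a pair-feature table from a node embedding
#'
#' @param pairs Data frame with columns `node1`, `node2` (raw IDs).
#' @param embedding [train_embedding()] result over the integrated network.
#' @param species Character(2) of species tags used to namespace raw IDs;
#'   `NULL` if `pairs` already uses the embedding's ID space.
#' @param mode `"concat"` or `"hadamard"` (see [pair_feature_embedding()]).
#' @return A tibble: `node1`, `node2`, then the numeric feature columns.
#' @export
embedding_pair_features <- function(pairs, embedding, species = NULL,
                                    mode = c("concat", "hadamard")) {
  mode <- match.arg(mode)
  pairs <- as_tibble(pairs)[, c("node1", "node2")]
  id1 <- if (is.null(species)) pairs$node1 else namespaced(species[1], pairs$node1)
  id2 <- if (is.null(species)) pairs$node2 else namespaced(species[2], pairs$node2)
  b1 <- lookup_block(id1, embedding, "n1")
  b2 <- lookup_block(id2, embedding, "n2")
  feats <- if (mode == "concat") cbind(b1, b2) else {
    h <- b1 * b2
    colnames(h) <- sub("^n1", "had", colnames(b1))
    h
  }
  dplyr::bind_cols(pairs, as_tibble(as.data.frame(feats)))
}
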