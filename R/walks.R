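# Random walks on the integrated network: unconstrained second-order
# (node2vec-style) walks and metapath-constrained walks.

#' Random-walk and embedding parameters
#'
#' Defaults follow the widely used node2vec settings: `walks_per_node = 10`,
#' `walk_length = 80`, return parameter `p = 1`, in-out parameter `q = 1`,
#' embedding `dim = 128`, context `window = 10`. `epochs`, `negative` and
#' `alpha` control the skip-gram trainer ([train_embedding()]).
#'
#' @param walks_per_node Walks started from each node.
#' @param walk_length Maximum walk length (nodes); a walk is shorter only if
#'   it hits a dead end.
#' @param p Return parameter (> 0): revisiting the previous node is weighted
#'   `1/p`.
#' @param q In-out parameter (> 0): moving to a node not adjacent to the
#'   previous one is weighted `1/q`.
#' @param dim Embedding dimension.
#' @param window Skip-gram context window.
#' @param epochs Training epochs.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate.
#' @param seed RNG seed used for walk generation and training.
#' @return A list of class `walk_params`.
#' @export
walk_params <- function(walks_per_node = 10L, walk_length = 80L, p = 1, q = 1,
                        dim = 128L, window = 10L, epochs = 5L, negative = 5L,
                        alpha = 0.025, seed = 1L) {
  stopifnot(walks_per_node >= 1, walk_length >= 1, p > 0, q > 0, dim >= 1,
            window >= 1, epochs >= 1, negative >= 1, alpha > 0)
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 p = p, q = q, dim = as.integer(dim),
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative = as.integer(negative), alpha = alpha,
                 seed = as.integer(seed)),
            class = "walk_params")
}

adjacency_index <- function(net) {
  et <- edge_table(net)
  nodes <- et$nodes
  n <- length(nodes)
  adj <- rep(list(integer(0)), n)
  if (nrow(et$edges) > 0L) {
    ei <- match(et$edges$from, nodes)
    ej <- match(et$edges$to, nodes)
    a <- c(ei, ej); b <- c(ej, ei)
    spl <- split(b, factor(a, levels = seq_len(n)))
    adj <- lapply(spl, function(x) sort(unique(x)))
  }
  list(nodes = nodes, adj = adj)
}

#' Generate biased second-order random walks
#'
#' Starts `walks_per_node` walks from every node. After the first (uniform)
#' step, the transition from `v` (having arrived from `t`) weights each
#' neighbour `x` of `v` by `1/p` if `x == t`, `1` if `x` is adjacent to `t`
#' and `1/q` otherwise. With `p = q = 1` this reduces to a first-order
#' uniform walk. Deterministic under a fixed `params$seed`; isolated nodes
#' yield length-1 walks.
#'
#' @param net A [ppi_network()] or integrated network.
#' @param params A [walk_params()] object.
#' @return A list of character vectors (one walk per element); exactly
#'   `walks_per_node * n_nodes` walks.
#' @export
generate_walks <- function(net, params = walk_params()) {
  ai <- adjacency_index(net)
  n <- length(ai$nodes)
  if (n == 0L) abort("cannot walk on an empty network")
  adj <- ai$adj
  inv_p <- 1 / params$p
  inv_q <- 1 / params$q
  l <- params$walk_length
  local_seed(params$seed, {
    walks <- vector("list", n * params$walks_per_node)
    wi <- 0L
    for (rep in seq_len(params$walks_per_node)) {
      for (start in seq_len(n)) {
        walk <- integer(l)
        walk[1L] <- start
        len <- 1L
        if (length(adj[[start]]) > 0L) {
          walk[2L] <- sample_safe(adj[[start]], 1L)
          len <- 2L
          while (len < l) {
            t <- walk[len - 1L]
            v <- walk[len]
            nb <- adj[[v]]
            if (length(nb) == 0L) break
            w <- ifelse(nb == t, inv_p, ifelse(nb %in% adj[[t]], 1, inv_q))
            walk[len + 1L] <- nb[sample.int(length(nb), 1L, prob = w)]
            len <- len + 1L
          }
        }
        wi <- wi + 1L
        walks[[wi]] <- ai$nodes[walk[seq_len(len)]]
      }
    }
    walks
  })
}

resolve_metapath <- function(metapath, species) {
  if (is.numeric(metapath)) {
    if (any(!metapath %in% c(1, 2))) abort("numeric metapath entries must be 1 or 2")
    metapath <- species[metapath]
  }
  if (!all(metapath %in% species)) {
    abort(sprintf("metapath names unknown species (network has: %s)",
                  paste(species, collapse = ", ")))
  }
  if (length(metapath) < 2L) abort("a metapath needs at least 2 node types")
  metapath
}

#' Generate metapath-constrained random walks
#'
#' Walks are constrained so the i-th visited node has the node type
#' prescribed by cycling through `metapath` (e.g. `c(1, 2, 1)` alternates
#' species 1 and species 2, forcing every second step across an anchor
#' link). Steps are uniform over the type-matching neighbours; a walk is
#' truncated when no neighbour of the required type exists.
#' `walks_per_node` walks are started from every node whose type matches
#' `metapath[1]`.
#'
#' @param net An integrated network (node types are the two species).
#' @param metapath Integer vector over `{1, 2}` or character vector of
#'   species tags; first and subsequent entries give the required types.
#' @param params A [walk_params()] (its `p`/`q` biases are not used:
#'   constrained steps are uniform).
#' @return A list of character vectors.
#' @export
generate_metapath_walks <- function(net, metapath = c(1L, 2L, 1L),
                                    params = walk_params()) {
  stopifnot(inherits(net, "integrated_network"))
  metapath <- resolve_metapath(metapath, net$species)
  ai <- adjacency_index(net)
  node_type <- net$nodes$species[match(ai$nodes, net$nodes$node)]
  starts <- which(node_type == metapath[1L])
  if (length(starts) == 0L) abort("no node matches the metapath's first type")
  cycle <- length(metapath) - 1L
  type_at <- function(i) metapath[((i - 1L) %% cycle) + 1L]
  l <- params$walk_length
  adj <- ai$adj
  local_seed(params$seed, {
    walks <- vector("list", length(starts) * params$walks_per_node)
    wi <- 0L
    for (rep in seq_len(params$walks_per_node)) {
      for (start in starts) {
        walk <- integer(l)
        walk[1L] <- start
        len <- 1L
        while (len < l) {
          nb <- adj[[walk[len]]]
          want <- type_at(len + 1L)
          nb <- nb[node_type[nb] == want]
          if (length(nb) == 0L) break
          walk[len + 1L] <- sample_safe(nb, 1L)
          len <- len + 1L
        }
        wi <- wi + 1L
        walks[[wi]] <- ai$nodes[walk[seq_len(len)]]
      }
    }
    walks
  })
}

#' Write a walk corpus as plain text
#'
#' One walk per line, node IDs space-separated.
#'
#' @param walks List of character vectors.
#' @param path Output path.
#' @export
write_walks <- function(walks, path) {
  writeLines(vapply(walks, paste, "", collapse = " "), path)
  invisible(path)
}
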