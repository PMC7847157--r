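# Independent oracles used to validate the package's own implementations.

# Brute-force graphlet orbit counter: enumerate every 3- and 4-node subset
# with utils::combn, keep connected induced subgraphs (igraph connectivity),
# and assign orbits from the induced degree. Deliberately different from the
# package's ESU-based counter.
brute_force_orbits <- function(net) {
  g <- funalign::as_igraph(net)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  orb <- matrix(0L, n, 15L, dimnames = list(nodes, paste0("orbit", 0:14)))
  orb[, 1L] <- rowSums(adj)
  assign_orbits <- function(sub) {
    a <- adj[sub, sub]
    d <- rowSums(a)
    m <- sum(a) / 2
    s <- length(sub)
    if (s == 3L) {
      if (m < 2) return(NULL)                       # disconnected
      if (m == 2) list(cbind(sub[d == 1], 2L), cbind(sub[d == 2], 3L))
      else list(cbind(sub, 4L))
    } else {
      sg <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      if (!igraph::is_connected(sg)) return(NULL)
      if (m == 3 && max(d) == 2) list(cbind(sub[d == 1], 5L), cbind(sub[d == 2], 6L))
      else if (m == 3) list(cbind(sub[d == 1], 7L), cbind(sub[d == 3], 8L))
      else if (m == 4 && max(d) == 2) list(cbind(sub, 9L))
      else if (m == 4) list(cbind(sub[d == 1], 10L), cbind(sub[d == 2], 11L),
                            cbind(sub[d == 3], 12L))
      else if (m == 5) list(cbind(sub[d == 2], 13L), cbind(sub[d == 3], 14L))
      else list(cbind(sub, 15L))
    }
  }
  for (s in c(3L, 4L)) {
    if (n < s) next
    sets <- utils::combn(n, s)
    for (ci in seq_len(ncol(sets))) {
      res <- assign_orbits(sets[, ci])
      if (is.null(res)) next
      for (blk in res) {
        if (length(blk) == 0L) next
        orb[blk] <- orb[blk] + 1L
      }
    }
  }
  out <- tibble::as_tibble(as.data.frame(orb))
  dplyr::bind_cols(tibble::tibble(node = nodes), out)
}

# Exhaustive hypergeometric upper tail: enumerate every O-subset of a
# population of M elements of which the first N are successes, and count
# subsets with at least P successes.
enumerate_upper_tail <- function(M, N, O, P) {
  if (O == 0L) return(if (P <= 0L) 1 else 0)
  draws <- utils::combn(M, O)
  succ <- colSums(draws <= N)
  mean(succ >= P)
}

random_er_network <- function(n, p, species = "er", seed = 1L, prefix = "v") {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(from = paste0(prefix, el[, 1]), to = paste0(prefix, el[, 2]))
  funalign::ppi_network(edges, species, nodes = paste0(prefix, seq_len(n)),
                        quiet = TRUE)
}
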