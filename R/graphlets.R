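# Graphlet orbit counting: automorphism orbits of the connected 2-4-node
# graphlets (15 orbits; orbit 0 is the degree). Counts are exact induced
# counts, obtained by ESU connected-subgraph enumeration with
# degree-sequence classification; 3- and 4-node connected graphs are
# uniquely identified by their degree sequences.

edge_table <- function(net) {
  if (inherits(net, "ppi_network")) {
    list(nodes = net$nodes, edges = net$edges[, c("from", "to")])
  } else if (inherits(net, "integrated_network")) {
    list(nodes = net$nodes$node, edges = net$edges[, c("from", "to")])
  } else {
    abort("`net` must be a ppi_network or integrated_network")
  }
}

#' Count graphlet orbit signatures for every node
#'
#' Computes, for each node, the number of times it touches each automorphism
#' orbit of the connected 2-4-node graphlets: orbit 0 (edge end, i.e. the
#' degree), orbits 1-2 (3-path end/middle), orbit 3 (triangle), orbits 4-5
#' (4-path end/middle), orbits 6-7 (3-star leaf/centre), orbit 8 (4-cycle),
#' orbits 9-11 (paw pendant / triangle rim / triangle-attachment), orbits
#' 12-13 (diamond rim/hub) and orbit 14 (4-clique). Counting is homogeneous:
#' on an integrated network, edge types are ignored.
#'
#' @param net A [ppi_network()] or [build_integrated_network()] result.
#' @return A tibble with a `node` column and columns `orbit0` ... `orbit14`.
#' @export
count_orbits <- function(net) {
  et <- edge_table(net)
  nodes <- et$nodes
  n <- length(nodes)
  orb <- matrix(0L, nrow = n, ncol = 15L)
  if (n == 0L) {
    out <- as_tibble(as.data.frame(orb))
    names(out) <- paste0("orbit", 0:14)
    return(tibble(node = character(0)) |> dplyr::bind_cols(out))
  }
  ei <- match(et$edges$from, nodes)
  ej <- match(et$edges$to, nodes)
  adj <- rep(list(integer(0)), n)
  if (length(ei) > 0L) {
    a <- c(ei, ej); b <- c(ej, ei)
    spl <- split(b, factor(a, levels = seq_len(n)))
    adj <- lapply(spl, function(x) sort(unique(x)))
  }
  orb[, 1L] <- vapply(adj, length, 1L)

  record <- function(sub) {
    s <- length(sub)
    d <- integer(s)
    m <- 0L
    for (i in 1L:(s - 1L)) {
      ni <- adj[[sub[i]]]
      for (j in (i + 1L):s) {
        if (sub[j] %in% ni) {
          d[i] <- d[i] + 1L; d[j] <- d[j] + 1L; m <- m + 1L
        }
      }
    }
    if (s == 3L) {
      if (m == 2L) {                       # 3-path
        orb[sub[d == 1L], 2L] <<- orb[sub[d == 1L], 2L] + 1L
        orb[sub[d == 2L], 3L] <<- orb[sub[d == 2L], 3L] + 1L
      } else {                             # triangle
        orb[sub, 4L] <<- orb[sub, 4L] + 1L
      }
    } else {
      if (m == 3L) {
        if (max(d) == 3L) {                # 3-star
          orb[sub[d == 1L], 7L] <<- orb[sub[d == 1L], 7L] + 1L
          orb[sub[d == 3L], 8L] <<- orb[sub[d == 3L], 8L] + 1L
        } else {                           # 4-path
          orb[sub[d == 1L], 5L] <<- orb[sub[d == 1L], 5L] + 1L
          orb[sub[d == 2L], 6L] <<- orb[sub[d == 2L], 6L] + 1L
        }
      } else if (m == 4L) {
        if (max(d) == 2L) {                # 4-cycle
          orb[sub, 9L] <<- orb[sub, 9L] + 1L
        } else {                           # paw
          orb[sub[d == 1L], 10L] <<- orb[sub[d == 1L], 10L] + 1L
          orb[sub[d == 2L], 11L] <<- orb[sub[d == 2L], 11L] + 1L
          orb[sub[d == 3L], 12L] <<- orb[sub[d == 3L], 12L] + 1L
        }
      } else if (m == 5L) {                # diamond
        orb[sub[d == 2L], 13L] <<- orb[sub[d == 2L], 13L] + 1L
        orb[sub[d == 3L], 14L] <<- orb[sub[d == 3L], 14L] + 1L
      } else {                             # 4-clique
        orb[sub, 15L] <<- orb[sub, 15L] + 1L
      }
    }
    invisible(NULL)
  }

  # ESU: each connected induced subgraph is reached exactly once, anchored
  # at its minimum-index vertex.
  extend <- function(sub, ext, v, blocked) {
    s <- length(sub)
    if (s >= 3L) record(sub)
    if (s == 4L) return(invisible(NULL))
    while (length(ext) > 0L) {
      w <- ext[1L]
      ext <- ext[-1L]
      nw <- adj[[w]]
      excl <- nw[nw > v & !(nw %in% blocked)]
      extend(c(sub, w), c(ext, excl), v, unique(c(blocked, w, nw)))
    }
    invisible(NULL)
  }
  for (v in seq_len(n)) {
    nv <- adj[[v]]
    extend(v, nv[nv > v], v, c(v, nv))
  }

  out <- as_tibble(as.data.frame(orb))
  names(out) <- paste0("orbit", 0:14)
  dplyr::bind_cols(tibble(node = nodes), out)
}

#' Combine two orbit signatures into a pair feature vector
#'
#' Concatenates the network-1 node's 15 orbit counts with the network-2
#' node's, each coordinate transformed as `log(count + 1)`, giving a
#' 30-dimensional pair feature.
#'
#' @param ov1,ov2 Numeric vectors of length 15 (orbit counts).
#' @return Numeric vector of length 30.
#' @export
pair_feature_graphlet <- function(ov1, ov2) {
  if (length(ov1) != 15L || length(ov2) != 15L) {
    abort("orbit vectors must have length 15")
  }
  log(c(as.numeric(ov1), as.numeric(ov2)) + 1)
}

#' Write an orbit-count matrix as TSV
#'
#' One row per node: the node ID then the 15 orbit counts, mirroring the
#' node-dump idiom of standalone orbit counters.
#'
#' @param orbits Result of [count_orbits()].
#' @param path Output path.
#' @export
write_orbit_matrix <- function(orbits, path) {
  readr::write_tsv(orbits, path, col_names = FALSE)
  invisible(path)
}
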