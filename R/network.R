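# Networks, anchors, and the integrated two-species network.

#' Construct a PPI network from an edge table
#'
#' A network is an undirected simple graph: self-loops are dropped and
#' duplicate (multi-)edges are collapsed, with a message reporting how many
#' of each were removed. Nodes are species-scoped string identifiers.
#'
#' @param edges A data frame whose first two columns are the edge endpoints.
#' @param species Short species tag, e.g. `"yeast"`.
#' @param nodes Optional character vector of node IDs; isolated nodes not
#'   touched by any edge can be declared here. Defaults to the endpoint set.
#' @param quiet Suppress the dropped-edge message.
#' @return An object of class `ppi_network`: a list with `species`,
#'   `nodes` (character) and `edges` (a tibble with columns `from`, `to`).
#' @export
ppi_network <- function(edges, species, nodes = NULL, quiet = FALSE) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  edges <- as_tibble(edges)
  if (ncol(edges) < 2L && nrow(edges) > 0L) {
    abort("`edges` must have at least two columns (endpoints).")
  }
  if (nrow(edges) == 0L) {
    edges <- tibble(from = character(), to = character())
  } else {
    edges <- tibble(from = as.character(edges[[1L]]), to = as.character(edges[[2L]]))
  }
  n_loops <- sum(edges$from == edges$to)
  edges <- dplyr::filter(edges, .data$from != .data$to)
  # canonical orientation so duplicates collapse regardless of direction
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]
  edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  n_before <- nrow(edges)
  edges <- distinct(edges)
  n_dup <- n_before - nrow(edges)
  if (!quiet && (n_loops > 0L || n_dup > 0L)) {
    inform(sprintf("ppi_network('%s'): dropped %d self-loop(s), %d duplicate edge(s)",
                   species, n_loops, n_dup))
  }
  all_nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes %||% character()))))
  structure(
    list(species = species, nodes = all_nodes, edges = arrange(edges, .data$from, .data$to)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network '%s': %d nodes, %d edges>\n",
              x$species, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

#' Read an undirected edge list
#'
#' Reads a delimited edge list (two ID columns; `#`-prefixed comment lines
#' skipped) into a [ppi_network()]. Duplicate edges are collapsed and
#' self-loops dropped, as for direct construction.
#'
#' @param path Path to the edge-list file.
#' @param species Species tag attached to the network.
#' @param delim Field delimiter, tab by default.
#' @inheritParams ppi_network
#' @return A `ppi_network`.
#' @export
read_edge_list <- function(path, species, delim = "\t", quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("edge-list file not found: %s", path))
  lines <- readr::read_lines(path)
  # '#node <id>' comment lines declare nodes without edges
  iso_lines <- lines[startsWith(lines, paste0("#node", delim))]
  iso <- if (length(iso_lines) > 0L) {
    vapply(strsplit(iso_lines, delim, fixed = TRUE), `[[`, "", 2L)
  } else character()
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    if (length(iso) == 0L) {
      warn(sprintf("edge-list file '%s' is empty; returning an empty network", path))
    }
    return(ppi_network(tibble(from = character(), to = character()), species,
                       nodes = iso, quiet = quiet))
  }
  parts <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("edge list '%s': line %d has fewer than 2 fields", path, bad[1L]))
  }
  edges <- tibble(
    from = vapply(parts, `[[`, "", 1L),
    to   = vapply(parts, `[[`, "", 2L)
  )
  ppi_network(edges, species, nodes = iso, quiet = quiet)
}

#' Read a cross-network anchor list
#'
#' Anchors are cross-species protein pairs, typically from sequence
#' comparison (e.g. BLASTP hits below an E-value cutoff). Lines hold
#' `node1 <delim> node2 [<delim> evalue]`. Duplicate pairs collapse to one.
#'
#' @param path Path to the anchor file.
#' @param evalue_threshold Keep only anchors with E-value at or below this
#'   threshold. `NULL` (default) keeps all pairs; pairs without an E-value
#'   column are always kept.
#' @param delim Field delimiter.
#' @return A tibble of class `anchor_set` with columns `node1`, `node2` and,
#'   when present in the file, `evalue`.
#' @export
read_anchor_list <- function(path, evalue_threshold = NULL, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("anchor file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn(sprintf("anchor file '%s' is empty", path))
    return(anchor_set(tibble(node1 = character(), node2 = character())))
  }
  parts <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("anchor list '%s': line %d has fewer than 2 fields", path, bad[1L]))
  }
  out <- tibble(
    node1 = vapply(parts, `[[`, "", 1L),
    node2 = vapply(parts, `[[`, "", 2L)
  )
  has_e <- vapply(parts, length, 1L) >= 3L
  if (any(has_e)) {
    ev <- rep(NA_real_, length(parts))
    ev[has_e] <- as.numeric(vapply(parts[has_e], `[[`, "", 3L))
    out$evalue <- ev
  }
  anchor_set(out, evalue_threshold = evalue_threshold)
}

#' Construct an anchor set
#'
#' @param pairs Data frame with columns `node1`, `node2` (or first two
#'   columns used positionally) and optionally `evalue`.
#' @inheritParams read_anchor_list
#' @return A tibble of class `anchor_set`.
#' @export
anchor_set <- function(pairs, evalue_threshold = NULL) {
  pairs <- as_tibble(pairs)
  if (!all(c("node1", "node2") %in% names(pairs)) && ncol(pairs) >= 2L) {
    names(pairs)[1:2] <- c("node1", "node2")
  }
  pairs$node1 <- as.character(pairs$node1)
  pairs$node2 <- as.character(pairs$node2)
  if (!is.null(evalue_threshold) && "evalue" %in% names(pairs)) {
    pairs <- dplyr::filter(pairs, is.na(.data$evalue) | .data$evalue <= evalue_threshold)
  }
  pairs <- distinct(pairs, .data$node1, .data$node2, .keep_all = TRUE)
  class(pairs) <- c("anchor_set", class(pairs))
  pairs
}

namespaced <- function(species, ids) paste0(species, ":", ids)

#' Integrate two PPI networks through anchor links
#'
#' Builds the single heterogeneous graph containing both species' PPI edges
#' plus the cross-species anchor edges. Node IDs are namespaced internally as
#' `"<species>:<raw id>"` so the two ID spaces are disjoint by construction.
#' Anchors whose endpoints are missing from their network are dropped with a
#' warning; anchors are unweighted edges of type `"anchor"`.
#'
#' @param n1,n2 The two [ppi_network()] objects (species tags must differ).
#' @param anchors An `anchor_set`; `node1` refers to `n1`, `node2` to `n2`.
#' @param namespace Prefix raw IDs with the species tag. Setting this to
#'   `FALSE` is an error when the two raw ID spaces overlap.
#' @return An object of class `integrated_network`: list with `nodes`
#'   (tibble: `node`, `species`), `edges` (tibble: `from`, `to`, `type` in
#'   `ppi_1`/`ppi_2`/`anchor`), `species` (the two tags) and
#'   `dropped_anchors` (count).
#' @export
build_integrated_network <- function(n1, n2, anchors, namespace = TRUE) {
  stopifnot(inherits(n1, "ppi_network"), inherits(n2, "ppi_network"))
  if (identical(n1$species, n2$species)) abort("the two networks must have distinct species tags")
  overlap <- intersect(n1$nodes, n2$nodes)
  if (!namespace && length(overlap) > 0L) {
    abort(sprintf("node ID spaces overlap (%d shared IDs) and namespacing is disabled",
                  length(overlap)))
  }
  amb <- anchors$node1 %in% overlap | anchors$node2 %in% overlap
  if (any(amb)) {
    abort(sprintf("%d anchor endpoint(s) appear in both species' ID spaces (ambiguous side)",
                  sum(amb)))
  }
  tag <- function(sp, ids) if (namespace) namespaced(sp, ids) else ids

  nodes <- bind_rows(
    tibble(node = tag(n1$species, n1$nodes), species = n1$species),
    tibble(node = tag(n2$species, n2$nodes), species = n2$species)
  )
  keep1 <- anchors$node1 %in% n1$nodes
  keep2 <- anchors$node2 %in% n2$nodes
  keep <- keep1 & keep2
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    warn(sprintf("dropped %d anchor(s) whose endpoint is absent from its network", n_drop))
  }
  edges <- bind_rows(
    tibble(from = tag(n1$species, n1$edges$from), to = tag(n1$species, n1$edges$to),
           type = "ppi_1"),
    tibble(from = tag(n2$species, n2$edges$from), to = tag(n2$species, n2$edges$to),
           type = "ppi_2"),
    tibble(from = tag(n1$species, anchors$node1[keep]),
           to = tag(n2$species, anchors$node2[keep]),
           type = "anchor")
  )
  structure(
    list(nodes = nodes, edges = edges, species = c(n1$species, n2$species),
         dropped_anchors = n_drop),
    class = "integrated_network"
  )
}

#' @export
print.integrated_network <- function(x, ...) {
  tab <- table(x$edges$type)
  cat(sprintf("<integrated_network [%s + %s]: %d nodes, %d edges (%s)>\n",
              x$species[1], x$species[2], nrow(x$nodes), nrow(x$edges),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param net A `ppi_network` or `integrated_network`.
#' @return An undirected [igraph::graph] carrying `species` vertex attributes
#'   and, for integrated networks, `type` edge attributes.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "ppi_network")) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::V(g)$species <- net$species
    return(g)
  }
  if (inherits(net, "integrated_network")) {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = data.frame(name = net$nodes$node, species = net$nodes$species)
    )
    return(g)
  }
  abort("`net` must be a ppi_network or integrated_network")
}

#' Write / read an integrated network as a typed edge list
#'
#' The on-disk format is a 3-column TSV (`node1`, `node2`, `edge_type`), with
#' isolated nodes recorded as `# node <id> <species>` comment-dialect lines
#' so a round trip preserves the full node set.
#'
#' @param net An `integrated_network`.
#' @param path Output path.
#' @export
write_integrated_network <- function(net, path) {
  stopifnot(inherits(net, "integrated_network"))
  touched <- unique(c(net$edges$from, net$edges$to))
  iso <- net$nodes[!net$nodes$node %in% touched, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#species\t%s\t%s", net$species[1], net$species[2]), con)
  if (nrow(iso) > 0L) {
    writeLines(sprintf("#node\t%s\t%s", iso$node, iso$species), con)
  }
  writeLines(sprintf("%s\t%s\t%s", net$edges$from, net$edges$to, net$edges$type), con)
  invisible(path)
}

#' @rdname write_integrated_network
#' @export
read_integrated_network <- function(path) {
  lines <- readr::read_lines(path)
  sp_line <- lines[startsWith(lines, "#species\t")]
  if (length(sp_line) != 1L) abort("missing '#species' header line")
  species <- strsplit(sp_line, "\t", fixed = TRUE)[[1]][2:3]
  iso_lines <- lines[startsWith(lines, "#node\t")]
  iso <- if (length(iso_lines) > 0L) {
    p <- strsplit(iso_lines, "\t", fixed = TRUE)
    tibble(node = vapply(p, `[[`, "", 2L), species = vapply(p, `[[`, "", 3L))
  } else tibble(node = character(), species = character())
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  p <- strsplit(body, "\t", fixed = TRUE)
  edges <- tibble(
    from = vapply(p, `[[`, "", 1L),
    to   = vapply(p, `[[`, "", 2L),
    type = vapply(p, `[[`, "", 3L)
  )
  sp_of <- function(nd, ty) {
    # edge type determines endpoint species; anchors go species1 -> species2
    dplyr::case_when(
      ty == "ppi_1" ~ species[1],
      ty == "ppi_2" ~ species[2],
      TRUE ~ NA_character_
    )
  }
  nodes <- bind_rows(
    tibble(node = edges$from,
           species = ifelse(edges$type == "anchor", species[1], sp_of(edges$from, edges$type))),
    tibble(node = edges$to,
           species = ifelse(edges$type == "anchor", species[2], sp_of(edges$to, edges$type))),
    iso
  )
  nodes <- distinct(nodes)
  nodes <- arrange(nodes, match(.data$species, species), .data$node)
  structure(
    list(nodes = nodes, edges = edges, species = species, dropped_anchors = 0L),
    class = "integrated_network"
  )
}
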