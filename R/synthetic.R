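# Synthetic two-species worlds: networks with planted cross-species
# functional modules, anchor links preferentially joining module
# counterparts, and GO-style annotations with tunable sparsity and noise.

#' Configuration for the synthetic world generator
#'
#' The generator plants `n_modules` functional modules, each present in
#' both species. Module members interact densely (`p_intra`), all nodes
#' interact sparsely at background rate (`p_background`), module members
#' are annotated by the module's GO terms (experimental evidence, aspect P)
#' with per-annotation `dropout`, and anchors join cross-species
#' same-module pairs at `anchor_true_rate` plus uniformly random
#' cross-species pairs (one per `anchor_random_rate` species-1 node on
#' average). A fraction of background nodes get a private singleton term
#' (annotated, but shared with nobody) and a fraction get a common
#' non-qualifying cellular-component term, so all three labeling outcomes
#' (related / unrelated / neither) occur.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Integer range `c(lo, hi)`; each module's size per
#'   species is drawn uniformly from it.
#' @param background_nodes Background (module-free) nodes per species.
#' @param p_intra Within-module edge probability.
#' @param p_background Background edge probability (all node pairs).
#' @param terms_per_module GO terms private to each module.
#' @param dropout Probability that a module member misses a module term.
#' @param anchor_true_rate Probability that a same-module cross pair gets
#'   an anchor.
#' @param anchor_random_rate Expected random anchors per species-1 node.
#' @param singleton_rate Fraction of background nodes with a private term.
#' @param cc_rate Fraction of all nodes carrying the shared
#'   cellular-component (non-qualifying) term.
#' @param noise_fraction Fraction of edges/anchor endpoints randomised by
#'   [inject_noise()] after generation (0 = clean world).
#' @param species The two species tags.
#' @param seed RNG seed: identical configs give identical worlds.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_modules = 8L, module_size = c(4L, 6L),
                         background_nodes = 25L, p_intra = 0.8,
                         p_background = 0.02, terms_per_module = 2L,
                         dropout = 0.1, anchor_true_rate = 0.7,
                         anchor_random_rate = 0.3, singleton_rate = 0.5,
                         cc_rate = 0.2, noise_fraction = 0,
                         species = c("sp1", "sp2"), seed = 1L) {
  stopifnot(n_modules >= 1, length(module_size) == 2L, module_size[1] >= 1,
            module_size[2] >= module_size[1], background_nodes >= 0,
            p_intra >= 0, p_intra <= 1, p_background >= 0, p_background <= 1,
            terms_per_module >= 1, dropout >= 0, dropout <= 1,
            anchor_true_rate >= 0, anchor_true_rate <= 1,
            noise_fraction >= 0, noise_fraction <= 1, length(species) == 2L)
  structure(as.list(environment()), class = "synth_config")
}

random_edges <- function(nodes, p) {
  n <- length(nodes)
  if (n < 2L || p <= 0) return(tibble(from = character(), to = character()))
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  tibble(from = nodes[idx[keep, 1L]], to = nodes[idx[keep, 2L]])
}

#' Generate a synthetic two-species world
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_world`: `network1`, `network2`
#'   ([ppi_network()]s), `anchors` ([anchor_set()]), `annotations`
#'   ([annotation_set()]), `modules` (tibble: `node`, `species`, `module`)
#'   and `config`.
#' @export
generate_world <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  world <- local_seed(cfg$seed, {
    sizes <- lapply(1:2, function(s) {
      sample_safe(seq(cfg$module_size[1], cfg$module_size[2]),
                  cfg$n_modules, replace = TRUE)
    })
    make_side <- function(s) {
      tag <- cfg$species[s]
      module_of <- rep(seq_len(cfg$n_modules), sizes[[s]])
      n_total <- length(module_of) + cfg$background_nodes
      nodes <- sprintf("%s_p%03d", tag, seq_len(n_total))
      modules <- tibble(node = nodes,
                        species = tag,
                        module = c(module_of, rep(NA_integer_, cfg$background_nodes)))
      edges <- bind_rows(
        purrr::map_dfr(seq_len(cfg$n_modules), function(m) {
          random_edges(modules$node[!is.na(modules$module) & modules$module == m],
                       cfg$p_intra)
        }),
        random_edges(nodes, cfg$p_background)
      )
      list(net = ppi_network(edges, tag, nodes = nodes, quiet = TRUE),
           modules = modules)
    }
    side1 <- make_side(1L)
    side2 <- make_side(2L)
    modules <- bind_rows(side1$modules, side2$modules)

    # annotations: module terms with dropout; singleton terms for some
    # background nodes; a shared non-qualifying CC term for some nodes
    module_terms <- lapply(seq_len(cfg$n_modules), function(m) {
      sprintf("GO:%07d", m * 100L + seq_len(cfg$terms_per_module))
    })
    ann <- purrr::map_dfr(seq_len(cfg$n_modules), function(m) {
      members <- modules$node[!is.na(modules$module) & modules$module == m]
      grid <- tidyr::expand_grid(protein = members, term = module_terms[[m]])
      grid[runif(nrow(grid)) >= cfg$dropout, ]
    })
    ann$evidence <- "EXP"
    ann$aspect <- "P"
    bg <- modules$node[is.na(modules$module)]
    singles <- bg[runif(length(bg)) < cfg$singleton_rate]
    if (length(singles) > 0L) {
      ann <- bind_rows(ann, tibble(
        protein = singles,
        term = sprintf("GO:9%06d", seq_along(singles)),
        evidence = "EXP", aspect = "P"
      ))
    }
    cc <- modules$node[runif(nrow(modules)) < cfg$cc_rate]
    if (length(cc) > 0L) {
      ann <- bind_rows(ann, tibble(protein = cc, term = "GO:0005575",
                                   evidence = "IEA", aspect = "C"))
    }

    # anchors: same-module cross pairs at the true rate + random pairs
    true_anchors <- purrr::map_dfr(seq_len(cfg$n_modules), function(m) {
      m1 <- modules$node[modules$species == cfg$species[1] &
                           !is.na(modules$module) & modules$module == m]
      m2 <- modules$node[modules$species == cfg$species[2] &
                           !is.na(modules$module) & modules$module == m]
      grid <- tidyr::expand_grid(node1 = m1, node2 = m2)
      grid[runif(nrow(grid)) < cfg$anchor_true_rate, ]
    })
    n_random <- round(cfg$anchor_random_rate * n_nodes(side1$net))
    random_anchors <- tibble(
      node1 = sample(side1$net$nodes, n_random, replace = TRUE),
      node2 = sample(side2$net$nodes, n_random, replace = TRUE)
    )
    anchors <- anchor_set(bind_rows(true_anchors, random_anchors))

    structure(list(network1 = side1$net, network2 = side2$net,
                   anchors = anchors, annotations = annotation_set(ann),
                   modules = modules, config = cfg),
              class = "synth_world")
  })
  if (cfg$noise_fraction > 0) world <- inject_noise(world, cfg$noise_fraction,
                                                    seed = cfg$seed + 10000L)
  world
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world: %d+%d nodes, %d+%d edges, %d anchors, %d annotation records>\n",
              n_nodes(x$network1), n_nodes(x$network2),
              n_edges(x$network1), n_edges(x$network2),
              nrow(x$anchors), nrow(x$annotations)))
  invisible(x)
}

# Degree-preserving double-edge swaps until at most (1-f)|E| of the
# original edges survive (or an attempt cap is hit).
rewire_edges <- function(edges, f, max_tries = NULL) {
  m <- nrow(edges)
  if (m < 2L || f <= 0) return(edges)
  max_tries <- max_tries %||% (200L * m)
  from <- edges$from; to <- edges$to
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  current <- new.env(parent = emptyenv())
  for (kk in key(from, to)) assign(kk, TRUE, envir = current)
  is_orig <- rep(TRUE, m)
  target <- round((1 - f) * m)
  survivors <- m
  tries <- 0L
  while (survivors > target && tries < max_tries) {
    tries <- tries + 1L
    ij <- sample.int(m, 2L)
    i <- ij[1L]; j <- ij[2L]
    a <- from[i]; b <- to[i]; c_ <- from[j]; d <- to[j]
    # propose (a,d),(c,b) or (a,c),(b,d)
    if (runif(1) < 0.5) { new1 <- c(a, d); new2 <- c(c_, b) }
    else { new1 <- c(a, c_); new2 <- c(b, d) }
    if (new1[1] == new1[2] || new2[1] == new2[2]) next
    k1 <- key(new1[1], new1[2]); k2 <- key(new2[1], new2[2])
    if (k1 == k2 || exists(k1, envir = current) || exists(k2, envir = current)) next
    rm(list = c(key(a, b), key(c_, d)), envir = current)
    assign(k1, TRUE, envir = current)
    assign(k2, TRUE, envir = current)
    survivors <- survivors - sum(is_orig[c(i, j)])
    from[i] <- new1[1]; to[i] <- new1[2]
    from[j] <- new2[1]; to[j] <- new2[2]
    is_orig[c(i, j)] <- FALSE
  }
  a <- pmin(from, to); b <- pmax(from, to)
  tibble(from = a, to = b)
}

#' Inject noise into a synthetic world
#'
#' Randomises a fraction `f` of each data layer: network edges are rewired
#' with degree-preserving double-edge swaps, anchors are re-targeted to
#' uniformly random cross-species pairs, and annotation records are
#' re-assigned to uniformly random proteins of the same species. `f = 0`
#' returns the world unchanged; `f = 1` is completely random data (no
#' original edge deliberately intact). Edge, anchor and record counts are
#' preserved, as are all node degrees.
#'
#' @param world A [generate_world()] result.
#' @param f Noise fraction in \[0, 1\].
#' @param seed RNG seed for the perturbation.
#' @param layers Which data layers to perturb (default all three).
#' @return The perturbed `synth_world`.
#' @export
inject_noise <- function(world, f, seed = 1L,
                         layers = c("edges", "anchors", "annotations")) {
  stopifnot(inherits(world, "synth_world"), f >= 0, f <= 1)
  layers <- match.arg(layers, several.ok = TRUE)
  if (f == 0) return(world)
  local_seed(seed, {
    if ("edges" %in% layers) {
      for (side in c("network1", "network2")) {
        net <- world[[side]]
        new_edges <- rewire_edges(net$edges, f)
        world[[side]] <- ppi_network(new_edges, net$species, nodes = net$nodes,
                                     quiet = TRUE)
      }
    }
    if ("annotations" %in% layers) {
      ann <- as_tibble(world$annotations)
      n_re <- round(f * nrow(ann))
      if (n_re > 0L) {
        idx <- sample.int(nrow(ann), n_re)
        sp1 <- startsWith(ann$protein[idx], world$network1$species)
        ann$protein[idx[sp1]] <- sample(world$network1$nodes, sum(sp1),
                                        replace = TRUE)
        ann$protein[idx[!sp1]] <- sample(world$network2$nodes, sum(!sp1),
                                         replace = TRUE)
        world$annotations <- annotation_set(ann)
      }
    }
    n_anchor <- nrow(world$anchors)
    n_retarget <- if ("anchors" %in% layers) round(f * n_anchor) else 0L
    if (n_retarget > 0L) {
      idx <- sample.int(n_anchor, n_retarget)
      anchors <- as_tibble(world$anchors)
      anchors$node1[idx] <- sample(world$network1$nodes, n_retarget, replace = TRUE)
      anchors$node2[idx] <- sample(world$network2$nodes, n_retarget, replace = TRUE)
      # keep the anchor count: redraw retargeted rows that collide
      for (tries in 1:50) {
        keys <- paste(anchors$node1, anchors$node2)
        counts <- table(keys)
        fix <- idx[counts[keys[idx]] > 1L]
        if (length(fix) == 0L) break
        anchors$node1[fix] <- sample(world$network1$nodes, length(fix), replace = TRUE)
        anchors$node2[fix] <- sample(world$network2$nodes, length(fix), replace = TRUE)
      }
      world$anchors <- anchor_set(anchors)
    }
    world
  })
}

#' Generate a random network of an exact size
#'
#' Uniform G(n, m) random graph (via [igraph::sample_gnm()]) with exactly
#' `n_nodes` nodes and `n_edges` edges: the degree structure of real PPI
#' networks is not emulated, only the printed sizes, which is what
#' integration-count checks need.
#'
#' @param n_nodes,n_edges Exact node and edge counts.
#' @param species Species tag.
#' @param seed RNG seed.
#' @return A [ppi_network()].
#' @export
generate_sized_network <- function(n_nodes, n_edges, species, seed = 1L) {
  local_seed(seed, {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    el <- igraph::as_edgelist(g, names = FALSE)
    ppi_network(tibble(from = sprintf("%s%06d", species, el[, 1]),
                       to = sprintf("%s%06d", species, el[, 2])),
                species,
                nodes = sprintf("%s%06d", species, seq_len(n_nodes)),
                quiet = TRUE)
  })
}

#' Generate an exact number of distinct random anchors
#'
#' @param net1,net2 The two [ppi_network()]s.
#' @param n Number of distinct cross-species pairs to draw.
#' @param seed RNG seed.
#' @return An [anchor_set()] of exactly `n` pairs.
#' @export
generate_sized_anchors <- function(net1, net2, n, seed = 1L) {
  local_seed(seed, {
    pairs <- tibble(node1 = character(0), node2 = character(0))
    while (nrow(pairs) < n) {
      need <- n - nrow(pairs)
      extra <- tibble(
        node1 = sample(net1$nodes, ceiling(need * 1.2), replace = TRUE),
        node2 = sample(net2$nodes, ceiling(need * 1.2), replace = TRUE)
      )
      pairs <- distinct(bind_rows(pairs, extra))
    }
    anchor_set(pairs[seq_len(n), ])
  })
}

#' Write a synthetic world in the pipeline's input formats
#'
#' Emits the two edge-list TSVs, the anchor TSV and a 4-column annotation
#' TSV into `dir`, so fixtures are indistinguishable from real inputs.
#'
#' @param world A `synth_world`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_net <- function(net) {
    path <- file.path(dir, paste0(net$species, ".edges.tsv"))
    iso <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(iso) > 0L) writeLines(sprintf("#node\t%s", iso), con)
    writeLines(sprintf("%s\t%s", net$edges$from, net$edges$to), con)
  }
  write_net(world$network1)
  write_net(world$network2)
  readr::write_tsv(as_tibble(world$anchors)[, c("node1", "node2")],
                   file.path(dir, "anchors.tsv"), col_names = FALSE)
  readr::write_tsv(as_tibble(world$annotations),
                   file.path(dir, "annotations.tsv"), col_names = FALSE)
  invisible(dir)
}
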