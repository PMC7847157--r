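wp_small <- function(...) {
  funalign::walk_params(walks_per_node = 4L, walk_length = 12L, dim = 16L,
                        window = 4L, epochs = 3L, seed = 11L, ...)
}

test_that("walk corpus has exactly r walks per node and respects dead ends", {
  net <- net_from_edges(c("a", "b"), nodes = c("a", "b", "iso"))
  wp <- wp_small()
  walks <- generate_walks(net, wp)
  expect_length(walks, 3L * wp$walks_per_node)
  # the single-edge component just alternates
  ab <- walks[vapply(walks, function(w) w[1] %in% c("a", "b"), TRUE)]
  for (w in ab) {
    expect_equal(length(w), wp$walk_length)
    expect_true(all(w == rep(c(w[1], setdiff(c("a", "b"), w[1])),
                             length.out = length(w))))
  }
  # the isolated node yields length-1 walks (still counted)
  iso <- walks[vapply(walks, function(w) w[1] == "iso", TRUE)]
  expect_length(iso, wp$walks_per_node)
  expect_true(all(lengths(iso) == 1L))
})

test_that("p=q=1 walks are first-order uniform (Monte-Carlo)", {
  # star centre with two leaves: successor of the centre should be ~50/50
  net <- net_from_edges(c("c", "l1"), c("c", "l2"))
  wp <- funalign::walk_params(walks_per_node = 150L, walk_length = 25L,
                              dim = 4L, window = 2L, seed = 5L)
  walks <- generate_walks(net, wp)
  succ <- unlist(lapply(walks, function(w) {
    if (length(w) < 2L) return(character())
    w[which(w[-length(w)] == "c") + 1L]
  }))
  expect_gt(length(succ), 5000)
  expect_equal(mean(succ == "l1"), 0.5, tolerance = 0.05)
})

test_that("walks and embeddings are deterministic under a fixed seed", {
  w <- small_world()
  ig <- build_integrated_network(w$network1, w$network2, w$anchors)
  wp <- wp_small()
  expect_identical(generate_walks(ig, wp), generate_walks(ig, wp))
  walks <- generate_walks(ig, wp)
  expect_equal(train_embedding(walks, wp), train_embedding(walks, wp))
  wp2 <- wp_small(); wp2$seed <- 12L
  expect_false(identical(generate_walks(ig, wp2), walks))
})

test_that("metapath walks obey the cycled type pattern", {
  w <- small_world()
  ig <- build_integrated_network(w$network1, w$network2, w$anchors)
  wp <- wp_small()
  walks <- generate_metapath_walks(ig, c(1L, 2L, 1L), wp)
  sp <- setNames(ig$nodes$species, ig$nodes$node)
  tags <- ig$species
  n_start <- sum(ig$nodes$species == tags[1])
  expect_length(walks, n_start * wp$walks_per_node)
  for (wk in walks) {
    types <- unname(sp[wk])
    expected <- tags[rep(c(1L, 2L), length.out = length(types))]
    expect_equal(types, expected)
  }
  expect_error(generate_metapath_walks(ig, c("sp1", "mars"), wp), "unknown species")
})

test_that("metapath walks truncate when no anchor exists", {
  nets <- toy_nets()
  empty_anchors <- anchor_set(tibble::tibble(node1 = character(),
                                             node2 = character()))
  ig <- build_integrated_network(nets$n1, nets$n2, empty_anchors)
  walks <- generate_metapath_walks(ig, c(1L, 2L, 1L), wp_small())
  expect_true(all(lengths(walks) == 1L))
})

test_that("embeddings reflect structural communities (barbell)", {
  cl <- function(tag) t(utils::combn(paste0(tag, 1:6), 2))
  edges <- rbind(cl("a"), cl("b"), c("a1", "b1"))
  net <- funalign::ppi_network(tibble::tibble(from = edges[, 1], to = edges[, 2]), "s")
  wp <- funalign::walk_params(walks_per_node = 10L, walk_length = 20L, dim = 16L,
                              window = 4L, epochs = 5L, seed = 3L)
  emb <- train_embedding(generate_walks(net, wp), wp)
  m <- as.matrix(emb[, -1]); rownames(m) <- emb$node
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  pair_mean <- function(nodes1, nodes2) {
    vals <- c()
    for (u in nodes1) for (v in nodes2) if (u < v) vals <- c(vals, cos(m[u, ], m[v, ]))
    mean(vals)
  }
  a_nodes <- paste0("a", 1:6); b_nodes <- paste0("b", 1:6)
  intra <- mean(c(pair_mean(a_nodes, a_nodes), pair_mean(b_nodes, b_nodes)))
  inter <- mean(vapply(a_nodes, function(u) {
    mean(vapply(b_nodes, function(v) cos(m[u, ], m[v, ]), 1))
  }, 1))
  expect_gt(intra, inter)
})

test_that("pair feature combination modes behave as documented", {
  expect_equal(pair_feature_embedding(c(1, 0), c(0, 1)), c(1, 0, 0, 1))
  expect_equal(pair_feature_embedding(c(1, 0), c(0, 1), mode = "hadamard"), c(0, 0))
  expect_equal(pair_feature_embedding(c(0, 0), c(0, 0)), rep(0, 4))
  expect_error(pair_feature_embedding(1:3, 1:2), "differ")

  emb <- tibble::tibble(node = c("s1:a", "s2:x"), dim1 = c(1, 3), dim2 = c(2, 4))
  pf <- embedding_pair_features(tibble::tibble(node1 = "a", node2 = "x"),
                                emb, species = c("s1", "s2"))
  expect_equal(unname(unlist(pf[1, -(1:2)])), c(1, 2, 3, 4))
})
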