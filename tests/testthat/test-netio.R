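test_that("edge lists are read as simple undirected graphs", {
  p <- write_lines_tmp(c("a\tb", "b\tc"))
  net <- read_edge_list(p, "y")
  expect_s3_class(net, "ppi_network")
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)

  # duplicates (either orientation) collapse, self-loops drop
  p2 <- write_lines_tmp(c("a\tb", "b\ta", "a\tb", "a\ta"))
  net2 <- suppressMessages(read_edge_list(p2, "y"))
  expect_equal(length(net2$nodes), 2L)
  expect_equal(nrow(net2$edges), 1L)

  # empty file: empty network plus a warning
  p3 <- write_lines_tmp(character())
  expect_warning(net3 <- read_edge_list(p3, "y"), "empty")
  expect_equal(length(net3$nodes), 0L)

  expect_error(read_edge_list(tempfile(), "y"), "not found")
  p4 <- write_lines_tmp(c("a\tb", "lonely"))
  expect_error(read_edge_list(p4, "y"), "line 2")
})

test_that("anchor lists honour E-value thresholds and set semantics", {
  p <- write_lines_tmp(c("a\tx", "b\tw"))
  expect_equal(nrow(read_anchor_list(p)), 2L)

  p2 <- write_lines_tmp(c("a\tx\t1e-9", "b\tw\t1e-5", "c\tz\t1e-8"))
  kept <- read_anchor_list(p2, evalue_threshold = 1e-7)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$node1, c("a", "c"))
  expect_equal(nrow(read_anchor_list(p2)), 3L)  # default keeps all

  p3 <- write_lines_tmp(c("a\tx", "a\tx", "b\tw"))
  expect_equal(nrow(read_anchor_list(p3)), 2L)
})

test_that("integration is additive with typed, species-consistent edges", {
  nets <- toy_nets()
  anchors <- anchor_set(tibble::tibble(node1 = c("a", "c"), node2 = c("x", "z")))
  ig <- build_integrated_network(nets$n1, nets$n2, anchors)
  expect_equal(nrow(ig$nodes), 3L + 4L)
  expect_equal(nrow(ig$edges), 2L + 3L + 2L)
  expect_setequal(unique(ig$edges$type), c("ppi_1", "ppi_2", "anchor"))

  # an anchor with an unknown endpoint is dropped with one warning
  bad <- anchor_set(tibble::tibble(node1 = c("a", "nope"), node2 = c("x", "z")))
  expect_warning(ig2 <- build_integrated_network(nets$n1, nets$n2, bad),
                 "dropped 1 anchor")
  expect_equal(sum(ig2$edges$type == "anchor"), 1L)

  # anchors never join same-species nodes
  sp <- setNames(ig$nodes$species, ig$nodes$node)
  an <- ig$edges[ig$edges$type == "anchor", ]
  expect_true(all(sp[an$from] != sp[an$to]))
})

test_that("overlapping ID spaces require namespacing", {
  n1 <- net_from_edges(c("a", "b"), species = "y")
  n2 <- net_from_edges(c("a", "c"), species = "h")
  anchors <- anchor_set(tibble::tibble(node1 = "b", node2 = "c"))
  expect_error(build_integrated_network(n1, n2, anchors, namespace = FALSE),
               "overlap")
  # an anchor endpoint in both ID spaces is ambiguous even when namespacing
  amb <- anchor_set(tibble::tibble(node1 = "a", node2 = "c"))
  expect_error(build_integrated_network(n1, n2, amb), "ambiguous")
  ig <- build_integrated_network(n1, n2, anchors)
  expect_equal(nrow(ig$nodes), 4L)
  expect_true(all(grepl("^(y|h):", ig$nodes$node)))
})

test_that("integration additivity holds on random worlds (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    n1 <- random_er_network(20, 0.2, species = "s1", seed = seed, prefix = "a")
    n2 <- random_er_network(25, 0.15, species = "s2", seed = seed + 100, prefix = "b")
    k <- 12L
    anchors <- anchor_set(tibble::tibble(
      node1 = sample(n1$nodes, k, replace = TRUE),
      node2 = sample(n2$nodes, k, replace = TRUE)
    ))
    ig <- build_integrated_network(n1, n2, anchors)
    expect_equal(nrow(ig$nodes), length(n1$nodes) + length(n2$nodes))
    expect_equal(nrow(ig$edges), nrow(n1$edges) + nrow(n2$edges) + nrow(anchors))
    # edge types partition the edge set
    tab <- table(factor(ig$edges$type, levels = c("ppi_1", "ppi_2", "anchor")))
    expect_equal(sum(tab), nrow(ig$edges))
    expect_equal(unname(tab[["anchor"]]), nrow(anchors))
    sp <- setNames(ig$nodes$species, ig$nodes$node)
    an <- ig$edges[ig$edges$type == "anchor", ]
    expect_true(all(sp[an$from] != sp[an$to]))
  }
})

test_that("typed edge-list round trip preserves the integrated structure", {
  w <- small_world()
  ig <- build_integrated_network(w$network1, w$network2, w$anchors)
  path <- tempfile(fileext = ".tsv")
  write_integrated_network(ig, path)
  back <- read_integrated_network(path)
  expect_setequal(back$nodes$node, ig$nodes$node)
  expect_equal(
    dplyr::arrange(back$nodes, node)$species,
    dplyr::arrange(ig$nodes, node)$species
  )
  canon <- function(e) dplyr::arrange(
    tibble::tibble(a = pmin(e$from, e$to), b = pmax(e$from, e$to), type = e$type),
    a, b, type)
  expect_equal(canon(back$edges), canon(ig$edges))
})
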