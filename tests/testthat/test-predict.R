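test_that("hypergeometric upper tail matches closed forms and edge cases", {
  expect_equal(hypergeom_upper_tail(10, 4, 3, 0), 1)
  expect_equal(hypergeom_upper_tail(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(20, 3, 3, 3), 1 / 1140, tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(4, 5, 2, 1), "invalid")
  expect_error(hypergeom_upper_tail(4, 2, 2, 3), "invalid")
})

test_that("hypergeometric upper tail equals exhaustive enumeration (M <= 12)", {
  for (M in c(2L, 5L, 8L, 12L)) {
    for (N in 0:M) {
      for (O in 0:M) {
        for (P in 0:min(N, O)) {
          expect_equal(hypergeom_upper_tail(M, N, O, P),
                       enumerate_upper_tail(M, N, O, P),
                       tolerance = 1e-12,
                       info = sprintf("M=%d N=%d O=%d P=%d", M, N, O, P))
        }
      }
    }
  }
})

make_gt <- function(ann, nets, k = 1, rarity = "ALL") {
  suppressWarnings(funalign::build_ground_truth(ann, nets$n1, nets$n2,
                                                k = k, rarity = rarity))
}

test_that("annotation transfer requires enrichment plus an annotated partner", {
  # 5 eligible proteins in species 1 (3 carry g1), 4 in species 2 (1 carries
  # g1): M = 20 pairs, N = 3, and an alignment of the 3 g1-sharing pairs
  # gives O = 3, P = 3, p = 1/C(20,3) ~ 8.77e-4 < 0.05.
  n1 <- net_from_edges(c("a", "b"), c("c", "d"), species = "y",
                       nodes = c("a", "b", "c", "d", "e"))
  n2 <- net_from_edges(c("x", "z"), c("t", "u"), species = "h",
                       nodes = c("x", "z", "t", "u"))
  ann <- funalign::annotation_set(tibble::tibble(
    protein = c("a", "b", "c", "x", "d", "e", "z", "t", "u"),
    term = c("g1", "g1", "g1", "g1", "s1", "s2", "s3", "s4", "s5"),
    evidence = "EXP", aspect = "P"
  ))
  gt <- make_gt(ann, list(n1 = n1, n2 = n2))
  al <- tibble::tibble(node1 = c("a", "b", "c"), node2 = c("x", "x", "x"),
                       prob = 0.9)
  class(al) <- c("alignment", class(al))
  preds <- suppressMessages(predict_annotations(al, gt, n1, n2, alpha = 0.05))
  enr <- attr(preds, "enrichment")
  expect_equal(enr$p_value[enr$term == "g1"], 1 / choose(20, 3),
               tolerance = 1e-12)
  # g1 transfers to every aligned protein with a g1-annotated partner
  expect_setequal(paste(preds$protein, preds$term),
                  c("a g1", "b g1", "c g1", "x g1"))
  # singleton terms are never enriched or transferred
  expect_false(any(preds$term != "g1"))
  expect_error(predict_annotations(al[0, ], gt, n1, n2), "empty")
  expect_error(predict_annotations(al, gt, n1, n2, alpha = 1.5), "alpha")
})

test_that("no-enrichment alignments yield an empty prediction set", {
  n1 <- net_from_edges(c("a", "b"), species = "y", nodes = c("a", "b", "c", "d"))
  n2 <- net_from_edges(c("x", "w"), species = "h", nodes = c("x", "w", "z", "t"))
  # every protein has a unique term: nothing can be shared or enriched
  ann <- funalign::annotation_set(tibble::tibble(
    protein = c(n1$nodes, n2$nodes),
    term = paste0("g", seq_len(8)),
    evidence = "EXP", aspect = "P"
  ))
  gt <- make_gt(ann, list(n1 = n1, n2 = n2))
  al <- tibble::tibble(node1 = "a", node2 = "x", prob = 0.9)
  expect_message(
    preds <- predict_annotations(al, gt, n1, n2),
    "no GO term enriched")
  expect_equal(nrow(preds), 0L)
})

test_that("precision and recall are set arithmetic over associations", {
  nets <- list(
    n1 = net_from_edges(c("a", "b"), species = "y", nodes = c("a", "b", "c")),
    n2 = net_from_edges(c("x", "w"), species = "h")
  )
  truth_ann <- funalign::annotation_set(tibble::tibble(
    protein = c("a", "b", "c"),
    term = c("g1", "g1", "g3"),
    evidence = "EXP", aspect = "P"
  ))
  gt <- make_gt(truth_ann, nets)
  pred <- tibble::tibble(protein = c("a", "a", "b"),
                         term = c("g1", "g2", "g1"),
                         p_value = 0.01)
  pr <- precision_recall(pred, gt)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 2 / 3)
  same <- precision_recall(
    dplyr::mutate(funalign::truth_associations(gt), p_value = 0.01), gt)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  disj <- precision_recall(tibble::tibble(protein = "a", term = "nope",
                                          p_value = 0.01), gt)
  expect_equal(disj$precision, 0)
  expect_equal(disj$recall, 0)
  expect_message(empty <- precision_recall(pred[0, ], gt), "precision reported as 1")
  expect_equal(empty$precision, 1)
})

test_that("prediction-set intersection and difference are true set operations", {
  ps <- function(keys) {
    out <- tibble::tibble(protein = sub(" .*", "", keys),
                          term = sub(".* ", "", keys), p_value = 0.01)
    attr(out, "provenance") <- list(k = 1L, rarity = "ALL")
    class(out) <- c("prediction_set", class(out))
    out
  }
  p1 <- ps(c("a g1", "a g2", "b g1"))
  p2 <- ps(c("a g2", "b g1", "c g3"))
  inter <- intersect_predictions(p1, p2)
  expect_setequal(paste(inter$protein, inter$term), c("a g2", "b g1"))
  expect_equal(attr(inter, "provenance")$source, "consensus")
  expect_equal(nrow(intersect_predictions(p1, p1)), nrow(p1))  # idempotent
  expect_warning(intersect_predictions(p1, ps("z g9")), "disjoint")

  diff <- difference_predictions(p1, p2)
  expect_setequal(paste(diff$protein, diff$term), "a g1")
  expect_equal(nrow(difference_predictions(p1, p1)), 0L)
  expect_equal(nrow(difference_predictions(p1, ps(character(0)))), nrow(p1))

  p_other <- ps("a g1")
  attr(p_other, "provenance")$rarity <- "50"
  expect_error(intersect_predictions(p1, p_other), "different ground truth")
})

test_that("consensus recall never exceeds either source's recall", {
  w <- small_world()
  gt <- suppressWarnings(build_ground_truth(w$annotations, w$network1,
                                            w$network2, k = 1, rarity = "ALL"))
  grid <- experiment_grid(
    feature_versions = c("graphlets_integrated", "graphlets_isolated"),
    y = 50L, n_replicates = 2L, n_splits = 2L,
    consensus = c("graphlets_isolated", "graphlets_integrated"))
  ex <- suppressMessages(suppressWarnings(run_experiment(
    w$network1, w$network2, w$anchors, w$annotations, grid)))
  by_rep <- split(ex$predictions, ex$predictions$replicate)
  for (chunk in by_rep) {
    cons <- chunk[chunk$version == "consensus", ]
    if (nrow(cons) == 0L) next
    for (v in grid$consensus) {
      src <- chunk[chunk$version == v, ]
      expect_lte(cons$recall, src$recall + 1e-12)
    }
  }
})
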