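fake_pairs <- function(n_pos, n_neg) {
  tibble::tibble(
    node1 = paste0("u", seq_len(n_pos + n_neg)),
    node2 = paste0("v", seq_len(n_pos + n_neg)),
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
}

test_that("balanced datasets keep all positives and resample negatives", {
  lp <- fake_pairs(5, 100)
  reps <- make_balanced_datasets(lp, n = 10, base_seed = 1)
  expect_length(reps, 10L)
  negs <- lapply(reps, function(b) sort(b$node1[b$label == 0L]))
  for (b in reps) {
    expect_equal(nrow(b), 10L)
    expect_equal(sum(b$label), 5L)
    expect_setequal(b$node1[b$label == 1L], paste0("u", 1:5))
  }
  expect_gt(length(unique(negs)), 1L)  # subsamples generally differ
  # equal classes force identical replicates
  same <- make_balanced_datasets(fake_pairs(4, 4), n = 3, base_seed = 1)
  expect_identical(sort(same[[1]]$node1), sort(same[[2]]$node1))
  expect_error(make_balanced_datasets(fake_pairs(5, 3)), "undersampling")
  expect_error(make_balanced_datasets(fake_pairs(0, 3)), "no positive")
})

test_that("stratified splits are balanced, disjoint and seed-reproducible", {
  bal <- make_balanced_datasets(fake_pairs(10, 50), n = 1, base_seed = 1)[[1]]
  splits <- stratified_split(bal, y = 50, n_splits = 10, base_seed = 0)
  expect_length(splits, 10L)
  for (sp in splits) {
    expect_equal(sum(sp$train$label), 5L)
    expect_equal(sum(sp$train$label == 0L), 5L)
    expect_equal(sum(sp$test$label), 5L)
    expect_equal(nrow(dplyr::inner_join(sp$train, sp$test,
                                        by = c("node1", "node2"))), 0L)
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(bal))
  }
  s90 <- stratified_split(bal, y = 90, n_splits = 1)[[1]]
  expect_equal(sum(s90$train$label), 9L)
  expect_equal(sum(s90$test$label), 1L)
  # the first split is seeded with exactly base_seed (0 by default)
  again <- stratified_split(bal, y = 50, n_splits = 1, base_seed = 0)[[1]]
  expect_identical(again$train[, c("node1", "node2")],
                   splits[[1]]$train[, c("node1", "node2")])
  expect_equal(splits[[1]]$seed, 0L)
  expect_error(stratified_split(bal, y = 2), "infeasible")
})

test_that("the classifier separates separable data and is calibrated on noise", {
  # 1-D separable
  sep <- tibble::tibble(f1 = c(rep(-1, 20), rep(1, 20)),
                        label = rep(0:1, each = 20))
  m <- train_classifier(sep)
  expect_equal(mean(predict(m, sep)$pred == sep$label), 1.0)
  expect_error(train_classifier(sep[1:20, ]), "single class")

  # null: labels independent of features -> held-out AUROC ~ 0.5
  set.seed(99)
  null_d <- tibble::tibble(f1 = rnorm(200), f2 = rnorm(200),
                           label = rep(0:1, 100))
  idx <- sample(200, 100)
  m0 <- train_classifier(null_d[idx, ])
  e0 <- evaluate_classifier(m0, null_d[-idx, ])
  expect_gt(e0$auroc, 0.4)
  expect_lt(e0$auroc, 0.6)

  # strong planted signal -> held-out AUROC > 0.95
  set.seed(100)
  lab <- rep(0:1, 150)
  sig <- tibble::tibble(f1 = lab * 3 + rnorm(300), f2 = lab * 3 + rnorm(300),
                        label = lab)
  idx <- sample(300, 150)
  ms <- train_classifier(sig[idx, ])
  expect_gt(evaluate_classifier(ms, sig[-idx, ])$auroc, 0.95)
})

test_that("evaluation metrics behave at the extremes", {
  d <- tibble::tibble(f1 = c(-2, -1, 1, 2), label = c(0L, 0L, 1L, 1L))
  m <- train_classifier(d)
  e <- evaluate_classifier(m, d)
  expect_equal(e$accuracy, 1.0)
  expect_equal(e$auroc, 1.0)
  # reversed ranking scores 0
  rev_d <- dplyr::mutate(d, label = rev(label))
  expect_equal(evaluate_classifier(m, rev_d)$auroc, 0.0)
  one_class <- dplyr::mutate(d, label = 1L)
  expect_message(e1 <- evaluate_classifier(m, one_class), "AUROC undefined")
  expect_true(is.na(e1$auroc))
})

test_that("two-level aggregation averages splits within replicates first", {
  grid <- tidyr::expand_grid(replicate = 1:2, split = 0:4)
  g1 <- dplyr::mutate(grid, accuracy = 0.8, auroc = 0.8)
  expect_equal(aggregate_metrics(g1)$accuracy, 0.8)
  # replicate means {0.6, 0.8} -> 0.7 even with unequal split counts
  g2 <- dplyr::bind_rows(
    tibble::tibble(replicate = 1, split = 0:3, accuracy = 0.6, auroc = 0.6),
    tibble::tibble(replicate = 2, split = 0:1, accuracy = 0.8, auroc = 0.8)
  )
  expect_equal(aggregate_metrics(g2)$accuracy, 0.7)
  expect_equal(aggregate_metrics(g2)$auroc, 0.7)
  expect_error(aggregate_metrics(g1[0, ]), "empty")
})

test_that("alignments come from the testing set only, above the threshold", {
  bal <- make_balanced_datasets(fake_pairs(10, 40), n = 1, base_seed = 2)[[1]]
  feats <- dplyr::mutate(bal[, c("node1", "node2")],
                         f1 = ifelse(bal$label == 1L, 1.5, -1.5) + rnorm(20, sd = 0.3))
  sp <- stratified_split(bal, y = 50, n_splits = 1)[[1]]
  train <- dplyr::inner_join(feats, sp$train, by = c("node1", "node2"))
  m <- train_classifier(train, provenance = list(key = sp$key))
  al <- build_alignment(m, sp, feats)
  expect_s3_class(al, "alignment")
  expect_true(all(al$prob >= 0.5))
  expect_equal(nrow(dplyr::inner_join(al, sp$train, by = c("node1", "node2"))), 0L)
  # all alignment pairs are test pairs
  expect_equal(nrow(dplyr::anti_join(al, sp$test, by = c("node1", "node2"))), 0L)
  # provenance guard refuses a different split
  sp2 <- stratified_split(bal, y = 50, n_splits = 2)[[2]]
  expect_error(build_alignment(m, sp2, feats), "circularity")
})
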