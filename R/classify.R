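# The classification protocol: balanced datasets, stratified y/(100-y)
# splits, logistic regression, two-level metric aggregation, and alignment
# construction from held-out predictions.

#' Create balanced datasets by undersampling negatives
#'
#' Each replicate keeps every positive pair and a uniform subsample of the
#' negative pairs of equal size; replicate `i` uses seed `base_seed + i`.
#'
#' @param pairs A `labeled_pairs` tibble (columns `node1`, `node2`, `label`).
#' @param n Number of balanced replicates (10 in the standard protocol).
#' @param base_seed Base RNG seed.
#' @return A list of `n` tibbles, each with attributes `replicate` and `seed`.
#' @export
make_balanced_datasets <- function(pairs, n = 10L, base_seed = 1L) {
  pos <- dplyr::filter(pairs, .data$label == 1L)
  neg <- dplyr::filter(pairs, .data$label == 0L)
  if (nrow(pos) == 0L) abort("no positive pairs: cannot build balanced datasets")
  if (nrow(neg) < nrow(pos)) {
    abort(sprintf("fewer negatives (%d) than positives (%d): undersampling impossible",
                  nrow(neg), nrow(pos)))
  }
  lapply(seq_len(n), function(i) {
    seed <- base_seed + i
    sub <- local_seed(seed, neg[sample.int(nrow(neg), nrow(pos)), ])
    out <- bind_rows(pos, sub)
    attr(out, "replicate") <- i
    attr(out, "seed") <- seed
    out
  })
}

split_key <- function(replicate, y, split) {
  sprintf("rep%s_y%s_split%s", replicate %||% "NA", y, split)
}

#' Stratified train/test splits of a balanced dataset
#'
#' Split `j` (0-based; the "first" split is `j = 0`, seeded with
#' `base_seed + j`, i.e. seed 0 under the defaults) samples `y` percent of
#' each class into the training side and the rest into testing, so both
#' sides stay 50/50 balanced up to rounding.
#'
#' @param balanced One balanced dataset from [make_balanced_datasets()].
#' @param y Training percentage, strictly between 0 and 100.
#' @param n_splits Number of random splits (10 in the standard protocol).
#' @param base_seed Base seed; the first split uses exactly this seed.
#' @return A list of `split_spec` objects: lists with `train`, `test`
#'   (tibbles), `y`, `split` (0-based index), `seed`, `replicate`, `key`.
#' @export
stratified_split <- function(balanced, y, n_splits = 10L, base_seed = 0L) {
  if (y <= 0 || y >= 100) abort("`y` must be strictly between 0 and 100")
  replicate <- attr(balanced, "replicate")
  pos <- dplyr::filter(balanced, .data$label == 1L)
  neg <- dplyr::filter(balanced, .data$label == 0L)
  lapply(seq_len(n_splits) - 1L, function(j) {
    seed <- base_seed + j
    pick <- function(df) {
      n_tr <- round(y / 100 * nrow(df))
      if (n_tr < 1L || n_tr >= nrow(df)) {
        abort(sprintf("split infeasible: %d pairs per class cannot give a non-empty %d/%d split",
                      nrow(df), y, 100 - y))
      }
      idx <- sample.int(nrow(df), n_tr)
      list(train = df[idx, ], test = df[-idx, ])
    }
    parts <- local_seed(seed, list(pos = pick(pos), neg = pick(neg)))
    structure(list(
      train = bind_rows(parts$pos$train, parts$neg$train),
      test  = bind_rows(parts$pos$test, parts$neg$test),
      y = y, split = j, seed = seed, replicate = replicate,
      key = split_key(replicate, y, j)
    ), class = "split_spec")
  })
}

feature_columns <- function(data, label_col = "label") {
  num <- vapply(data, is.numeric, TRUE)
  setdiff(names(data)[num], c(label_col, "prob"))
}

#' Train the pair classifier
#'
#' Fits an L2-penalised logistic regression (ridge penalty of strength
#' `1/(n * C)` in the glmnet parameterisation, i.e. unit inverse
#' regularisation strength `C = 1` by default; deterministic coordinate
#' descent, unstandardised features). All numeric columns except the label
#' are used as features.
#'
#' @param data Data frame of features plus a 0/1 `label` column.
#' @param label_col Name of the label column.
#' @param C Inverse regularisation strength.
#' @param threshold Decision threshold on the predicted probability.
#' @param provenance Optional list tying the model to its training split
#'   (set by the pipeline; used by [build_alignment()]'s circularity guard).
#' @return An object of class `funalign_model`.
#' @export
train_classifier <- function(data, label_col = "label", C = 1, threshold = 0.5,
                             provenance = NULL) {
  y <- data[[label_col]]
  if (is.null(y)) abort(sprintf("no '%s' column in training data", label_col))
  if (length(unique(y)) < 2L) abort("training data contains a single class")
  fcols <- feature_columns(data, label_col)
  if (length(fcols) == 0L) abort("no numeric feature columns found")
  x <- as.matrix(data[fcols])
  if (any(!is.finite(x))) abort("non-finite feature values")
  # glmnet needs >= 2 columns; a constant dummy is shrunk to zero
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, `.pad` = 0)
  lambda <- 1 / (nrow(x) * C)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = lambda, standardize = FALSE,
                   thresh = 1e-10),
    warning = function(w) {
      # small balanced splits routinely trip glmnet's class-size caution
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(fit = fit, features = fcols, padded = padded, C = C,
                 threshold = threshold, n_train = nrow(x),
                 provenance = provenance),
            class = "funalign_model")
}

#' @export
print.funalign_model <- function(x, ...) {
  cat(sprintf("<funalign_model: logistic ridge, %d features, n=%d, C=%g, threshold=%g>\n",
              length(x$features), x$n_train, x$C, x$threshold))
  invisible(x)
}

#' Predict related-pair probabilities
#'
#' @param object A [train_classifier()] model.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return `newdata` with added columns `prob` (predicted probability of
#'   functional relatedness) and `pred` (0/1 at the model threshold).
#' @export
predict.funalign_model <- function(object, newdata, ...) {
  x <- as.matrix(as_tibble(newdata)[object$features])
  if (object$padded) x <- cbind(x, `.pad` = 0)
  p <- as.numeric(predict(object$fit, newx = x, type = "response"))
  out <- as_tibble(newdata)
  out$prob <- p
  out$pred <- as.integer(p >= object$threshold)
  out
}

#' @export
tidy.funalign_model <- function(x, ...) {
  co <- as.matrix(stats::coef(x$fit))
  tibble(term = rownames(co), estimate = as.numeric(co)) |>
    dplyr::filter(.data$term != ".pad")
}

#' @export
glance.funalign_model <- function(x, ...) {
  tibble(n_train = x$n_train, n_features = length(x$features),
         C = x$C, threshold = x$threshold)
}

#' Evaluate a trained classifier on a test set
#'
#' Accuracy at the model threshold plus AUROC from the predicted
#' probabilities (trapezoidal, midrank tie handling; a reversed ranking
#' scores 0). A single-class test set has no defined AUROC: it is reported
#' as `NA` with a message.
#'
#' @param model A `funalign_model`.
#' @param test Data frame of features plus `label`.
#' @param label_col Name of the label column.
#' @return A one-row tibble: `accuracy`, `auroc`, `n_test`.
#' @export
evaluate_classifier <- function(model, test, label_col = "label") {
  if (nrow(test) == 0L) abort("empty test set")
  scored <- predict(model, test)
  y <- test[[label_col]]
  acc <- mean(scored$pred == y)
  auroc <- if (length(unique(y)) < 2L) {
    inform("single-class test set: AUROC undefined, reported as NA")
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = scored$prob,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  }
  tibble(accuracy = acc, auroc = auroc, n_test = nrow(test))
}

#' Two-level averaging of the metrics grid
#'
#' Averages accuracy and AUROC over the splits within each balanced
#' replicate, then over the replicates, yielding the final score for one
#' (feature version, dataset, y) cell. Missing AUROC entries (single-class
#' test sets) are excluded from the means and counted.
#'
#' @param metrics Tibble with columns `replicate`, `split`, `accuracy`,
#'   `auroc` (extra columns are ignored).
#' @return A one-row tibble: `accuracy`, `auroc`, `n_missing_auroc`.
#' @export
aggregate_metrics <- function(metrics) {
  if (nrow(metrics) == 0L) abort("empty metrics grid")
  per_rep <- metrics |>
    group_by(.data$replicate) |>
    summarise(accuracy = mean(.data$accuracy),
              auroc = mean(.data$auroc, na.rm = TRUE),
              .groups = "drop")
  tibble(
    accuracy = mean(per_rep$accuracy),
    auroc = mean(per_rep$auroc, na.rm = TRUE),
    n_missing_auroc = sum(is.na(metrics$auroc))
  )
}

#' Build an alignment from a split's testing set
#'
#' The alignment is the set of testing-set pairs the model predicts as
#' functionally related (probability at or above the threshold). Because it
#' is drawn from the testing side only, it cannot contain trained-on pairs;
#' this is asserted, and a model whose provenance names a different split
#' is rejected.
#'
#' @param model A `funalign_model` trained on `split$train`'s features.
#' @param split A `split_spec` from [stratified_split()].
#' @param features Pair-feature table (`node1`, `node2`, numeric columns)
#'   covering the split's test pairs.
#' @return A tibble of class `alignment` (`node1`, `node2`, `prob`) with a
#'   `provenance` attribute.
#' @export
build_alignment <- function(model, split, features) {
  stopifnot(inherits(split, "split_spec"))
  if (!is.null(model$provenance$key) && !identical(model$provenance$key, split$key)) {
    abort(sprintf("model was trained for split '%s', not '%s' (circularity guard)",
                  model$provenance$key, split$key))
  }
  test_feats <- inner_join(split$test[, c("node1", "node2")], features,
                           by = c("node1", "node2"))
  if (nrow(test_feats) != nrow(split$test)) {
    abort("feature table does not cover all test pairs")
  }
  scored <- predict(model, test_feats)
  out <- scored[scored$pred == 1L, c("node1", "node2", "prob")]
  if (nrow(out) == 0L) warn("empty alignment: no test pair predicted related")
  leaked <- inner_join(out, split$train, by = c("node1", "node2"))
  stopifnot(nrow(leaked) == 0L)
  attr(out, "provenance") <- list(y = split$y, split = split$split,
                                  replicate = split$replicate, key = split$key,
                                  feature_version = model$provenance$feature_version)
  class(out) <- c("alignment", class(out))
  out
}

#' Write an alignment as TSV
#'
#' Columns `node1`, `node2`, `prob`.
#'
#' @param alignment An `alignment` tibble.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  readr::write_tsv(alignment[, c("node1", "node2", "prob")], path, col_names = FALSE)
  invisible(path)
}
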