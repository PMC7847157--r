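# Orchestration: the full experiment grid (feature versions x ground
# truth-rarity datasets x training percentages x balanced replicates),
# alignment construction, functional prediction and the consensus ensemble.

#' Define an experiment grid
#'
#' @param feature_versions Subset of `"graphlets_integrated"`,
#'   `"graphlets_isolated"`, `"walks"`, `"metapath_walks"`. The first counts
#'   graphlet orbits on the integrated network, the second on each species'
#'   network separately (topology only), the last two embed the integrated
#'   network via unconstrained / metapath-constrained random walks.
#' @param k Shared-term thresholds to evaluate (e.g. `1:3`).
#' @param rarity Rarity thresholds (`"ALL"`, `50`, `25`, ...).
#' @param y Training percentages, integers within 10..90.
#' @param n_replicates Balanced datasets per ground-truth configuration.
#' @param n_splits Random stratified splits per (replicate, y).
#' @param balanced_seed,split_seed Base seeds for the two sampling layers;
#'   the first split uses exactly `split_seed` (0 by default).
#' @param alpha Enrichment significance level for functional prediction.
#' @param walk [walk_params()] for the embedding versions.
#' @param metapath Metapath for `"metapath_walks"` (default alternates the
#'   two species, forcing anchor traversal).
#' @param embedding_combiner How the two nodes' embedding vectors combine
#'   into a pair feature: `"hadamard"` (elementwise product, the standard
#'   choice for pair prediction with a linear classifier, default) or
#'   `"concat"` (ordered concatenation).
#' @param C,threshold Classifier settings (see [train_classifier()]).
#' @param consensus Character(2) naming the two feature versions whose
#'   prediction overlap forms the consensus ensemble, or `NULL` to skip.
#' @return A list of class `experiment_grid`.
#' @export
experiment_grid <- function(feature_versions = c("graphlets_integrated", "walks",
                                                 "metapath_walks"),
                            k = 1L, rarity = "ALL", y = seq(10L, 90L, by = 10L),
                            n_replicates = 10L, n_splits = 10L,
                            balanced_seed = 1L, split_seed = 0L, alpha = 0.05,
                            walk = walk_params(), metapath = c(1L, 2L, 1L),
                            embedding_combiner = c("hadamard", "concat"),
                            C = 1, threshold = 0.5, consensus = NULL) {
  embedding_combiner <- match.arg(embedding_combiner)
  known <- c("graphlets_integrated", "graphlets_isolated", "walks", "metapath_walks")
  if (length(feature_versions) == 0L || !all(feature_versions %in% known)) {
    abort(sprintf("feature_versions must be a non-empty subset of: %s",
                  paste(known, collapse = ", ")))
  }
  if (length(y) == 0L || any(y < 10 | y > 90)) {
    abort("training percentages must lie within 10..90")
  }
  if (is.null(consensus) && length(feature_versions) >= 2L) {
    gl <- intersect(c("graphlets_isolated", "graphlets_integrated"), feature_versions)
    em <- intersect(c("walks", "metapath_walks"), feature_versions)
    if (length(gl) > 0L && length(em) > 0L) consensus <- c(gl[1L], em[1L])
  }
  structure(list(feature_versions = feature_versions, k = as.integer(k),
                 rarity = rarity, y = as.integer(y),
                 n_replicates = as.integer(n_replicates),
                 n_splits = as.integer(n_splits),
                 balanced_seed = as.integer(balanced_seed),
                 split_seed = as.integer(split_seed), alpha = alpha,
                 walk = walk, metapath = metapath,
                 embedding_combiner = embedding_combiner, C = C,
                 threshold = threshold, consensus = consensus),
            class = "experiment_grid")
}

# Per-version node representations on the integrated (or isolated) networks.
compute_node_features <- function(net1, net2, integrated, grid) {
  out <- list()
  for (v in grid$feature_versions) {
    out[[v]] <- switch(
      v,
      graphlets_integrated = list(orbits = count_orbits(integrated)),
      graphlets_isolated = list(orbits1 = count_orbits(net1),
                                orbits2 = count_orbits(net2)),
      walks = list(embedding = train_embedding(
        generate_walks(integrated, grid$walk), grid$walk)),
      metapath_walks = list(embedding = train_embedding(
        generate_metapath_walks(integrated, grid$metapath, grid$walk), grid$walk))
    )
  }
  out
}

pair_features_for <- function(version, pairs, node_feats, species,
                              combiner = "hadamard") {
  nf <- node_feats[[version]]
  switch(version,
         graphlets_integrated = graphlet_pair_features(pairs, nf$orbits,
                                                       species = species),
         graphlets_isolated = graphlet_pair_features(pairs, nf$orbits1, nf$orbits2),
         embedding_pair_features(pairs, nf$embedding, species = species,
                                 mode = combiner))
}

#' Run the full supervised alignment experiment
#'
#' Integrates the two networks, extracts per-version pair features, builds
#' the ground truth-rarity datasets, runs the balanced-classification
#' protocol over the grid, constructs one alignment per (feature version,
#' y, balanced replicate) from the first split, transfers GO terms from
#' each alignment, and (optionally) intersects two versions' prediction
#' sets into the consensus ensemble. Ground-truth cells too small to split
#' are skipped and recorded.
#'
#' @param net1,net2 The two [ppi_network()]s.
#' @param anchors An [anchor_set()].
#' @param annotations The full [annotation_set()].
#' @param grid An [experiment_grid()].
#' @param out_dir Optional directory for artifacts (metrics CSV, alignment
#'   and prediction TSVs, manifest JSON).
#' @return An object of class `funalign_experiment`: list with `metrics`
#'   (per-split tibble), `summary` (two-level averages per cell),
#'   `alignments` (tibble with a list-column), `predictions` (per-alignment
#'   precision/recall tibble with list-column of prediction sets),
#'   `skipped` (tibble), `manifest`, `grid`.
#' @export
run_experiment <- function(net1, net2, anchors, annotations,
                           grid = experiment_grid(), out_dir = NULL) {
  integrated <- build_integrated_network(net1, net2, anchors)
  node_feats <- compute_node_features(net1, net2, integrated, grid)
  species <- integrated$species

  metrics <- list(); alignments <- list(); predictions <- list()
  skipped <- list()

  gt_cells <- tidyr::expand_grid(k = grid$k, rarity = grid$rarity)
  for (ci in seq_len(nrow(gt_cells))) {
    k <- gt_cells$k[[ci]]; rarity <- gt_cells$rarity[[ci]]
    rar_lab <- as.character(rarity)
    gt <- tryCatch(
      suppressWarnings(build_ground_truth(annotations, net1, net2,
                                          k = k, rarity = rarity)),
      error = function(e) NULL)
    n_pos <- if (is.null(gt)) 0L else sum(gt$pairs$label == 1L)
    n_neg <- if (is.null(gt)) 0L else sum(gt$pairs$label == 0L)
    feasible <- n_pos >= 1L && n_neg >= n_pos &&
      all(vapply(grid$y, function(yv) {
        n_tr <- round(yv / 100 * n_pos)
        n_tr >= 1L && n_tr <= n_pos - 1L
      }, TRUE))
    if (!feasible) {
      skipped[[length(skipped) + 1L]] <- tibble(
        k = k, rarity = rar_lab, n_positives = n_pos,
        reason = "too small to perform classification")
      next
    }
    balanced <- make_balanced_datasets(gt$pairs, grid$n_replicates,
                                       grid$balanced_seed)
    all_pairs <- distinct(bind_rows(balanced)[, c("node1", "node2")])
    feats <- lapply(grid$feature_versions, function(v) {
      pair_features_for(v, all_pairs, node_feats, species,
                        combiner = grid$embedding_combiner %||% "hadamard")
    })
    names(feats) <- grid$feature_versions

    for (v in grid$feature_versions) {
      fv <- feats[[v]]
      for (rep_i in seq_along(balanced)) {
        bal <- balanced[[rep_i]]
        bal_feats <- inner_join(bal, fv, by = c("node1", "node2"))
        for (yv in grid$y) {
          splits <- stratified_split(bal, yv, grid$n_splits, grid$split_seed)
          models <- vector("list", length(splits))
          for (si in seq_along(splits)) {
            sp <- splits[[si]]
            train <- semi_join(bal_feats, sp$train, by = c("node1", "node2"))
            test <- semi_join(bal_feats, sp$test, by = c("node1", "node2"))
            models[[si]] <- train_classifier(train, C = grid$C,
                                             threshold = grid$threshold,
                                             provenance = list(key = sp$key,
                                                               feature_version = v))
            em <- evaluate_classifier(models[[si]], test)
            metrics[[length(metrics) + 1L]] <- dplyr::bind_cols(
              tibble(version = v, k = k, rarity = rar_lab, y = yv,
                     replicate = rep_i, split = sp$split), em)
          }
          # alignment from the first split only (seed split_seed)
          al <- withCallingHandlers(
            build_alignment(models[[1L]], splits[[1L]], fv),
            warning = function(w) invokeRestart("muffleWarning"))
          alignments[[length(alignments) + 1L]] <- tibble(
            version = v, k = k, rarity = rar_lab, y = yv, replicate = rep_i,
            n_pairs = nrow(al), alignment = list(al))
          pred <- if (nrow(al) > 0L) {
            suppressMessages(predict_annotations(al, gt, net1, net2,
                                                 alpha = grid$alpha))
          } else NULL
          pr <- if (is.null(pred)) {
            tibble(precision = NA_real_, recall = 0, n_predictions = 0L,
                   n_truth = nrow(truth_associations(gt)))
          } else {
            suppressMessages(precision_recall(pred, gt, alignment = al))[
              , c("precision", "recall", "n_predictions", "n_truth")]
          }
          predictions[[length(predictions) + 1L]] <- dplyr::bind_cols(
            tibble(version = v, k = k, rarity = rar_lab, y = yv,
                   replicate = rep_i), pr,
            tibble(prediction_set = list(pred)))
        }
      }
    }
  }

  metrics <- bind_rows(metrics)
  alignments <- bind_rows(alignments)
  predictions <- bind_rows(predictions)
  skipped <- if (length(skipped) > 0L) bind_rows(skipped) else
    tibble(k = integer(), rarity = character(), n_positives = integer(),
           reason = character())

  # consensus ensemble: overlap of the two configured versions' predictions
  if (!is.null(grid$consensus) && nrow(predictions) > 0L &&
      all(grid$consensus %in% predictions$version)) {
    base <- dplyr::filter(predictions, .data$version == grid$consensus[1L])
    other <- dplyr::filter(predictions, .data$version == grid$consensus[2L])
    joint <- inner_join(
      base[, c("k", "rarity", "y", "replicate", "prediction_set", "n_truth")],
      other[, c("k", "rarity", "y", "replicate", "prediction_set")],
      by = c("k", "rarity", "y", "replicate"),
      suffix = c("_1", "_2"))
    cons <- purrr::pmap_dfr(joint, function(k, rarity, y, replicate,
                                            prediction_set_1, n_truth,
                                            prediction_set_2) {
      if (is.null(prediction_set_1) || is.null(prediction_set_2)) {
        return(tibble(version = "consensus", k = k, rarity = rarity, y = y,
                      replicate = replicate, precision = NA_real_, recall = 0,
                      n_predictions = 0L, n_truth = n_truth,
                      prediction_set = list(NULL)))
      }
      pc <- suppressWarnings(intersect_predictions(prediction_set_1,
                                                   prediction_set_2))
      tibble(version = "consensus", k = k, rarity = rarity, y = y,
             replicate = replicate, prediction_set = list(pc),
             n_predictions = nrow(pc))
    })
    # score consensus sets against their ground truth
    if (nrow(cons) > 0L) {
      gt_cache <- list()
      cons_scored <- purrr::map_dfr(seq_len(nrow(cons)), function(i) {
        row <- cons[i, ]
        keyc <- paste(row$k, row$rarity)
        if (is.null(gt_cache[[keyc]])) {
          rar <- if (row$rarity == "ALL") "ALL" else as.numeric(row$rarity)
          gt_cache[[keyc]] <<- suppressWarnings(
            build_ground_truth(annotations, net1, net2, k = row$k, rarity = rar))
        }
        ps <- row$prediction_set[[1L]]
        pr <- if (is.null(ps)) {
          tibble(precision = NA_real_, recall = 0, n_predictions = 0L,
                 n_truth = nrow(truth_associations(gt_cache[[keyc]])))
        } else {
          suppressMessages(precision_recall(ps, gt_cache[[keyc]]))[
            , c("precision", "recall", "n_predictions", "n_truth")]
        }
        dplyr::bind_cols(row[, c("version", "k", "rarity", "y", "replicate")],
                         pr, row[, "prediction_set"])
      })
      predictions <- bind_rows(predictions, cons_scored)
    }
  }

  summary <- if (nrow(metrics) > 0L) {
    metrics |>
      group_by(.data$version, .data$k, .data$rarity, .data$y) |>
      dplyr::group_modify(~ aggregate_metrics(.x)) |>
      ungroup()
  } else tibble()

  manifest <- list(
    feature_versions = grid$feature_versions,
    k = grid$k, rarity = as.character(grid$rarity), y = grid$y,
    n_replicates = grid$n_replicates, n_splits = grid$n_splits,
    balanced_seed = grid$balanced_seed, split_seed = grid$split_seed,
    alpha = grid$alpha, C = grid$C, threshold = grid$threshold,
    n_alignments = nrow(alignments),
    skipped_cells = nrow(skipped)
  )

  out <- structure(list(metrics = metrics, summary = summary,
                        alignments = alignments, predictions = predictions,
                        skipped = skipped, manifest = manifest, grid = grid),
                   class = "funalign_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.funalign_experiment <- function(x, ...) {
  cat(sprintf("<funalign_experiment: %d metric rows, %d alignments, %d prediction rows, %d skipped cells>\n",
              nrow(x$metrics), nrow(x$alignments), nrow(x$predictions),
              nrow(x$skipped)))
  invisible(x)
}

#' @export
tidy.funalign_experiment <- function(x, ...) x$summary

#' @export
glance.funalign_experiment <- function(x, ...) {
  tibble(n_versions = length(x$grid$feature_versions),
         n_alignments = nrow(x$alignments),
         n_skipped_cells = nrow(x$skipped),
         mean_accuracy = mean(x$summary$accuracy),
         mean_auroc = mean(x$summary$auroc))
}

#' Write experiment artifacts to a directory
#'
#' Metrics and per-alignment statistics as CSV, alignments and prediction
#' sets as TSV, and a JSON manifest of seeds and settings.
#'
#' @param experiment A `funalign_experiment`.
#' @param dir Output directory.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(experiment$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(experiment$summary, file.path(dir, "summary.csv"))
  readr::write_csv(experiment$predictions |>
                     select(-"prediction_set"),
                   file.path(dir, "prediction_metrics.csv"))
  adir <- file.path(dir, "alignments"); dir.create(adir, showWarnings = FALSE)
  pdir <- file.path(dir, "predictions"); dir.create(pdir, showWarnings = FALSE)
  for (i in seq_len(nrow(experiment$alignments))) {
    row <- experiment$alignments[i, ]
    write_alignment(row$alignment[[1L]],
                    file.path(adir, sprintf("%s_k%s_r%s_y%s_rep%s.tsv",
                                            row$version, row$k, row$rarity,
                                            row$y, row$replicate)))
  }
  for (i in seq_len(nrow(experiment$predictions))) {
    row <- experiment$predictions[i, ]
    ps <- row$prediction_set[[1L]]
    if (!is.null(ps) && nrow(ps) > 0L) {
      write_predictions(ps, file.path(pdir, sprintf("%s_k%s_r%s_y%s_rep%s.tsv",
                                                    row$version, row$k, row$rarity,
                                                    row$y, row$replicate)))
    }
  }
  readr::write_csv(experiment$skipped, file.path(dir, "skipped.csv"))
  jsonlite::write_json(experiment$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' End-to-end noise robustness sweep
#'
#' For each seed, generates a clean world, then perturbs a fraction `f` of
#' every data layer ([inject_noise()]) and runs a reduced pipeline (one
#' feature version, one training percentage) on the noised inputs. The
#' resulting prediction sets are scored against the *clean* world's ground
#' truth-rarity dataset — the fixed external knowledge the noised run tries
#' to recover. An empty prediction set scores `empty_as` precision
#' (default 0: no correct prediction was made), so completely random
#' worlds register as failures rather than vacuous successes.
#'
#' @param cfg Base [synth_config()] (its `noise_fraction`/`seed` are
#'   overridden per run).
#' @param fractions Noise fractions to visit.
#' @param seeds One world per seed at each fraction.
#' @param version Feature version to run.
#' @param y Training percentage.
#' @param n_replicates,n_splits Reduced protocol sizes.
#' @param empty_as Precision assigned to empty prediction sets.
#' @param alpha Enrichment significance level.
#' @return A tibble of class `noise_sweep`: `fraction`, `seed`, `auroc`,
#'   `precision`, `recall`, `n_predictions`.
#' @export
noise_sweep <- function(cfg = synth_config(), fractions = seq(0, 1, by = 0.25),
                        seeds = 1:5, version = "graphlets_integrated",
                        y = 50L, n_replicates = 2L, n_splits = 2L,
                        empty_as = 0, alpha = 0.05) {
  stopifnot(cfg$noise_fraction == 0)
  grid_tbl <- tidyr::expand_grid(fraction = fractions, seed = seeds)
  out <- purrr::pmap_dfr(grid_tbl, function(fraction, seed) {
    cfg$seed <- as.integer(seed)
    clean <- generate_world(cfg)
    world <- inject_noise(clean, fraction, seed = cfg$seed + 10000L)
    gt_clean <- suppressWarnings(build_ground_truth(
      clean$annotations, clean$network1, clean$network2, k = 1, rarity = "ALL"))
    grid <- experiment_grid(feature_versions = version, y = y,
                            n_replicates = n_replicates, n_splits = n_splits,
                            alpha = alpha, consensus = NULL)
    ex <- suppressMessages(suppressWarnings(
      run_experiment(world$network1, world$network2, world$anchors,
                     world$annotations, grid)))
    if (nrow(ex$predictions) == 0L) {
      return(tibble(fraction = fraction, seed = seed, auroc = NA_real_,
                    precision = empty_as, recall = 0, n_predictions = 0L))
    }
    scored <- purrr::map_dfr(ex$predictions$prediction_set, function(ps) {
      if (is.null(ps) || nrow(ps) == 0L) {
        return(tibble(precision = empty_as, recall = 0, n_predictions = 0L))
      }
      suppressMessages(precision_recall(ps, gt_clean))[
        , c("precision", "recall", "n_predictions")]
    })
    tibble(fraction = fraction, seed = seed,
           auroc = mean(ex$summary$auroc, na.rm = TRUE),
           precision = mean(scored$precision), recall = mean(scored$recall),
           n_predictions = sum(scored$n_predictions))
  })
  class(out) <- c("noise_sweep", class(out))
  out
}
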