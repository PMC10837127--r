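#' Pseudo-label the most confidently predicted cells
#'
#' One round of self-training: train the uncertainty model on the labeled
#' cells, predict the remaining cells, rank them by predictive entropy
#' (ascending: most confident first) and attach the model's argmax label
#' to the top `top_percent` of the unlabeled pool (round half up, ties by
#' cell id). Oracle labels are never overwritten.
#'
#' @param x Cell x feature matrix (typically embedding scores) covering
#'   labeled and unlabeled cells; rownames are cell ids.
#' @param labeled Labels for the oracle-annotated cells (tibble
#'   `cell_id`,`cell_type` or named vector); at least two classes.
#' @param model_kind `"random_forest"` or `"logistic_regression"`.
#' @param top_percent Percent of the unlabeled pool to pseudo-label:
#'   10, 50 or 100 in the standard designs.
#' @param seed Integer seed.
#' @return An `augmented_labels` tibble: `cell_id`, `cell_type`, `source`
#'   (`"oracle"`/`"pseudo"`), `confidence` (scaled entropy at prediction
#'   time; 0 for oracle cells).
#' @export
pseudo_label <- function(x, labeled, model_kind = "random_forest",
                         top_percent = 100, seed = 1) {
  lf <- assert_no_reserved(labeled, "labeled")
  unlabeled <- setdiff(rownames(x), lf$cell_id)
  oracle_rows <- tibble(cell_id = lf$cell_id, cell_type = lf$cell_type,
                        source = "oracle", confidence = 0)
  if (length(unlabeled) == 0) {
    warn("no unlabeled cells to pseudo-label; returning the labeled set")
    out <- oracle_rows
  } else {
    model <- train_uncertainty_model(x[lf$cell_id, , drop = FALSE], lf,
                                     kind = model_kind, seed = seed)
    p <- predict_probabilities(model, x[unlabeled, , drop = FALSE])
    se <- scaled_entropy(entropy(p))
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    n_take <- round_half_up(top_percent / 100 * length(unlabeled))
    ord <- order(se$value, se$cell_id)
    take <- head(ord, n_take)
    out <- bind_rows(
      oracle_rows,
      tibble(cell_id = se$cell_id[take], cell_type = pred[take],
             source = "pseudo", confidence = se$value[take])
    )
  }
  class(out) <- c("augmented_labels", class(out))
  out
}

#' Measure the downstream gain from self-training
#'
#' Trains the downstream classifier twice — on the oracle-labeled cells
#' alone, and on the pseudo-label-augmented set — and evaluates both on
#' the same held-out test cells, returning the paired metric records and
#' their difference.
#'
#' @param ds Transformed `expr_dataset` covering training pool and test
#'   cells.
#' @param labeled Oracle labels for the annotated training cells.
#' @param truth Ground-truth labels (used to label the test set).
#' @param test_ids Held-out cell ids; must not overlap the training pool.
#' @param pool_ids Cells eligible for pseudo-labelling (default: all
#'   non-test cells of `ds`).
#' @param model_kind Self-training model, `"random_forest"` or
#'   `"logistic_regression"`.
#' @param top_percent Percent of the unlabeled pool to pseudo-label.
#' @param n_components Embedding dimension for the self-training model.
#' @param grid Downstream classifier grid, see [train_downstream_rf()].
#' @param seed Integer seed.
#' @return A `self_training_gain` object: `metrics` (two `MetricsRecord`
#'   rows, `training` = `"oracle_only"`/`"augmented"`), `gain` (their
#'   difference, augmented minus oracle-only) and the `augmented` label
#'   set.
#' @export
self_training_gain <- function(ds, labeled, truth, test_ids,
                               pool_ids = NULL, model_kind = "random_forest",
                               top_percent = 50, n_components = 20,
                               grid = downstream_grid(), seed = 1) {
  lf <- assert_no_reserved(labeled, "labeled")
  pool_ids <- pool_ids %||% setdiff(ds$cell_ids, test_ids)
  if (length(intersect(pool_ids, test_ids)) > 0 ||
      length(intersect(lf$cell_id, test_ids)) > 0) {
    abort("test cells overlap the training pool")
  }
  pool <- ds[pool_ids, ]
  emb <- fit_embedding(pool, min(n_components, min(dim(pool))))
  aug <- pseudo_label(emb$scores, lf, model_kind = model_kind,
                      top_percent = top_percent, seed = seed)
  truth_lk <- label_lookup(truth)
  test_labels <- tibble(cell_id = test_ids,
                        cell_type = unname(truth_lk[test_ids]))
  eval_one <- function(lab, tag) {
    fit <- train_downstream_rf(ds[lab$cell_id, ], lab, grid = grid,
                               seed = seed)
    pred <- predict(fit, ds[test_ids, ])
    evaluate_predictions(pred, test_labels) |>
      mutate(training = tag, .before = 1)
  }
  metrics <- bind_rows(
    eval_one(lf, "oracle_only"),
    eval_one(select(aug, "cell_id", "cell_type"), "augmented")
  )
  metric_cols <- c("sensitivity", "f1", "mcc", "kappa", "balanced_accuracy")
  gain <- metrics[metrics$training == "augmented", metric_cols] -
    metrics[metrics$training == "oracle_only", metric_cols]
  structure(list(metrics = metrics, gain = as_tibble(gain), augmented = aug),
            class = "self_training_gain")
}

#' @export
print.self_training_gain <- function(x, ...) {
  cat("<self_training_gain>\n")
  print(x$metrics)
  cat("gain (augmented - oracle_only):\n")
  print(x$gain)
  invisible(x)
}

#' Corrupt a fraction of ground-truth labels
#'
#' Reassigns a uniformly chosen `round(fraction * n)` cells to a different
#' class drawn uniformly from the remaining classes — the standard way to
#' probe whether high predictive entropy flags mis-annotated training
#' cells.
#'
#' @param truth Ground-truth labels with at least two classes.
#' @param fraction Fraction of cells to corrupt, default 0.10.
#' @param seed Integer seed.
#' @return A tibble `cell_id`, `cell_type` (corrupted), `corrupted`
#'   (logical mask).
#' @export
corrupt_labels <- function(truth, fraction = 0.10, seed = 1) {
  lf <- as_label_frame(truth, "truth")
  classes <- unique(lf$cell_type)
  if (length(classes) < 2) abort("need at least two classes to corrupt labels")
  n_corrupt <- round_half_up(fraction * nrow(lf))
  out <- mutate(lf, corrupted = FALSE)
  if (n_corrupt > 0) {
    with_seed(seed, {
      idx <- sample(nrow(lf), n_corrupt)
      new_lab <- vapply(idx, function(i) {
        sample(setdiff(classes, lf$cell_type[i]), 1)
      }, character(1))
      out$cell_type[idx] <- new_lab
      out$corrupted[idx] <- TRUE
    })
  }
  out
}

#' Flag possibly mislabeled training cells by predictive entropy
#'
#' Trains the uncertainty model on the given (possibly corrupted) training
#' labels and scores every training cell's scaled predictive entropy under
#' that same model; mis-assigned cells sit in the wrong class region and
#' surface with elevated entropy. An optional cross-validated mode scores
#' each cell with a model that did not see it.
#'
#' @param x Cell x feature matrix of the training cells.
#' @param labels Their (possibly corrupted) labels.
#' @param model_kind `"random_forest"` or `"logistic_regression"`.
#' @param cv Integer number of folds for the cross-validated variant, or
#'   `NULL` (default) to score with the in-sample model.
#' @param seed Integer seed.
#' @return A tibble `cell_id`, `cell_type`, `scaled_entropy`, `rank`
#'   (1 = most suspect), sorted by decreasing entropy.
#' @export
detect_mislabeled <- function(x, labels, model_kind = "random_forest",
                              cv = NULL, seed = 1) {
  lf <- assert_no_reserved(labels)
  x <- x[lf$cell_id, , drop = FALSE]
  if (is.null(cv)) {
    model <- train_uncertainty_model(x, lf, kind = model_kind, seed = seed)
    p <- predict_probabilities(model, x)
    se <- scaled_entropy(entropy(p))
  } else {
    fold <- with_seed(derive_seed(seed, 11L),
                      sample(rep_len(seq_len(cv), nrow(lf))))
    vals <- numeric(nrow(lf))
    for (f in seq_len(cv)) {
      model <- train_uncertainty_model(x[fold != f, , drop = FALSE],
                                       lf[fold != f, ],
                                       kind = model_kind, seed = seed)
      p <- predict_probabilities(model, x[fold == f, , drop = FALSE])
      vals[fold == f] <- scaled_entropy(entropy(p))$value
    }
    se <- tibble(cell_id = lf$cell_id, value = vals)
  }
  out <- tibble(cell_id = se$cell_id,
                cell_type = lf$cell_type[match(se$cell_id, lf$cell_id)],
                scaled_entropy = se$value) |>
    arrange(desc(.data$scaled_entropy), .data$cell_id) |>
    mutate(rank = row_number())
  out
}
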