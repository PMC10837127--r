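#' Active-learning configuration
#'
#' Bundles the knobs of the annotation loop: which probabilistic model
#' supplies uncertainties, which uncertainty metric is used, the certainty
#' percentile at which batches are drawn, the batch size, the size of the
#' initial labeled set, the total labelling budget, and the embedding
#' dimension.
#'
#' @param model_kind `"random_forest"` or `"logistic_regression"`.
#' @param metric `"entropy"` or `"max_probability"`.
#' @param q Certainty percentile: 100 (maximum uncertainty), 95 or 75.
#' @param batch_size Cells queried per iteration, default 10.
#' @param initial_n Size of the initial labeled set, default 20.
#' @param budget Total cells to label (100, 250 or 500 in the standard
#'   benchmark designs); must be at least `initial_n`.
#' @param n_components Principal components used as features, default 20.
#' @param seed Integer seed.
#' @return An `al_config` list.
#' @export
al_config <- function(model_kind = c("random_forest", "logistic_regression"),
                      metric = c("entropy", "max_probability"),
                      q = 100, batch_size = 10, initial_n = 20,
                      budget = 100, n_components = 20, seed = 1) {
  model_kind <- match.arg(model_kind)
  metric <- match.arg(metric)
  if (budget < initial_n) abort("budget must be >= initial_n")
  if (batch_size < 1) abort("batch_size must be >= 1")
  structure(list(model_kind = model_kind, metric = metric, q = q,
                 batch_size = batch_size, initial_n = initial_n,
                 budget = budget, n_components = n_components, seed = seed),
            class = "al_config")
}

#' Run the active-learning annotation loop
#'
#' Starting from a labeled initial selection, repeats
#' \{train classifier, score unlabeled cells, select a batch at the
#' configured certainty percentile, reveal their oracle labels\} until the
#' budget is reached. The principal-component embedding is fit once on the
#' whole pool (transductively), so uncertainty scores live in a fixed
#' feature space across iterations. The classifier is retrained from
#' scratch each iteration.
#'
#' @param ds A transformed `expr_dataset`: the selectable training pool.
#' @param oracle Ground-truth labels for every cell in `ds` (the simulated
#'   annotator); reserved tokens are rejected.
#' @param config An [al_config()].
#' @param initial A `cellpick_selection` of already-labeled cells (its
#'   size should equal `config$initial_n`).
#' @param eval_x,eval_labels Optional held-out evaluation matrix in the
#'   same embedding space is not needed — pass a transformed
#'   `expr_dataset` and labels to record a per-iteration accuracy trace.
#' @return An `al_run` object: `selection` (a `cellpick_selection` with
#'   per-cell iteration indices), the fitted `embedding`, the final
#'   `model`, and a `trace` tibble (iteration, n_labeled, and accuracy if
#'   an evaluation set was given).
#' @export
active_learning_loop <- function(ds, oracle, config = al_config(),
                                 initial, eval_x = NULL, eval_labels = NULL) {
  lf <- assert_no_reserved(oracle, "oracle")
  lk <- setNames(lf$cell_type, lf$cell_id)
  miss <- setdiff(ds$cell_ids, names(lk))
  if (length(miss) > 0) {
    abort(sprintf("oracle is missing labels for %d pool cells", length(miss)))
  }
  if (config$budget > length(ds$cell_ids)) {
    abort(sprintf("budget %d exceeds pool of %d cells",
                  config$budget, length(ds$cell_ids)))
  }
  emb <- fit_embedding(ds, config$n_components)
  x <- emb$scores
  labeled <- if (is.data.frame(initial)) initial$cell_id else as.character(initial)
  if (anyDuplicated(labeled)) abort("initial selection has duplicate cells")
  iteration <- rep(0L, length(labeled))
  eval_scores <- if (!is.null(eval_x)) {
    if (inherits(eval_x, "expr_dataset")) project_cells(eval_x, emb) else eval_x
  }
  trace <- list()
  it <- 0L
  repeat {
    model <- train_uncertainty_model(
      x[labeled, , drop = FALSE],
      tibble(cell_id = labeled, cell_type = unname(lk[labeled])),
      kind = config$model_kind, seed = derive_seed(config$seed, it)
    )
    if (!is.null(eval_scores) && !is.null(eval_labels)) {
      p <- predict_probabilities(model, eval_scores)
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      elk <- label_lookup(eval_labels)
      acc <- mean(pred == elk[rownames(eval_scores)])
      trace[[it + 1L]] <- tibble(iteration = it, n_labeled = length(labeled),
                                 accuracy = acc)
    } else {
      trace[[it + 1L]] <- tibble(iteration = it, n_labeled = length(labeled),
                                 accuracy = NA_real_)
    }
    if (length(labeled) >= config$budget) break
    unlabeled <- setdiff(ds$cell_ids, labeled)
    p <- predict_probabilities(model, x[unlabeled, , drop = FALSE])
    u <- if (config$metric == "entropy") entropy(p) else max_probability(p)
    batch <- min(config$batch_size, config$budget - length(labeled))
    sel <- select_at_percentile(u, q = config$q, batch = batch)
    it <- it + 1L
    labeled <- c(labeled, sel$cell_id)
    iteration <- c(iteration, rep(it, nrow(sel)))
  }
  selection <- new_selection(
    labeled,
    paste0("al_", sub("max_probability", "maxprob", config$metric)),
    params = unclass(config)
  )
  selection$iteration <- iteration
  structure(list(selection = selection, embedding = emb, model = model,
                 trace = bind_rows(trace), config = config),
            class = "al_run")
}

#' @export
print.al_run <- function(x, ...) {
  cat(sprintf("<al_run> %s/%s q=%s: %d cells in %d iterations\n",
              x$config$model_kind, x$config$metric, x$config$q,
              nrow(x$selection), max(x$selection$iteration)))
  invisible(x)
}

#' @describeIn active_learning_loop Per-cell tidy view of the selection.
#' @param x An `al_run`.
#' @param ... Unused.
#' @export
tidy.al_run <- function(x, ...) {
  as_tibble(x$selection)
}

#' @describeIn active_learning_loop One-row summary of the run.
#' @export
glance.al_run <- function(x, ...) {
  tibble(model_kind = x$config$model_kind, metric = x$config$metric,
         q = x$config$q, budget = x$config$budget,
         n_selected = nrow(x$selection),
         n_iterations = max(x$selection$iteration),
         final_accuracy = utils::tail(x$trace$accuracy, 1))
}

#' Entropy landscape when a cell type is (nearly) absent from training
#'
#' Builds a 20-cell initial training set containing exactly `n_copies`
#' cells of `held_out_type` (the remainder drawn randomly or by marker
#' ranking from the other types), trains the uncertainty model once on
#' those cells, and reports scaled entropies for all remaining cells
#' grouped by their ground-truth type. A distinct unseen type should stand
#' out with high entropy; a type closely mirroring a retained type will
#' not.
#'
#' @param ds Transformed `expr_dataset`.
#' @param oracle Ground-truth labels for all cells.
#' @param held_out_type Type whose representation in the initial set is
#'   controlled.
#' @param n_copies 0, 1, 2 or 3 cells of that type in the initial set.
#' @param config An [al_config()]; its `model_kind`, `n_components`,
#'   `initial_n` and `seed` are used.
#' @param init `"random"` or `"ranked"`; ranked needs `markers`.
#' @param markers A `marker_spec` when `init = "ranked"`.
#' @return A `novel_type_report`: `cells` tibble (`cell_id`, `cell_type`,
#'   `scaled_entropy`) over all non-initial cells, and `medians` tibble of
#'   per-type median scaled entropy.
#' @export
novel_type_entropy_report <- function(ds, oracle, held_out_type,
                                      n_copies = 0, config = al_config(),
                                      init = c("random", "ranked"),
                                      markers = NULL) {
  init <- match.arg(init)
  lf <- assert_no_reserved(oracle, "oracle")
  lk <- setNames(lf$cell_type, lf$cell_id)
  pool <- ds$cell_ids
  type_cells <- pool[lk[pool] == held_out_type]
  if (length(type_cells) == 0) {
    abort(sprintf("held_out_type '%s' is absent from the data", held_out_type))
  }
  if (n_copies > length(type_cells)) {
    abort(sprintf("only %d cells of '%s' available", length(type_cells),
                  held_out_type))
  }
  keep <- with_seed(derive_seed(config$seed, 7L),
                    sample(type_cells, n_copies))
  rest_pool <- setdiff(pool, type_cells)
  n_rest <- config$initial_n - n_copies
  rest <- if (init == "random") {
    select_initial_random(rest_pool, n_rest, seed = config$seed)$cell_id
  } else {
    if (is.null(markers)) abort("ranked initial selection needs `markers`")
    sc <- score_cells_by_markers(ds[rest_pool, ], markers)
    select_initial_ranked(sc, n_rest)$cell_id
  }
  initial <- c(keep, rest)
  emb <- fit_embedding(ds, config$n_components)
  model <- train_uncertainty_model(
    emb$scores[initial, , drop = FALSE],
    tibble(cell_id = initial, cell_type = unname(lk[initial])),
    kind = config$model_kind, seed = config$seed
  )
  rest_cells <- setdiff(pool, initial)
  p <- predict_probabilities(model, emb$scores[rest_cells, , drop = FALSE])
  se <- scaled_entropy(entropy(p))
  cells <- tibble(cell_id = se$cell_id,
                  cell_type = unname(lk[se$cell_id]),
                  scaled_entropy = se$value)
  medians <- cells |>
    group_by(.data$cell_type) |>
    summarise(median_scaled_entropy = median(.data$scaled_entropy),
              n = n(), .groups = "drop")
  structure(list(cells = cells, medians = medians,
                 held_out_type = held_out_type, n_copies = n_copies,
                 model_kind = config$model_kind),
            class = "novel_type_report")
}

#' @export
print.novel_type_report <- function(x, ...) {
  cat(sprintf("<novel_type_report> '%s' x%d in initial set (%s)\n",
              x$held_out_type, x$n_copies, x$model_kind))
  print(x$medians)
  invisible(x)
}

#' @describeIn novel_type_entropy_report Cell-level tidy view.
#' @param x A `novel_type_report`.
#' @param ... Unused.
#' @export
tidy.novel_type_report <- function(x, ...) x$cells
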