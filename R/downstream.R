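#' Downstream random-forest grid
#'
#' The hyperparameter grid of the downstream cell-type classifier:
#' maximum features per split (mtry), number of trees, and the number of
#' principal components of the scaled expression used as input. The
#' defaults are the benchmark grid — `n_pcs` 25/50 for transcriptomics
#' and 20/39 (the full marker panel) for CyTOF.
#'
#' @param max_features Candidate mtry values.
#' @param num_trees Candidate tree counts.
#' @param n_pcs Candidate numbers of principal components; defaults
#'   depend on `modality`.
#' @param modality `"rna"` or `"cytof"`.
#' @return A `downstream_grid` list.
#' @export
downstream_grid <- function(max_features = c(4, 6, 10),
                            num_trees = c(100, 150),
                            n_pcs = NULL,
                            modality = c("rna", "cytof")) {
  modality <- match.arg(modality)
  n_pcs <- n_pcs %||% if (modality == "rna") c(25, 50) else c(20, 39)
  structure(list(max_features = max_features, num_trees = num_trees,
                 n_pcs = n_pcs), class = "downstream_grid")
}

#' Train the downstream random-forest cell-type classifier
#'
#' The supervised classifier evaluated by the benchmarking harness:
#' scaled-and-centered transformed expression is PCA-projected, and a
#' random forest is tuned by stratified 5-fold cross-validated macro-F1
#' over the grid of mtry, tree count and PC count, then refit on all
#' training cells with the winning configuration. Everything is seeded.
#' Classes with fewer than 5 cells make clean stratification impossible;
#' folds are then filled as evenly as the counts allow, with a warning.
#'
#' @param ds Transformed `expr_dataset` of the training cells.
#' @param labels Their labels (at least two classes).
#' @param grid A [downstream_grid()]; candidate PC counts above
#'   `min(cells, features)` are clipped.
#' @param nfolds Cross-validation folds, default 5.
#' @param seed Integer seed.
#' @return A `downstream_rf` model with a [predict()] method returning
#'   labels (pass `type = "prob"` for probabilities). `glance()` reports
#'   the chosen configuration and its CV score.
#' @export
train_downstream_rf <- function(ds, labels, grid = downstream_grid(),
                                nfolds = 5, seed = 1) {
  assert_state(ds, c("lognorm", "arcsinh"), "train_downstream_rf")
  lf <- assert_no_reserved(labels)
  lk <- setNames(lf$cell_type, lf$cell_id)
  if (!all(ds$cell_ids %in% names(lk))) {
    abort("labels are missing for some training cells")
  }
  y <- factor(lk[ds$cell_ids])
  if (nlevels(y) < 2) abort("need at least two classes")
  counts <- table(y)
  if (any(counts < nfolds)) {
    warn(sprintf("classes with fewer than %d cells (%s); folds stratified as evenly as possible",
                 nfolds, paste(names(counts)[counts < nfolds], collapse = ", ")))
  }
  max_pc <- min(dim(ds)) - 1L
  pcs <- sort(unique(pmin(grid$n_pcs, max_pc)))
  emb <- fit_embedding(ds, max(pcs))
  scores <- emb$scores
  fold <- integer(length(y))
  with_seed(derive_seed(seed, 21L), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
  })
  configs <- expand.grid(mtry = grid$max_features, num_trees = grid$num_trees,
                         n_pcs = pcs, KEEP.OUT.ATTRS = FALSE)
  cv_scores <- vapply(seq_len(nrow(configs)), function(ci) {
    cfg <- configs[ci, ]
    f1 <- numeric(nfolds)
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2 || sum(!tr) == 0) { f1[f] <- NA; next }
      fit <- fit_ranger(scores[tr, seq_len(cfg$n_pcs), drop = FALSE],
                        droplevels(y[tr]), cfg$mtry, cfg$num_trees,
                        derive_seed(seed, 100L + ci))
      pred <- predict_ranger_labels(fit, scores[!tr, seq_len(cfg$n_pcs),
                                                drop = FALSE])
      f1[f] <- evaluate_predictions(pred, as.character(y[!tr]))$f1
    }
    mean(f1, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_scores)  # ties -> first (lowest-index) config
  cfg <- configs[best, ]
  fit <- fit_ranger(scores[, seq_len(cfg$n_pcs), drop = FALSE], y,
                    cfg$mtry, cfg$num_trees, derive_seed(seed, 999L))
  structure(
    list(fit = fit, embedding = emb, n_pcs = cfg$n_pcs, mtry = cfg$mtry,
         num_trees = cfg$num_trees, cv_f1 = cv_scores[best],
         cv_table = mutate(as_tibble(configs), cv_f1 = cv_scores),
         classes = levels(y), seed = seed),
    class = "downstream_rf"
  )
}

fit_ranger <- function(x, y, mtry, num_trees, seed) {
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 probability = TRUE, num.trees = num_trees,
                 mtry = min(mtry, ncol(x)), seed = seed, num.threads = 1)
}

predict_ranger_labels <- function(fit, x) {
  p <- predict(fit, data = data.frame(x, check.names = FALSE),
               num.threads = 1)$predictions
  colnames(p)[max.col(p, ties.method = "first")]
}

#' @export
print.downstream_rf <- function(x, ...) {
  cat(sprintf("<downstream_rf> %d classes; chosen: mtry=%d, trees=%d, pcs=%d (CV macro-F1 %.3f)\n",
              length(x$classes), x$mtry, x$num_trees, x$n_pcs, x$cv_f1))
  invisible(x)
}

#' Predict cell types with a downstream classifier
#'
#' @param object A `downstream_rf`.
#' @param newdata A transformed `expr_dataset` (or a score matrix already
#'   in the model's embedding).
#' @param type `"label"` (default) for a tibble of labels, `"prob"` for
#'   the probability matrix.
#' @param ... Unused.
#' @return A tibble `cell_id`, `cell_type`, or a probability matrix.
#' @export
predict.downstream_rf <- function(object, newdata, type = c("label", "prob"),
                                  ...) {
  type <- match.arg(type)
  s <- if (inherits(newdata, "expr_dataset")) {
    project_cells(newdata, object$embedding)
  } else newdata
  s <- s[, seq_len(object$n_pcs), drop = FALSE]
  p <- predict(object$fit, data = data.frame(s, check.names = FALSE),
               num.threads = 1)$predictions
  rownames(p) <- rownames(s)
  if (type == "prob") return(p)
  tibble(cell_id = rownames(s),
         cell_type = colnames(p)[max.col(p, ties.method = "first")])
}

#' @describeIn train_downstream_rf One-row summary of the fitted model.
#' @param x A `downstream_rf`.
#' @param ... Unused.
#' @export
glance.downstream_rf <- function(x, ...) {
  tibble(mtry = x$mtry, num_trees = x$num_trees, n_pcs = x$n_pcs,
         cv_f1 = x$cv_f1, n_classes = length(x$classes))
}

#' @describeIn train_downstream_rf The full cross-validation grid table.
#' @export
tidy.downstream_rf <- function(x, ...) x$cv_table
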