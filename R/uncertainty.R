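#' Train a probabilistic uncertainty model
#'
#' The classifier driving the active-learning loop. Two kinds are
#' supported: a probability random forest (500 trees, square-root feature
#' subsampling) and an L2-regularised multinomial logistic regression
#' whose penalty strength (weight decay) is picked by stratified 5-fold
#' cross-validated log-loss over a small fixed grid (falling back to a
#' default strength of 0.1 when a class is too small to cross-validate).
#' Both are fully seeded; training always starts from scratch.
#'
#' @param x Cell x feature numeric matrix (typically embedding scores),
#'   with cell ids as rownames.
#' @param labels Labels for the rows of `x` (tibble or named vector);
#'   at least two distinct classes, no reserved tokens.
#' @param kind `"random_forest"` (alias `"rf"`) or
#'   `"logistic_regression"` (alias `"lr"`).
#' @param seed Integer seed.
#' @return An `uncertainty_model`; use [predict_probabilities()] on it.
#' @export
train_uncertainty_model <- function(x, labels,
                                    kind = c("random_forest",
                                             "logistic_regression",
                                             "rf", "lr"),
                                    seed = 1) {
  kind <- match.arg(kind)
  kind <- c(random_forest = "random_forest", rf = "random_forest",
            logistic_regression = "logistic_regression",
            lr = "logistic_regression")[[kind]]
  lf <- assert_no_reserved(labels)
  if (is.null(rownames(x))) abort("`x` needs cell ids as rownames")
  lk <- setNames(lf$cell_type, lf$cell_id)
  if (!all(rownames(x) %in% names(lk))) {
    abort("labels are missing for some rows of `x`")
  }
  y <- factor(lk[rownames(x)])
  if (nlevels(y) < 2) {
    abort("training labels contain a single class; uncertainty is undefined")
  }
  fit <- if (kind == "random_forest") {
    df <- data.frame(x, check.names = FALSE)
    df$.y <- y
    ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = 500, mtry = max(1L, floor(sqrt(ncol(x)))),
      seed = seed, num.threads = 1
    )
  } else {
    fit_l2_multinom(x, y, seed = seed)
  }
  structure(list(kind = kind, fit = fit, classes = levels(y),
                 features = colnames(x), seed = seed),
            class = "uncertainty_model")
}

# L2-regularised multinomial logistic regression with CV-chosen penalty
# (weight decay); robust to singleton classes, which arise in 20-cell
# initial training sets.
fit_l2_multinom <- function(x, y, seed,
                            decay_grid = c(10, 1, 0.1, 0.01, 0.001),
                            default_decay = 0.1) {
  min_class <- min(table(y))
  decay <- default_decay
  if (min_class >= 2 && length(y) >= 10) {
    nfolds <- min(5L, min_class)
    fold <- integer(length(y))
    with_seed(derive_seed(seed, 101L), {
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(nfolds), length(idx))
      }
    })
    loss <- vapply(decay_grid, function(dc) {
      ll <- 0
      for (f in seq_len(nfolds)) {
        tr <- fold != f
        ytr <- droplevels(y[tr])
        if (nlevels(ytr) < 2) next
        fit <- multinom_fit(x[tr, , drop = FALSE], ytr, dc,
                            derive_seed(seed, 200L + f))
        p <- multinom_probs(fit, x[!tr, , drop = FALSE], levels(y))
        pt <- p[cbind(seq_len(sum(!tr)), match(y[!tr], colnames(p)))]
        ll <- ll - sum(log(pmax(pt, 1e-12)))
      }
      ll
    }, numeric(1))
    decay <- decay_grid[which.min(loss)]
  }
  fit <- multinom_fit(x, y, decay, derive_seed(seed, 300L))
  list(multinom_fit = fit, decay = decay, classes = levels(y))
}

multinom_fit <- function(x, y, decay, seed) {
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  with_seed(seed, {
    out <- utils::capture.output(
      fit <- nnet::multinom(.y ~ ., data = df, decay = decay,
                            maxit = 300, MaxNWts = 10000, trace = FALSE)
    )
    fit
  })
}

# Predict class probabilities from a multinom fit, aligned to the full
# class set (classes unseen by the fit get probability 0).
multinom_probs <- function(fit, newx, classes) {
  mf <- if (is.list(fit) && !is.null(fit$multinom_fit)) fit$multinom_fit else fit
  pr <- predict(mf, newdata = data.frame(newx, check.names = FALSE),
                type = "probs")
  lev <- mf$lev
  if (is.null(dim(pr))) {
    if (length(lev) == 2) {
      # two-class fits return P(second level) as a vector
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- lev
    } else {
      # single prediction row comes back as a named vector
      pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
    }
  }
  out <- matrix(0, nrow(newx), length(classes),
                dimnames = list(rownames(newx), classes))
  out[, colnames(pr)] <- pr
  out / pmax(rowSums(out), 1e-12)
}

#' Predict class probabilities
#'
#' @param model An `uncertainty_model`.
#' @param x Cell x feature matrix with the same columns as at training.
#' @return Cell x class probability matrix; rows sum to 1, columns are the
#'   classes seen in the training labels.
#' @export
predict_probabilities <- function(model, x) {
  if (!inherits(model, "uncertainty_model")) {
    abort("predict_probabilities() needs an uncertainty_model")
  }
  if (!identical(colnames(x), model$features)) {
    x <- x[, model$features, drop = FALSE]
  }
  p <- if (model$kind == "random_forest") {
    pr <- predict(model$fit, data = data.frame(x, check.names = FALSE),
                  num.threads = 1)$predictions
    rownames(pr) <- rownames(x)
    pr[, model$classes, drop = FALSE]
  } else {
    multinom_probs(model$fit, x, model$classes)
  }
  validate_probability_matrix(p)
  p
}

validate_probability_matrix <- function(p, tol = 1e-6) {
  if (any(p < -tol) || any(p > 1 + tol)) {
    abort("probabilities outside [0, 1]")
  }
  dev <- abs(rowSums(p) - 1)
  if (any(dev > tol)) {
    abort(sprintf("%d probability rows do not sum to 1 (max deviation %.2e)",
                  sum(dev > tol), max(dev)))
  }
  invisible(p)
}

new_uncertainty <- function(cell_ids, values, metric, n_classes) {
  out <- tibble(cell_id = cell_ids, value = unname(values))
  attr(out, "metric") <- metric
  attr(out, "n_classes") <- n_classes
  class(out) <- c("uncertainty_scores", class(out))
  out
}

#' Predictive entropy per cell
#'
#' Base-2 Shannon entropy of each cell's class-probability vector,
#' `H(p) = -sum(p_i * log2(p_i))` with `0 * log2(0) = 0`. Bounded by
#' `log2(n_classes)`; the least certain predictions score highest.
#'
#' @param p Cell x class probability matrix (rows must sum to 1).
#' @return An `uncertainty_scores` tibble (`cell_id`, `value`) with
#'   attributes `metric = "entropy"` and `n_classes`.
#' @export
entropy <- function(p) {
  validate_probability_matrix(p)
  pl <- ifelse(p > 0, p * log2(p), 0)
  h <- -rowSums(pl)
  new_uncertainty(rownames(p), h, "entropy", ncol(p))
}

#' Maximum predicted probability per cell
#'
#' The largest class probability of each cell; the lowest values mark the
#' least certain predictions. Bounded below by `1/n_classes`.
#'
#' @inheritParams entropy
#' @return An `uncertainty_scores` tibble with `metric = "max_probability"`.
#' @export
max_probability <- function(p) {
  validate_probability_matrix(p)
  new_uncertainty(rownames(p), apply(p, 1, max), "max_probability", ncol(p))
}

#' Scale entropy to `[0, 1]`
#'
#' Divides entropies by their maximum possible value `log2(n_classes)`,
#' making scores comparable across experiments with different numbers of
#' classes. Ranks are unchanged.
#'
#' @param u An `uncertainty_scores` tibble with `metric = "entropy"`.
#' @return An `uncertainty_scores` tibble with `metric = "scaled_entropy"`.
#' @export
scaled_entropy <- function(u) {
  if (!inherits(u, "uncertainty_scores") ||
      !attr(u, "metric") %in% c("entropy", "scaled_entropy")) {
    abort("scaled_entropy() expects entropy scores")
  }
  if (attr(u, "metric") == "scaled_entropy") return(u)
  k <- attr(u, "n_classes")
  new_uncertainty(u$cell_id, u$value / log2(k), "scaled_entropy", k)
}

#' Select a batch of cells at an uncertainty percentile
#'
#' Scores are oriented so that larger means more uncertain (entropy as-is,
#' maximum probability negated). The q-th percentile of the oriented
#' distribution is computed (q = 100 is the maximum) and the batch is
#' filled with the cells at or below that value, walking downward —
#' i.e. preferring the most uncertain eligible cells — with residual ties
#' broken by cell id. q = 100 therefore reduces exactly to top-batch by
#' uncertainty; q = 95 or 75 targets cells near that certainty threshold,
#' a guard against preferentially querying doublets or mislabeled cells,
#' whose uncertainty tends to be extreme.
#'
#' @param u An `uncertainty_scores` tibble.
#' @param q Percentile in `(0, 100]` of the *uncertainty* distribution
#'   (100, 95, 75 are the conventional settings; for maximum probability
#'   these correspond to the 0th/5th/25th percentile of the probability).
#' @param batch Number of cells to select, default 10.
#' @return A `cellpick_selection` tibble.
#' @export
select_at_percentile <- function(u, q = 100, batch = 10) {
  if (!inherits(u, "uncertainty_scores")) {
    abort("select_at_percentile() needs uncertainty_scores")
  }
  if (batch > nrow(u)) {
    abort(sprintf("batch %d exceeds pool of %d cells", batch, nrow(u)))
  }
  oriented <- if (attr(u, "metric") == "max_probability") -u$value else u$value
  thr <- unname(quantile(oriented, q / 100, type = 7))
  eligible <- which(oriented <= thr + 1e-12)
  ord <- eligible[order(-oriented[eligible], u$cell_id[eligible])]
  take <- head(ord, batch)
  if (length(take) < batch) {
    # fewer cells at/below the percentile than requested: fill with the
    # nearest cells above it
    above <- setdiff(seq_len(nrow(u)), eligible)
    ord2 <- above[order(oriented[above], u$cell_id[above])]
    take <- c(take, head(ord2, batch - length(take)))
  }
  strategy <- paste0("al_", sub("max_probability", "maxprob",
                                sub("^scaled_", "", attr(u, "metric"))))
  new_selection(u$cell_id[take], strategy,
                list(q = q, batch = batch, metric = attr(u, "metric")))
}
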