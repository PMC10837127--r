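#' Cell-type similarity by variance-weighted cosine distance
#'
#' Each cell type is summarised by its centroid in principal-component
#' space (conventionally the first 20 PCs) and pairwise similarity is the
#' cosine of the angle between centroids under the inner product weighted
#' by each component's variance-explained fraction; distance is one minus
#' that. With uniform weights this is the ordinary cosine distance.
#'
#' @param scores Cell x component matrix, cell ids as rownames.
#' @param variance_explained Per-component weights (the embedding's
#'   variance-explained fractions).
#' @param truth Ground-truth labels; every type needs at least one cell.
#' @return A symmetric, zero-diagonal type x type distance matrix of
#'   class `similarity_matrix`.
#' @export
cell_type_similarity <- function(scores, variance_explained, truth) {
  if (length(variance_explained) != ncol(scores)) {
    abort("one weight per component is required")
  }
  lk <- label_lookup(truth)
  types <- sort(unique(lk[rownames(scores)]))
  cent <- t(vapply(types, function(t) {
    colMeans(scores[names(lk)[lk == t] |> intersect(rownames(scores)), ,
                    drop = FALSE])
  }, numeric(ncol(scores))))
  w <- variance_explained
  wnorm <- sqrt(rowSums(sweep(cent^2, 2, w, "*")))
  if (any(wnorm == 0)) {
    abort(sprintf("zero-norm centroid for: %s",
                  paste(types[wnorm == 0], collapse = ", ")))
  }
  sim <- (cent %*% (t(cent) * w)) / tcrossprod(wnorm)
  d <- 1 - sim
  d[abs(d) < 1e-12] <- 0
  diag(d) <- 0
  dimnames(d) <- list(types, types)
  class(d) <- c("similarity_matrix", class(d))
  d
}

#' @describeIn cell_type_similarity Long view of the distance matrix.
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(m, rownames = "type_a") |>
    tidyr::pivot_longer(-"type_a", names_to = "type_b",
                        values_to = "distance") |>
    filter(.data$type_a < .data$type_b)
}

#' Construct artificially (im)balanced benchmark datasets
#'
#' Subsamples a dataset to one of the standard imbalance designs:
#' \describe{
#'   \item{two_type_similar / two_type_different}{450 cells of a majority
#'     type and 50 of a minority type (500 total), the pair chosen as the
#'     most similar (resp. most distant) from a [cell_type_similarity()]
#'     matrix unless given explicitly.}
#'   \item{two_type_balanced}{250 cells of each of the two types.}
#'   \item{multi_imbalanced}{400 majority cells plus 25 from each of four
#'     minority types (500 total).}
#'   \item{multi_balanced}{100 cells from each of five types.}
#' }
#'
#' @param ds An `expr_dataset` (any transform state).
#' @param truth Ground-truth labels.
#' @param scheme One of the designs above.
#' @param similarity Optional `similarity_matrix`, needed to auto-pick
#'   the two-type pair.
#' @param types Optional explicit types, majority first; overrides the
#'   similarity-based choice. Five types for the multi schemes.
#' @param seed Integer seed.
#' @return A list: `dataset` (the subsampled `expr_dataset`), `truth`
#'   (its labels), `design` (tibble of per-type target counts).
#' @export
make_imbalanced_subsets <- function(ds, truth,
                                    scheme = c("two_type_similar",
                                               "two_type_different",
                                               "two_type_balanced",
                                               "multi_imbalanced",
                                               "multi_balanced"),
                                    similarity = NULL, types = NULL,
                                    seed = 1) {
  scheme <- match.arg(scheme)
  lk <- label_lookup(truth)
  lk <- lk[names(lk) %in% ds$cell_ids]
  avail <- table(lk)
  two_type <- grepl("^two_type", scheme)
  if (is.null(types)) {
    if (two_type) {
      if (is.null(similarity)) {
        abort("supply `types` or a `similarity` matrix to pick the pair")
      }
      m <- unclass(similarity)
      diag(m) <- NA
      pick <- if (scheme == "two_type_different") {
        which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
      } else {
        which(m == min(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
      }
      pair <- sort(rownames(m)[pick])
      # majority = the more abundant of the pair
      types <- pair[order(-avail[pair])]
    } else {
      types <- names(sort(avail, decreasing = TRUE))[1:5]
    }
  }
  counts <- switch(scheme,
    two_type_similar = c(450, 50),
    two_type_different = c(450, 50),
    two_type_balanced = c(250, 250),
    multi_imbalanced = c(400, 25, 25, 25, 25),
    multi_balanced = rep(100, 5)
  )
  if (length(types) != length(counts)) {
    abort(sprintf("scheme '%s' needs %d types, got %d", scheme,
                  length(counts), length(types)))
  }
  short <- counts > as.integer(avail[types])
  short[is.na(short)] <- TRUE
  if (any(short)) {
    abort(sprintf("not enough cells of: %s",
                  paste(types[short], collapse = ", ")))
  }
  picked <- with_seed(seed, purrr::map2(types, counts, function(t, k) {
    sample(names(lk)[lk == t], k)
  }))
  ids <- unlist(picked, use.names = FALSE)
  list(
    dataset = ds[ids, ],
    truth = tibble(cell_id = ids, cell_type = unname(lk[ids])),
    design = tibble(cell_type = types, n = counts, scheme = scheme)
  )
}

#' Randomly corrupt a fraction of a marker file
#'
#' Replaces a uniformly chosen `round(fraction * n)` of the marker entries
#' (pooled over types and directions) with random genes drawn from the
#' 10,000 most highly expressed genes of the dataset, excluding every gene
#' already present in the original marker file. Per-type membership and
#' direction are preserved. Used to probe the sensitivity of marker-aware
#' selection to mis-specified markers.
#'
#' @param spec A `marker_spec`.
#' @param ds An `expr_dataset` providing the expression ranking.
#' @param fraction Fraction of marker entries to corrupt (0.10, 0.25,
#'   0.50, 0.75 or 1.0 in the standard design).
#' @param seed Integer seed.
#' @param top_n Size of the highly-expressed replacement pool,
#'   default 10000 (clipped to the number of genes).
#' @return A corrupted `marker_spec`.
#' @export
corrupt_markers <- function(spec, ds, fraction = 0.10, seed = 1,
                            top_n = 10000) {
  long <- tidy.marker_spec(spec)
  n_corrupt <- round_half_up(fraction * nrow(long))
  if (n_corrupt == 0) return(spec)
  totals <- Matrix::colSums(ds$values)
  top <- names(sort(totals, decreasing = TRUE))[seq_len(min(top_n,
                                                            length(totals)))]
  pool <- setdiff(top, marker_union(spec))
  if (length(pool) < n_corrupt) {
    abort(sprintf("replacement pool exhausted: need %d genes, have %d",
                  n_corrupt, length(pool)))
  }
  with_seed(seed, {
    idx <- sample(nrow(long), n_corrupt)
    long$marker[idx] <- sample(pool, n_corrupt)
  })
  pos <- lapply(setNames(spec$types, spec$types), function(t)
    long$marker[long$cell_type == t & long$direction == "positive"])
  neg <- lapply(setNames(spec$types, spec$types), function(t)
    long$marker[long$cell_type == t & long$direction == "negative"])
  marker_spec(pos, neg[vapply(neg, length, integer(1)) > 0])
}

# Dispatch one selection strategy on a training pool; returns the
# selected cell ids (length = budget).
run_strategy <- function(strategy, pool_ds, oracle, markers, budget, seed,
                         al_args = list()) {
  switch(strategy,
    random = select_initial_random(pool_ds$cell_ids, budget, seed)$cell_id,
    ranked = {
      if (is.null(markers)) abort("'ranked' strategy needs markers")
      sc <- score_cells_by_markers(pool_ds, markers)
      select_initial_ranked(sc, budget)$cell_id
    },
    al_entropy = ,
    al_maxprob = {
      metric <- if (strategy == "al_entropy") "entropy" else "max_probability"
      cfg <- do.call(al_config, utils::modifyList(
        list(model_kind = "random_forest", metric = metric, budget = budget,
             seed = seed), al_args))
      init <- if (!is.null(markers)) {
        sc <- score_cells_by_markers(pool_ds, markers)
        select_initial_ranked(sc, cfg$initial_n)
      } else {
        select_initial_random(pool_ds$cell_ids, cfg$initial_n, seed)
      }
      active_learning_loop(pool_ds, oracle, cfg, init)$selection$cell_id
    },
    ar_naive = adaptive_reweighting(pool_ds, budget, markers = NULL,
                                    seed = seed)$cell_id,
    ar_marker = {
      if (is.null(markers)) abort("'ar_marker' strategy needs markers")
      adaptive_reweighting(pool_ds, budget, markers = markers,
                           seed = seed)$cell_id
    },
    abort(sprintf("unknown strategy '%s'", strategy))
  )
}

#' Benchmark cell-selection strategies
#'
#' The full comparison harness: for every stratified train/test split,
#' selection strategy and labelling budget, cells are selected from the
#' training half, labeled with ground truth, used to train the downstream
#' random-forest classifier, and evaluated on the held-out test half with
#' the five-metric panel. The result is a tidy table, one `MetricsRecord`
#' row per (split, strategy, budget) cell of the factorial grid;
#' identical seeds reproduce it exactly.
#'
#' @param ds Transformed `expr_dataset`.
#' @param truth Ground-truth labels for all cells.
#' @param strategies Character vector from `random`, `ranked`,
#'   `al_entropy`, `al_maxprob`, `ar_naive`, `ar_marker`.
#' @param budgets Numbers of cells to label (conventionally 100, 250,
#'   500).
#' @param markers `marker_spec`, required by the marker-aware strategies
#'   (and used for ranked active-learning initialisation when present).
#' @param n_splits Number of stratified 50/50 splits, default 10.
#' @param grid Downstream classifier grid.
#' @param al_args Named list of [al_config()] overrides (e.g.
#'   `list(q = 95, model_kind = "logistic_regression")`).
#' @param seed Integer seed governing splits, selections and model fits.
#' @return A `cellpick_benchmark` tibble with columns `split`, `strategy`,
#'   `budget`, the five metrics, and `n_cells`.
#' @export
run_benchmark <- function(ds, truth, strategies = c("random", "al_entropy"),
                          budgets = 100, markers = NULL, n_splits = 10,
                          grid = downstream_grid(), al_args = list(),
                          seed = 1) {
  lf <- assert_no_reserved(truth, "truth")
  splits <- stratified_split(lf, 0.5, n_splits, seed = seed)
  design <- expand.grid(split = seq_len(n_splits), strategy = strategies,
                        budget = budgets, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  rows <- purrr::pmap(design, function(split, strategy, budget) {
    sp <- split_ids(splits, split)
    pool <- ds[sp$train, ]
    test <- ds[sp$test, ]
    lk <- label_lookup(lf)
    run_seed <- derive_seed(seed, split * 131L + match(strategy, strategies))
    sel <- run_strategy(strategy, pool, lf, markers, budget, run_seed,
                        al_args)
    train_labels <- tibble(cell_id = sel, cell_type = unname(lk[sel]))
    fit <- train_downstream_rf(ds[sel, ], train_labels, grid = grid,
                               seed = run_seed)
    pred <- predict(fit, test)
    evaluate_predictions(pred,
                         tibble(cell_id = sp$test,
                                cell_type = unname(lk[sp$test]))) |>
      mutate(split = split, strategy = strategy, budget = budget,
             .before = 1)
  })
  out <- bind_rows(rows)
  class(out) <- c("cellpick_benchmark", class(out))
  out
}

#' Rank strategies from a benchmark table
#'
#' Orders strategies by median balanced accuracy (and reports the median
#' sensitivity alongside) across splits and budgets, the headline ranking
#' of the selection-strategy comparison.
#'
#' @param results A `cellpick_benchmark` tibble.
#' @return A tibble, one row per strategy, best first.
#' @export
rank_strategies <- function(results) {
  results |>
    group_by(.data$strategy) |>
    summarise(median_balanced_accuracy = median(.data$balanced_accuracy),
              median_sensitivity = median(.data$sensitivity),
              median_f1 = median(.data$f1),
              n_records = n(), .groups = "drop") |>
    arrange(desc(.data$median_balanced_accuracy)) |>
    mutate(rank = row_number(), .before = 1)
}
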