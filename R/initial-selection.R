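#' Score cells by marker expression
#'
#' For every cell type in the marker spec, each cell's score is the mean
#' transformed expression of that type's positive markers present in the
#' data. Markers absent from the data are dropped with a warning; a type
#' with none of its markers present is an error. Negative markers are not
#' used here (they enter only in marker-aware adaptive reweighting).
#'
#' @param ds A transformed `expr_dataset` (lognorm/arcsinh scale, so
#'   marker means are comparable).
#' @param spec A `marker_spec`.
#' @return A cell x type numeric matrix (class `marker_scores`), columns
#'   in marker-spec order.
#' @export
score_cells_by_markers <- function(ds, spec) {
  assert_state(ds, c("lognorm", "arcsinh"), "score_cells_by_markers")
  x <- ds$values
  scores <- matrix(NA_real_, nrow(x), length(spec$types),
                   dimnames = list(ds$cell_ids, spec$types))
  for (t in spec$types) {
    mk <- spec$positive[[t]]
    present <- mk[mk %in% ds$feature_ids]
    missing <- setdiff(mk, present)
    if (length(present) == 0) {
      abort(sprintf("no positive markers of type '%s' are present in the data", t))
    }
    if (length(missing) > 0) {
      warn(sprintf("type '%s': dropping %d markers absent from the data (%s)",
                   t, length(missing), paste(missing, collapse = ", ")))
    }
    scores[, t] <- Matrix::rowMeans(x[, present, drop = FALSE])
  }
  class(scores) <- c("marker_scores", class(scores))
  scores
}

new_selection <- function(cell_ids, strategy, params = list(),
                          iteration = NA_integer_) {
  out <- tibble(cell_id = cell_ids, strategy = strategy,
                rank = seq_along(cell_ids),
                iteration = rep_len(iteration, length(cell_ids)))
  attr(out, "params") <- params
  class(out) <- c("cellpick_selection", class(out))
  out
}

#' Randomly select an initial training set
#'
#' Uniform sample without replacement from the cell pool — the baseline
#' way to seed an active-learning model, which under class imbalance will
#' typically miss rare types.
#'
#' @param cell_ids Character vector: the selectable pool.
#' @param n Number of cells, default 20.
#' @param seed Integer seed.
#' @return A `cellpick_selection` tibble (`cell_id`, `strategy`, `rank`,
#'   `iteration`).
#' @export
select_initial_random <- function(cell_ids, n = 20, seed = 1) {
  if (n > length(cell_ids)) {
    abort(sprintf("requested %d cells from a pool of %d", n, length(cell_ids)))
  }
  picked <- with_seed(seed, sample(cell_ids, n))
  new_selection(picked, "random", list(n = n, seed = seed), iteration = 0L)
}

#' Marker-ranked initial selection
#'
#' Round-robin over cell types in marker-spec order: at each turn the
#' highest-scoring not-yet-selected cell for the current type is taken,
#' looping over types until `n` cells are chosen. Deterministic: score
#' ties break lexicographically by cell id; a type whose best cell was
#' already claimed takes its runner-up.
#'
#' @param scores A `marker_scores` matrix from [score_cells_by_markers()].
#' @param n Number of cells, default 20.
#' @return A `cellpick_selection` tibble, with a `cell_type` column naming
#'   the type whose turn selected each cell.
#' @export
select_initial_ranked <- function(scores, n = 20) {
  if (n < 1) abort("n must be >= 1")
  if (n > nrow(scores)) {
    abort(sprintf("requested %d cells from a pool of %d", n, nrow(scores)))
  }
  types <- colnames(scores)
  cells <- rownames(scores)
  # per-type ranking, ties lexicographic by cell id
  order_by_type <- lapply(types, function(t)
    cells[order(-scores[, t], cells)])
  names(order_by_type) <- types
  picked <- character(0)
  picked_for <- character(0)
  turn <- 0L
  while (length(picked) < n) {
    t <- types[(turn %% length(types)) + 1L]
    cand <- order_by_type[[t]]
    nxt <- cand[!(cand %in% picked)][1]
    if (!is.na(nxt)) {
      picked <- c(picked, nxt)
      picked_for <- c(picked_for, t)
    }
    turn <- turn + 1L
  }
  out <- new_selection(picked, "ranked", list(n = n), iteration = 0L)
  out$cell_type <- picked_for
  out
}

#' Cell-type coverage of a selection
#'
#' Fraction of all ground-truth cell types represented among the selected
#' cells — the headline property distinguishing ranked from random initial
#' selection.
#'
#' @param selection A `cellpick_selection` (or anything with a `cell_id`
#'   column / character vector of ids).
#' @param truth Ground-truth labels covering the selected cells.
#' @return A fraction in `[0, 1]`.
#' @export
cell_type_coverage <- function(selection, truth) {
  ids <- if (is.data.frame(selection)) selection$cell_id else as.character(selection)
  lk <- label_lookup(truth)
  miss <- setdiff(ids, names(lk))
  if (length(miss) > 0) {
    abort(sprintf("truth is missing labels for %d selected cells", length(miss)))
  }
  length(unique(lk[ids])) / length(unique(lk))
}
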