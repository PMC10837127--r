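#' Fit a principal-component embedding
#'
#' Features are centered and scaled to unit variance (zero-variance
#' features keep scale 1 so they survive without dividing by zero), then a
#' truncated PCA is fit. A fixed sign convention — the largest-magnitude
#' loading of every component is positive — makes the embedding
#' deterministic, which matters because downstream cell selection depends
#' on it.
#'
#' @param ds A transformed `expr_dataset` (`lognorm` or `arcsinh`).
#' @param n_components Number of components to keep; at most
#'   `min(cells, features)`.
#' @return A `cell_embedding`: rotation (feature x component), center and
#'   scale vectors, `variance_explained` fractions, and `scores`, the
#'   cell x component projection of the training data.
#' @export
fit_embedding <- function(ds, n_components = 20) {
  assert_state(ds, c("lognorm", "arcsinh"), "fit_embedding")
  x <- dense_values(ds)
  if (n_components < 1 || n_components > min(dim(x))) {
    abort(sprintf("n_components must be in [1, %d]", min(dim(x))))
  }
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  scl <- ifelse(sdv > 0, sdv, 1)
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  pc <- prcomp(xs, center = FALSE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  # sign convention: largest |loading| per component is positive
  flip <- vapply(seq_len(ncol(rot)), function(k) {
    v <- rot[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  total_var <- sum(apply(xs, 2, stats::var))
  ve <- pc$sdev[seq_len(n_components)]^2 / total_var
  scores <- xs %*% rot
  rownames(scores) <- ds$cell_ids
  structure(
    list(n_components = n_components, rotation = rot, center = ctr,
         scale = scl, variance_explained = ve, scores = scores),
    class = "cell_embedding"
  )
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat(sprintf("<cell_embedding> %d components over %d features (%.1f%% variance)\n",
              x$n_components, nrow(x$rotation),
              100 * sum(x$variance_explained)))
  invisible(x)
}

#' Project cells into a fitted embedding
#'
#' @param ds A transformed `expr_dataset` with the same features the
#'   embedding was fit on.
#' @param embedding A `cell_embedding` from [fit_embedding()].
#' @return Cell x component score matrix.
#' @export
project_cells <- function(ds, embedding) {
  assert_state(ds, c("lognorm", "arcsinh"), "project_cells")
  x <- dense_values(ds)
  if (!identical(colnames(x), rownames(embedding$rotation))) {
    if (!all(rownames(embedding$rotation) %in% colnames(x))) {
      abort("dataset is missing features the embedding was fit on")
    }
    x <- x[, rownames(embedding$rotation), drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, embedding$center, "-"), 2, embedding$scale, "/")
  s <- xs %*% embedding$rotation
  rownames(s) <- ds$cell_ids
  s
}

#' Stratified train/test splits
#'
#' Repeated stratified splits: within every cell type,
#' `floor(n_type * fraction)` cells go to train and the remainders are
#' topped up largest-fraction-first until the overall train size is
#' `round(n * fraction)`, so per-type proportions are preserved to within
#' one cell. Each type keeps at least one cell on both sides.
#'
#' @param labels Ground-truth labels (tibble `cell_id`,`cell_type` or named
#'   vector); every type needs at least 2 cells.
#' @param train_fraction Fraction of cells in the train half, default 0.5.
#' @param n_splits Number of independent replicates, default 10.
#' @param seed Integer seed; same seed, same splits.
#' @return A tibble with columns `split` (1..n_splits), `cell_id`,
#'   `cell_type`, `role` (`"train"`/`"test"`).
#' @export
stratified_split <- function(labels, train_fraction = 0.5, n_splits = 10,
                             seed = 1) {
  lf <- as_label_frame(labels)
  counts <- table(lf$cell_type)
  if (any(counts < 2)) {
    abort(sprintf("types with a single cell cannot be split: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  types <- unique(lf$cell_type)
  n <- nrow(lf)
  target_total <- round_half_up(n * train_fraction)
  n_type <- as.integer(counts[types])
  base <- floor(n_type * train_fraction)
  frac <- n_type * train_fraction - base
  extra <- target_total - sum(base)
  quota <- base
  if (extra > 0) {
    ord <- order(-frac, seq_along(types))
    bump <- head(ord[quota[ord] < n_type[ord] - 1L], extra)
    quota[bump] <- quota[bump] + 1L
  }
  quota <- pmax(pmin(quota, n_type - 1L), 1L)  # both sides non-empty
  purrr::map_dfr(seq_len(n_splits), function(s) {
    with_seed(derive_seed(seed, s), {
      rows <- purrr::map2_dfr(types, quota, function(t, q) {
        ids <- lf$cell_id[lf$cell_type == t]
        tr <- sample(ids, q)
        tibble(cell_id = ids, cell_type = t,
               role = ifelse(ids %in% tr, "train", "test"))
      })
      mutate(rows, split = s, .before = 1)
    })
  })
}

#' Extract one split from a [stratified_split()] table
#' @param splits Output of [stratified_split()].
#' @param i Split number.
#' @return List with character vectors `train` and `test` of cell ids.
#' @export
split_ids <- function(splits, i) {
  s <- dplyr::filter(splits, .data$split == i)
  if (nrow(s) == 0) abort(sprintf("no split %s in table", i))
  list(train = s$cell_id[s$role == "train"],
       test = s$cell_id[s$role == "test"])
}
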