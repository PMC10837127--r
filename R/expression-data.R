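#' Construct an expression dataset
#'
#' The central container for a cells-by-features expression matrix together
#' with its identifiers, modality and transformation state. RNA modalities
#' hold raw counts; the CyTOF modality holds nonnegative marker intensities.
#' Sparse matrices (`Matrix::dgCMatrix`) are kept sparse until an operation
#' (scaling ahead of PCA) requires densification.
#'
#' @param values Numeric matrix or sparse Matrix, cells in rows, features in
#'   columns.
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   rownames of `values`).
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to colnames of `values`).
#' @param modality `"rna"` or `"cytof"`.
#' @param transform_state One of `"raw"`, `"lognorm"`, `"arcsinh"`,
#'   `"scaled"`. New data should always enter as `"raw"`.
#' @return An object of class `expr_dataset`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 4), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' ds <- expression_dataset(m)
#' ds
expression_dataset <- function(values,
                               cell_ids = rownames(values),
                               feature_ids = colnames(values),
                               modality = c("rna", "cytof"),
                               transform_state = c("raw", "lognorm",
                                                   "arcsinh", "scaled")) {
  modality <- match.arg(modality)
  transform_state <- match.arg(transform_state)
  if (is.null(cell_ids) || is.null(feature_ids)) {
    abort("cell and feature identifiers are required (rownames/colnames or explicit)")
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values) || length(feature_ids) != ncol(values)) {
    abort("identifier lengths must match matrix dimensions")
  }
  if (anyDuplicated(cell_ids)) {
    abort(sprintf("duplicate cell ids: %s",
                  paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(feature_ids)) {
    abort(sprintf("duplicate feature ids: %s",
                  paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")))
  }
  if (transform_state == "raw" && any(values < 0)) {
    abort("raw expression values must be nonnegative")
  }
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         modality = modality, transform_state = transform_state),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d cells x %d features [%s, %s, %s]\n",
              nrow(x$values), ncol(x$values), x$modality, x$transform_state,
              if (inherits(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Subset an expression dataset by cells and/or features
#'
#' @param x An `expr_dataset`.
#' @param i Cell ids (character) or indices.
#' @param j Feature ids (character) or indices.
#' @param ... Unused.
#' @return An `expr_dataset` with the requested cells/features.
#' @export
`[.expr_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$cell_ids)
  if (missing(j)) j <- seq_along(x$feature_ids)
  v <- x$values[i, j, drop = FALSE]
  expression_dataset(v, modality = x$modality,
                     transform_state = x$transform_state)
}

# Internal: dense numeric matrix view of the values.
dense_values <- function(ds) {
  as.matrix(ds$values)
}

assert_state <- function(ds, allowed, op) {
  if (!inherits(ds, "expr_dataset")) abort(sprintf("%s() needs an expr_dataset", op))
  if (!ds$transform_state %in% allowed) {
    abort(sprintf("%s() requires transform_state in {%s}, got '%s'",
                  op, paste(allowed, collapse = ", "), ds$transform_state))
  }
  invisible(ds)
}

#' Log-normalize RNA counts
#'
#' Library-size normalization followed by a log2 transform: each cell's
#' size factor is its total count divided by the mean total over cells
#' (factors average to 1), and each value becomes
#' `log2(count / size_factor + 1)`. This is the standard logcounts
#' computation used throughout single-cell RNA workflows.
#'
#' @param ds An `expr_dataset` with `modality = "rna"` and raw counts.
#' @return An `expr_dataset` with `transform_state = "lognorm"`.
#' @export
lognormalize <- function(ds) {
  assert_state(ds, "raw", "lognormalize")
  if (ds$modality != "rna") abort("lognormalize() applies to the rna modality")
  totals <- Matrix::rowSums(ds$values)
  zero <- totals == 0
  if (any(zero)) {
    abort(sprintf("cells with zero total counts: %s",
                  paste(ds$cell_ids[zero], collapse = ", ")))
  }
  sf <- totals / mean(totals)
  if (inherits(ds$values, "sparseMatrix")) {
    v <- methods::as(Matrix::Diagonal(x = 1 / sf) %*% ds$values, "CsparseMatrix")
    v@x <- log2(v@x + 1)  # log2(0 + 1) = 0, zeros stay zero
    dimnames(v) <- dimnames(ds$values)
  } else {
    v <- log2(ds$values / sf + 1)
  }
  out <- ds
  out$values <- v
  out$transform_state <- "lognorm"
  out
}

#' Arcsinh-transform CyTOF intensities
#'
#' The conventional mass-cytometry variance-stabilizing transform
#' `asinh(value / cofactor)` with a default cofactor of 5.
#'
#' @param ds An `expr_dataset` with `modality = "cytof"` and raw values.
#' @param cofactor Positive scaling constant, default 5.
#' @return An `expr_dataset` with `transform_state = "arcsinh"`.
#' @export
arcsinh_transform <- function(ds, cofactor = 5) {
  assert_state(ds, "raw", "arcsinh_transform")
  if (ds$modality != "cytof") abort("arcsinh_transform() applies to the cytof modality")
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    abort("cofactor must be a single positive number")
  }
  v <- ds$values
  if (inherits(v, "sparseMatrix")) {
    v@x <- asinh(v@x / cofactor)
  } else {
    v <- asinh(v / cofactor)
  }
  out <- ds
  out$values <- v
  out$transform_state <- "arcsinh"
  out
}

#' Apply the modality-appropriate default transform
#'
#' Convenience wrapper: `lognormalize()` for RNA, `arcsinh_transform()`
#' for CyTOF. Datasets already transformed are returned unchanged.
#'
#' @param ds An `expr_dataset`.
#' @param cofactor Arcsinh cofactor for the cytof modality.
#' @return A transformed `expr_dataset`.
#' @export
transform_default <- function(ds, cofactor = 5) {
  if (ds$transform_state != "raw") return(ds)
  if (ds$modality == "rna") lognormalize(ds) else arcsinh_transform(ds, cofactor)
}
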