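#' Read an expression matrix from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx`}{MatrixMarket triplet file with TSV sidecars. `path` is the
#'     `.mtx` file; `<stem>_barcodes.tsv` (or `barcodes.tsv` next to it) holds
#'     cell ids and `<stem>_features.tsv` (or `features.tsv`) feature ids, one
#'     per line. The stored matrix is features x cells (the community
#'     convention) and is transposed on read; data stay sparse.}
#'   \item{`csv`}{Dense cells x features table; header row = feature ids,
#'     first column = cell ids.}
#'   \item{`h5container`}{HDF5 single-cell container in the community h5ad
#'     layout: `X` (dense, or CSR group with data/indices/indptr),
#'     `obs`/`var` with an `_index` column. Requires the rhdf5 package.}
#' }
#'
#' @param path File to read.
#' @param format One of `"mtx"`, `"csv"`, `"h5container"`.
#' @param modality `"rna"` or `"cytof"`.
#' @return An `expr_dataset` with `transform_state = "raw"`.
#' @export
load_expression <- function(path, format = c("mtx", "csv", "h5container"),
                            modality = c("rna", "cytof")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  switch(format,
    mtx = load_expression_mtx(path, modality),
    csv = load_expression_csv(path, modality),
    h5container = load_expression_h5(path, modality)
  )
}

mtx_sidecar <- function(path, kind) {
  stem <- sub("\\.mtx$", "", path)
  cands <- c(paste0(stem, "_", kind, ".tsv"),
             file.path(dirname(path), paste0(kind, ".tsv")))
  hit <- cands[file.exists(cands)]
  if (length(hit) == 0) {
    abort(sprintf("missing %s sidecar for %s (looked for %s)",
                  kind, path, paste(cands, collapse = ", ")))
  }
  hit[[1]]
}

load_expression_mtx <- function(path, modality) {
  m <- Matrix::readMM(path)
  feats <- read.delim(mtx_sidecar(path, "features"), header = FALSE)[[1]]
  cells <- read.delim(mtx_sidecar(path, "barcodes"), header = FALSE)[[1]]
  if (nrow(m) != length(feats) || ncol(m) != length(cells)) {
    abort(sprintf(
      "matrix is %d x %d but sidecars list %d features and %d cells",
      nrow(m), ncol(m), length(feats), length(cells)))
  }
  m <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(m) <- list(as.character(cells), as.character(feats))
  expression_dataset(m, modality = modality)
}

load_expression_csv <- function(path, modality) {
  df <- read.csv(path, check.names = FALSE)
  cells <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- cells
  storage.mode(m) <- "double"
  expression_dataset(m, modality = modality)
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    abort("HDF5 container support needs the rhdf5 package")
  }
}

h5_index <- function(path, group) {
  attrs <- rhdf5::h5readAttributes(path, group)
  idx_col <- attrs[["_index"]] %||% "_index"
  as.character(rhdf5::h5read(path, paste0(group, "/", idx_col)))
}

load_expression_h5 <- function(path, modality) {
  require_rhdf5()
  on.exit(rhdf5::h5closeAll())
  cells <- h5_index(path, "obs")
  feats <- h5_index(path, "var")
  xattr <- rhdf5::h5readAttributes(path, "X")
  enc <- xattr[["encoding-type"]] %||% ""
  if (identical(enc, "csr_matrix") ||
      all(c("data", "indices", "indptr") %in% rhdf5::h5ls(path)$name[
        rhdf5::h5ls(path)$group == "/X"])) {
    dat <- as.numeric(rhdf5::h5read(path, "X/data"))
    ind <- as.integer(rhdf5::h5read(path, "X/indices"))
    ptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    # CSR over cells x features == CSC of the transposed matrix
    m <- Matrix::sparseMatrix(j = ind + 1L, p = ptr, x = dat,
                              dims = c(length(cells), length(feats)))
    m <- methods::as(m, "CsparseMatrix")
  } else {
    m <- rhdf5::h5read(path, "X")
    # h5 stores column-major; anndata writes cells x features transposed
    m <- t(m)
    storage.mode(m) <- "double"
  }
  dimnames(m) <- list(cells, feats)
  expression_dataset(m, modality = modality)
}

#' Write an expression matrix to disk
#'
#' Inverse of [load_expression()] for each format; see that function for
#' the on-disk layouts. Raw or transformed datasets may be written; only
#' the values and identifiers are stored.
#'
#' @param ds An `expr_dataset`.
#' @param path Output file.
#' @param format One of `"mtx"`, `"csv"`, `"h5container"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path, format = c("mtx", "csv", "h5container")) {
  format <- match.arg(format)
  switch(format,
    mtx = {
      m <- Matrix::t(methods::as(methods::as(ds$values, "CsparseMatrix"),
                                 "generalMatrix"))
      Matrix::writeMM(m, path)
      stem <- sub("\\.mtx$", "", path)
      writeLines(ds$feature_ids, paste0(stem, "_features.tsv"))
      writeLines(ds$cell_ids, paste0(stem, "_barcodes.tsv"))
    },
    csv = {
      df <- data.frame(cell_id = ds$cell_ids, dense_values(ds),
                       check.names = FALSE)
      write.csv(df, path, row.names = FALSE)
    },
    h5container = {
      require_rhdf5()
      on.exit(rhdf5::h5closeAll())
      if (file.exists(path)) file.remove(path)
      rhdf5::h5createFile(path)
      rhdf5::h5write(t(dense_values(ds)), path, "X")
      for (grp in c("obs", "var")) rhdf5::h5createGroup(path, grp)
      rhdf5::h5write(ds$cell_ids, path, "obs/_index")
      rhdf5::h5write(ds$feature_ids, path, "var/_index")
    }
  )
  invisible(path)
}

#' Read a per-cell label table
#'
#' Two-column CSV `cell_id, cell_type`.
#'
#' @param path CSV file.
#' @return A tibble with columns `cell_id`, `cell_type`.
#' @export
load_labels <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) abort("label file needs columns cell_id, cell_type")
  as_label_frame(setNames(df[, 1:2], c("cell_id", "cell_type")), arg = path)
}

#' Write a per-cell label table
#' @param labels Labels (tibble or named vector).
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.csv(as_label_frame(labels), path, row.names = FALSE)
  invisible(path)
}
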