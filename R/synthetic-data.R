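#' Synthetic-data generator configuration
#'
#' Describes a dataset with K cell types, each over-expressing its own
#' marker genes, with tunable type proportions (down to rare types),
#' tunable between-type similarity (pairs sharing a fraction of their
#' expression program), negative-binomial counts for RNA modalities and
#' nonnegative continuous intensities for CyTOF-like data.
#'
#' @param n_cells Number of cells, default 2000.
#' @param n_genes Number of genes/markers measured, default 200.
#' @param proportions Named numeric vector of per-type proportions summing
#'   to 1; names are the type names. Default: five equal types.
#' @param markers_per_type Marker genes per type, default 5.
#' @param marker_effect Log2-fold over-expression of a type's markers,
#'   default 2 (four-fold).
#' @param similarity Optional tibble/data frame with columns
#'   `type_a`, `type_b`, `shared_fraction` in `[0, 1]`: `type_b`'s mean
#'   program is blended toward `type_a`'s by that fraction.
#' @param modality `"rna"` (negative-binomial counts) or `"cytof"`
#'   (truncated-Gaussian intensities).
#' @param dispersion Negative-binomial size parameter, default 2 (smaller
#'   = more overdispersed).
#' @param seed Integer seed; fixes every byte of the output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cells = 2000, n_genes = 200,
                             proportions = NULL, markers_per_type = 5,
                             marker_effect = 2, similarity = NULL,
                             modality = c("rna", "cytof"),
                             dispersion = 2, seed = 1) {
  modality <- match.arg(modality)
  if (is.null(proportions)) {
    proportions <- setNames(rep(1 / 5, 5), paste0("type", 1:5))
  }
  if (is.null(names(proportions)) || any(names(proportions) == "")) {
    abort("`proportions` must be named by cell type")
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    abort(sprintf("proportions must sum to 1 (got %.4f)", sum(proportions)))
  }
  if (marker_effect < 0) abort("marker_effect must be >= 0")
  if (!is.null(similarity)) {
    need <- c("type_a", "type_b", "shared_fraction")
    if (!all(need %in% names(similarity))) {
      abort("`similarity` needs columns type_a, type_b, shared_fraction")
    }
    if (any(similarity$shared_fraction < 0 | similarity$shared_fraction > 1)) {
      abort("shared_fraction must be in [0, 1]")
    }
  }
  k <- length(proportions)
  if (n_genes < k * markers_per_type) {
    abort("n_genes must accommodate markers_per_type markers per type")
  }
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 proportions = proportions,
                 markers_per_type = markers_per_type,
                 marker_effect = marker_effect, similarity = similarity,
                 modality = modality, dispersion = dispersion, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic expression dataset
#'
#' Draws a dataset under a [generator_config()]: per-type mean vectors are
#' a shared lognormal baseline with each type's markers up-shifted by
#' `2^marker_effect`; similarity links convexly blend one type's mean
#' program toward another's; cell types are assigned multinomially by the
#' configured proportions. RNA counts are negative-binomial around the
#' type mean; CyTOF intensities are Gaussian around it, truncated at
#' zero. The returned marker spec lists each type's true markers.
#'
#' @param config A `generator_config` (or arguments forwarded to it via
#'   `...`).
#' @param ... Passed to [generator_config()] when `config` is missing.
#' @return A list: `dataset` (raw `expr_dataset`), `truth` (label
#'   tibble), `markers` (`marker_spec`), `config`.
#' @export
simulate_cells <- function(config = NULL, ...) {
  config <- config %||% generator_config(...)
  k <- length(config$proportions)
  types <- names(config$proportions)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  cells <- sprintf("cell%05d", seq_len(config$n_cells))
  with_seed(config$seed, {
    baseline <- rlnorm(config$n_genes, meanlog = log(2), sdlog = 0.6)
    marker_idx <- split(seq_len(k * config$markers_per_type),
                        rep(seq_len(k), each = config$markers_per_type))
    mu <- matrix(rep(baseline, k), nrow = k, byrow = TRUE,
                 dimnames = list(types, genes))
    for (i in seq_len(k)) {
      mu[i, marker_idx[[i]]] <- mu[i, marker_idx[[i]]] * 2^config$marker_effect
    }
    if (!is.null(config$similarity)) {
      for (r in seq_len(nrow(config$similarity))) {
        a <- config$similarity$type_a[r]
        b <- config$similarity$type_b[r]
        s <- config$similarity$shared_fraction[r]
        if (!all(c(a, b) %in% types)) abort("similarity names unknown types")
        mu[b, ] <- (1 - s) * mu[b, ] + s * mu[a, ]
      }
    }
    type_of <- sample(types, config$n_cells, replace = TRUE,
                      prob = config$proportions)
    m <- matrix(0, config$n_cells, config$n_genes,
                dimnames = list(cells, genes))
    for (t in types) {
      rows <- which(type_of == t)
      if (length(rows) == 0) next
      n_draw <- length(rows) * config$n_genes
      vals <- if (config$modality == "rna") {
        rnbinom(n_draw, mu = rep(mu[t, ], each = length(rows)),
                size = config$dispersion)
      } else {
        pmax(0, rnorm(n_draw, mean = rep(mu[t, ], each = length(rows)),
                      sd = rep(0.3 * mu[t, ] + 0.5, each = length(rows))))
      }
      m[rows, ] <- vals
    }
    markers <- marker_spec(lapply(setNames(seq_len(k), types),
                                  function(i) genes[marker_idx[[i]]]))
    list(
      dataset = expression_dataset(m, modality = config$modality),
      truth = tibble(cell_id = cells, cell_type = type_of),
      markers = markers,
      config = config
    )
  })
}

#' Generate a dataset with a pair of types at controlled similarity
#'
#' Convenience wrapper around [simulate_cells()] producing a pair of
#' types whose mean programs share the given fraction, plus a small
#' anchor type with its own program. The anchor matters: centroids in
#' centered principal-component space are positions relative to the grand
#' mean, so with only two types the angle between two near-identical
#' types is dominated by sampling noise; a third type fixes the frame.
#' The weighted-cosine distance between the pair's centroids then
#' decreases monotonically as `shared_fraction` rises (0 = maximally
#' distinct for the configuration, 1 = indistinguishable in expectation).
#'
#' @param shared_fraction Fraction of the second type's mean program
#'   copied from the first, in `[0, 1]`.
#' @param proportions Pair proportions, default
#'   `c(typeA = 0.5, typeB = 0.5)`; rescaled to leave room for the
#'   anchor.
#' @param anchor_proportion Share of cells given to the anchor type,
#'   default 0.2; set to 0 to omit it.
#' @param ... Further [generator_config()] arguments.
#' @return As [simulate_cells()]; the pair types keep their given names,
#'   the anchor is named `"anchor"`.
#' @export
simulate_similar_pair <- function(shared_fraction,
                                  proportions = c(typeA = 0.5, typeB = 0.5),
                                  anchor_proportion = 0.2, ...) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("shared_fraction must be in [0, 1]")
  }
  if (length(proportions) != 2) abort("exactly two pair types are required")
  props <- proportions / sum(proportions) * (1 - anchor_proportion)
  if (anchor_proportion > 0) props <- c(props, anchor = anchor_proportion)
  cfg <- generator_config(
    proportions = props,
    similarity = tibble(type_a = names(proportions)[1],
                        type_b = names(proportions)[2],
                        shared_fraction = shared_fraction),
    ...
  )
  simulate_cells(cfg)
}
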