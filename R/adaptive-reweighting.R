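#' Cluster cells on a shared-nearest-neighbor graph
#'
#' The unsupervised backbone of adaptive reweighting: k nearest Euclidean
#' neighbors in the embedding, a shared-nearest-neighbor graph with
#' Jaccard edge weights (edges below 1/15 pruned), and modularity-based
#' community detection (Louvain) at the given resolution. Cluster ids are
#' contiguous from 0, ordered by decreasing cluster size for determinism.
#'
#' @param embedding Cell x component score matrix (conventionally the
#'   first 30 principal components), cell ids as rownames.
#' @param resolution Modularity resolution parameter (0.4, 0.8, 1.2 are
#'   the conventional settings).
#' @param n_neighbors Neighborhood size k (10, 20 or 30); needs at least
#'   `n_neighbors + 1` cells.
#' @param seed Integer seed for the community search.
#' @param prune Jaccard weight below which SNN edges are dropped,
#'   default 1/15.
#' @return A `cluster_assignment` tibble (`cell_id`, `cluster`) with the
#'   parameters stored as an attribute.
#' @export
cluster_cells <- function(embedding, resolution = 0.8, n_neighbors = 20,
                          seed = 1, prune = 1 / 15) {
  n <- nrow(embedding)
  if (n < n_neighbors + 1) {
    abort(sprintf("need at least %d cells for %d neighbors",
                  n_neighbors + 1, n_neighbors))
  }
  if (is.null(rownames(embedding))) abort("embedding needs cell ids as rownames")
  d <- as.matrix(stats::dist(embedding))
  # neighbor sets include the cell itself, as is conventional for SNN
  nb <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    head(ord, n_neighbors)
  })
  nb_mat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) nb_mat[i, nb[[i]]] <- TRUE
  shared <- tcrossprod(nb_mat * 1)            # |N_i intersect N_j|
  jac <- shared / (2 * n_neighbors - shared)  # Jaccard of equal-size sets
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  # contiguous ids from 0, largest cluster first; ties by first member
  sizes <- table(memb)
  first <- vapply(names(sizes), function(cl) min(which(memb == cl)), numeric(1))
  ord <- names(sizes)[order(-as.integer(sizes), first)]
  new_id <- setNames(seq_along(ord) - 1L, ord)
  out <- tibble(cell_id = rownames(embedding),
                cluster = unname(new_id[as.character(memb)]))
  attr(out, "params") <- list(resolution = resolution,
                              n_neighbors = n_neighbors, seed = seed,
                              prune = prune)
  class(out) <- c("cluster_assignment", class(out))
  out
}

# Seeded uniform sampling of `quota` cells from each pool (a named list of
# cell-id vectors); pools sampled in order for reproducibility.
sample_pools <- function(pools, quota, seed) {
  with_seed(seed, {
    purrr::map2(pools, quota, function(ids, q) {
      if (q >= length(ids)) ids else sample(ids, q)
    })
  })
}

#' Evenly subsample cells per cluster (naive adaptive reweighting)
#'
#' The requested number of cells is divided by the number of clusters;
#' clusters smaller than their share contribute all their cells, with the
#' deficit redistributed evenly over the remaining clusters
#' (largest-remainder rounding, ties to the lowest cluster id). Because
#' clusters track cell types, the result approximates a class-balanced
#' labeled set without using any labels.
#'
#' @param clusters A `cluster_assignment` from [cluster_cells()].
#' @param n_requested Total cells to select (at most the number of cells).
#' @param seed Integer seed for within-cluster sampling.
#' @return A `cellpick_selection` tibble with a `cluster` column.
#' @export
sample_even_by_cluster <- function(clusters, n_requested, seed = 1) {
  if (n_requested > nrow(clusters)) {
    abort(sprintf("requested %d cells from %d", n_requested, nrow(clusters)))
  }
  ids <- sort(unique(clusters$cluster))
  pools <- lapply(ids, function(cl) clusters$cell_id[clusters$cluster == cl])
  quota <- distribute_quota(lengths(pools), n_requested)
  picked <- sample_pools(pools, quota, seed)
  out <- new_selection(unlist(picked, use.names = FALSE), "ar_naive",
                       list(n = n_requested, seed = seed))
  out$cluster <- rep(ids, lengths(picked))
  out
}

#' Assign clusters to putative cell types by marker enrichment
#'
#' For every cluster and marker-spec type, the enrichment score is the
#' cluster mean of the type's average positive-marker expression minus its
#' average negative-marker expression (zero when no negatives are given).
#' Each cluster is assigned the type with its highest enrichment (ties to
#' the earlier type in the spec). Several clusters may map to one type —
#' the situation the marker-aware sampler exists to repair.
#'
#' @param ds Transformed `expr_dataset`.
#' @param clusters A `cluster_assignment`.
#' @param spec A `marker_spec`.
#' @return A `cluster_type_map`: `enrichment` (cluster x type matrix) and
#'   `assigned_type` (named by cluster id).
#' @export
assign_clusters_to_types <- function(ds, clusters, spec) {
  pos_scores <- score_cells_by_markers(ds, spec)
  has_neg <- vapply(spec$types, function(t) length(spec$negative[[t]]) > 0,
                    logical(1))
  neg_scores <- matrix(0, nrow(pos_scores), ncol(pos_scores),
                       dimnames = dimnames(pos_scores))
  for (t in spec$types[has_neg]) {
    mk <- intersect(spec$negative[[t]], ds$feature_ids)
    if (length(mk) > 0) {
      neg_scores[, t] <- Matrix::rowMeans(ds$values[, mk, drop = FALSE])
    }
  }
  net <- pos_scores - neg_scores
  ids <- sort(unique(clusters$cluster))
  enrich <- t(vapply(ids, function(cl) {
    colMeans(net[clusters$cell_id[clusters$cluster == cl], , drop = FALSE])
  }, numeric(length(spec$types))))
  rownames(enrich) <- ids
  colnames(enrich) <- spec$types
  assigned <- spec$types[apply(enrich, 1, which.max)]  # ties -> earlier type
  unassigned <- setdiff(spec$types, assigned)
  if (length(unassigned) > 0) {
    warn(sprintf("marker-spec types winning no cluster: %s",
                 paste(unassigned, collapse = ", ")))
  }
  structure(list(enrichment = enrich,
                 assigned_type = setNames(assigned, ids)),
            class = "cluster_type_map")
}

#' @export
print.cluster_type_map <- function(x, ...) {
  cat(sprintf("<cluster_type_map> %d clusters -> %d assigned types\n",
              nrow(x$enrichment), length(unique(x$assigned_type))))
  print(tibble(cluster = as.integer(names(x$assigned_type)),
               assigned_type = unname(x$assigned_type)))
  invisible(x)
}

#' @describeIn assign_clusters_to_types Long view of the enrichment matrix.
#' @param x A `cluster_type_map`.
#' @param ... Unused.
#' @export
tidy.cluster_type_map <- function(x, ...) {
  as_tibble(x$enrichment, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "cell_type",
                        values_to = "enrichment") |>
    mutate(cluster = as.integer(.data$cluster),
           assigned = x$assigned_type[as.character(.data$cluster)] ==
             .data$cell_type)
}

#' Evenly subsample cells per putative cell type (marker-aware variant)
#'
#' Cells are pooled by the cell type their cluster was assigned to (the
#' union of all clusters mapped to a type) and sampled in equal numbers
#' per assigned type, with the same deficit-redistribution contract as
#' [sample_even_by_cluster()] (pools in marker-spec type order). This
#' undoes the over-representation that arises when one abundant type
#' spans several clusters.
#'
#' @param type_map A `cluster_type_map` from [assign_clusters_to_types()].
#' @param clusters The matching `cluster_assignment`.
#' @param n_requested Total cells to select.
#' @param seed Integer seed.
#' @return A `cellpick_selection` tibble with a `putative_type` column.
#' @export
sample_even_by_type <- function(type_map, clusters, n_requested, seed = 1) {
  if (n_requested > nrow(clusters)) {
    abort(sprintf("requested %d cells from %d", n_requested, nrow(clusters)))
  }
  assigned <- type_map$assigned_type
  # pools in marker-spec order, only types that won >= 1 cluster
  spec_order <- colnames(type_map$enrichment)
  types <- spec_order[spec_order %in% assigned]
  pools <- lapply(types, function(t) {
    cl <- as.integer(names(assigned)[assigned == t])
    clusters$cell_id[clusters$cluster %in% cl]
  })
  quota <- distribute_quota(lengths(pools), n_requested)
  picked <- sample_pools(pools, quota, seed)
  out <- new_selection(unlist(picked, use.names = FALSE), "ar_marker",
                       list(n = n_requested, seed = seed))
  out$putative_type <- rep(types, lengths(picked))
  out
}

#' One-call adaptive reweighting selection
#'
#' Convenience wrapper: embed (30 PCs), cluster, and sample — per cluster
#' when no markers are given (naive variant), per marker-assigned type
#' otherwise (marker-aware variant).
#'
#' @param ds Transformed `expr_dataset`.
#' @param n_requested Total cells to select.
#' @param markers Optional `marker_spec`; switches on the marker-aware
#'   variant.
#' @param resolution,n_neighbors Clustering parameters.
#' @param n_components Principal components for clustering, default 30.
#' @param seed Integer seed.
#' @return A `cellpick_selection` tibble.
#' @export
adaptive_reweighting <- function(ds, n_requested, markers = NULL,
                                 resolution = 0.8, n_neighbors = 20,
                                 n_components = 30, seed = 1) {
  emb <- fit_embedding(ds, min(n_components, min(dim(ds))))
  cl <- cluster_cells(emb$scores, resolution = resolution,
                      n_neighbors = n_neighbors, seed = seed)
  if (is.null(markers)) {
    sample_even_by_cluster(cl, n_requested, seed = derive_seed(seed, 2L))
  } else {
    tm <- assign_clusters_to_types(ds, cl, markers)
    sample_even_by_type(tm, cl, n_requested, seed = derive_seed(seed, 2L))
  }
}
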