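blob_embedding <- function(n_per = 60, k = 3, d = 5, shift = 12, seed = 2) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    mu <- rep(0, d); mu[i] <- shift
    matrix(rnorm(n_per * d, mean = rep(mu, each = n_per)), n_per, d)
  }))
  rownames(x) <- sprintf("c%03d", seq_len(k * n_per))
  list(x = x, truth = rep(paste0("blob", seq_len(k)), each = n_per))
}

test_that("SNN clustering recovers well-separated blobs (ARI = 1)", {
  skip_if_not_installed("mclust")
  fx <- blob_embedding()
  cl <- cluster_cells(fx$x, resolution = 0.8, n_neighbors = 20, seed = 1)
  expect_equal(length(unique(cl$cluster)), 3)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, fx$truth), 1)
  expect_true(all(sort(unique(cl$cluster)) == 0:2))
})

test_that("one blob collapses to one cluster at low resolution", {
  set.seed(3)
  x <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(sprintf("c%02d", 1:40), NULL))
  cl <- cluster_cells(x, resolution = 0.1, n_neighbors = 15, seed = 1)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_error(cluster_cells(x[1:5, ], n_neighbors = 10), "at least")
})

test_that("clustering is seeded-deterministic", {
  fx <- blob_embedding(n_per = 40, seed = 9)
  a <- cluster_cells(fx$x, seed = 7)
  b <- cluster_cells(fx$x, seed = 7)
  expect_identical(a$cluster, b$cluster)
})

test_that("even-by-cluster sampling follows the redistribution contract", {
  mk_clusters <- function(sizes) {
    structure(
      tibble::tibble(
        cell_id = sprintf("c%04d", seq_len(sum(sizes))),
        cluster = rep(seq_along(sizes) - 1L, sizes)
      ),
      class = c("cluster_assignment", class(tibble::tibble()))
    )
  }
  # exact division
  cl <- mk_clusters(rep(30, 5))
  sel <- sample_even_by_cluster(cl, 100, seed = 1)
  expect_equal(unname(table(sel$cluster)), rep(20, 5), ignore_attr = TRUE)

  # deficit case from the redistribution oracle
  cl2 <- mk_clusters(c(5, 50, 50, 50))
  sel2 <- sample_even_by_cluster(cl2, 40, seed = 1)
  expect_equal(as.integer(table(factor(sel2$cluster, levels = 0:3))),
               c(5, 12, 12, 11))

  # request = total returns everything
  sel3 <- sample_even_by_cluster(cl2, 155, seed = 1)
  expect_setequal(sel3$cell_id, cl2$cell_id)
  expect_error(sample_even_by_cluster(cl2, 156), "requested")

  # per-cluster counts differ by at most 1 when no pool is exhausted
  cl4 <- mk_clusters(c(40, 40, 40))
  sel4 <- sample_even_by_cluster(cl4, 50, seed = 2)
  counts <- table(factor(sel4$cluster, levels = 0:2))
  expect_lte(diff(range(counts)), 1)
})

test_that("cluster-to-type assignment follows marker enrichment", {
  sim <- quick_sim(n_cells = 300, n_genes = 80, seed = 17, marker_effect = 4)
  ds <- lognormalize(sim$dataset)
  emb <- fit_embedding(ds, 20)
  cl <- cluster_cells(emb$scores, resolution = 0.8, n_neighbors = 20, seed = 1)
  tm <- assign_clusters_to_types(ds, cl, sim$markers)
  # every cluster's assigned type is the argmax of its enrichment row
  for (i in seq_len(nrow(tm$enrichment))) {
    expect_identical(unname(tm$assigned_type[i]),
                     colnames(tm$enrichment)[which.max(tm$enrichment[i, ])])
  }
  # with strong markers, cluster-majority truth matches the assignment
  lk <- setNames(sim$truth$cell_type, sim$truth$cell_id)
  for (cid in unique(cl$cluster)) {
    maj <- names(which.max(table(lk[cl$cell_id[cl$cluster == cid]])))
    expect_identical(unname(tm$assigned_type[as.character(cid)]), maj)
  }
})

test_that("negative markers subtract from enrichment", {
  m <- matrix(c(4, 4,
                4, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("pos1", "neg1")))
  ds <- expression_dataset(m)
  ds$transform_state <- "lognorm"
  cl <- structure(tibble::tibble(cell_id = c("c1", "c2"), cluster = c(0L, 0L)),
                  class = c("cluster_assignment", class(tibble::tibble())))
  spec <- marker_spec(list(A = "pos1", B = "pos1"),
                      list(A = "neg1"))
  suppressWarnings(tm <- assign_clusters_to_types(ds, cl, spec))
  # equal positive and negative means cancel exactly for type A
  expect_equal(unname(tm$enrichment[1, "A"]), 0)
  expect_equal(unname(tm$enrichment[1, "B"]), 4)
  expect_identical(unname(tm$assigned_type[1]), "B")
})

test_that("two clusters of one type both map to it (many-to-one)", {
  sim <- quick_sim(n_cells = 240, n_genes = 60, seed = 19,
                   proportions = c(big = 0.7, small = 0.3),
                   marker_effect = 4)
  ds <- lognormalize(sim$dataset)
  emb <- fit_embedding(ds, 10)
  # force over-clustering with high resolution
  cl <- cluster_cells(emb$scores, resolution = 2.5, n_neighbors = 10, seed = 1)
  tm <- suppressWarnings(assign_clusters_to_types(ds, cl, sim$markers))
  expect_gte(length(unique(cl$cluster)), 2)
  expect_lte(length(unique(tm$assigned_type)), 2)
})

test_that("even-by-type sampling pools clusters and redistributes deficits", {
  # hand-built map: 4 types, one with a 10-cell pool, request 100
  cl <- structure(
    tibble::tibble(cell_id = sprintf("c%04d", 1:160),
                   cluster = rep(0:3, times = c(10, 50, 50, 50))),
    class = c("cluster_assignment", class(tibble::tibble()))
  )
  enrich <- diag(4)
  dimnames(enrich) <- list(0:3, paste0("T", 1:4))
  tm <- structure(list(enrichment = enrich,
                       assigned_type = setNames(paste0("T", 1:4), 0:3)),
                  class = "cluster_type_map")
  sel <- sample_even_by_type(tm, cl, 100, seed = 1)
  counts <- table(factor(sel$putative_type, levels = paste0("T", 1:4)))
  expect_equal(as.integer(counts), c(10, 30, 30, 30))
  expect_equal(nrow(sel), 100)

  # all pools comfortable: 4 x 25
  cl2 <- structure(
    tibble::tibble(cell_id = sprintf("d%04d", 1:200),
                   cluster = rep(0:3, each = 50)),
    class = c("cluster_assignment", class(tibble::tibble()))
  )
  sel2 <- sample_even_by_type(tm, cl2, 100, seed = 1)
  expect_equal(as.integer(table(sel2$putative_type)), rep(25, 4))
})

test_that("marker-aware selection balances a 90/5/5 imbalanced pool", {
  sim <- quick_sim(
    n_cells = 600, n_genes = 60, seed = 23, marker_effect = 4,
    proportions = c(major = 0.9, rare1 = 0.05, rare2 = 0.05)
  )
  ds <- lognormalize(sim$dataset)
  counts <- purrr::map(1:5, function(s) {
    sel <- adaptive_reweighting(ds, 60, markers = sim$markers, seed = s)
    lk <- setNames(sim$truth$cell_type, sim$truth$cell_id)
    table(factor(lk[sel$cell_id], levels = names(sim$config$proportions)))
  })
  med <- apply(do.call(rbind, counts), 2, median)
  expect_true(all(abs(med - 20) <= 2))
})

test_that("selections are invariant to cluster relabeling", {
  cl <- structure(
    tibble::tibble(cell_id = sprintf("c%04d", 1:90),
                   cluster = rep(0:2, each = 30)),
    class = c("cluster_assignment", class(tibble::tibble()))
  )
  sel <- sample_even_by_cluster(cl, 30, seed = 6)
  counts <- table(sel$cluster)
  expect_equal(as.integer(counts), rep(10, 3))
})

test_that("duplicating every cell leaves blob cluster structure intact", {
  fx <- blob_embedding(n_per = 30, k = 3, seed = 12)
  dup <- rbind(fx$x, fx$x)
  rownames(dup) <- c(rownames(fx$x), paste0(rownames(fx$x), "_copy"))
  cl1 <- cluster_cells(fx$x, n_neighbors = 15, seed = 1)
  cl2 <- cluster_cells(dup, n_neighbors = 15, seed = 1)
  expect_equal(length(unique(cl2$cluster)), length(unique(cl1$cluster)))
  # originals and copies co-cluster
  m <- setNames(cl2$cluster, cl2$cell_id)
  expect_equal(unname(m[rownames(fx$x)]),
               unname(m[paste0(rownames(fx$x), "_copy")]))
})
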