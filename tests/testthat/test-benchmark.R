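test_that("weighted cosine distance reduces to cosine under uniform weights", {
  set.seed(4)
  x <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(sprintf("c%02d", 1:40), NULL))
  truth <- tibble::tibble(cell_id = rownames(x),
                          cell_type = rep(c("A", "B"), 20))
  d <- cell_type_similarity(x, rep(1 / 3, 3), truth)
  ca <- colMeans(x[truth$cell_type == "A", ])
  cb <- colMeans(x[truth$cell_type == "B", ])
  plain <- 1 - sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  expect_equal(unname(d["A", "B"]), plain)
  expect_equal(unname(diag(unclass(d))), c(0, 0))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
})

test_that("identical and weight-orthogonal centroids hit the extremes", {
  x <- rbind(a1 = c(1, 2), a2 = c(1, 2), b1 = c(1, 2), b2 = c(1, 2))
  truth <- tibble::tibble(cell_id = rownames(x),
                          cell_type = c("A", "A", "B", "B"))
  d <- cell_type_similarity(x, c(0.6, 0.4), truth)
  expect_equal(unname(d["A", "B"]), 0)

  y <- rbind(a = c(1, 0), b = c(0, 1))
  t2 <- tibble::tibble(cell_id = c("a", "b"), cell_type = c("A", "B"))
  d2 <- cell_type_similarity(y, c(0.5, 0.5), t2)
  expect_equal(unname(d2["A", "B"]), 1)

  z <- rbind(a = c(0, 0), b = c(1, 1))
  t3 <- tibble::tibble(cell_id = c("a", "b"), cell_type = c("A", "B"))
  expect_error(cell_type_similarity(z, c(0.5, 0.5), t3), "zero-norm")
})

test_that("imbalance designs produce the prescribed counts", {
  sim <- quick_sim(n_cells = 2500, n_genes = 40, seed = 71)
  lk <- setNames(sim$truth$cell_type, sim$truth$cell_id)

  two <- make_imbalanced_subsets(sim$dataset, sim$truth, "two_type_similar",
                                 types = c("type1", "type2"), seed = 1)
  expect_equal(dim(two$dataset)[1], 500)
  expect_equal(as.integer(sort(table(two$truth$cell_type))), c(50L, 450L))

  bal <- make_imbalanced_subsets(sim$dataset, sim$truth, "two_type_balanced",
                                 types = c("type1", "type2"), seed = 1)
  expect_equal(unname(table(bal$truth$cell_type)), c(250, 250),
               ignore_attr = TRUE)

  multi <- make_imbalanced_subsets(sim$dataset, sim$truth, "multi_imbalanced",
                                   types = paste0("type", 1:5), seed = 1)
  expect_equal(unname(sort(table(multi$truth$cell_type), decreasing = TRUE)),
               c(400, 25, 25, 25, 25), ignore_attr = TRUE)

  mb <- make_imbalanced_subsets(sim$dataset, sim$truth, "multi_balanced",
                                types = paste0("type", 1:5), seed = 1)
  expect_equal(unname(table(mb$truth$cell_type)), rep(100, 5),
               ignore_attr = TRUE)
  expect_error(
    make_imbalanced_subsets(sim$dataset, sim$truth, "two_type_similar",
                            types = c("type1", "no_such_type")),
    "not enough cells"
  )
})

test_that("similarity-driven pair choice matches the arg-min/max oracle", {
  sim <- quick_sim(n_cells = 3000, n_genes = 60, seed = 73)
  ds <- lognormalize(sim$dataset)
  emb <- fit_embedding(ds, 10)
  d <- cell_type_similarity(emb$scores, emb$variance_explained, sim$truth)
  m <- unclass(d); diag(m) <- NA

  sim_pick <- make_imbalanced_subsets(sim$dataset, sim$truth,
                                      "two_type_similar", similarity = d,
                                      seed = 1)
  expect_setequal(
    sim_pick$design$cell_type,
    rownames(m)[which(m == min(m, na.rm = TRUE), arr.ind = TRUE)[1, ]]
  )
  diff_pick <- make_imbalanced_subsets(sim$dataset, sim$truth,
                                       "two_type_different", similarity = d,
                                       seed = 1)
  expect_setequal(
    diff_pick$design$cell_type,
    rownames(m)[which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]]
  )
})

test_that("marker corruption preserves structure and avoids originals", {
  sim <- quick_sim(n_cells = 100, n_genes = 120, seed = 75)
  spec <- sim$markers
  expect_identical(corrupt_markers(spec, sim$dataset, 0, seed = 1), spec)

  full <- corrupt_markers(spec, sim$dataset, 1.0, seed = 1)
  expect_identical(full$types, spec$types)
  expect_length(intersect(marker_union(full), marker_union(spec)), 0)
  expect_identical(lengths(full$positive), lengths(spec$positive))

  half <- corrupt_markers(spec, sim$dataset, 0.5, seed = 2)
  n_total <- nrow(tidy(spec))
  n_kept <- sum(tidy(half)$marker %in% marker_union(spec))
  expect_equal(n_total - n_kept, floor(0.5 * n_total + 0.5))  # round half up
  # replacements never come from the original marker file
  new_genes <- setdiff(tidy(half)$marker, marker_union(spec))
  expect_length(intersect(new_genes, marker_union(spec)), 0)
})

test_that("the benchmark grid emits one record per design cell", {
  sim <- quick_sim(n_cells = 240, n_genes = 50, seed = 77)
  ds <- lognormalize(sim$dataset)
  g <- downstream_grid(max_features = 4, num_trees = 100, n_pcs = 10)
  res <- run_benchmark(ds, sim$truth, strategies = c("random", "ranked"),
                       budgets = 60, markers = sim$markers, n_splits = 1,
                       grid = g, seed = 5)
  expect_equal(nrow(res), 2)
  expect_setequal(res$strategy, c("random", "ranked"))
  expect_true(all(res$balanced_accuracy >= 0 & res$balanced_accuracy <= 1))

  ranked <- rank_strategies(res)
  expect_equal(nrow(ranked), 2)
  expect_identical(ranked$rank, 1:2)
  expect_false(is.unsorted(-ranked$median_balanced_accuracy))
})
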