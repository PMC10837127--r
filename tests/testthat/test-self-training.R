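st_fixture <- function(seed = 51, n_cells = 300) {
  sim <- quick_sim(n_cells = n_cells, n_genes = 60, seed = seed)
  ds <- lognormalize(sim$dataset)
  emb <- fit_embedding(ds, 15)
  list(sim = sim, ds = ds, x = emb$scores)
}

test_that("pseudo-labelling covers the pool at 100% and rounds half up", {
  fx <- st_fixture()
  lab <- dplyr::slice_sample(fx$sim$truth, n = 60)
  aug <- pseudo_label(fx$x, lab, top_percent = 100, seed = 1)
  expect_equal(sum(aug$source == "pseudo"), nrow(fx$sim$truth) - 60)
  expect_equal(sum(aug$source == "oracle"), 60)

  # pool of 37, top 10% -> 4 pseudo cells
  small <- fx$x[1:97, ]
  lab37 <- fx$sim$truth[fx$sim$truth$cell_id %in% rownames(small), ][1:60, ]
  aug37 <- pseudo_label(small, lab37, top_percent = 10, seed = 1)
  expect_equal(sum(aug37$source == "pseudo"), 4)
})

test_that("oracle labels are never overwritten and confidence is entropy", {
  fx <- st_fixture(seed = 53)
  lab <- dplyr::slice_sample(fx$sim$truth, n = 50)
  aug <- pseudo_label(fx$x, lab, top_percent = 50, seed = 2)
  ora <- aug[aug$source == "oracle", ]
  expect_identical(
    setNames(ora$cell_type, ora$cell_id)[lab$cell_id],
    setNames(lab$cell_type, lab$cell_id)
  )
  expect_true(all(ora$confidence == 0))
  ps <- aug[aug$source == "pseudo", ]
  expect_true(all(ps$confidence >= 0 & ps$confidence <= 1))
  # most-confident-first: pseudo cells are the lowest-entropy half
  expect_false(anyDuplicated(aug$cell_id) > 0)
})

test_that("pseudo-label accuracy is highest at the most confident cut", {
  accs <- purrr::map(1:5, function(s) {
    sim <- quick_sim(n_cells = 300, n_genes = 60, seed = 60 + s,
                     marker_effect = 2)
    ds <- lognormalize(sim$dataset)
    x <- fit_embedding(ds, 15)$scores
    lab <- with(list(), {
      set.seed(s); dplyr::slice_sample(sim$truth, n = 50)
    })
    lk <- setNames(sim$truth$cell_type, sim$truth$cell_id)
    vapply(c(10, 100), function(tp) {
      aug <- pseudo_label(x, lab, top_percent = tp, seed = s)
      ps <- aug[aug$source == "pseudo", ]
      mean(ps$cell_type == lk[ps$cell_id])
    }, numeric(1))
  })
  m <- do.call(rbind, accs)
  expect_gte(median(m[, 1]), median(m[, 2]))
})

test_that("an empty unlabeled pool warns and returns the input", {
  fx <- st_fixture(seed = 55, n_cells = 100)
  lab <- fx$sim$truth
  expect_warning(aug <- pseudo_label(fx$x, lab, top_percent = 50), "no unlabeled")
  expect_equal(nrow(aug), nrow(lab))
  expect_true(all(aug$source == "oracle"))
})

test_that("label corruption hits its quota and always changes the class", {
  truth <- quick_sim(n_cells = 250)$truth
  cor <- corrupt_labels(truth, 0.10, seed = 3)
  expect_equal(sum(cor$corrupted), 25)
  changed <- cor$cell_type != truth$cell_type
  expect_identical(changed, cor$corrupted)
  expect_true(all(cor$cell_type %in% unique(truth$cell_type)))

  none <- corrupt_labels(truth, 0, seed = 3)
  expect_identical(none$cell_type, truth$cell_type)
  expect_false(any(none$corrupted))

  single <- tibble::tibble(cell_id = c("a", "b"), cell_type = c("X", "X"))
  expect_error(corrupt_labels(single), "two classes")
})

test_that("corruption is seeded-deterministic", {
  truth <- quick_sim(n_cells = 200)$truth
  expect_identical(corrupt_labels(truth, 0.2, seed = 9),
                   corrupt_labels(truth, 0.2, seed = 9))
})

test_that("mislabel detection ranks every training cell once", {
  fx <- st_fixture(seed = 57, n_cells = 200)
  cor <- corrupt_labels(fx$sim$truth, 0.1, seed = 1)
  det <- detect_mislabeled(fx$x, cor, "random_forest", seed = 1)
  expect_setequal(det$cell_id, cor$cell_id)
  expect_identical(det$rank, seq_len(nrow(det)))
  expect_true(all(det$scaled_entropy >= 0 & det$scaled_entropy <= 1))
  expect_false(is.unsorted(-det$scaled_entropy))
})

test_that("corrupted cells surface with higher entropy than clean ones", {
  fx <- st_fixture(seed = 59, n_cells = 250)
  cor <- corrupt_labels(fx$sim$truth, 0.1, seed = 2)
  for (kind in c("random_forest", "logistic_regression")) {
    det <- detect_mislabeled(fx$x, cor, kind, seed = 2)
    j <- dplyr::left_join(det, dplyr::select(cor, "cell_id", "corrupted"),
                          by = "cell_id")
    expect_gt(median(j$scaled_entropy[j$corrupted]),
              median(j$scaled_entropy[!j$corrupted]))
    expect_gt(auroc(j$scaled_entropy, j$corrupted), 0.5)
  }
})

test_that("self-training gain is computed against a shared test set", {
  sim <- quick_sim(n_cells = 300, n_genes = 60, seed = 61, marker_effect = 2)
  ds <- lognormalize(sim$dataset)
  sp <- stratified_split(sim$truth, 0.5, 1, seed = 1)
  ids <- split_ids(sp, 1)
  set.seed(1)
  lab <- sim$truth[sim$truth$cell_id %in% sample(ids$train, 50), ]
  g <- downstream_grid(max_features = 4, num_trees = 100, n_pcs = 15)
  res <- self_training_gain(ds, lab, sim$truth, ids$test,
                            top_percent = 50, grid = g, seed = 1)
  expect_identical(res$metrics$training, c("oracle_only", "augmented"))
  expect_true(all(is.finite(unlist(res$gain))))
  expect_error(
    self_training_gain(ds, lab, sim$truth, c(ids$test, lab$cell_id[1]),
                       grid = g),
    "overlap"
  )
})

test_that("a zero-percent confidence cut yields exactly zero gain", {
  sim <- quick_sim(n_cells = 200, n_genes = 50, seed = 63)
  ds <- lognormalize(sim$dataset)
  sp <- stratified_split(sim$truth, 0.5, 1, seed = 2)
  ids <- split_ids(sp, 2 - 1)
  set.seed(2)
  lab <- sim$truth[sim$truth$cell_id %in% sample(ids$train, 40), ]
  g <- downstream_grid(max_features = 4, num_trees = 100, n_pcs = 10)
  suppressWarnings(  # a 40-cell draw can leave a class under the fold count
    res <- self_training_gain(ds, lab, sim$truth, ids$test,
                              top_percent = 0, grid = g, seed = 3)
  )
  expect_true(all(abs(unlist(res$gain)) < 1e-12))
  expect_equal(sum(res$augmented$source == "pseudo"), 0)
})
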