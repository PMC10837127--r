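test_that("entropy has its closed forms", {
  p <- rbind(c(0.5, 0.5), c(1, 0), c(0.25, 0.75))
  rownames(p) <- c("even", "hot", "skew")
  h <- entropy(p)
  expect_equal(h$value[h$cell_id == "even"], 1)
  expect_equal(h$value[h$cell_id == "hot"], 0)
  expect_equal(h$value[h$cell_id == "skew"],
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))

  u4 <- uniform_probs(3, 4)
  expect_equal(entropy(u4)$value, rep(2, 3))        # log2(4)
  expect_equal(scaled_entropy(entropy(u4))$value, rep(1, 3))

  bad <- rbind(c(0.7, 0.7))
  rownames(bad) <- "b"
  expect_error(entropy(bad), "sum to 1")
})

test_that("max probability respects its bounds", {
  p <- uniform_probs(2, 4)
  expect_equal(max_probability(p)$value, c(0.25, 0.25))
  onehot <- diag(3); rownames(onehot) <- paste0("c", 1:3)
  expect_equal(max_probability(onehot)$value, rep(1, 3))
  set.seed(2)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    v <- runif(k); v <- v / sum(v)
    m <- matrix(v, 1, dimnames = list("x", NULL))
    expect_gte(max_probability(m)$value, 1 / k)
    expect_lte(entropy(m)$value, log2(k) + 1e-12)
  }
})

test_that("scaled entropy preserves ranks", {
  set.seed(7)
  p <- t(apply(matrix(runif(60), 20, 3), 1, function(r) r / sum(r)))
  rownames(p) <- sprintf("c%02d", 1:20)
  h <- entropy(p)
  s <- scaled_entropy(h)
  expect_identical(order(h$value), order(s$value))
  expect_true(all(s$value >= 0 & s$value <= 1))
})

brute_percentile_pick <- function(values, ids, q, batch) {
  thr <- unname(quantile(values, q / 100))
  df <- data.frame(id = ids, v = values)
  below <- df[df$v <= thr + 1e-12, ]
  below <- below[order(-below$v, below$id), ]
  picked <- head(below$id, batch)
  if (length(picked) < batch) {
    above <- df[!(df$id %in% below$id), ]
    above <- above[order(above$v, above$id), ]
    picked <- c(picked, head(above$id, batch - length(picked)))
  }
  picked
}

test_that("percentile selection matches the brute-force sort oracle", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(30:120, 1)
    v <- runif(n)
    ids <- sprintf("c%04d", sample(9999, n))
    u <- structure(tibble::tibble(cell_id = ids, value = v),
                   metric = "entropy", n_classes = 4,
                   class = c("uncertainty_scores", class(tibble::tibble())))
    for (q in c(100, 95, 75)) {
      sel <- select_at_percentile(u, q, batch = 10)
      expect_identical(sel$cell_id, brute_percentile_pick(v, ids, q, 10))
    }
  }
})

test_that("percentile selection edge cases: top batch, ties, errors", {
  v <- seq(0.1, 1.0, by = 0.1)
  ids <- sprintf("c%02d", 1:10)
  u <- structure(tibble::tibble(cell_id = ids, value = v),
                 metric = "entropy", n_classes = 4,
                 class = c("uncertainty_scores", class(tibble::tibble())))
  expect_identical(select_at_percentile(u, 100, 3)$cell_id,
                   c("c10", "c09", "c08"))
  # all scores equal: first `batch` cells by id
  u2 <- structure(tibble::tibble(cell_id = rev(ids), value = rep(0.5, 10)),
                  metric = "entropy", n_classes = 4,
                  class = c("uncertainty_scores", class(tibble::tibble())))
  expect_identical(select_at_percentile(u2, 100, 3)$cell_id,
                   c("c01", "c02", "c03"))
  expect_error(select_at_percentile(u, 100, 11), "exceeds pool")
})

test_that("entropy and negated max-probability agree on binary top picks", {
  set.seed(17)
  p1 <- runif(40, 0.01, 0.99)
  p <- cbind(p1, 1 - p1)
  rownames(p) <- sprintf("c%02d", 1:40)
  top_h <- select_at_percentile(entropy(p), 100, 5)$cell_id
  top_m <- select_at_percentile(max_probability(p), 100, 5)$cell_id
  expect_setequal(top_h, top_m)
})

test_that("both model kinds separate two clean blobs perfectly", {
  fx <- blob_matrix(n_per = 40, seed = 5)
  tr <- c(1:25, 41:65)
  te <- setdiff(seq_len(80), tr)
  for (kind in c("random_forest", "logistic_regression")) {
    model <- train_uncertainty_model(fx$x[tr, ], fx$labels[tr, ],
                                     kind = kind, seed = 1)
    p <- predict_probabilities(model, fx$x[te, ])
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    expect_equal(mean(pred == fx$labels$cell_type[te]), 1)
  }
})

test_that("training is deterministic given a seed", {
  fx <- blob_matrix(n_per = 20, seed = 8)
  for (kind in c("random_forest", "logistic_regression")) {
    m1 <- train_uncertainty_model(fx$x, fx$labels, kind = kind, seed = 3)
    m2 <- train_uncertainty_model(fx$x, fx$labels, kind = kind, seed = 3)
    expect_equal(predict_probabilities(m1, fx$x),
                 predict_probabilities(m2, fx$x))
  }
})

test_that("logistic probabilities are monotone along a 1-D threshold", {
  set.seed(12)
  x <- matrix(sort(runif(60, -3, 3)), ncol = 1,
              dimnames = list(sprintf("c%02d", 1:60), "f"))
  labels <- tibble::tibble(cell_id = rownames(x),
                           cell_type = ifelse(x[, 1] > 0, "hi", "lo"))
  model <- train_uncertainty_model(x, labels, "logistic_regression", seed = 1)
  p <- predict_probabilities(model, x)[, "hi"]
  expect_false(is.unsorted(p))
})

test_that("single-class training labels are rejected", {
  fx <- blob_matrix(n_per = 10)
  lab <- fx$labels
  lab$cell_type <- "A"
  expect_error(train_uncertainty_model(fx$x, lab, "rf"), "single class")
})
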