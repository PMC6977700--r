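make_labeled_data <- function(n = 60L, n_informative = 1L, n_noise = 4L,
                              sep = 2, sd = 0.2, seed = 1L) {
  set.seed(seed)
  y <- factor(rep(c("control", "case"), each = n / 2L), levels = c("control", "case"))
  X <- matrix(rnorm(n * (n_informative + n_noise)), n)
  for (j in seq_len(n_informative)) {
    X[, j] <- ifelse(y == "case", sep, -sep) + rnorm(n, 0, sd)
  }
  colnames(X) <- c(sprintf("inf%d", seq_len(n_informative)),
                   sprintf("noise%d", seq_len(n_noise)))
  list(X = X, y = y)
}

test_that("one reduction round removes the lowest-scoring third", {
  d <- make_labeled_data(n = 40L, n_informative = 2L, n_noise = 8L, seed = 2L)
  kept <- importance_reduction(d$X, d$y, target_k = 7L, seed = 1L, ntree = 100L)
  expect_length(kept, 7L)  # floor(10 / 3) = 3 removed in one pass
  trace <- attr(kept, "trace")
  expect_equal(trace$n_features, 10L)
  expect_equal(trace$step, 1L)
})

test_that("informative features survive iterative importance reduction", {
  d <- make_labeled_data(n = 60L, n_informative = 3L, n_noise = 27L,
                         sep = 1.5, sd = 0.5, seed = 3L)
  kept <- importance_reduction(d$X, d$y, target_k = 3L, seed = 7L)
  expect_setequal(kept, paste0("inf", 1:3))
  # target_k >= feature count returns the input unchanged
  kept_all <- importance_reduction(d$X, d$y, target_k = 40L, seed = 7L)
  expect_equal(as.character(kept_all), colnames(d$X))
  expect_error(importance_reduction(d$X, factor(rep("a", 60L)), 3L), "two classes")
})

test_that("subset enumeration is complete and ordered by size then lexicographically", {
  subs <- enumerate_subsets(3L)
  expect_length(subs, 7L)
  expect_equal(subs, list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3))
  expect_length(enumerate_subsets(10L), 1023L)
  expect_error(enumerate_subsets(17L), "force")
  expect_length(enumerate_subsets(17L, force = TRUE), 2L^17L - 1L)
})

test_that("exhaustive search finds a perfectly separating panel and is sound", {
  d <- make_labeled_data(seed = 4L)
  res <- exhaustive_panel_search(d$X, d$y, folds = 5L, seed = 1L)
  expect_equal(res$n_subsets, 31L)
  expect_equal(res$cv_accuracy, 1.0)
  expect_true("inf1" %in% res$features)
  # the full feature set is one evaluated subset, so best >= full
  full_acc <- res$subset_scores$cv_accuracy[res$subset_scores$size == 5L]
  expect_true(res$cv_accuracy >= max(full_acc))
  expect_true(res$auc >= 0.99)
  # bit-reproducible under the same seed
  res2 <- exhaustive_panel_search(d$X, d$y, folds = 5L, seed = 1L)
  expect_identical(res$subset_scores, res2$subset_scores)
  expect_identical(res$fold_assignments, res2$fold_assignments)
})

test_that("ties are broken toward fewer features", {
  d <- make_labeled_data(n = 40L, n_informative = 1L, n_noise = 0L, seed = 5L)
  X <- cbind(d$X, inf1_copy = d$X[, "inf1"])  # duplicated separating feature
  res <- exhaustive_panel_search(X, d$y, folds = 5L, seed = 2L)
  expect_equal(res$cv_accuracy, 1.0)
  expect_equal(res$features, "inf1")  # singleton wins over equally-good supersets
})

test_that("null labels do not let subset selection fabricate accuracy", {
  set.seed(31)
  accs <- replicate(20L, {
    X <- matrix(rnorm(100L * 5L), 100L)
    colnames(X) <- paste0("f", 1:5)
    y <- factor(rep(c("a", "b"), each = 50L))
    exhaustive_panel_search(X, y, folds = 5L,
                            seed = sample.int(1e6, 1L))$cv_accuracy
  })
  expect_lt(mean(accs), 0.75)
})

test_that("two-cluster composition separates identical blocks and reports rates", {
  X <- rbind(matrix(0, 10L, 3L), matrix(5, 8L, 3L))
  labels <- rep(c("MI", "control"), c(10L, 8L))
  res <- two_cluster_composition(X, labels)
  expect_equal(length(unique(res$assignment[1:10])), 1L)
  expect_equal(length(unique(res$assignment[11:18])), 1L)
  expect_true(all(apply(res$composition, 1L, max) == 100))

  # rate arithmetic in the reporting style: 71 of 98 -> 72.4%
  set.seed(2)
  X2 <- rbind(matrix(rnorm(98 * 2, 0, 0.1), 98), matrix(rnorm(21 * 2, 5, 0.1), 21))
  lab2 <- c(rep("MI", 71L), rep("control", 27L), rep("MI", 2L), rep("control", 19L))
  res2 <- two_cluster_composition(X2, lab2)
  big <- which.max(table(res2$assignment))
  expect_equal(unname(res2$composition[big, "MI"]), 100 * 71 / 98, tolerance = 1e-9)

  # permuting label names cannot change the partition
  res3 <- two_cluster_composition(X2, rev(lab2))
  expect_identical(res3$assignment, res2$assignment)
  expect_error(two_cluster_composition(X[1L, , drop = FALSE], "MI"), "at least 2")
})
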