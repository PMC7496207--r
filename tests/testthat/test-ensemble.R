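test_that("bootstrap resamples have round(0.3 N) indices, with replacement", {
  sets <- bootstrap_training_sets(1000, seeds = 1:10)
  expect_length(sets, 10L)
  expect_true(all(lengths(sets) == 300L))
  expect_true(all(unlist(sets) >= 1 & unlist(sets) <= 1000))

  expect_identical(bootstrap_training_sets(1000, 7)[[1]],
                   bootstrap_training_sets(1000, 7)[[1]])

  # with-replacement: duplicates must occur across many small draws
  draws <- bootstrap_training_sets(10, seeds = 1:200, fraction = 0.3)
  expect_true(any(vapply(draws, anyDuplicated, integer(1)) > 0))

  # rounding is to the nearest integer
  expect_length(bootstrap_training_sets(15, 1)[[1]], round(0.3 * 15))
})

blob_data <- function(n_per_class = 60, n_genes = 12, seed = 2) {
  set.seed(seed)
  a <- matrix(rpois(n_per_class * n_genes, 2), n_per_class)
  b <- matrix(rpois(n_per_class * n_genes, 20), n_per_class)
  X <- log1p(rbind(a, b))
  list(X = X, labels = rep(c("a", "b"), each = n_per_class))
}

test_that("a trained network separates linear blobs and outputs softmax rows", {
  d <- blob_data()
  net <- mlp_train(d$X, d$labels, epochs = 120, seed = 3)
  P <- predict(net, d$X)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  acc <- mean(colnames(P)[max.col(P)] == d$labels)
  expect_gte(acc, 0.95)

  # identical seed and data give identical predictions
  net2 <- mlp_train(d$X, d$labels, epochs = 120, seed = 3)
  expect_identical(predict(net2, d$X), P)
})

test_that("member prediction applies a strict confidence threshold", {
  fake <- structure(
    list(par = NULL, class_order = c("a", "b"), widths = c(2L, 2L)),
    class = "cellvote_mlp"
  )
  # bypass the net: test the thresholding rule directly on probabilities
  probs <- rbind(c(0.8, 0.2), c(0.6, 0.4), c(0.7, 0.3))
  top <- max.col(probs)
  out <- ifelse(probs[cbind(1:3, top)] > 0.7, fake$class_order[top],
                "unassigned")
  expect_equal(out, c("a", "unassigned", "unassigned"))

  # and end-to-end through a real network on easy data
  d <- blob_data(seed = 4)
  net <- mlp_train(d$X, d$labels, epochs = 120, seed = 5)
  lab <- predict_member(net, d$X, gamma = 0.7)
  expect_true(all(lab %in% c("a", "b", "unassigned")))
  expect_gte(mean(lab == d$labels), 0.9)
})

test_that("voting requires a strict majority and ignores unassigned votes", {
  v <- function(...) vote(matrix(c(...), ncol = 1))
  expect_equal(unname(v(rep("alpha", 6), rep("beta", 4))), "alpha")
  expect_equal(unname(v(rep("alpha", 5), rep("beta", 5))), "unassigned")
  expect_equal(unname(v(rep("unassigned", 10))), "unassigned")
  expect_equal(unname(v(rep("alpha", 5), rep("unassigned", 5))),
               "unassigned")
  expect_equal(unname(v(rep("alpha", 6), rep("unassigned", 4))), "alpha")
})

test_that("vote truth table: assigned iff some class reaches 6 of 10", {
  # exhaustive multisets of 10 votes over {A, B, unassigned}
  for (nA in 0:10) for (nB in 0:(10 - nA)) {
    nu <- 10 - nA - nB
    votes <- matrix(c(rep("A", nA), rep("B", nB), rep("unassigned", nu)),
                    ncol = 1)
    got <- unname(vote(votes))
    want <- if (nA >= 6) "A" else if (nB >= 6) "B" else "unassigned"
    expect_identical(got, want)
  }
})

test_that("ensemble training is reproducible and collapse-resistant", {
  sim <- simulate_cells(n_cells = 150, n_genes = 60, n_classes = 3,
                        seed = 6)
  ens <- train_ensemble(sim, sim$gene_names[1:30], n_members = 3,
                        epochs = 8, seed = 7)
  expect_length(ens$members, 3L)
  expect_equal(ens$class_order, c("type1", "type2", "type3"))
  p1 <- predict(ens, sim)
  ens2 <- train_ensemble(sim, sim$gene_names[1:30], n_members = 3,
                         epochs = 8, seed = 7)
  expect_identical(predict(ens2, sim), p1)

  # a near-collapsed class forces the retry path to find both classes
  skew <- simulate_cells(n_cells = 60, n_genes = 40, n_classes = 2,
                         class_proportions = c(0.94, 0.06), seed = 8)
  ens3 <- train_ensemble(skew, skew$gene_names[1:20], n_members = 2,
                         bootstrap_fraction = 0.1, epochs = 4, seed = 9)
  for (m in ens3$members) expect_equal(m$class_order, c("type1", "type2"))
})
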