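test_that("rare-class detection uses an inclusive 0.5% boundary", {
  labels <- c(rep("big", 995), rep("tiny", 5))
  expect_equal(identify_few_sample_classes(labels), "tiny")   # 5 <= 5

  labels6 <- c(rep("big", 994), rep("tiny", 6))
  expect_equal(identify_few_sample_classes(labels6), character(0))

  expect_equal(identify_few_sample_classes(rep(c("a", "b"), 50)),
               character(0))
})

few_cells <- function(labels, n_genes = 4, seed = 1) {
  set.seed(seed)
  expression_dataset(
    matrix(rpois(length(labels) * n_genes, 3), length(labels), n_genes),
    sprintf("g%d", seq_len(n_genes)),
    sprintf("c%d", seq_along(labels)),
    labels = labels
  )
}

test_that("pair training set has n x n samples, 2 x D features, identity labels", {
  d <- few_cells(c("a", "a", "b"))
  pairs <- build_pair_training_set(d, c("g1", "g2"))
  expect_equal(nrow(pairs$features), 9L)
  expect_equal(ncol(pairs$features), 4L)
  # left-major enumeration over {a, a, b}
  expect_equal(pairs$label, c(1, 1, 0, 1, 1, 0, 0, 0, 1))
  # features are left block then right block
  expect_equal(pairs$features[2, ], c(d$values[1, 1:2], d$values[2, 1:2]),
               ignore_attr = TRUE)

  single <- few_cells("a")
  expect_error(build_pair_training_set(single, "g1"), "too few rare cells")
})

test_that("pair test set has n x M samples with reference on the left", {
  ref <- few_cells(c("a", "a", "b"), seed = 2)
  qry <- few_cells(rep("z", 5), seed = 3)
  qry$labels <- NULL
  tst <- build_pair_test_set(ref, qry, c("g1", "g3"))
  expect_equal(nrow(tst$features), 15L)
  expect_equal(ncol(tst$features), 4L)
  i <- which(tst$left == 2 & tst$right == 4)
  expect_equal(tst$features[i, ],
               c(ref$values[2, c("g1", "g3")], qry$values[4, c("g1", "g3")]),
               ignore_attr = TRUE)

  empty <- few_cells(character(0), seed = 4)
  expect_equal(nrow(build_pair_test_set(ref, empty, c("g1", "g3"))$features),
               0L)
})

test_that("pair cardinalities hold over a parameter grid", {
  for (n in c(2, 4, 7)) for (M in c(1, 3, 6)) for (D in c(2, 3)) {
    ref <- few_cells(rep(c("a", "b"), length.out = n), n_genes = 4,
                     seed = n * 10 + M)
    qry <- few_cells(rep("q", M), n_genes = 4, seed = n * 100 + M)
    genes <- paste0("g", seq_len(D))
    tr <- build_pair_training_set(ref, genes)
    ts <- build_pair_test_set(ref, qry, genes)
    expect_equal(dim(tr$features), c(n * n, 2 * D))
    expect_equal(length(tr$label), n * n)
    expect_equal(dim(ts$features), c(n * M, 2 * D))
  }
})

test_that("pair regressor separates separable pairs and is reproducible", {
  # two well-separated clusters: same-cluster pairs labeled 1. The groups
  # are deliberately unequal: with exactly balanced classes the pair
  # labels form an XOR in the two cells' features and every root split
  # has zero gain, so greedy boosting cannot start.
  set.seed(5)
  vals <- rbind(matrix(rpois(50, 2), 5), matrix(rpois(30, 40), 3))
  d <- expression_dataset(vals, paste0("g", 1:10), paste0("c", 1:8),
                          labels = rep(c("lo", "hi"), c(5, 3)))
  pairs <- build_pair_training_set(d, d$gene_names)
  fit <- train_pair_regressor(pairs, seed = 9)
  pred <- cellvote:::predict_pairs(fit, pairs$features)
  expect_true(all(pred[pairs$label == 1] >= 0.9))
  expect_true(all(pred[pairs$label == 0] <= 0.1))
  expect_true(all(pred >= 0 & pred <= 1))

  fit2 <- train_pair_regressor(pairs, seed = 9)
  expect_equal(cellvote:::predict_pairs(fit2, pairs$features), pred)

  all_same <- few_cells(c("a", "a", "a"))
  degenerate <- build_pair_training_set(all_same, c("g1", "g2"))
  expect_error(train_pair_regressor(degenerate), "pair labels degenerate")
})

test_that("score aggregation matches the weighted-mean formula", {
  # one class, two reference cells: r = (0.5, 0.25), c = (1, 0)
  s <- aggregate_pair_scores(r = matrix(c(0.5, 0.25), 2, 1),
                             c_pred = matrix(c(1, 0), 2, 1),
                             ref_classes = c("x", "x"))
  expect_equal(unname(s["x", 1]), 2 / 3)

  # all c = 1 with positive weights gives exactly 1
  s1 <- aggregate_pair_scores(matrix(0.3, 3, 2), matrix(1, 3, 2),
                              rep("x", 3))
  expect_true(all(s1 == 1))

  # no positive correlation to the class -> no evidence -> score 0
  s0 <- aggregate_pair_scores(matrix(c(-0.2, -0.5), 2, 1),
                              matrix(c(1, 1), 2, 1), c("x", "x"))
  expect_equal(unname(s0["x", 1]), 0)

  # scores stay in [0, 1] whenever c does
  set.seed(8)
  r <- matrix(runif(20, -1, 1), 4, 5)
  cp <- matrix(runif(20), 4, 5)
  sc <- aggregate_pair_scores(r, cp, c("x", "x", "y", "y"))
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("assignment is strict at gamma and breaks ties lexicographically", {
  s <- matrix(c(0.8, 0.2,   # assigned to x
                0.7, 0.3,   # max exactly gamma -> unassigned
                0.9, 0.9),  # tie above gamma -> lexicographically first
              nrow = 2,
              dimnames = list(c("x", "y"), c("c1", "c2", "c3")))
  lab <- assign_few_sample(s, gamma = 0.7)
  expect_equal(unname(lab), c("x", "unassigned", "x"))
})

test_that("zero-variance cells get zero correlation weight with a warning", {
  ref <- few_cells(c("a", "a", "b"), n_genes = 4, seed = 6)
  qry <- expression_dataset(rbind(c(1, 1, 1, 1), c(0, 3, 1, 2)),
                            paste0("g", 1:4), c("q1", "q2"))
  pairs <- build_pair_training_set(ref, ref$gene_names)
  fit <- train_pair_regressor(pairs, nrounds = 5, seed = 2)
  expect_warning(
    sc <- score_query_cells(fit, ref, qry, ref$gene_names),
    "zero-variance"
  )
  expect_true(all(sc$r[, "q1"] == 0))
})
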