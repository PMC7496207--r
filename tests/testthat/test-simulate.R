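test_that("class proportions convert to exact cell counts", {
  s <- simulate_cells(n_cells = 100, n_genes = 30,
                      class_proportions = c(0.5, 0.5),
                      n_marker_genes_per_class = 5, seed = 1)
  expect_equal(unname(table(s$labels)), c(50L, 50L), ignore_attr = TRUE)

  expect_error(
    simulate_cells(n_cells = 50, n_genes = 30,
                   class_proportions = c(0.999, 0.001),
                   n_marker_genes_per_class = 5, seed = 1),
    "too small"
  )
  expect_error(
    simulate_cells(n_cells = 50, n_genes = 30,
                   class_proportions = c(0.6, 0.6),
                   n_marker_genes_per_class = 5, seed = 1),
    "sum to 1"
  )
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_cells(n_cells = 80, n_genes = 40, n_classes = 2, seed = 9)
  b <- simulate_cells(n_cells = 80, n_genes = 40, n_classes = 2, seed = 9)
  expect_identical(a$values, b$values)
  expect_identical(a$labels, b$labels)
  c_ <- simulate_cells(n_cells = 80, n_genes = 40, n_classes = 2, seed = 10)
  expect_false(identical(a$values, c_$values))
})

test_that("vanishing dropout width recovers the negative-binomial zero mass", {
  # midpoint 0 and tiny width: the logistic curve becomes a step below any
  # expressed gene's mean, so only NB zeros remain
  theta <- 2
  s <- simulate_cells(n_cells = 4000, n_genes = 10, n_classes = 2,
                      n_marker_genes_per_class = 1, marker_fold_change = 2,
                      class_effect_log_sd = 0, dispersion = theta,
                      baseline_log_sd = 0.2,
                      dropout_midpoint = 0, dropout_steepness = 1e-6,
                      seed = 3)
  # non-marker genes share one mean per class; compare observed zero
  # fraction with (1 + mu/theta)^(-theta) within Monte-Carlo error
  for (j in 5:10) {
    obs <- mean(s$values[, j] == 0)
    mu <- mean(s$values[, j])
    expected <- (1 + mu / theta)^(-theta)
    expect_lt(abs(obs - expected), 0.05)
  }
})

test_that("marker genes rank at the top of the entropy residual", {
  med_rank <- vapply(1:5, function(seed) {
    s <- simulate_cells(n_cells = 400, n_genes = 100, n_classes = 4,
                        n_marker_genes_per_class = 5, seed = seed)
    tab <- compute_gene_scores(s)$table
    markers <- sprintf("gene%04d", 1:20)
    ranks <- rank(-tab$dF2)[tab$gene_name %in% markers]
    median(ranks)
  }, numeric(1))
  # markers (20 of 100 genes) concentrate far above a random median of 50
  expect_true(all(med_rank <= 25))
})

test_that("corruption zeroes exactly floor(fraction x nnz) entries", {
  s <- simulate_cells(n_cells = 30, n_genes = 20, n_classes = 2, seed = 4)
  nnz <- sum(s$values != 0)

  same <- corrupt_dropout(s, 0, seed = 1)
  expect_identical(same$values, s$values)

  half <- corrupt_dropout(s, 0.5, seed = 1)
  expect_equal(sum(half$values != 0), nnz - floor(0.5 * nnz))
  # zeros stay zeros; labels and names untouched
  expect_true(all(half$values[s$values == 0] == 0))
  expect_identical(half$labels, s$labels)
  expect_identical(half$gene_names, s$gene_names)

  dead <- corrupt_dropout(s, 1, seed = 1)
  expect_true(all(dead$values == 0))
})

test_that("observed sparsity increases with the corruption fraction", {
  s <- simulate_cells(n_cells = 50, n_genes = 40, n_classes = 2, seed = 5)
  zf <- vapply(c(0, 0.2, 0.4, 0.6),
               function(f) mean(corrupt_dropout(s, f, seed = 2)$values == 0),
               numeric(1))
  expect_true(all(diff(zf) > 0))
})

test_that("rare-class split hits its reference and query compositions", {
  sp <- make_rare_class_split(n_reference = 5000, n_query = 1000,
                              n_genes = 100, seed = 6)
  rt <- table(sp$reference$labels)
  qt <- table(sp$query$labels)
  expect_equal(unname(rt[["type4"]]), 20L)   # 0.4% of 5000
  expect_equal(unname(qt[["type4"]]), 300L)  # 30% of 1000
  expect_identical(sp$reference$gene_names, sp$query$gene_names)
  # union of splits is the whole simulated population
  expect_equal(nrow(sp$reference$values) + nrow(sp$query$values), 6000L)
  expect_length(intersect(sp$reference$cell_ids, sp$query$cell_ids), 0L)
  # the rare classes sit at or below the few-sample boundary
  expect_true(all(c("type4", "type5", "type6") %in%
                    identify_few_sample_classes(sp$reference$labels)))
})
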