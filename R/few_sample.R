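#' Identify few-sample (rare) cell types
#'
#' A class is few-sample when its cell count does not exceed
#' `threshold * N` (boundary inclusive), with N the total number of
#' reference cells.
#'
#' @param labels character vector of reference cell-type labels.
#' @param threshold fraction of the reference below or at which a class is
#'   rare; default 0.005 (0.5\%).
#' @return Character vector of rare class names (possibly empty), sorted.
#' @export
identify_few_sample_classes <- function(labels, threshold = 0.005) {
  stopifnot(length(labels) > 0, threshold > 0, threshold < 1)
  counts <- table(labels)
  sort(names(counts)[counts <= threshold * length(labels)])
}

# Pair-feature matrix: left cell block then right cell block (2 * D columns).
pair_features <- function(left_mat, right_mat, log1p_values = FALSE) {
  if (log1p_values) {
    left_mat <- log1p(left_mat)
    right_mat <- log1p(right_mat)
  }
  cbind(left_mat, right_mat)
}

#' Build the n-by-n pair training set over rare-class cells
#'
#' Every ordered pair of rare-class reference cells (self-pairs included)
#' becomes one training sample whose features are the two cells'
#' selected-gene vectors concatenated left-then-right (2 * D features) and
#' whose label is 1 when the cells share a class, else 0.
#'
#' @param reference_few [expression_dataset()] holding only rare-class cells,
#'   with labels.
#' @param selected_genes character vector of the D selected genes.
#' @param log1p_values apply `log1p` to the expression values first.
#' @return List with `features` (n^2 x 2D matrix), `label` (0/1 vector),
#'   `left`, `right` (cell indices into `reference_few`).
#' @export
build_pair_training_set <- function(reference_few, selected_genes,
                                    log1p_values = FALSE) {
  n <- nrow(reference_few$values)
  if (n < 2L) stop_cv("too few rare cells to pair (need at least 2)")
  if (is.null(reference_few$labels)) stop_cv("reference cells must be labeled")
  X <- reference_few$values[, selected_genes, drop = FALSE]
  # row-major over left: pair (j, k) = left j, right k
  left <- rep(seq_len(n), each = n)
  right <- rep(seq_len(n), times = n)
  list(
    features = pair_features(X[left, , drop = FALSE], X[right, , drop = FALSE],
                             log1p_values),
    label = as.numeric(reference_few$labels[left] ==
                         reference_few$labels[right]),
    left = left, right = right
  )
}

#' Build the n-by-M pair test set (rare reference cells x query cells)
#'
#' @param reference_few rare-class reference cells.
#' @param query query [expression_dataset()] (M cells).
#' @param selected_genes the D selected genes.
#' @inheritParams build_pair_training_set
#' @return List with `features` (nM x 2D matrix; left = reference cell,
#'   right = query cell), `left` (reference index), `right` (query index).
#' @export
build_pair_test_set <- function(reference_few, query, selected_genes,
                                log1p_values = FALSE) {
  n <- nrow(reference_few$values)
  M <- nrow(query$values)
  Xr <- reference_few$values[, selected_genes, drop = FALSE]
  Xq <- query$values[, selected_genes, drop = FALSE]
  left <- rep(seq_len(n), each = max(M, 0L))
  right <- rep(seq_len(M), times = n)
  list(
    features = pair_features(Xr[left, , drop = FALSE],
                             Xq[right, , drop = FALSE], log1p_values),
    left = left, right = right
  )
}

#' Train the gradient-boosted pair regressor
#'
#' Fits a gradient-boosted tree ensemble with a regression objective to the
#' 0/1 same-class pair labels (learning rate 0.05, `nrounds` boosting
#' rounds, single thread for reproducibility). Predictions are real-valued
#' and are clipped to `[0, 1]` when used.
#'
#' @param pairs a pair training set from [build_pair_training_set()].
#' @param nrounds boosting rounds, default 100.
#' @param learning_rate shrinkage, default 0.05.
#' @param seed RNG seed for the booster.
#' @return An `xgb.Booster`.
#' @export
train_pair_regressor <- function(pairs, nrounds = 100, learning_rate = 0.05,
                                 seed = 1L) {
  y <- pairs$label
  if (length(unique(y)) < 2L) {
    stop_cv("pair labels degenerate: training pairs must include both ",
            "same-class (1) and different-class (0) pairs")
  }
  dtrain <- xgboost::xgb.DMatrix(pairs$features, label = y)
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = learning_rate,
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0
  ))
}

# Predict pair scores, clipped to [0, 1].
predict_pairs <- function(model, features) {
  pmin(pmax(predict(model, xgboost::xgb.DMatrix(features)), 0), 1)
}

#' Aggregate pair predictions into per-class scores
#'
#' For query cell i and rare class x with reference cells j = 1..N_x, the
#' class score is the Pearson-weighted mean of the pair predictions c_ij,
#' `score(x, i) = sum_j w_ij c_ij / sum_j w_ij` with `w_ij = max(r_ij, 0)`
#' (negative correlations are clamped so the denominator stays positive).
#' When every weight vanishes — the query cell correlates with no reference
#' cell of the class — there is no evidence for the class and the score is
#' 0, so the cell falls through to the neural-network stage.
#'
#' @param r n x M matrix of Pearson correlations between rare reference
#'   cells (rows) and query cells (columns); `NA` entries (zero-variance
#'   cells) are treated as 0.
#' @param c_pred n x M matrix of clipped pair predictions.
#' @param ref_classes length-n character vector of the reference cells'
#'   classes.
#' @return Classes x query-cells score matrix.
#' @export
aggregate_pair_scores <- function(r, c_pred, ref_classes) {
  stopifnot(all(dim(r) == dim(c_pred)), nrow(r) == length(ref_classes))
  r[is.na(r)] <- 0
  w <- pmax(r, 0)
  classes <- sort(unique(ref_classes))
  scores <- matrix(NA_real_, length(classes), ncol(r),
                   dimnames = list(classes, colnames(c_pred)))
  for (x in classes) {
    rows <- which(ref_classes == x)
    wx <- w[rows, , drop = FALSE]
    cx <- c_pred[rows, , drop = FALSE]
    denom <- colSums(wx)
    s <- ifelse(denom > 0, colSums(wx * cx) / denom, 0)
    scores[x, ] <- s
  }
  scores
}

#' Score query cells against the rare classes
#'
#' Computes the Pearson correlation r_ij between each rare reference cell
#' and each query cell over the selected genes, predicts c_ij with the pair
#' regressor, and aggregates with [aggregate_pair_scores()].
#'
#' @param model trained pair regressor.
#' @param reference_few rare-class reference cells (labeled).
#' @param query query dataset.
#' @param selected_genes the D selected genes.
#' @inheritParams build_pair_training_set
#' @return List of class `"few_sample_scores"`: `scores` (classes x query
#'   cells), `r`, `c` (the n x M ingredient matrices).
#' @export
score_query_cells <- function(model, reference_few, query, selected_genes,
                              log1p_values = FALSE) {
  Xr <- reference_few$values[, selected_genes, drop = FALSE]
  Xq <- query$values[, selected_genes, drop = FALSE]
  if (log1p_values) {
    Xr <- log1p(Xr)
    Xq <- log1p(Xq)
  }
  n <- nrow(Xr)
  M <- nrow(Xq)

  sd_r <- apply(Xr, 1L, stats::sd)
  sd_q <- apply(Xq, 1L, stats::sd)
  if (any(sd_r == 0) || any(sd_q == 0)) {
    warning("zero-variance expression vectors: their Pearson weights are ",
            "set to 0", call. = FALSE)
  }
  r <- suppressWarnings(cor(t(Xr), t(Xq)))
  r[is.na(r)] <- 0

  test <- build_pair_test_set(reference_few, query, selected_genes,
                              log1p_values)
  c_flat <- if (length(test$left)) predict_pairs(model, test$features) else
    numeric(0)
  c_pred <- matrix(0, n, M)
  c_pred[cbind(test$left, test$right)] <- c_flat
  dimnames(r) <- dimnames(c_pred) <- list(reference_few$cell_ids,
                                          query$cell_ids)

  structure(
    list(scores = aggregate_pair_scores(r, c_pred, reference_few$labels),
         r = r, c = c_pred),
    class = "few_sample_scores"
  )
}

#' Assign query cells from few-sample scores
#'
#' A cell is assigned to its highest-scoring rare class only when that score
#' strictly exceeds `gamma`; otherwise it is `"unassigned"` and falls
#' through to the neural-network stage. Ties above `gamma` go to the
#' lexicographically smaller class name.
#'
#' @param scores a `"few_sample_scores"` object or a classes x cells score
#'   matrix.
#' @param gamma confidence threshold, default 0.7.
#' @return Character vector, one entry per query cell.
#' @export
assign_few_sample <- function(scores, gamma = 0.7) {
  s <- if (inherits(scores, "few_sample_scores")) scores$scores else scores
  if (ncol(s) == 0L) return(character(0))
  classes <- rownames(s)
  # rows are sorted class names, so which.max's first-hit rule breaks ties
  # toward the lexicographically smaller class
  out <- apply(s, 2L, function(col) {
    top <- which.max(col)
    if (col[top] > gamma) classes[top] else UNASSIGNED
  })
  setNames(as.character(out), colnames(s))
}
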