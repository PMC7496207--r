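#' Bootstrap index sets for the ensemble members
#'
#' Each member trains on `round(fraction * N)` cells drawn uniformly with
#' replacement; the draws are reproducible from the per-member seeds.
#'
#' @param n_cells number of reference cells N.
#' @param seeds integer vector, one seed per member.
#' @param fraction resample size as a fraction of N, default 0.3.
#' @param stratified if `TRUE`, draw with replacement within each class in
#'   proportion to class size (requires `labels`). Default `FALSE`.
#' @param labels class labels, needed only when `stratified = TRUE`.
#' @return List of integer index vectors, one per seed.
#' @export
bootstrap_training_sets <- function(n_cells, seeds, fraction = 0.3,
                                    stratified = FALSE, labels = NULL) {
  size <- round(fraction * n_cells)
  lapply(seeds, function(s) {
    with_seed(s, {
      if (!stratified) {
        sample.int(n_cells, size, replace = TRUE)
      } else {
        stopifnot(!is.null(labels), length(labels) == n_cells)
        idx <- unlist(lapply(split(seq_len(n_cells), labels), function(i) {
          k <- max(1L, round(fraction * length(i)))
          sample(i, k, replace = TRUE)
        }), use.names = FALSE)
        idx
      }
    })
  })
}

# Network input features. Default "log1p" (the field's minimal standard
# transform); "log1p_zscore" additionally centers/scales per gene with
# statistics from the full reference so members and query share one
# feature space; "none" feeds raw values.
make_scaler <- function(X, feature_scaling = "log1p") {
  out <- list(mode = feature_scaling)
  if (feature_scaling == "log1p_zscore") {
    L <- log1p(X)
    out$center <- colMeans(L)
    out$scale <- apply(L, 2L, stats::sd)
    out$scale[out$scale == 0] <- 1
  }
  out
}

apply_scaler <- function(scaler, X) {
  switch(scaler$mode,
    none = X,
    log1p = log1p(X),
    log1p_zscore = sweep(sweep(log1p(X), 2L, scaler$center), 2L,
                         scaler$scale, `/`),
    stop_cv("unknown feature scaling '", scaler$mode, "'")
  )
}

#' Train one ensemble member
#'
#' Trains an [mlp_train()] network on a bootstrap subset. A bootstrap
#' accident can collapse the subset to a single class; in that case the
#' resample is redrawn with a fresh seed, up to 5 attempts.
#'
#' @param X preprocessed reference features (all cells).
#' @param labels reference labels (all cells).
#' @param idx bootstrap indices for this member (`NULL` = all cells).
#' @param class_order fixed output class order shared by all members.
#' @param seed member seed.
#' @param n_cells_total reference size, used to redraw after a collapse.
#' @param bootstrap_fraction resample fraction, used only to redraw.
#' @param ... passed to [mlp_train()] (`epochs`, `batch_size`, ...).
#' @return A `"cellvote_mlp"`.
#' @export
train_member <- function(X, labels, idx, class_order, seed,
                         n_cells_total = nrow(X), bootstrap_fraction = 0.3,
                         ...) {
  attempt <- 0L
  while (TRUE) {
    sub_idx <- if (is.null(idx)) seq_len(nrow(X)) else idx
    if (length(unique(labels[sub_idx])) >= 2L) break
    attempt <- attempt + 1L
    if (attempt > 5L) {
      stop_cv("bootstrap subset collapsed to one class 5 times in a row")
    }
    idx <- bootstrap_training_sets(n_cells_total, seed + 7919L * attempt,
                                   fraction = bootstrap_fraction)[[1L]]
  }
  mlp_train(X[sub_idx, , drop = FALSE], labels[sub_idx],
            class_order = class_order, seed = seed, ...)
}

#' Per-member prediction with confidence rejection
#'
#' A cell gets the argmax class only when the maximum softmax probability
#' strictly exceeds `gamma`; otherwise `"unassigned"`.
#'
#' @param member a `"cellvote_mlp"`.
#' @param X preprocessed query features (same genes, same order as
#'   training).
#' @param gamma confidence threshold, default 0.7.
#' @return Character vector of class names / `"unassigned"`.
#' @export
predict_member <- function(member, X, gamma = 0.7) {
  P <- predict(member, X)
  if (nrow(P) == 0L) return(character(0))
  top <- max.col(P, ties.method = "first")
  pmax_ <- P[cbind(seq_len(nrow(P)), top)]
  ifelse(pmax_ > gamma, member$class_order[top], UNASSIGNED)
}

#' Strict-majority vote over member predictions
#'
#' A cell is assigned class x only when strictly more than half of the
#' members predict x; `"unassigned"` member votes never count toward a
#' class. With 10 members this means at least 6 concordant votes, so two
#' classes can never tie at the winning count.
#'
#' @param member_predictions list of per-member character vectors (equal
#'   lengths), or a members x cells character matrix.
#' @return Character vector of voted labels / `"unassigned"`.
#' @export
vote <- function(member_predictions) {
  m <- if (is.list(member_predictions)) {
    do.call(rbind, member_predictions)
  } else {
    member_predictions
  }
  n_members <- nrow(m)
  apply(m, 2L, function(votes) {
    votes <- votes[votes != UNASSIGNED]
    if (!length(votes)) return(UNASSIGNED)
    counts <- table(votes)
    top <- which.max(counts)
    if (counts[top] > n_members / 2) names(counts)[top] else UNASSIGNED
  })
}

#' Train the full voting ensemble
#'
#' Fits `n_members` networks on bootstrap resamples of the reference
#' restricted to the selected genes. Features are log1p-transformed by
#' default (`feature_scaling`); query cells are transformed identically at
#' prediction time. With
#' `n_members = 1` the single network trains on the full reference (the
#' no-ensemble ablation); bootstrap resampling is what the ensemble
#' averages over.
#'
#' @param reference labeled [expression_dataset()] already restricted (or
#'   restrictable) to the selected genes.
#' @param selected_genes the D selected genes, in order.
#' @param n_members number of networks, default 10.
#' @param gamma confidence threshold stored for prediction, default 0.7.
#' @param bootstrap_fraction resample size fraction, default 0.3.
#' @param stratified stratify resamples by class, default `FALSE`.
#' @param epochs,batch_size,learning_rate training hyperparameters passed to
#'   [mlp_train()].
#' @param feature_scaling `"log1p"` (default), `"log1p_zscore"`, or
#'   `"none"`.
#' @param seed master seed; member seeds are `seed + 1 .. seed + n_members`.
#' @return An object of class `"cellvote_ensemble"`.
#' @export
train_ensemble <- function(reference, selected_genes, n_members = 10,
                           gamma = 0.7, bootstrap_fraction = 0.3,
                           stratified = FALSE, epochs = 50, batch_size = 64,
                           learning_rate = 1e-3,
                           feature_scaling = c("log1p", "log1p_zscore",
                                               "none"),
                           seed = 1L) {
  feature_scaling <- match.arg(feature_scaling)
  stopifnot(!is.null(reference$labels))
  Xraw <- reference$values[, selected_genes, drop = FALSE]
  scaler <- make_scaler(Xraw, feature_scaling)
  X <- apply_scaler(scaler, Xraw)
  class_order <- sort(unique(reference$labels))
  member_seeds <- as.integer(seed) + seq_len(n_members)

  idx_lists <- if (n_members > 1L) {
    bootstrap_training_sets(nrow(X), member_seeds,
                            fraction = bootstrap_fraction,
                            stratified = stratified,
                            labels = reference$labels)
  } else {
    list(NULL)
  }
  members <- mapply(function(idx, s) {
    train_member(X, reference$labels, idx, class_order, s,
                 n_cells_total = nrow(X),
                 bootstrap_fraction = bootstrap_fraction,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate)
  }, idx_lists, member_seeds, SIMPLIFY = FALSE)

  structure(
    list(members = members, bootstrap_seeds = member_seeds,
         class_order = class_order, gamma = gamma, scaler = scaler,
         selected_genes = selected_genes,
         hyperparams = list(n_members = n_members,
                            bootstrap_fraction = bootstrap_fraction,
                            stratified = stratified, epochs = epochs,
                            batch_size = batch_size,
                            learning_rate = learning_rate,
                            feature_scaling = feature_scaling,
                            optimizer = "adam",
                            loss = "categorical cross-entropy")),
    class = "cellvote_ensemble"
  )
}

#' Voted ensemble prediction
#'
#' @param object a `"cellvote_ensemble"`.
#' @param query [expression_dataset()] containing the selected genes.
#' @param gamma override the stored confidence threshold.
#' @param ... unused.
#' @return Named character vector of voted labels / `"unassigned"`.
#' @export
predict.cellvote_ensemble <- function(object, query, gamma = object$gamma,
                                      ...) {
  missing <- setdiff(object$selected_genes, query$gene_names)
  if (length(missing)) {
    stop_cv("query is missing selected genes: ",
            paste(head(missing, 10L), collapse = ", "))
  }
  Xq <- apply_scaler(object$scaler,
                     query$values[, object$selected_genes, drop = FALSE])
  if (nrow(Xq) == 0L) return(setNames(character(0), character(0)))
  preds <- lapply(object$members, function(m) predict_member(m, Xq, gamma))
  setNames(vote(preds), query$cell_ids)
}
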