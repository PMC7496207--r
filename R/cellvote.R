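#' Fit a cell-type classifier on a labeled reference
#'
#' The full cascade: (1) rank genes shared with the query by the
#' dropout-residual score and keep the top `k_features`; (2) if any cell
#' type comprises at most `few_sample_threshold` of the reference, train
#' the pairwise few-sample learner on those rare classes; (3) train
#' `n_members` multilayer perceptrons on bootstrap resamples of the full
#' reference. At prediction time the few-sample stage assigns confident
#' rare-class cells first, the voted ensemble classifies the rest, and
#' cells no stage is confident about are `"unassigned"`.
#'
#' @param reference labeled [expression_dataset()].
#' @param query_genes gene names available in the query; feature selection
#'   is restricted to genes shared with the reference. Defaults to the
#'   reference's own genes (self-projection).
#' @param k_features number of genes to select, default 100.
#' @param alpha dropout-residual weight in the gene score, default 0.5.
#' @param log_base logarithm base for the gene score, default natural.
#' @param few_sample enable the rare-class pairwise stage, default `TRUE`.
#' @param few_sample_threshold rare-class reference fraction (inclusive
#'   boundary), default 0.005.
#' @param gamma confidence threshold shared by both stages, default 0.7.
#' @param pair_log1p compute pair features on `log1p` expression instead of
#'   raw selected-gene values, default `FALSE`.
#' @param n_boost_rounds boosting rounds of the pair regressor, default 100.
#' @param n_members ensemble size, default 10.
#' @param bootstrap_fraction member resample fraction, default 0.3.
#' @param stratified stratify bootstrap resamples by class, default `FALSE`.
#' @param epochs,batch_size,learning_rate network training hyperparameters.
#' @param feature_scaling network input transform: `"log1p"` (default),
#'   `"log1p_zscore"`, or `"none"`.
#' @param seed master seed; all stage seeds derive from it.
#' @return An object of class `"cellvote"` with components `gene_scores`,
#'   `selected_genes`, `few_sample` (`NULL` when inactive), `ensemble`,
#'   `config`.
#' @examples
#' sim <- simulate_cells(n_cells = 120, n_genes = 60, n_classes = 2,
#'                       seed = 1)
#' fit <- cellvote(sim, k_features = 30, epochs = 10, n_members = 3,
#'                 seed = 1)
#' table(predict(fit, sim))
#' @export
cellvote <- function(reference, query_genes = reference$gene_names,
                     k_features = 100, alpha = 0.5,
                     log_base = c("natural", "2", "10"),
                     few_sample = TRUE, few_sample_threshold = 0.005,
                     gamma = 0.7, pair_log1p = FALSE, n_boost_rounds = 100,
                     n_members = 10, bootstrap_fraction = 0.3,
                     stratified = FALSE, epochs = 50, batch_size = 64,
                     learning_rate = 1e-3,
                     feature_scaling = c("log1p", "log1p_zscore", "none"),
                     seed = 1L) {
  log_base <- match.arg(log_base)
  feature_scaling <- match.arg(feature_scaling)
  if (is.null(reference$labels)) stop_cv("reference must be labeled")

  shared <- reference$gene_names[reference$gene_names %in% query_genes]
  if (!length(shared)) stop_cv("no shared genes between reference and query")
  ref_shared <- subset_genes(reference, shared)

  gene_scores <- compute_gene_scores(ref_shared, alpha = alpha,
                                     log_base = log_base)
  ranked <- rank_genes(gene_scores$table)
  if (k_features > length(ranked)) {
    warning("k_features = ", k_features, " exceeds the ", length(ranked),
            " shared genes; using all of them", call. = FALSE)
    k_features <- length(ranked)
  }
  selected <- ranked[seq_len(k_features)]

  few_model <- NULL
  if (few_sample) {
    rare <- identify_few_sample_classes(reference$labels,
                                        threshold = few_sample_threshold)
    if (length(rare) >= 1L) {
      idx <- which(reference$labels %in% rare)
      ref_few <- subset_cells(ref_shared, idx)
      if (length(idx) >= 2L &&
          length(unique(ref_few$labels)) >= 2L) {
        pairs <- build_pair_training_set(ref_few, selected,
                                         log1p_values = pair_log1p)
        regressor <- train_pair_regressor(pairs, nrounds = n_boost_rounds,
                                          seed = as.integer(seed) + 1000L)
        few_model <- list(classes = rare, regressor = regressor,
                          reference_few = ref_few,
                          pair_log1p = pair_log1p)
      } else {
        warning("rare classes found but pairing needs at least two cells ",
                "from at least two classes; few-sample stage inactive",
                call. = FALSE)
      }
    }
  }

  ensemble <- train_ensemble(ref_shared, selected, n_members = n_members,
                             gamma = gamma,
                             bootstrap_fraction = bootstrap_fraction,
                             stratified = stratified, epochs = epochs,
                             batch_size = batch_size,
                             learning_rate = learning_rate,
                             feature_scaling = feature_scaling, seed = seed)

  structure(
    list(
      gene_scores = gene_scores,
      selected_genes = selected,
      few_sample = few_model,
      ensemble = ensemble,
      config = list(k_features = k_features, alpha = alpha,
                    log_base = log_base, few_sample = few_sample,
                    few_sample_threshold = few_sample_threshold,
                    gamma = gamma, pair_log1p = pair_log1p,
                    n_boost_rounds = n_boost_rounds, n_members = n_members,
                    bootstrap_fraction = bootstrap_fraction,
                    stratified = stratified, epochs = epochs,
                    batch_size = batch_size, learning_rate = learning_rate,
                    feature_scaling = feature_scaling,
                    seed = as.integer(seed)),
      call = match.call()
    ),
    class = "cellvote"
  )
}

#' Classify query cells with a fitted cascade
#'
#' Cells whose maximum few-sample score strictly exceeds `gamma` keep the
#' few-sample label and never reach the ensemble; all other cells are
#' classified by the strict-majority vote of the networks; cells rejected
#' by both stages are `"unassigned"`. Every query cell receives exactly one
#' of \{a class, `"unassigned"`\}.
#'
#' @param object a fitted `"cellvote"` model.
#' @param query [expression_dataset()] containing all selected genes.
#' @param ... unused.
#' @return Named character vector of predicted labels (names = cell ids).
#' @export
predict.cellvote <- function(object, query, ...) {
  missing <- setdiff(object$selected_genes, query$gene_names)
  if (length(missing)) {
    stop_cv("query is missing selected genes: ",
            paste(head(missing, 10L), collapse = ", "))
  }
  M <- nrow(query$values)
  out <- setNames(rep(UNASSIGNED, M), query$cell_ids)
  if (M == 0L) return(out)

  remaining <- rep(TRUE, M)
  if (!is.null(object$few_sample)) {
    fs <- score_query_cells(object$few_sample$regressor,
                            object$few_sample$reference_few, query,
                            object$selected_genes,
                            log1p_values = object$few_sample$pair_log1p)
    fs_labels <- assign_few_sample(fs, gamma = object$config$gamma)
    hit <- fs_labels != UNASSIGNED
    out[hit] <- fs_labels[hit]
    remaining <- !hit
  }
  if (any(remaining)) {
    rest <- subset_cells(query, which(remaining))
    out[remaining] <- predict(object$ensemble, rest)
  }
  out
}

#' @export
print.cellvote <- function(x, ...) {
  cfg <- x$config
  cat("cellvote classifier\n")
  cat("  classes: ", length(x$ensemble$class_order), " (",
      paste(head(x$ensemble$class_order, 5L), collapse = ", "),
      if (length(x$ensemble$class_order) > 5L) ", ..." else "", ")\n",
      sep = "")
  cat("  selected genes: ", length(x$selected_genes),
      " (alpha = ", cfg$alpha, ")\n", sep = "")
  if (is.null(x$few_sample)) {
    cat("  few-sample stage: inactive\n")
  } else {
    cat("  few-sample stage: classes ",
        paste(x$few_sample$classes, collapse = ", "), "\n", sep = "")
  }
  cat("  ensemble: ", cfg$n_members, " networks, gamma = ", cfg$gamma,
      ", seed = ", cfg$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.cellvote <- function(object, ...) {
  print(object)
  cat("\nDropout fit: F ~ ",
      format(coef(object)[["slope"]], digits = 4), " * D + ",
      format(coef(object)[["intercept"]], digits = 4), "\n", sep = "")
  cat("Top selected genes:\n")
  print(head(object$selected_genes, 10L))
  invisible(object)
}

#' Coefficients of the dropout least-squares line
#'
#' @param object a fitted `"cellvote"`.
#' @param ... unused.
#' @return `c(slope, intercept)` of the fit of `F` on the dropout rate.
#' @export
coef.cellvote <- function(object, ...) object$gene_scores$fit

#' Gene-score residuals of a fitted model
#'
#' @param object a fitted `"cellvote"`.
#' @param ... unused.
#' @return Data frame with per-gene `dF1` (dropout residual) and `dF2`
#'   (entropy residual).
#' @export
residuals.cellvote <- function(object, ...) {
  tab <- object$gene_scores$table
  data.frame(gene_name = tab$gene_name, dF1 = tab$dF1, dF2 = tab$dF2,
             stringsAsFactors = FALSE)
}

#' Plot the dropout fit behind the gene score
#'
#' Scatter of per-gene log mean expression `F` against dropout rate `D`,
#' the least-squares line, and the selected genes highlighted.
#'
#' @param x a fitted `"cellvote"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cellvote <- function(x, ...) {
  tab <- x$gene_scores$table
  sel <- tab$gene_name %in% x$selected_genes
  graphics::plot(tab$dropout_rate, tab$F, pch = 16,
                 col = ifelse(sel, "firebrick", "grey60"),
                 xlab = "dropout rate D", ylab = "log mean expression F",
                 ...)
  graphics::abline(a = coef(x)[["intercept"]], b = coef(x)[["slope"]],
                   lwd = 2)
  graphics::legend("topright", legend = c("selected", "other", "OLS fit"),
                   col = c("firebrick", "grey60", "black"),
                   pch = c(16, 16, NA), lty = c(NA, NA, 1), bty = "n")
  invisible(x)
}

#' Self-projection cross-validation
#'
#' Stratified k-fold cross-validation within one labeled dataset: each fold
#' in turn is held out as the query, the model is fitted on the remaining
#' cells, and predictions are scored with [evaluate_predictions()]. The
#' internal-consistency benchmark for a classifier with a reject option.
#'
#' @param dataset labeled [expression_dataset()].
#' @param folds number of folds, default 5.
#' @param seed seed for fold assignment and fits.
#' @param ... passed to [cellvote()].
#' @return Object of class `"self_projection"`: `reports` (per-fold
#'   [evaluate_predictions()] results), `fold_of` (fold index per cell),
#'   `kappa_mean`, `kappa_var`, `assigned_rate_mean`, `assigned_rate_var`.
#' @export
self_project <- function(dataset, folds = 5, seed = 1L, ...) {
  stopifnot(folds >= 2)
  if (is.null(dataset$labels)) stop_cv("dataset must be labeled")
  small <- names(which(table(dataset$labels) < folds))
  if (length(small)) {
    warning("classes smaller than the fold count may be absent from some ",
            "training folds: ", paste(small, collapse = ", "),
            call. = FALSE)
  }
  fold_of <- stratified_folds(dataset$labels, folds, seed)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- subset_cells(dataset, which(fold_of != f))
    test <- subset_cells(dataset, which(fold_of == f))
    fit <- cellvote(train, query_genes = dataset$gene_names,
                    seed = as.integer(seed) + f, ...)
    pred <- predict(fit, test)
    reports[[f]] <- evaluate_predictions(test$labels, pred)
  }
  kappas <- vapply(reports, `[[`, numeric(1), "kappa")
  rates <- vapply(reports, `[[`, numeric(1), "assigned_rate")
  structure(
    list(reports = reports, fold_of = fold_of,
         kappa_mean = mean(kappas), kappa_var = var(kappas),
         assigned_rate_mean = mean(rates), assigned_rate_var = var(rates)),
    class = "self_projection"
  )
}

#' @export
print.self_projection <- function(x, ...) {
  cat("self_projection over ", length(x$reports), " folds\n", sep = "")
  cat(sprintf("  kappa: mean %.4f, var %.2e\n", x$kappa_mean, x$kappa_var))
  cat(sprintf("  assigned rate: mean %.4f, var %.2e\n",
              x$assigned_rate_mean, x$assigned_rate_var))
  invisible(x)
}
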