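#' Evaluate predictions with Cohen's kappa over assigned cells
#'
#' Agreement is chance-corrected on the assigned cells only: with per-class
#' true counts a_c and predicted counts b_c among the n assigned cells,
#' `p_o` is the accuracy among assigned cells,
#' `p_e = sum_c a_c * b_c / n^2`, and `kappa = (p_o - p_e) / (1 - p_e)`.
#' The assigned rate is `n / N` over all `N` query cells. The classes C are
#' those present in either vector among the assigned cells.
#'
#' @param true_labels character vector of true cell types.
#' @param predicted_labels same-length character vector; may contain
#'   `"unassigned"`.
#' @return An object of class `"eval_report"`: list with `a` and `b`
#'   (named per-class counts), `n_assigned`, `n_query`, `p_o`, `p_e`,
#'   `kappa`, `assigned_rate`. With zero assigned cells `p_o`, `p_e` and
#'   `kappa` are `NaN` and `assigned_rate` is 0.
#' @examples
#' evaluate_predictions(c("a", "a", "b"), c("a", "unassigned", "b"))
#' @export
evaluate_predictions <- function(true_labels, predicted_labels) {
  stopifnot(length(true_labels) == length(predicted_labels))
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  N <- length(true_labels)
  assigned <- predicted_labels != UNASSIGNED
  n <- sum(assigned)

  if (n == 0L) {
    rep_ <- list(a = numeric(0), b = numeric(0), n_assigned = 0L,
                 n_query = N, p_o = NaN, p_e = NaN, kappa = NaN,
                 assigned_rate = 0)
    return(structure(rep_, class = "eval_report"))
  }

  tr <- true_labels[assigned]
  pr <- predicted_labels[assigned]
  classes <- sort(unique(c(tr, pr)))
  a <- vapply(classes, function(x) sum(tr == x), numeric(1))
  b <- vapply(classes, function(x) sum(pr == x), numeric(1))
  p_o <- mean(tr == pr)
  p_e <- sum(a * b) / n^2
  kappa <- if (p_e == 1) NaN else (p_o - p_e) / (1 - p_e)

  structure(
    list(a = a, b = b, n_assigned = n, n_query = N,
         p_o = p_o, p_e = p_e, kappa = kappa, assigned_rate = n / N),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: ", x$n_assigned, "/", x$n_query, " cells assigned (",
      sprintf("%.1f%%", 100 * x$assigned_rate), ")\n", sep = "")
  cat(sprintf("  p_o = %.4f, p_e = %.4f, kappa = %.4f\n",
              x$p_o, x$p_e, x$kappa))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# to folds round-robin, so fold sizes differ by at most one per class.
stratified_folds <- function(labels, folds, seed) {
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}
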