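#' Per-gene dropout rates
#'
#' The dropout rate of a gene is the fraction of cells in which it is an
#' exact zero.
#'
#' @param data an [expression_dataset()].
#' @return Named numeric vector in `[0, 1]`, one entry per gene.
#' @export
compute_dropout_rates <- function(data) {
  colMeans(data$values == 0)
}

#' Score genes by dropout and entropy residuals
#'
#' For each gene j with expression values `E[, j]` over n cells, computes
#' \itemize{
#'   \item `F = log(mean(E) + 1)`, the log-plus-one of the arithmetic mean;
#'   \item `F1_hat = a * D + b`, the ordinary-least-squares fit of F on the
#'     dropout rate D across genes, predicting expression level from how
#'     often the gene drops out;
#'   \item `F2_hat = mean(log(E + 1))`, the mean of log-plus-one values, an
#'     entropy-like summary that is depressed by uneven expression;
#'   \item the residuals `dF1 = F - F1_hat` and `dF2 = F - F2_hat`
#'     (`dF2 >= 0` always, by Jensen's inequality);
#'   \item the combined score `G = alpha * dF1 + (1 - alpha) * dF2`.
#' }
#' Genes that are expressed more than their dropout rate predicts, and more
#' unevenly than a flat profile, score high.
#'
#' @param data an [expression_dataset()] with at least 2 genes.
#' @param alpha weight of the dropout residual in `G`, in `[0, 1]`;
#'   default 0.5.
#' @param log_base `"natural"` (default), `"2"`, or `"10"`.
#' @return A list of class `"gene_scores"`: `table` (data.frame with columns
#'   `gene_name, dropout_rate, F, F1_hat, F2_hat, dF1, dF2, G`), and `fit`
#'   (`c(slope, intercept)` of the least-squares line).
#' @export
compute_gene_scores <- function(data, alpha = 0.5,
                                log_base = c("natural", "2", "10")) {
  log_base <- match.arg(log_base)
  base <- switch(log_base, natural = exp(1), `2` = 2, `10` = 10)
  stopifnot(alpha >= 0, alpha <= 1)
  E <- data$values
  p <- ncol(E)
  if (p < 2L) stop_cv("need at least 2 genes to fit the dropout line")

  D <- compute_dropout_rates(data)
  F_ <- log(colMeans(E) + 1, base = base)
  F2_hat <- colMeans(log(E + 1, base = base))
  if (var(D) == 0) {
    stop_cv("degenerate dropout fit: all genes share one dropout rate")
  }
  ols <- stats::lm.fit(cbind(intercept = 1, dropout = D), F_)
  a <- unname(ols$coefficients["dropout"])
  b <- unname(ols$coefficients["intercept"])
  F1_hat <- a * D + b
  dF1 <- F_ - F1_hat
  dF2 <- F_ - F2_hat
  G <- alpha * dF1 + (1 - alpha) * dF2

  structure(
    list(
      table = data.frame(
        gene_name = data$gene_names, dropout_rate = unname(D),
        F = unname(F_), F1_hat = unname(F1_hat), F2_hat = unname(F2_hat),
        dF1 = unname(dF1), dF2 = unname(dF2), G = unname(G),
        stringsAsFactors = FALSE
      ),
      fit = c(slope = a, intercept = b),
      alpha = alpha, log_base = log_base
    ),
    class = "gene_scores"
  )
}

#' @export
print.gene_scores <- function(x, ...) {
  cat("gene_scores: ", nrow(x$table), " genes; fit F ~ ",
      format(x$fit[["slope"]], digits = 4), " * D + ",
      format(x$fit[["intercept"]], digits = 4),
      "; alpha = ", x$alpha, ", log base ", x$log_base, "\n", sep = "")
  top <- x$table[order(-x$table$G, x$table$gene_name), ]
  print(head(top[, c("gene_name", "dropout_rate", "F", "dF1", "dF2", "G")],
             5L), row.names = FALSE)
  invisible(x)
}

# Rank by G descending, ties by gene name ascending.
rank_genes <- function(score_table) {
  score_table$gene_name[order(-score_table$G, score_table$gene_name)]
}

#' Select the top-scoring genes shared by reference and query
#'
#' Scores are computed on the reference dataset restricted to the genes
#' shared with the query (run [align_common_genes()] first, or pass already
#' aligned datasets); the highest-scoring `k` shared genes are returned,
#' ties broken by gene name for determinism.
#'
#' @param reference,query aligned [expression_dataset()] objects.
#' @param k number of genes to keep (default 100). If `k` exceeds the number
#'   of shared genes, all shared genes are returned with a warning.
#' @inheritParams compute_gene_scores
#' @return Character vector of `min(k, n_shared)` gene names, best first.
#' @export
select_features <- function(reference, query, k = 100, alpha = 0.5,
                            log_base = c("natural", "2", "10")) {
  stopifnot(k >= 1)
  aligned <- align_common_genes(reference, query)
  scores <- compute_gene_scores(aligned$reference, alpha = alpha,
                                log_base = log_base)
  ranked <- rank_genes(scores$table)
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds the ", length(ranked),
            " shared genes; using all of them", call. = FALSE)
    k <- length(ranked)
  }
  ranked[seq_len(k)]
}
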