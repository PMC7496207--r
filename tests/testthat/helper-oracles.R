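# Independent brute-force oracles. Deliberately written with explicit loops
# and closed forms, sharing no code with the package internals.

# Per-gene dropout/expression scores by explicit loops; OLS by the
# closed form a = cov(D, F) / var(D), b = mean(F) - a * mean(D).
oracle_gene_scores <- function(E, alpha = 0.5) {
  n <- nrow(E)
  p <- ncol(E)
  D <- F_ <- F2 <- numeric(p)
  for (j in seq_len(p)) {
    zeros <- 0
    s <- 0
    slog <- 0
    for (i in seq_len(n)) {
      if (E[i, j] == 0) zeros <- zeros + 1
      s <- s + E[i, j]
      slog <- slog + log(E[i, j] + 1)
    }
    D[j] <- zeros / n
    F_[j] <- log(s / n + 1)
    F2[j] <- slog / n
  }
  a <- sum((D - mean(D)) * (F_ - mean(F_))) / sum((D - mean(D))^2)
  b <- mean(F_) - a * mean(D)
  F1 <- a * D + b
  dF1 <- F_ - F1
  dF2 <- F_ - F2
  list(D = D, F = F_, F1_hat = F1, F2_hat = F2, dF1 = dF1, dF2 = dF2,
       G = alpha * dF1 + (1 - alpha) * dF2, a = a, b = b)
}

# Textbook Cohen's kappa from the confusion matrix of the assigned cells.
oracle_kappa <- function(true, pred) {
  keep <- pred != "unassigned"
  true <- true[keep]
  pred <- pred[keep]
  lev <- sort(unique(c(true, pred)))
  cm <- table(factor(true, lev), factor(pred, lev))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (po - pe) / (1 - pe)
}

# Small random expression matrix with guaranteed non-degenerate dropout.
random_expr_dataset <- function(n_cells, n_genes, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(n_cells * n_genes, lambda = 1.2), n_cells, n_genes)
    D <- colMeans(m == 0)
    if (length(unique(D)) > 1) break
  }
  expression_dataset(m, paste0("g", seq_len(n_genes)),
                     paste0("c", seq_len(n_cells)))
}
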