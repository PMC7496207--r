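#' Simulate a labeled single-cell expression dataset
#'
#' Counts are negative-binomial with class-specific means: every gene has a
#' baseline mean drawn once from a log-normal, each class modulates every
#' gene by a mild log-normal factor (cell types differ transcriptome-wide,
#' not only at markers), and each class owns a disjoint block of on/off
#' identity markers: up-shifted by `marker_fold_change` in the class,
#' down-shifted by the same factor everywhere else. Technical
#' dropout then zeroes entries with a Bernoulli probability that follows a
#' logistic curve decreasing in the gene's (class-specific) mean:
#' `p_drop = plogis((dropout_midpoint - log1p(mu)) / dropout_steepness)`.
#' `dropout_steepness` is the logistic width: as it shrinks toward 0 the
#' curve sharpens to a step at the midpoint, so with midpoint 0 essentially
#' no extra dropout is added and the observed zero fraction approaches the
#' negative-binomial zero mass `(1 + mu/dispersion)^(-dispersion)`.
#'
#' @param n_cells total number of cells.
#' @param n_genes number of genes.
#' @param class_proportions numeric vector summing to 1 (entries below
#'   0.005 create few-sample classes). Default: balanced over `n_classes`.
#' @param n_classes number of cell types when `class_proportions` is not
#'   given, default 5.
#' @param n_marker_genes_per_class genes up-shifted per class, default 10.
#' @param marker_fold_change multiplicative marker shift, > 1, default 12
#'   (markers are identity genes: near-off outside their class, highly
#'   expressed within it).
#' @param class_effect_log_sd standard deviation (log scale) of the
#'   per-gene, per-class modulation factor, default 0.1; 0 disables it so
#'   classes differ only at their markers.
#' @param dispersion negative-binomial size parameter theta, default 0.6
#'   (smaller = more overdispersed).
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   baseline gene means, defaults `log(2)` and 1.
#' @param dropout_midpoint logistic midpoint on the `log1p(mu)` scale,
#'   default 2.5 (drop-seq-like overall sparsity around 85 percent).
#' @param dropout_steepness logistic width (see above), default 1.
#' @param sibling_of optional integer vector (length = number of classes;
#'   `NA` = independent class). A class with `sibling_of[k] = s` inherits
#'   class s's whole mean profile (including s's markers) and adds only its
#'   own private marker block — a subtype/relative of s, the typical
#'   situation for rare cell types.
#' @param seed RNG seed; identical configuration and seed give identical
#'   matrices.
#' @return A labeled [expression_dataset()]; labels are `type1, type2, ...`
#'   in proportion order.
#' @export
simulate_cells <- function(n_cells, n_genes, class_proportions = NULL,
                           n_classes = 5, n_marker_genes_per_class = 10,
                           marker_fold_change = 12, class_effect_log_sd = 0.1,
                           dispersion = 0.6,
                           baseline_log_mean = log(2), baseline_log_sd = 1,
                           dropout_midpoint = 2.5, dropout_steepness = 1,
                           sibling_of = NULL, seed = 1L) {
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  stopifnot(n_cells >= 1, n_genes >= 1, marker_fold_change > 1,
            dispersion > 0, dropout_steepness > 0)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop_cv("class_proportions must sum to 1")
  }
  n_classes <- length(class_proportions)
  counts_per_class <- proportions_to_counts(class_proportions, n_cells)
  if (any(counts_per_class == 0L)) {
    stop_cv("class proportions too small for n_cells: a class received 0 ",
            "cells")
  }
  if (n_marker_genes_per_class * n_classes > n_genes) {
    stop_cv("not enough genes for ", n_classes, " classes with ",
            n_marker_genes_per_class, " markers each")
  }

  with_seed(seed, {
    base_mu <- exp(rnorm(n_genes, baseline_log_mean, baseline_log_sd))
    class_mu <- matrix(rep(base_mu, n_classes), n_classes, n_genes,
                       byrow = TRUE)
    if (class_effect_log_sd > 0) {
      class_mu <- class_mu *
        exp(matrix(rnorm(n_classes * n_genes, 0, class_effect_log_sd),
                   n_classes, n_genes))
    }
    # markers behave like on/off cell-identity genes: up-shifted in their
    # class, down-shifted everywhere else (so most off-state draws are 0)
    marker_block <- function(k) {
      (k - 1L) * n_marker_genes_per_class + seq_len(n_marker_genes_per_class)
    }
    for (k in seq_len(n_classes)) {
      markers <- marker_block(k)
      class_mu[, markers] <- class_mu[, markers] / marker_fold_change
      class_mu[k, markers] <- class_mu[k, markers] * marker_fold_change^2
    }
    if (!is.null(sibling_of)) {
      stopifnot(length(sibling_of) == n_classes)
      for (k in seq_len(n_classes)) {
        s <- sibling_of[k]
        if (!is.na(s) && s > 0) {
          own <- marker_block(k)
          class_mu[k, ] <- class_mu[s, ]
          class_mu[k, own] <- base_mu[own] * marker_fold_change
        }
      }
    }

    labels <- rep(paste0("type", seq_len(n_classes)), counts_per_class)
    mu <- class_mu[rep(seq_len(n_classes), counts_per_class), ,
                   drop = FALSE]
    counts <- matrix(
      rnbinom(n_cells * n_genes, size = dispersion, mu = as.vector(mu)),
      n_cells, n_genes
    )
    p_drop <- plogis((dropout_midpoint - log1p(mu)) / dropout_steepness)
    keep <- matrix(runif(n_cells * n_genes) >= as.vector(p_drop),
                   n_cells, n_genes)
    counts <- counts * keep

    expression_dataset(
      counts,
      sprintf("gene%04d", seq_len(n_genes)),
      sprintf("cell%05d", seq_len(n_cells)),
      labels = labels
    )
  })
}

# Largest-remainder apportionment of n_cells to proportions.
proportions_to_counts <- function(props, n_cells) {
  raw <- props * n_cells
  counts <- floor(raw)
  rem <- n_cells - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Zero a fraction of the non-zero entries (sparsity corruption)
#'
#' Exactly `floor(fraction * nnz)` non-zero entries, chosen uniformly
#' without replacement, are set to 0; zero entries, labels and names are
#' never touched.
#'
#' @param data an [expression_dataset()].
#' @param fraction fraction of non-zero entries to zero, in `[0, 1]`.
#' @param seed RNG seed for the entry choice.
#' @return The corrupted [expression_dataset()].
#' @export
corrupt_dropout <- function(data, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  values <- data$values
  nz <- which(values != 0)
  n_zero <- floor(fraction * length(nz))
  if (n_zero > 0) {
    chosen <- with_seed(seed, sample(nz, n_zero, replace = FALSE))
    values[chosen] <- 0
  }
  expression_dataset(values, data$gene_names, data$cell_ids,
                     labels = data$labels)
}

#' Simulate a reference/query split with rare reference classes
#'
#' Simulates one population whose class structure mirrors the hard
#' label-transfer regime: designated classes are rare in the reference
#' (at or below the few-sample boundary) but abundant in the query, the
#' situation in which a classifier trained conventionally never learns the
#' rare types. The remaining cells are split evenly over the common
#' classes. The union of the two returned datasets is exactly the
#' simulated population.
#'
#' @param n_reference,n_query cells in each split, defaults 5000 and 1000.
#' @param n_common_classes number of abundant classes, default 3.
#' @param rare_reference_fractions fractions of the reference taken by each
#'   rare class, default `c(0.004, 0.003, 0.002)` (real references carry
#'   several sub-0.5\% cell types).
#' @param rare_query_fractions fractions of the query taken by the same
#'   rare classes, default `c(0.30, 0.04, 0.03)`.
#' @param siblings if `TRUE`, each rare class is generated as a subtype of
#'   one common class (shared profile plus a private marker block).
#'   Default `FALSE`: rare types carry their own identity markers, the
#'   regime in which correlation weighting can screen out cells of
#'   unrelated abundant types.
#' @param seed RNG seed.
#' @param ... passed to [simulate_cells()] (`n_genes`, markers, ...).
#' @return List with `reference` and `query` [expression_dataset()]s; the
#'   rare classes are the last `length(rare_reference_fractions)` types.
#' @export
make_rare_class_split <- function(n_reference = 5000, n_query = 1000,
                                  n_common_classes = 3,
                                  rare_reference_fractions =
                                    c(0.004, 0.003, 0.002),
                                  rare_query_fractions = c(0.30, 0.04, 0.03),
                                  siblings = FALSE, seed = 1L, ...) {
  stopifnot(length(rare_reference_fractions) ==
              length(rare_query_fractions))
  n_rare <- length(rare_reference_fractions)
  ref_rare <- proportions_to_counts_exact(rare_reference_fractions,
                                          n_reference)
  qry_rare <- proportions_to_counts_exact(rare_query_fractions, n_query)
  ref_common <- spread_evenly(n_reference - sum(ref_rare), n_common_classes)
  qry_common <- spread_evenly(n_query - sum(qry_rare), n_common_classes)

  per_class <- c(ref_common + qry_common, ref_rare + qry_rare)
  total <- sum(per_class)
  dots <- list(...)
  n_genes <- dots$n_genes %||% 500
  dots$n_genes <- NULL
  if (siblings && is.null(dots$sibling_of)) {
    dots$sibling_of <- c(rep(NA_integer_, n_common_classes),
                         ((seq_len(n_rare) - 1L) %% n_common_classes) + 1L)
  }
  sim <- do.call(simulate_cells, c(
    list(n_cells = total, n_genes = n_genes,
         class_proportions = per_class / total, seed = seed),
    dots
  ))

  ref_counts <- c(ref_common, ref_rare)
  ref_idx <- unlist(lapply(seq_along(per_class), function(k) {
    idx <- which(sim$labels == paste0("type", k))
    idx[seq_len(ref_counts[k])]
  }), use.names = FALSE)
  list(reference = subset_cells(sim, sort(ref_idx)),
       query = subset_cells(sim, sort(setdiff(seq_len(total), ref_idx))))
}

proportions_to_counts_exact <- function(fracs, n) {
  pmax(1L, as.integer(round(fracs * n)))
}

spread_evenly <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  as.integer(base + (seq_len(k) <= extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
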