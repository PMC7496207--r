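#' Construct an expression dataset
#'
#' The package's container for single-cell expression data: a dense
#' cells-by-genes matrix of non-negative values together with unique gene
#' names, unique cell identifiers, and (for a reference) one cell-type label
#' per cell. All readers normalize to this orientation, whatever the on-disk
#' layout.
#'
#' @param values numeric matrix, rows = cells, columns = genes; all entries
#'   must be finite and non-negative (raw counts or normalized expression —
#'   downstream formulas apply `log(x + 1)` and no further normalization).
#' @param gene_names character vector of unique gene names, one per column.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param labels optional character vector of cell-type labels, one per cell.
#'   The token `"unassigned"` is reserved for classifier output and rejected
#'   here.
#' @param uppercase_genes if `TRUE`, gene names are uppercased before the
#'   uniqueness check (useful for cross-species matching by symbol).
#'   Default `FALSE`: matching is exact.
#'
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `values`, `gene_names`, `cell_ids`, `labels`.
#' @examples
#' m <- matrix(c(0, 2, 1, 0, 5, 3), nrow = 2)
#' expression_dataset(m, paste0("g", 1:3), c("cellA", "cellB"))
#' @export
expression_dataset <- function(values, gene_names, cell_ids, labels = NULL,
                               uppercase_genes = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (uppercase_genes) gene_names <- toupper(gene_names)

  if (length(gene_names) != ncol(values)) {
    stop_cv("gene_names length (", length(gene_names),
            ") does not match number of genes (", ncol(values), ")")
  }
  if (length(cell_ids) != nrow(values)) {
    stop_cv("cell_ids length (", length(cell_ids),
            ") does not match number of cells (", nrow(values), ")")
  }
  if (anyDuplicated(gene_names)) {
    dup <- unique(gene_names[duplicated(gene_names)])
    stop_cv("duplicate gene names: ", paste(head(dup, 10L), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop_cv("duplicate cell ids")
  }
  if (any(!is.finite(values))) stop_cv("non-finite expression values")
  if (any(values < 0)) stop_cv("negative expression values")

  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values)) {
      stop_cv("labels length (", length(labels),
              ") does not match number of cells (", nrow(values), ")")
    }
    if (any(is.na(labels)) || any(!nzchar(labels))) {
      stop_cv("labels must be non-empty strings")
    }
    if (any(labels == UNASSIGNED)) {
      stop_cv("label '", UNASSIGNED, "' is reserved for classifier output")
    }
  }

  dimnames(values) <- list(cell_ids, gene_names)
  structure(
    list(values = values, gene_names = gene_names, cell_ids = cell_ids,
         labels = labels),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$values), " cells x ",
      ncol(x$values), " genes\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- sort(table(x$labels), decreasing = TRUE)
    cat("labels: ", length(tab), " cell types (",
        paste(head(names(tab), 5L), collapse = ", "),
        if (length(tab) > 5L) ", ..." else "", ")\n", sep = "")
  } else {
    cat("labels: none\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset cells of an expression dataset
#'
#' @param data an [expression_dataset()].
#' @param idx integer (possibly negative) or logical row index.
#' @return The subsetted [expression_dataset()], labels kept in step.
#' @export
subset_cells <- function(data, idx) {
  expression_dataset(
    data$values[idx, , drop = FALSE],
    data$gene_names,
    data$cell_ids[idx],
    labels = if (!is.null(data$labels)) data$labels[idx] else NULL
  )
}

#' Subset genes of an expression dataset by name
#'
#' @param data an [expression_dataset()].
#' @param genes character vector of gene names; the result preserves the
#'   order of `genes`.
#' @return The subsetted [expression_dataset()].
#' @export
subset_genes <- function(data, genes) {
  missing <- setdiff(genes, data$gene_names)
  if (length(missing)) {
    stop_cv("genes absent from dataset: ",
            paste(head(missing, 10L), collapse = ", "))
  }
  expression_dataset(
    data$values[, genes, drop = FALSE],
    genes,
    data$cell_ids,
    labels = data$labels
  )
}
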