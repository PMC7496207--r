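#' Read a dense expression matrix from CSV/TSV
#'
#' Reads a delimited file with one header row of names and one index column
#' of names. The on-disk orientation is declared by `orientation`; the
#' returned dataset is always cells-by-genes.
#'
#' @param path path to a CSV (or TSV, by `.tsv`/`.txt` extension or
#'   `sep = "\t"`) file.
#' @param orientation `"cells-by-genes"` (rows are cells) or
#'   `"genes-by-cells"` (rows are genes; the matrix is transposed on read).
#' @param label_path optional path to a two-column CSV with header
#'   `cell_id,label`. Labels are matched to cells by id, not by row order;
#'   ids in the label file that are absent from the matrix are an error.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
read_dense <- function(path,
                       orientation = c("cells-by-genes", "genes-by-cells"),
                       label_path = NULL, sep = NULL,
                       uppercase_genes = FALSE) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- read.csv(path, sep = sep, header = TRUE, check.names = FALSE)
  rn <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_cv("non-numeric entries in ", path)
  rownames(m) <- rn
  if (orientation == "genes-by-cells") m <- t(m)
  if (any(m < 0, na.rm = TRUE)) stop_cv("negative expression values in ", path)

  data <- expression_dataset(m, colnames(m), rownames(m),
                             uppercase_genes = uppercase_genes)
  if (!is.null(label_path)) data <- attach_labels(data, label_path)
  data
}

#' Read cell-type labels and attach them to a dataset
#'
#' @param data an [expression_dataset()].
#' @param label_path two-column CSV with header `cell_id,label`.
#' @return The dataset with `labels` filled, in matrix cell order.
#' @export
attach_labels <- function(data, label_path) {
  lab <- read.csv(label_path, header = TRUE, check.names = FALSE,
                  colClasses = "character")
  if (ncol(lab) < 2L) stop_cv("label file must have two columns: cell_id,label")
  ids <- lab[[1L]]
  unknown <- setdiff(ids, data$cell_ids)
  if (length(unknown)) {
    stop_cv("label file has cell ids absent from the matrix: ",
            paste(head(unknown, 10L), collapse = ", "))
  }
  missing <- setdiff(data$cell_ids, ids)
  if (length(missing)) {
    stop_cv("cells without a label: ",
            paste(head(missing, 10L), collapse = ", "))
  }
  labels <- setNames(lab[[2L]], ids)[data$cell_ids]
  expression_dataset(data$values, data$gene_names, data$cell_ids,
                     labels = unname(labels))
}

#' Read a sparse triplet (MatrixMarket) expression matrix
#'
#' Reads a 10x-style export: a MatrixMarket coordinate file (1-based
#' indices) whose rows are genes and columns are cells, plus
#' newline-delimited gene-name and cell-barcode sidecar files. Entries
#' absent from the triplet list are exact zeros.
#'
#' @param matrix_path MatrixMarket `.mtx` file, coordinate format.
#' @param genes_path file with one gene name per line (matrix rows).
#' @param barcodes_path file with one cell barcode per line (matrix columns).
#' @param label_path optional label CSV as in [read_dense()].
#' @inheritParams expression_dataset
#' @return An [expression_dataset()] (cells-by-genes, densified).
#' @export
read_sparse_triplet <- function(matrix_path, genes_path, barcodes_path,
                                label_path = NULL, uppercase_genes = FALSE) {
  check_mtx_indices(matrix_path)
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  # genes.tsv may carry an id column before the symbol; keep the first field
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (nrow(m) != length(genes)) {
    stop_cv("matrix declares ", nrow(m), " rows but genes file has ",
            length(genes), " entries")
  }
  if (ncol(m) != length(barcodes)) {
    stop_cv("matrix declares ", ncol(m), " columns but barcodes file has ",
            length(barcodes), " entries")
  }
  data <- expression_dataset(t(as.matrix(m)), genes, barcodes,
                             uppercase_genes = uppercase_genes)
  if (!is.null(label_path)) data <- attach_labels(data, label_path)
  data
}

# MatrixMarket coordinate indices are 1-based; a 0 index is a common export
# bug and readMM's own failure mode is cryptic, so check up front.
check_mtx_indices <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^%", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stop_cv("empty MatrixMarket file")
  if (length(body) > 1L) {
    for (ln in body[-1L]) {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
      if (length(f) >= 2L && (f[1L] == "0" || f[2L] == "0")) {
        stop_cv("1-based indices expected in MatrixMarket file")
      }
    }
  }
  invisible(TRUE)
}

#' Align a reference and a query dataset to their shared genes
#'
#' Both returned datasets carry exactly the intersection of the two gene
#' sets, in the reference dataset's original gene order. Idempotent.
#'
#' @param reference,query [expression_dataset()] objects.
#' @return A list with elements `reference`, `query`, `shared_genes`.
#' @export
align_common_genes <- function(reference, query) {
  shared <- reference$gene_names[reference$gene_names %in% query$gene_names]
  if (!length(shared)) stop_cv("no shared genes between reference and query")
  list(
    reference = subset_genes(reference, shared),
    query = subset_genes(query, shared),
    shared_genes = shared
  )
}

#' Write a dataset as dense CSV (cells-by-genes) plus optional labels
#'
#' @param data an [expression_dataset()].
#' @param path output CSV path.
#' @param label_path optional path for a `cell_id,label` CSV (written only
#'   when the dataset has labels).
#' @return `path`, invisibly.
#' @export
write_dense <- function(data, path, label_path = NULL) {
  df <- as.data.frame(data$values, check.names = FALSE)
  write.csv(df, path, row.names = TRUE, quote = FALSE)
  if (!is.null(label_path) && !is.null(data$labels)) {
    write.csv(data.frame(cell_id = data$cell_ids, label = data$labels),
              label_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write per-cell predictions as CSV
#'
#' Two columns, `cell_id,predicted_label`; rejected cells carry the literal
#' label `"unassigned"`.
#'
#' @param predictions named character vector (names = cell ids) as returned
#'   by [predict.cellvote()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.csv(data.frame(cell_id = names(predictions),
                       predicted_label = unname(predictions)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
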