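#' Construct an expression dataset
#'
#' Container for a sparse cells-by-genes raw count matrix plus per-cell
#' observation metadata, the unit of input for the co-expression statistic.
#' Counts must be non-negative integers (raw counts, not normalized values):
#' the method is defined on raw expression.
#'
#' @param counts A cells-by-genes matrix of raw counts (`matrix` or any
#'   `Matrix` class; stored as `dgCMatrix`). Row names are cell barcodes,
#'   column names gene identifiers; both are required and must be unique.
#' @param obs Per-cell metadata: a data frame with one row per cell, e.g.
#'   `cell_type`, `disease_state`, `region`. A `cell_id` column is added from
#'   the count matrix row names if absent. Defaults to barcode-only metadata.
#'
#' @return An object of class `expr_dataset`: a list with elements `counts`
#'   (`dgCMatrix`, cells x genes) and `obs` (tibble).
#' @export
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' ds <- expr_dataset(m, obs = data.frame(cell_type = c("A", "A", "B")))
#' ds
expr_dataset <- function(counts, obs = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have cell barcodes as rownames and gene ids as colnames.")
  }
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (anyDuplicated(rownames(counts))) abort("Cell barcodes must be unique.")
  if (anyDuplicated(colnames(counts))) abort("Gene identifiers must be unique.")
  if (length(counts@x) && (min(counts@x) < 0 || !is_wholenumber(counts@x))) {
    abort("`counts` must contain non-negative integer raw counts.")
  }
  if (is.null(obs)) {
    obs <- tibble::tibble(cell_id = rownames(counts))
  } else {
    obs <- tibble::as_tibble(obs)
    if (!"cell_id" %in% names(obs)) {
      obs <- tibble::add_column(obs, cell_id = rownames(counts), .before = 1)
    }
    if (nrow(obs) != nrow(counts)) {
      abort(sprintf("`obs` has %d rows but `counts` has %d cells.",
                    nrow(obs), nrow(counts)))
    }
    if (!identical(obs$cell_id, rownames(counts))) {
      abort("`obs$cell_id` must match the count matrix rownames in order.")
    }
  }
  structure(list(counts = counts, obs = obs), class = "expr_dataset")
}

#' @export
#' @method print expr_dataset
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d cells x %d genes (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  meta <- setdiff(names(x$obs), "cell_id")
  if (length(meta)) cat("obs:", paste(meta, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$counts)

#' Cell and gene identifiers of a dataset
#' @param ds An [expr_dataset()].
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(ds) colnames(ds$counts)

#' @rdname gene_ids
#' @export
cell_ids <- function(ds) rownames(ds$counts)

#' Filter cells by observation metadata
#'
#' Restricts a dataset to the cells matching all of the given criteria (exact
#' string equality, combined conjunctively) — typically one cell type, with
#' optional extra delimiters such as disease state or tissue region. Cell
#' order is preserved and the gene axis is untouched. Cells whose total count
#' is zero after filtering are dropped with a warning, as they carry no
#' correlation information.
#'
#' @param ds An [expr_dataset()].
#' @param ... Named criteria: each name is an `obs` column, each value the
#'   vector of allowed values, e.g. `cell_type = "cardiomyocyte",
#'   disease = c("normal", "control")`.
#' @param criteria Alternatively, a named list of allowed-value vectors.
#' @param drop_empty Drop zero-total cells after filtering (default `TRUE`).
#'
#' @return A filtered `expr_dataset`. Errors if a criterion names an unknown
#'   `obs` column (the message lists the available ones) or if no cell
#'   matches (the statistic is undefined on an empty population).
#' @export
#' @examples
#' m <- matrix(rpois(40, 2), 10, 4,
#'             dimnames = list(paste0("c", 1:10), paste0("g", 1:4)))
#' ds <- expr_dataset(m, obs = data.frame(cell_type = rep(c("A", "B"), 5)))
#' filter_cells(ds, cell_type = "A")
filter_cells <- function(ds, ..., criteria = NULL, drop_empty = TRUE) {
  stopifnot(inherits(ds, "expr_dataset"))
  criteria <- c(list(...), criteria)
  available <- setdiff(names(ds$obs), "cell_id")
  unknown <- setdiff(names(criteria), names(ds$obs))
  if (length(unknown)) {
    abort(sprintf(
      "Unknown obs key%s: %s. Available keys: %s.",
      if (length(unknown) > 1) "s" else "",
      paste(unknown, collapse = ", "),
      paste(available, collapse = ", ")
    ))
  }
  keep <- rep(TRUE, nrow(ds$obs))
  for (key in names(criteria)) {
    keep <- keep & as.character(ds$obs[[key]]) %in% as.character(criteria[[key]])
  }
  if (!any(keep)) {
    abort("No cells match the filter; the co-expression statistic is undefined on an empty population.")
  }
  out <- expr_dataset(ds$counts[keep, , drop = FALSE], ds$obs[keep, , drop = FALSE])
  if (drop_empty) {
    totals <- Matrix::rowSums(out$counts)
    if (any(totals == 0)) {
      warn(sprintf("Dropping %d cell(s) with zero total count after filtering.",
                   sum(totals == 0)))
      if (!any(totals > 0)) abort("All matching cells have zero total count.")
      out <- expr_dataset(out$counts[totals > 0, , drop = FALSE],
                          out$obs[totals > 0, , drop = FALSE])
    }
  }
  out
}
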