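#' Rank genes by raw expression
#'
#' Orders genes by total raw count across cells (or, alternatively, by the
#' number of cells expressing them), the ranking used to define the search
#' space of evaluable genes. Genes with zero total count are never returned,
#' even when `n_top` exceeds the number of expressed genes; ties are broken
#' by gene identifier, ascending, for determinism.
#'
#' @param ds An [expr_dataset()].
#' @param n_top Number of top genes to return, or `NULL` for all expressed
#'   genes (used when a surplus is needed before annotation filtering).
#' @param metric `"total_count"` (default) or `"n_cells_expressed"`.
#'
#' @return A tibble with columns `gene`, `score`, `expr_rank` in rank order.
#' @export
rank_genes <- function(ds, n_top = 3500,
                       metric = c("total_count", "n_cells_expressed")) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (nrow(ds$counts) < 1) abort("Dataset has no cells.")
  metric <- match.arg(metric)
  score <- switch(metric,
    total_count = Matrix::colSums(ds$counts),
    n_cells_expressed = Matrix::colSums(ds$counts > 0)
  )
  expressed <- Matrix::colSums(ds$counts) > 0
  out <- tibble::tibble(gene = gene_ids(ds), score = as.numeric(score))[expressed, ]
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$gene)
  if (!is.null(n_top)) {
    stopifnot(n_top >= 1)
    out <- head(out, n_top)
  }
  dplyr::mutate(out, expr_rank = dplyr::row_number())
}

#' Build the genomically ordered search space
#'
#' Intersects an expression ranking with the gene annotation to form the
#' search space: the `n_top` most highly expressed annotated genes (default
#' 3500, roughly one gene per megabase genome-wide), arranged by chromosome
#' and start position. Ranked genes without an annotation record are dropped
#' and replaced by the next-ranked annotated genes, so the search space keeps
#' its configured size whenever the ranking allows.
#'
#' @param ranked Output of [rank_genes()], called with a surplus
#'   (`n_top = NULL` recommended).
#' @param ann A `gene_annotation`.
#' @param n_top Search-space size (default 3500).
#'
#' @return A `search_space` tibble with columns `gene`, `chrom`, `start`,
#'   `score`, `expr_rank`, genomically sorted; the number of unannotated
#'   ranked genes that were skipped is attached as attribute `n_unannotated`.
#' @export
build_search_space <- function(ranked, ann, n_top = 3500) {
  stopifnot(inherits(ann, "gene_annotation"), n_top >= 1)
  lev <- attr(ann, "chromosome_set")
  merged <- dplyr::inner_join(ranked, ann, by = "gene")
  merged <- head(dplyr::arrange(merged, .data$expr_rank), n_top)
  if (nrow(merged) < 2) {
    abort("Fewer than 2 annotated expressed genes; the statistic is undefined.")
  }
  out <- dplyr::arrange(merged, chrom_rank(.data$chrom, lev), .data$start, .data$gene)
  out <- dplyr::select(out, "gene", "chrom", "start", "score", "expr_rank")
  structure(out,
            n_top = n_top,
            n_unannotated = nrow(ranked) - sum(ranked$gene %in% ann$gene),
            chromosome_set = lev,
            class = c("search_space", class(tibble::tibble())))
}

#' Select standard marker genes
#'
#' Picks the markers at which the co-expression statistic is evaluated:
#' by default every `stride`-th gene of the genomically ordered search space
#' (stride 10 on a 3500-gene space gives 350 markers, ~10 Mb genome
#' coverage), or an explicit user-supplied gene list.
#'
#' @param ss A `search_space` from [build_search_space()].
#' @param stride Marker spacing in search-space order (default 10). The first
#'   gene in genomic order is always a marker, so `ceiling(N / stride)`
#'   markers result; `stride = 1` makes every search-space gene a marker.
#' @param markers Optional explicit marker genes; each must be present in the
#'   search space. Overrides `stride`.
#'
#' @return A `marker_set` tibble (subset of the search-space rows, genomic
#'   order preserved) with the stride recorded as an attribute.
#' @export
select_markers <- function(ss, stride = 10, markers = NULL) {
  stopifnot(inherits(ss, "search_space"))
  if (is.null(markers)) {
    stopifnot(stride >= 1)
    idx <- seq(1, nrow(ss), by = stride)
    out <- ss[idx, ]
    used_stride <- stride
  } else {
    missing_m <- setdiff(markers, ss$gene)
    if (length(missing_m)) {
      abort(sprintf("Marker gene(s) not in the search space: %s.",
                    paste(missing_m, collapse = ", ")))
    }
    out <- ss[ss$gene %in% markers, ]
    used_stride <- "custom"
  }
  structure(tibble::as_tibble(out),
            stride = used_stride,
            chromosome_set = attr(ss, "chromosome_set"),
            class = c("marker_set", class(tibble::tibble())))
}
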