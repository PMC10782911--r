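#' Run the full co-expression pipeline
#'
#' File-in/files-out driver: loads an h5ad dataset (or takes one in memory),
#' filters cells by observation metadata, computes the genome-wide
#' co-expression statistic ([brooklyn()]), and optionally writes a results
#' TSV, a JSON summary and plots into an output directory. Every stage logs
#' its cell/gene counts and exclusions when `verbose = TRUE`, since silent
#' exclusions shift the statistic.
#'
#' @param input Path to an `.h5ad` file, or an [expr_dataset()].
#' @param annotation Path to an annotation TSV / GTF, or a `gene_annotation`.
#' @param filters Named list of obs criteria passed to [filter_cells()],
#'   e.g. `list(cell_type = "cardiomyocyte", disease = "normal")`.
#' @param layer Optional h5ad matrix source override (see [read_h5ad()]).
#' @param chromosome_set Chromosomes to consider (default 1-22, X, Y);
#'   applied when `annotation` is a path.
#' @param n_top,stride,k,method,markers,metric,log1p,positive_only
#'   Passed to [brooklyn()]; defaults are the method's published parameters
#'   (3500-gene search space, stride 10, top 50, Pearson).
#' @param out_dir Output directory; `NULL` (default) writes nothing.
#' @param prefix Filename prefix for outputs (default `"brooklyn"`).
#' @param plot_format `"png"`, `"pdf"` or `"svg"`.
#' @param locality_markers Optional marker gene names for which locality
#'   profiles are plotted (`{prefix}_{marker}_locality.{ext}`).
#' @param bin_width_bp,window_bins Locality profile parameters.
#' @param verbose Stage-by-stage logging (default `TRUE`).
#'
#' @return The `brooklyn` result, invisibly when files are written.
#' @export
run_brooklyn <- function(input, annotation, filters = list(), layer = NULL,
                         chromosome_set = default_chromosomes(),
                         n_top = 3500, stride = 10, k = 50,
                         method = c("pearson", "kendall"), markers = NULL,
                         metric = "total_count", log1p = FALSE,
                         positive_only = FALSE,
                         out_dir = NULL, prefix = "brooklyn",
                         plot_format = "png", locality_markers = NULL,
                         bin_width_bp = 1e6, window_bins = 5,
                         verbose = TRUE) {
  method <- match.arg(method)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  ds <- stage("load", {
    if (inherits(input, "expr_dataset")) input else read_h5ad(input, layer = layer)
  })
  if (verbose) inform(sprintf("[load] %d cells x %d genes", nrow(ds$counts), ncol(ds$counts)))
  ann <- stage("annotation", {
    if (inherits(annotation, "gene_annotation")) annotation
    else read_annotation(annotation, chromosome_set = chromosome_set)
  })
  if (verbose) inform(sprintf("[annotation] %d genes on %d chromosomes",
                              nrow(ann), length(unique(ann$chrom))))
  if (length(filters)) {
    ds <- stage("filter", filter_cells(ds, criteria = filters))
    if (verbose) inform(sprintf("[filter] %d cells retained", nrow(ds$counts)))
  }
  res <- stage("statistic", {
    brooklyn(ds, ann, n_top = n_top, stride = stride, k = k, method = method,
             markers = markers, metric = metric, log1p = log1p,
             positive_only = positive_only, verbose = verbose)
  })
  res$config$filters <- filters
  if (!is.null(out_dir)) {
    stage("write", {
      write_brooklyn(res, out_dir, prefix = prefix)
      plot_brooklyn(res, file.path(out_dir, sprintf("%s_brooklyn.%s", prefix, plot_format)))
      for (mg in locality_markers) {
        prof <- locality_profile(res, marker = mg, ann = ann,
                                 bin_width_bp = bin_width_bp,
                                 window_bins = window_bins)
        plot_locality(prof, file.path(out_dir, sprintf("%s_%s_locality.%s",
                                                       prefix, mg, plot_format)))
      }
    })
    if (verbose) inform(sprintf("[write] outputs in %s (prefix '%s')", out_dir, prefix))
    return(invisible(res))
  }
  res
}

#' Write a result's tables to disk
#'
#' Writes `{prefix}_results.tsv` (one row per marker: marker, chromosome,
#' start_bp, cumulative_bp, percent, expected_percent, k_used) and
#' `{prefix}_summary.json` (global percentage, per-chromosome means, the full
#' configuration snapshot and exclusion tallies). If the result holds stored
#' top-K sets, `{prefix}_top_hits.tsv` is written too.
#'
#' @param result A `brooklyn` result.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Named list of written paths, invisibly.
#' @export
write_brooklyn <- function(result, dir, prefix = "brooklyn") {
  stopifnot(inherits(result, "brooklyn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, "_results.tsv"))
  readr::write_tsv(
    result$markers |>
      dplyr::transmute(
        marker = .data$gene, chromosome = .data$chrom,
        start_bp = .data$start, cumulative_bp = .data$cum_pos,
        percent = .data$percent, expected_percent = .data$expected_pct,
        k_used = .data$k_used
      ),
    tsv
  )
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(
    list(
      global_percent = result$global_percent,
      chance_percent = genome_chance(result$baseline),
      per_chromosome_mean = result$per_chromosome,
      config = result$config,
      exclusions = result$exclusions
    ),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- list(results = tsv, summary = js)
  if (!is.null(result$top_hits)) {
    hits <- file.path(dir, paste0(prefix, "_top_hits.tsv"))
    readr::write_tsv(result$top_hits, hits)
    paths$top_hits <- hits
  }
  invisible(paths)
}

#' Read a results TSV back
#'
#' Reads a `*_results.tsv` written by [write_brooklyn()] into the per-marker
#' tibble layout used by the plotting functions, enabling re-plotting and
#' multi-dataset overlays without recomputation.
#'
#' @param path Path to a results TSV.
#' @return A tibble with columns `gene`, `chrom`, `start`, `cum_pos`,
#'   `percent`, `expected_pct`, `k_used`.
#' @export
read_brooklyn_results <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("marker", "chromosome", "start_bp", "cumulative_bp", "percent",
            "expected_percent", "k_used")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("'%s' is not a results TSV (missing: %s).",
                  path, paste(missing_cols, collapse = ", ")))
  }
  dplyr::transmute(df,
    gene = .data$marker, chrom = as.character(.data$chromosome),
    start = .data$start_bp, cum_pos = .data$cumulative_bp,
    percent = .data$percent, expected_pct = .data$expected_percent,
    k_used = .data$k_used
  )
}
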