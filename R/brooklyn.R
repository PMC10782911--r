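#' Same-chromosome percentage of a top-K set
#'
#' The per-marker statistic: the percentage of a marker's top-K co-expressed
#' genes that lie on the marker's own chromosome. A marker on chromosome 3
#' with 10 of its top 50 partners on chromosome 3 scores 20%.
#'
#' @param topk A `top_k` from [top_k()].
#' @param ann Optional `gene_annotation` used to (re)derive chromosome
#'   membership; by default the annotation carried in the top-K rows is used.
#'
#' @return A percentage in `[0, 100]`, an integer multiple of `100 / k_used`.
#' @export
same_chromosome_percent <- function(topk, ann = NULL) {
  stopifnot(inherits(topk, "top_k"))
  if (!nrow(topk)) abort("Empty top-K set.")
  chrom <- topk$chrom
  if (!is.null(ann)) {
    stopifnot(inherits(ann, "gene_annotation"))
    hit <- match(topk$gene, ann$gene)
    if (anyNA(hit)) {
      abort(sprintf("Top-K gene(s) missing from the annotation: %s.",
                    paste(topk$gene[is.na(hit)], collapse = ", ")))
    }
    chrom <- ann$chrom[hit]
  }
  100 * sum(chrom == attr(topk, "marker_chrom")) / nrow(topk)
}

# Cumulative genome coordinate offsets. Each chromosome's span is proxied by
# its maximum annotated gene start (no assembly lengths needed; only the
# relative plot layout depends on this).
chrom_offsets <- function(ann) {
  lev <- attr(ann, "chromosome_set")
  spans <- ann |>
    dplyr::summarise(span = max(.data$start), .by = "chrom") |>
    dplyr::arrange(chrom_rank(.data$chrom, lev))
  spans$offset <- cumsum(c(0, head(spans$span, -1)))
  spans
}

#' Assemble per-marker percentages into a genome-wide result
#'
#' Attaches expected-by-chance baselines and cumulative genome coordinates to
#' per-marker same-chromosome percentages and summarizes them genome-wide.
#' Usually called via [brooklyn()]; exposed for composing the steps manually.
#'
#' @param markers A `marker_set` from [select_markers()].
#' @param percents Numeric vector of same-chromosome percentages, one per
#'   marker row.
#' @param baseline A `chromosome_baseline` from [chromosome_baseline()].
#' @param ann The `gene_annotation` (for chromosome spans).
#' @param k_used Integer vector (or scalar) of top-K sizes actually used.
#' @param config Optional named list recording the run configuration.
#'
#' @return A `brooklyn` object; see [brooklyn()].
#' @export
assemble_brooklyn <- function(markers, percents, baseline, ann,
                              k_used = NA_integer_, config = list()) {
  stopifnot(inherits(markers, "marker_set"), inherits(baseline, "chromosome_baseline"))
  if (nrow(markers) != length(percents)) {
    abort("Need exactly one percentage per marker.")
  }
  offs <- chrom_offsets(ann)
  rows <- markers |>
    dplyr::select("gene", "chrom", "start") |>
    dplyr::mutate(
      cum_pos = .data$start + offs$offset[match(.data$chrom, offs$chrom)],
      percent = as.numeric(percents),
      expected_pct = baseline$expected_pct[match(.data$chrom, baseline$chrom)],
      k_used = as.integer(k_used)
    ) |>
    dplyr::arrange(.data$cum_pos)
  per_chrom <- rows |>
    dplyr::summarise(mean_percent = mean(.data$percent), n_markers = dplyr::n(),
                     .by = "chrom")
  structure(
    list(
      markers = rows,
      per_chromosome = per_chrom,
      baseline = baseline,
      global_percent = mean(rows$percent),
      chrom_spans = offs,
      config = config
    ),
    class = "brooklyn"
  )
}

#' Genome-wide chromosomal co-expression statistic
#'
#' Runs the full co-expression analysis on a filtered cell population:
#' ranks genes by raw expression, builds the genomically ordered search space
#' of the `n_top` most expressed annotated genes, selects every `stride`-th
#' gene as a standard marker, correlates each marker against the search
#' space, takes each marker's top-`k` partners by Bonferroni-corrected
#' p-value, and scores the percentage located on the marker's own chromosome.
#' With the defaults (3500 genes, stride 10, k = 50, Pearson) this evaluates
#' 350 markers at ~10 Mb spacing, each probing a ~25 Mb window either side.
#'
#' @param ds An [expr_dataset()], already filtered to one cell type (the
#'   statistic is invalid across mixed clusters).
#' @param ann A `gene_annotation`.
#' @param n_top Search-space size (default 3500).
#' @param stride Marker spacing (default 10); see [select_markers()].
#' @param k Top-K size per marker (default 50).
#' @param method `"pearson"` (default) or `"kendall"`.
#' @param markers Optional explicit marker gene list.
#' @param metric Expression ranking metric, see [rank_genes()].
#' @param log1p,positive_only See [correlate_marker()] and [top_k()].
#' @param keep_hits Keep the per-marker top-K gene table in the result
#'   (default `TRUE`; needed for [locality_profile()] on the result).
#' @param verbose Log per-stage counts and exclusions via [message()].
#'
#' @return A `brooklyn` object: list with `markers` (per-marker tibble of
#'   `gene`, `chrom`, `start`, `cum_pos`, `percent`, `expected_pct`,
#'   `k_used`), `per_chromosome` means, `baseline`, `global_percent`,
#'   `config`, `exclusions`, and (optionally) `top_hits`. Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @export
brooklyn <- function(ds, ann, n_top = 3500, stride = 10, k = 50,
                     method = c("pearson", "kendall"), markers = NULL,
                     metric = "total_count", log1p = FALSE,
                     positive_only = FALSE, keep_hits = TRUE, verbose = FALSE) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ann, "gene_annotation"))
  method <- match.arg(method)
  say <- function(...) if (verbose) inform(sprintf(...))
  n <- nrow(ds$counts)
  if (n < 3) abort("At least 3 cells are required.")
  say("Input: %d cells x %d genes", n, ncol(ds$counts))

  baseline <- chromosome_baseline(ann)
  ranked <- rank_genes(ds, n_top = NULL, metric = metric)
  ss <- build_search_space(ranked, ann, n_top = n_top)
  say("Search space: %d annotated expressed genes (%d unannotated ranked genes skipped)",
      nrow(ss), attr(ss, "n_unannotated"))
  mk <- select_markers(ss, stride = stride, markers = markers)
  say("Markers: %d (stride %s)", nrow(mk), as.character(attr(mk, "stride")))

  counts <- ds$counts[, ss$gene, drop = FALSE]
  if (log1p) counts <- log1p(counts)
  marker_idx <- match(mk$gene, ss$gene)
  lev <- attr(ss, "chromosome_set")

  blk <- switch(method,
    pearson = pearson_r_block(counts, marker_idx, seq_len(nrow(ss))),
    kendall = kendall_r_block(counts, marker_idx, seq_len(nrow(ss)))
  )
  ok_marker <- blk$var_m > 0 & is.finite(blk$var_m)
  if (!all(ok_marker)) {
    warn(sprintf("Dropping %d marker(s) with zero variance across cells.",
                 sum(!ok_marker)))
  }
  if (!any(ok_marker)) abort("All markers have zero variance; statistic undefined.")
  n_zero_var_genes <- sum(!(blk$var_g > 0 & is.finite(blk$var_g)))
  m <- nrow(ss) - 1

  keep_rows <- which(ok_marker)
  percents <- numeric(length(keep_rows))
  k_used <- integer(length(keep_rows))
  hits <- if (keep_hits) vector("list", length(keep_rows))
  short_profiles <- 0L
  for (ii in seq_along(keep_rows)) {
    i <- keep_rows[ii]
    r <- blk$r[i, ]
    r[marker_idx[i]] <- NA # self-entry excluded
    usable <- which(is.finite(r) & blk$var_g > 0)
    if (positive_only) usable <- usable[r[usable] > 0]
    p <- cor_p_value(r[usable], n, method)
    p_adj <- pmin(1, m * p)
    ord <- usable[rank_profile_order(p_adj, r[usable], ss$chrom[usable],
                                     ss$start[usable], lev)]
    sel <- head(ord, k)
    if (length(sel) < k) short_profiles <- short_profiles + 1L
    k_used[ii] <- length(sel)
    percents[ii] <- 100 * sum(ss$chrom[sel] == mk$chrom[i]) / length(sel)
    if (keep_hits) {
      hits[[ii]] <- tibble::tibble(
        marker = mk$gene[i],
        gene = ss$gene[sel], chrom = ss$chrom[sel], start = ss$start[sel],
        r = r[sel], p_adj = pmin(1, m * cor_p_value(r[sel], n, method)),
        rank = seq_along(sel)
      )
    }
  }
  if (short_profiles > 0) {
    warn(sprintf("%d marker profile(s) had fewer than k = %d usable genes.",
                 short_profiles, k))
  }

  mk_kept <- structure(mk[keep_rows, ],
                       stride = attr(mk, "stride"),
                       chromosome_set = lev,
                       class = class(mk))
  config <- list(
    n_top = n_top, stride = stride, k = k, method = method,
    metric = metric, log1p = log1p, positive_only = positive_only,
    n_cells = n, n_genes_input = ncol(ds$counts),
    search_space_size = nrow(ss),
    n_markers = length(keep_rows),
    custom_markers = !is.null(markers)
  )
  res <- assemble_brooklyn(mk_kept, percents, baseline, ann,
                           k_used = k_used, config = config)
  res$exclusions <- list(
    unannotated_ranked_genes = attr(ss, "n_unannotated"),
    zero_variance_genes = n_zero_var_genes,
    zero_variance_markers = sum(!ok_marker),
    short_profiles = short_profiles
  )
  res$search_space <- ss
  if (keep_hits) res$top_hits <- dplyr::bind_rows(hits)
  say("Global same-chromosome co-expression: %.2f%%", res$global_percent)
  res
}

#' @export
#' @method print brooklyn
print.brooklyn <- function(x, ...) {
  cat(sprintf("<brooklyn> %d markers, method = %s, k = %d\n",
              nrow(x$markers), x$config$method %||% "?", x$config$k %||% NA))
  cat(sprintf("  global same-chromosome co-expression: %.2f%%\n", x$global_percent))
  cat(sprintf("  genome-wide chance level: %.2f%%\n", genome_chance(x$baseline)))
  invisible(x)
}

#' Tidy a Brooklyn result
#'
#' @param x A `brooklyn` object.
#' @param ... Unused.
#' @return `tidy()`: the per-marker tibble (one row per standard marker).
#'   `glance()`: a one-row summary with `global_percent`, `chance_percent`,
#'   marker/cell counts and the configuration.
#' @export
tidy.brooklyn <- function(x, ...) x$markers

#' @rdname tidy.brooklyn
#' @export
glance.brooklyn <- function(x, ...) {
  tibble::tibble(
    global_percent = x$global_percent,
    chance_percent = genome_chance(x$baseline),
    n_markers = nrow(x$markers),
    n_cells = x$config$n_cells %||% NA_integer_,
    n_top = x$config$n_top %||% NA_integer_,
    stride = as.character(x$config$stride %||% NA),
    k = x$config$k %||% NA_integer_,
    method = x$config$method %||% NA_character_
  )
}

#' Analytic chance level of a search space
#'
#' Expected same-chromosome percentage for markers when top-K partners are
#' drawn at random from the search space: for a marker on chromosome c,
#' `100 * (N_c - 1) / (N - 1)` (the marker is excluded from its own candidate
#' set), averaged over the markers. Used to calibrate null simulations.
#'
#' @param ss A `search_space`.
#' @param markers Optional `marker_set`; defaults to all search-space genes.
#' @return Expected percentage.
#' @export
search_space_chance <- function(ss, markers = NULL) {
  stopifnot(inherits(ss, "search_space"))
  counts <- table(ss$chrom)
  chroms <- if (is.null(markers)) ss$chrom else markers$chrom
  mean(100 * (as.numeric(counts[chroms]) - 1) / (nrow(ss) - 1))
}

#' Locality profile of a marker's same-chromosome partners
#'
#' Bins a marker's same-chromosome top-K genes by start position along the
#' marker's chromosome and smooths the counts with a centered moving average
#' (the running-average view of where co-expression concentrates). A peak at
#' the marker's own position indicates neighboring co-expression, as expected
#' from broad transcriptional bursts, rather than chromosome-wide diffusion.
#'
#' @param x A `top_k` object, or a `brooklyn` result (then `marker` selects
#'   which marker's stored top-K set to profile).
#' @param ann A `gene_annotation` (defines the chromosome span).
#' @param bin_width_bp Bin width in bp (default 1 Mb).
#' @param window_bins Moving-average window in bins (default 5); edge bins
#'   average over the available neighbors.
#' @param ... Passed between methods.
#'
#' @return A `locality_profile` tibble with columns `bin`, `bin_start`,
#'   `bin_mid`, `count`, `smoothed`, plus marker metadata attributes. A
#'   top-K set with no same-chromosome genes yields all-zero bins.
#' @export
locality_profile <- function(x, ...) UseMethod("locality_profile")

#' @rdname locality_profile
#' @export
locality_profile.top_k <- function(x, ann, bin_width_bp = 1e6,
                                   window_bins = 5, ...) {
  stopifnot(inherits(ann, "gene_annotation"), bin_width_bp >= 1, window_bins >= 1)
  marker_chrom <- attr(x, "marker_chrom")
  span <- max(ann$start[ann$chrom == marker_chrom])
  breaks <- seq(1, span + bin_width_bp, by = bin_width_bp)
  same <- x$start[x$chrom == marker_chrom]
  counts <- tabulate(findInterval(same, breaks), nbins = length(breaks) - 1)
  prof <- tibble::tibble(
    bin = seq_along(counts),
    bin_start = breaks[-length(breaks)],
    bin_mid = breaks[-length(breaks)] + bin_width_bp / 2,
    count = counts,
    smoothed = moving_average(counts, window_bins)
  )
  structure(prof,
            marker = attr(x, "marker"),
            marker_chrom = marker_chrom,
            marker_start = attr(x, "marker_start"),
            bin_width_bp = bin_width_bp,
            window_bins = window_bins,
            class = c("locality_profile", class(tibble::tibble())))
}

#' @rdname locality_profile
#' @param marker Marker gene identifier (for the `brooklyn` method).
#' @export
locality_profile.brooklyn <- function(x, marker, ann, bin_width_bp = 1e6,
                                      window_bins = 5, ...) {
  if (is.null(x$top_hits)) {
    abort("Result was built with keep_hits = FALSE; no stored top-K sets.")
  }
  hits <- x$top_hits[x$top_hits$marker == marker, ]
  if (!nrow(hits)) abort(sprintf("No stored top-K set for marker '%s'.", marker))
  row <- x$markers[x$markers$gene == marker, ]
  tk <- structure(dplyr::select(hits, "gene", "chrom", "start", "r", "p_adj"),
                  marker = marker,
                  marker_chrom = row$chrom[1],
                  marker_start = row$start[1],
                  k = nrow(hits), k_used = nrow(hits),
                  class = c("top_k", class(tibble::tibble())))
  locality_profile(tk, ann = ann, bin_width_bp = bin_width_bp,
                   window_bins = window_bins)
}
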