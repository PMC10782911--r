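# ---- internal correlation engine -------------------------------------------
# Both the single-marker user functions and the whole-pipeline batch path go
# through these, so there is exactly one implementation of each statistic.

# Pearson r between selected marker columns and all gene columns of a sparse
# (or dense) cells x genes matrix, without densifying the gene block.
# Returns list(r = markers x genes matrix, var_m, var_g).
pearson_r_block <- function(counts, marker_idx, gene_idx) {
  n <- nrow(counts)
  Xm <- counts[, marker_idx, drop = FALSE]
  Xg <- counts[, gene_idx, drop = FALSE]
  sm <- Matrix::colSums(Xm)
  sg <- Matrix::colSums(Xg)
  cp <- as.matrix(Matrix::crossprod(Xm, Xg))
  cv <- (cp - outer(sm, sg) / n) / (n - 1)
  vm <- as.numeric(Matrix::colSums(Xm^2) - sm^2 / n) / (n - 1)
  vg <- as.numeric(Matrix::colSums(Xg^2) - sg^2 / n) / (n - 1)
  r <- cv / outer(sqrt(pmax(vm, 0)), sqrt(pmax(vg, 0)))
  r[r > 1] <- 1
  r[r < -1] <- -1
  list(r = r, var_m = vm, var_g = vg)
}

# Kendall tau-b between marker columns and gene columns (dense C++ kernel).
kendall_r_block <- function(counts, marker_idx, gene_idx) {
  Yg <- as.matrix(counts[, gene_idx, drop = FALSE])
  Xm <- as.matrix(counts[, marker_idx, drop = FALSE])
  r <- t(vapply(seq_len(ncol(Xm)),
                function(j) .kendall_tau(Xm[, j], Yg),
                numeric(ncol(Yg))))
  vm <- apply(Xm, 2, stats::var)
  vg <- apply(Yg, 2, stats::var)
  list(r = r, var_m = vm, var_g = vg)
}

# Two-sided p-values. Pearson: t transform, t = r sqrt((n-2)/(1-r^2)) on
# n - 2 df. Kendall: normal approximation to the tau null,
# z = 3 tau sqrt(n(n-1)) / sqrt(2(2n+5)).
cor_p_value <- function(r, n, method) {
  if (method == "pearson") {
    t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
    p[abs(r) >= 1] <- 0
  } else {
    z <- 3 * r * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    p <- 2 * pnorm(-abs(z))
  }
  p
}

# ---- user-facing operations -------------------------------------------------

#' Correlation profile of one marker against the search space
#'
#' Correlates a standard marker gene's raw counts with every other gene of
#' the search space across cells, attaching two-sided p-values and
#' Bonferroni-adjusted p-values (`p_adj = min(1, m * p)` with `m` the number
#' of tests designed per marker, i.e. the search-space size minus the marker
#' itself). The marker's self-entry is excluded; genes with zero variance
#' across the cells are dropped (their correlation is undefined) and counted
#' in the `n_dropped` attribute, without reducing `m`.
#'
#' @param ds An [expr_dataset()] (already filtered to one cell population).
#' @param marker A gene identifier present in the search space.
#' @param ss A `search_space` from [build_search_space()].
#' @param method `"pearson"` (default) or `"kendall"` (tau-b, tie-corrected,
#'   p from the normal approximation).
#' @param log1p Correlate `log1p`-transformed counts instead of raw counts
#'   (off by default; the statistic is defined on raw counts).
#'
#' @return A `correlation_profile` tibble with columns `gene`, `chrom`,
#'   `start`, `r`, `p`, `p_adj`, plus attributes `marker`, `marker_chrom`,
#'   `n_cells`, `method`, `m`, `n_dropped`.
#' @export
correlate_marker <- function(ds, marker, ss,
                             method = c("pearson", "kendall"), log1p = FALSE) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ss, "search_space"))
  method <- match.arg(method)
  if (!marker %in% ss$gene) abort(sprintf("Marker '%s' is not in the search space.", marker))
  n <- nrow(ds$counts)
  if (n < 3) abort("At least 3 cells are required for a correlation profile.")
  counts <- ds$counts[, ss$gene, drop = FALSE]
  if (log1p) counts <- log1p(counts)
  others <- which(ss$gene != marker)
  blk <- switch(method,
    pearson = pearson_r_block(counts, which(ss$gene == marker), others),
    kendall = kendall_r_block(counts, which(ss$gene == marker), others)
  )
  if (blk$var_m[1] <= 0 || !is.finite(blk$var_m[1])) {
    abort(sprintf("Marker '%s' has zero variance across cells; profile undefined.", marker))
  }
  r <- as.numeric(blk$r[1, ])
  m <- nrow(ss) - 1
  keep <- is.finite(r) & blk$var_g > 0
  prof <- tibble::tibble(
    gene = ss$gene[others][keep],
    chrom = ss$chrom[others][keep],
    start = ss$start[others][keep],
    r = r[keep],
    p = cor_p_value(r[keep], n, method),
    p_adj = pmin(1, m * cor_p_value(r[keep], n, method))
  )
  structure(prof,
            marker = marker,
            marker_chrom = ss$chrom[ss$gene == marker],
            marker_start = ss$start[ss$gene == marker],
            n_cells = n,
            method = method,
            m = m,
            n_dropped = sum(!keep),
            chromosome_set = attr(ss, "chromosome_set"),
            class = c("correlation_profile", class(tibble::tibble())))
}

# Ranking rule shared by top_k() and the batch pipeline: ascending adjusted
# p, ties by descending |r|, remaining ties by genomic order.
rank_profile_order <- function(p_adj, r, chrom, start, chrom_levels) {
  order(p_adj, -abs(r), chrom_rank(chrom, chrom_levels), start)
}

#' Top-K co-expressed genes of a profile
#'
#' Subselects the `k` most significantly correlated genes of a marker's
#' profile (default 50, giving a ~25 Mb effective search window on each side
#' of the marker). Ranking is by ascending Bonferroni-adjusted p-value, ties
#' broken by descending `|r|`, and any remaining ties by genomic order, so
#' the selection is deterministic. No significance threshold is applied:
#' exactly `k` genes are taken regardless of p-value magnitude.
#'
#' @param profile A `correlation_profile` from [correlate_marker()].
#' @param k Number of genes to keep (default 50). Shorter profiles return
#'   all available genes with a warning.
#' @param positive_only Restrict to positively correlated genes (`r > 0`)
#'   before ranking (off by default: two-sided p-values rank by `|r|`).
#'
#' @return A `top_k` tibble of the selected rows in rank order, with
#'   attributes carried over from the profile plus `k` and `k_used`.
#' @export
top_k <- function(profile, k = 50, positive_only = FALSE) {
  stopifnot(inherits(profile, "correlation_profile"), k >= 1)
  if (!nrow(profile)) abort("Empty correlation profile.")
  prof <- if (positive_only) profile[profile$r > 0, ] else profile
  ord <- rank_profile_order(prof$p_adj, prof$r, prof$chrom, prof$start,
                            attr(profile, "chromosome_set"))
  out <- head(prof[ord, ], k)
  if (nrow(out) < k) {
    warn(sprintf("Profile of marker '%s' has only %d usable genes (k = %d requested).",
                 attr(profile, "marker"), nrow(out), k))
  }
  structure(tibble::as_tibble(out),
            marker = attr(profile, "marker"),
            marker_chrom = attr(profile, "marker_chrom"),
            marker_start = attr(profile, "marker_start"),
            method = attr(profile, "method"),
            chromosome_set = attr(profile, "chromosome_set"),
            k = k,
            k_used = nrow(out),
            class = c("top_k", class(tibble::tibble())))
}
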