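#' Default chromosome set
#'
#' Human primary chromosomes: autosomes 1-22 plus X and Y. Mitochondrial and
#' scaffold/patch contigs are excluded by default.
#'
#' @return Character vector of chromosome labels.
#' @export
default_chromosomes <- function() c(as.character(1:22), "X", "Y")

# Strip a leading "chr" prefix so "chr3" and "3" refer to the same chromosome.
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

# Conventional genome-plot ordering: numeric chromosomes ascending, then X, Y,
# then anything else alphabetically.
chrom_order <- function(labels) {
  labels <- unique(as.character(labels))
  num <- suppressWarnings(as.numeric(labels))
  is_num <- !is.na(num)
  sex <- labels %in% c("X", "Y")
  c(
    labels[is_num][order(num[is_num])],
    intersect(c("X", "Y"), labels),
    sort(labels[!is_num & !sex])
  )
}

# Integer rank of each chromosome label under chrom_order(); used as the
# primary genomic sort key.
chrom_rank <- function(x, levels = NULL) {
  levels <- levels %||% chrom_order(x)
  match(as.character(x), levels)
}

is_wholenumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}

# Centered moving average with edges averaged over the available neighbours
# (window truncated, never padded).
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  if (window == 1 || length(x) < 2) return(as.numeric(x))
  as.numeric(zoo::rollapply(zoo::zoo(x), width = window, FUN = mean,
                            align = "center", partial = TRUE))
}
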