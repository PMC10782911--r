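#' Build a gene annotation table
#'
#' Normalizes a gene -> (chromosome, start) mapping into the annotation
#' container used throughout the package. Chromosome labels are stripped of a
#' leading `"chr"` prefix, genes outside `chromosome_set` are excluded, and a
#' gene appearing more than once keeps its smallest start position (the
#' minimum over transcripts/records; strand is ignored since only a total
#' order along the chromosome is needed).
#'
#' @param df A data frame with columns `gene`, `chromosome` (or `chrom`) and
#'   `start` (1-based bp).
#' @param chromosome_set Chromosome labels to keep; defaults to
#'   [default_chromosomes()] (1-22, X, Y; MT and scaffolds excluded).
#'
#' @return A `gene_annotation` tibble with columns `gene`, `chrom`, `start`,
#'   sorted genomically, carrying the chromosome set as an attribute.
#' @export
as_annotation <- function(df, chromosome_set = default_chromosomes()) {
  df <- as.data.frame(df)
  if ("chromosome" %in% names(df) && !"chrom" %in% names(df)) {
    names(df)[names(df) == "chromosome"] <- "chrom"
  }
  missing_cols <- setdiff(c("gene", "chrom", "start"), names(df))
  if (length(missing_cols)) {
    abort(sprintf("Annotation needs columns gene, chromosome, start; missing: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  chromosome_set <- normalize_chrom(chromosome_set)
  ann <- tibble::tibble(
    gene = as.character(df$gene),
    chrom = normalize_chrom(df$chrom),
    start = as.numeric(df$start)
  )
  if (any(!is.finite(ann$start)) || any(ann$start < 1) ||
      !is_wholenumber(ann$start[is.finite(ann$start)])) {
    bad <- which(!is.finite(ann$start) | ann$start < 1 |
                   abs(ann$start - round(ann$start)) >= 1e-8)[1]
    abort(sprintf("Start positions must be positive integers (first bad record: line %d, gene '%s').",
                  bad, ann$gene[bad]))
  }
  ann <- ann |>
    dplyr::filter(.data$chrom %in% chromosome_set) |>
    dplyr::summarise(start = min(.data$start), .by = c("gene", "chrom"))
  if (anyDuplicated(ann$gene)) {
    # same gene on two chromosomes: keep the record with the smallest start
    ann <- ann |>
      dplyr::arrange(.data$gene, .data$start) |>
      dplyr::distinct(.data$gene, .keep_all = TRUE)
  }
  if (!nrow(ann)) abort("No annotated genes on the requested chromosomes.")
  lev <- chrom_order(chromosome_set)
  ann <- dplyr::arrange(ann, chrom_rank(.data$chrom, lev), .data$start, .data$gene)
  structure(ann,
            chromosome_set = lev,
            class = c("gene_annotation", class(tibble::tibble())))
}

#' Load a gene annotation from TSV or GTF/GFF3
#'
#' Reads gene chromosomal locations (e.g. a Biomart export) from either a
#' tab-separated table with header columns `gene`, `chromosome`, `start`, or
#' a GTF/GFF3 file, from which one record per gene is extracted as the
#' minimum start over all of its feature lines. See [as_annotation()] for the
#' normalization rules.
#'
#' @param path Path to a `.tsv`/`.txt` table or `.gtf`/`.gff`/`.gff3` file.
#' @param chromosome_set Chromosome labels to keep (default 1-22, X, Y).
#'
#' @return A `gene_annotation` tibble.
#' @export
read_annotation <- function(path, chromosome_set = default_chromosomes()) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.(gtf|gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::readGFF(path)
    gene <- if (!is.null(g$gene_name)) as.character(g$gene_name) else NULL
    if (is.null(gene) || all(is.na(gene) | gene == "")) gene <- as.character(g$gene_id)
    if (!is.null(g$gene_id)) {
      fill <- is.na(gene) | gene == ""
      gene[fill] <- as.character(g$gene_id)[fill]
    }
    if (is.null(gene) || all(is.na(gene))) {
      abort("No gene_name/gene_id attributes found in the GTF/GFF file.")
    }
    df <- data.frame(gene = gene, chrom = as.character(g$seqid), start = g$start)
    df <- df[!is.na(df$gene) & df$gene != "", , drop = FALSE]
  } else {
    df <- tryCatch(
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
      error = function(e) abort(sprintf("Cannot parse '%s' as TSV: %s", path, conditionMessage(e)))
    )
    probs <- readr::problems(df)
    if (nrow(probs)) {
      abort(sprintf("Malformed TSV '%s' at line %d: %s.",
                    path, probs$row[1], probs$expected[1]))
    }
  }
  as_annotation(df, chromosome_set = chromosome_set)
}

#' Expected-by-chance chromosome baselines
#'
#' The null expectation for the same-chromosome co-expression percentage of a
#' marker on chromosome c is simply c's share of all annotated genes,
#' `100 * N_c / N_total`. For the human genome (~20,452 Biomart genes) this
#' ranges from under 2% to near 10% and averages 4.35% over 23 chromosomes.
#'
#' @param ann A `gene_annotation` from [as_annotation()] / [read_annotation()].
#'
#' @return A `chromosome_baseline` tibble with columns `chrom`, `n_genes`,
#'   `expected_pct`, one row per chromosome present, in genomic order. The
#'   unweighted mean of `expected_pct` is attached as attribute
#'   `genome_wide` (see [genome_chance()]).
#' @export
#' @examples
#' ann <- as_annotation(data.frame(
#'   gene = paste0("g", 1:8),
#'   chromosome = rep(c("1", "2"), each = 4),
#'   start = rep(c(1e6, 2e6, 3e6, 4e6), 2)
#' ))
#' chromosome_baseline(ann)
chromosome_baseline <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  lev <- attr(ann, "chromosome_set")
  bl <- ann |>
    dplyr::count(.data$chrom, name = "n_genes") |>
    dplyr::mutate(expected_pct = 100 * .data$n_genes / sum(.data$n_genes)) |>
    dplyr::arrange(chrom_rank(.data$chrom, lev))
  structure(bl,
            genome_wide = mean(bl$expected_pct),
            class = c("chromosome_baseline", class(tibble::tibble())))
}

#' @rdname chromosome_baseline
#' @param baseline A `chromosome_baseline`.
#' @return `genome_chance()`: the genome-wide chance level in percent, the
#'   unweighted mean of the per-chromosome expected percentages (100/23 for a
#'   23-chromosome annotation).
#' @export
genome_chance <- function(baseline) {
  stopifnot(inherits(baseline, "chromosome_baseline"))
  attr(baseline, "genome_wide")
}
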