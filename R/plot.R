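# Shared scaffolding for genome-wide scatter ("Brooklyn") plots: percent vs
# cumulative coordinate, chromosomes in alternating colors, a red horizontal
# segment per chromosome at its expected-by-chance level, x labelled at each
# chromosome's coordinate midpoint.
brooklyn_gg <- function(rows, ylim = c(0, 100), point_colors = c("grey25", "steelblue3"),
                        baseline_color = "red", dataset = NULL) {
  stopifnot(nrow(rows) > 0)
  lev <- chrom_order(rows$chrom)
  rows$chrom_i <- chrom_rank(rows$chrom, lev)
  seg <- rows |>
    dplyr::summarise(
      x0 = min(.data$cum_pos), x1 = max(.data$cum_pos),
      y = .data$expected_pct[1], chrom_i = .data$chrom_i[1],
      .by = "chrom"
    )
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$cum_pos, y = .data$percent))
  if (is.null(dataset)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(color = factor(.data$chrom_i %% 2)), size = 1.1,
      show.legend = FALSE
    ) +
      ggplot2::scale_color_manual(values = point_colors)
  } else {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(color = .data[[dataset]]), size = 1.1
    ) +
      ggplot2::labs(color = NULL)
  }
  p +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y, yend = .data$y),
      color = baseline_color, linewidth = 0.7, inherit.aes = FALSE
    ) +
    ggplot2::scale_x_continuous(
      breaks = (seg$x0 + seg$x1) / 2, labels = seg$chrom,
      expand = ggplot2::expansion(mult = 0.01)
    ) +
    ggplot2::coord_cartesian(ylim = ylim) +
    ggplot2::labs(
      x = "Chromosome",
      y = "Same-chromosome co-expression (%)"
    ) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}

#' Brooklyn plot of a result
#'
#' Genome-wide scatter of per-marker same-chromosome percentages against
#' cumulative genomic position, points alternately colored by chromosome,
#' with a red horizontal segment per chromosome at its expected-by-chance
#' level. The y axis is fixed to 0-100% by default so datasets are visually
#' comparable.
#'
#' @param object A `brooklyn` result.
#' @param ylim Y-axis limits (default `c(0, 100)`).
#' @param point_colors Two colors alternated across chromosomes.
#' @param baseline_color Color of the expected-by-chance segments.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.brooklyn <- function(object, ylim = c(0, 100),
                              point_colors = c("grey25", "steelblue3"),
                              baseline_color = "red", ...) {
  brooklyn_gg(object$markers, ylim = ylim, point_colors = point_colors,
              baseline_color = baseline_color)
}

#' @export
#' @method plot brooklyn
plot.brooklyn <- function(x, ...) print(autoplot(x, ...))

# Validate that an explicit format matches the output path's extension.
plot_format <- function(path, format = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "pdf", "svg")) {
    abort(sprintf("Unsupported plot format '%s' (use png, pdf or svg).", ext))
  }
  if (!is.null(format) && !identical(tolower(format), ext)) {
    abort(sprintf("Requested format '%s' does not match extension of '%s'.",
                  format, basename(path)))
  }
  ext
}

save_gg <- function(p, path, format = NULL, width = 10, height = 4) {
  ext <- plot_format(path, format)
  dev <- switch(ext, png = grDevices::png, pdf = grDevices::pdf,
                svg = grDevices::svg)
  ggplot2::ggsave(path, plot = p, device = dev, width = width, height = height,
                  dpi = 150)
  invisible(path)
}

#' Render a Brooklyn plot (or overlay of several) to a file
#'
#' With a single result, renders its Brooklyn plot. With a named list of
#' results, overlays them in one panel, colored per dataset with a legend —
#' the combined view used to compare cell types or studies.
#'
#' @param result A `brooklyn` result, or a named list of them.
#' @param path Output file (`.png`, `.pdf` or `.svg`); `NULL` returns the
#'   ggplot unrendered.
#' @param format Optional explicit format; must match the extension.
#' @param width,height Size in inches.
#' @param ... Passed to [autoplot.brooklyn()].
#' @return The output path (or the ggplot when `path` is `NULL`), invisibly.
#' @export
plot_brooklyn <- function(result, path = NULL, format = NULL,
                          width = 10, height = 4, ...) {
  if (inherits(result, "brooklyn")) {
    p <- autoplot(result, ...)
  } else {
    stopifnot(is.list(result), length(result) >= 1)
    labels <- names(result) %||% paste0("dataset_", seq_along(result))
    rows <- dplyr::bind_rows(
      lapply(seq_along(result), function(i) {
        df <- if (inherits(result[[i]], "brooklyn")) result[[i]]$markers else result[[i]]
        dplyr::mutate(df, dataset = labels[i])
      })
    )
    p <- brooklyn_gg(rows, dataset = "dataset", ...)
  }
  if (is.null(path)) return(invisible(p))
  save_gg(p, path, format, width, height)
}

#' Running-average locality plot
#'
#' Smoothed count of a marker's same-chromosome top-K genes along its
#' chromosome, with a vertical line at the marker's own position. Peaks
#' adjacent to the marker indicate neighboring co-expression rather than
#' chromosome-wide diffusion.
#'
#' @param object,profile A `locality_profile` from [locality_profile()].
#' @param line_color Curve color (default green, the conventional color for
#'   these running averages).
#' @param ... Unused.
#' @return `autoplot`: a ggplot. `plot_locality`: the path (or ggplot).
#' @export
autoplot.locality_profile <- function(object, line_color = "forestgreen", ...) {
  marker <- attr(object, "marker")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid / 1e6)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count),
                      fill = "grey80", width = attr(object, "bin_width_bp") / 1e6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                       color = line_color, linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = attr(object, "marker_start") / 1e6,
                        linetype = "dashed", color = "grey30") +
    ggplot2::labs(
      x = sprintf("Chromosome %s position (Mb)", attr(object, "marker_chrom")),
      y = "Top-K same-chromosome genes per bin",
      title = marker
    ) +
    ggplot2::theme_classic()
}

#' @rdname autoplot.locality_profile
#' @param path,format,width,height As in [plot_brooklyn()].
#' @export
plot_locality <- function(profile, path = NULL, format = NULL,
                          width = 7, height = 3.5, ...) {
  p <- autoplot(profile, ...)
  if (is.null(path)) return(invisible(p))
  save_gg(p, path, format, width, height)
}
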