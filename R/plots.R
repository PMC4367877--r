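#' Plots of landscape results
#'
#' Each result type has an `autoplot()` method or a `plot_*()` helper
#' returning a ggplot, mirroring the tool's graphical panels: occurrence
#' curves and histograms as bar/step charts, category and GO
#' distributions as pies (slices under the display threshold pooled as
#' "other" in the plot only).
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_step geom_point
#'   geom_line labs coord_polar theme_minimal theme element_blank
#' @export
ggplot2::autoplot

#' Plot a binned curve (occurrence, size or gap-distance histogram)
#'
#' @param object A `binned_curve` from [chromosome_distribution()],
#'   [size_histogram()] or [region_position_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binned_curve <- function(object, ...) {
  axis <- attr(object, "axis") %||% "position"
  xlab <- c(position = "chromosome position (bp)",
            size = "copy size (bp)",
            gap = "distance from gene boundary (bp)")[[axis]]
  ggplot(object, aes(x = (.data$bin_start + .data$bin_end) / 2,
                     y = .data$count)) +
    geom_col(width = (object$bin_end[1] - object$bin_start[1]) * 0.95,
             fill = "steelblue") +
    labs(x = xlab, y = "occurrences") +
    theme_minimal()
}

#' @export
plot.binned_curve <- function(x, ...) print(autoplot(x, ...))

#' Plot the genome frequency table
#'
#' Bars show each chromosome's share of the genome length; points and
#' lines show each family's share of its genome-wide copies.
#'
#' @param freq Output of [genome_frequency()].
#' @return A ggplot.
#' @export
plot_genome_frequency <- function(freq) {
  chrom_part <- distinct(freq, .data$chrom, .data$chrom_length_pct)
  ggplot() +
    geom_col(data = chrom_part,
             aes(x = .data$chrom, y = .data$chrom_length_pct),
             fill = "grey70") +
    geom_line(data = freq,
              aes(x = .data$chrom, y = .data$copy_pct,
                  group = .data$family, colour = .data$family)) +
    geom_point(data = freq,
               aes(x = .data$chrom, y = .data$copy_pct,
                   colour = .data$family)) +
    labs(x = NULL, y = "percent of genome / of family copies",
         colour = "family") +
    theme_minimal()
}

.pie <- function(df, fill_lab) {
  ggplot(df, aes(x = "", y = .data$proportion, fill = .data$slice)) +
    geom_col(width = 1, colour = "white") +
    coord_polar(theta = "y") +
    labs(x = NULL, y = NULL, fill = fill_lab) +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
}

#' Pie chart of TE region categories
#'
#' @param cats Output of [category_distribution()] (or the
#'   `distance_categories` table of a run).
#' @return A ggplot.
#' @export
plot_category_distribution <- function(cats) {
  df <- mutate(cats, slice = .data$category)
  .pie(df, "region")
}

#' Pie chart of a GO slim distribution
#'
#' Slices with proportion below the display threshold (default 1%) are
#' pooled into an "other" slice; the underlying table stays itemised.
#'
#' @param object A `go_distribution`.
#' @param threshold Display threshold as a fraction; defaults to the
#'   value recorded on the object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.go_distribution <- function(object, threshold = NULL, ...) {
  thr <- threshold %||% attr(object, "display_threshold") %||% 0.01
  df <- as_tibble(object) |>
    mutate(slice = if_else(.data$proportion > thr, .data$label, "other")) |>
    group_by(.data$slice) |>
    summarise(proportion = sum(.data$proportion), .groups = "drop") |>
    arrange(.data$slice == "other", desc(.data$proportion))
  df$slice <- factor(df$slice, levels = df$slice)
  .pie(df, "GO family")
}

#' @export
plot.go_distribution <- function(x, ...) print(autoplot(x, ...))

#' Location track of TE copies and gene features on one chromosome
#'
#' @param tes TE-copy tibble.
#' @param genome A `genome_annotation`.
#' @param chrom Chromosome id.
#' @param window Optional `c(start, end)` coordinate window.
#' @param kinds Feature kinds to draw under the TE track.
#' @return A ggplot with one horizontal lane per family/feature kind.
#' @export
plot_te_tracks <- function(tes, genome, chrom, window = NULL,
                           kinds = c("gene", "pseudogene")) {
  tt <- filter(tes, .data$chrom == !!chrom) |>
    mutate(lane = .data$family)
  ff <- extract_features(genome, kinds, chrom = chrom) |>
    mutate(lane = .data$kind)
  df <- bind_rows(select(tt, "start", "end", "lane"),
                  select(ff, "start", "end", "lane"))
  if (!is.null(window)) {
    df <- filter(df, .data$end >= window[1], .data$start <= window[2])
  }
  ggplot(df) +
    ggplot2::geom_segment(aes(x = .data$start, xend = .data$end,
                              y = .data$lane, yend = .data$lane,
                              colour = .data$lane),
                          linewidth = 4, show.legend = FALSE) +
    labs(x = sprintf("%s position (bp)", chrom), y = NULL) +
    theme_minimal()
}
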