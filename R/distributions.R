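#' Genome-scale TE distributions
#'
#' Panel computations: per-chromosome occurrence curves, the genome
#' frequency table, copy-size histograms and genome coverage proportions.
#'
#' @name te_distributions
NULL

new_binned_curve <- function(bin_start, bin_end, count, axis = "position") {
  structure(
    tibble(bin = seq_along(count), bin_start = bin_start,
           bin_end = bin_end, count = as.integer(count)),
    class = c("binned_curve", "tbl_df", "tbl", "data.frame"),
    axis = axis)
}

#' Occurrence curve of TE copies along a chromosome
#'
#' Splits the chromosome `[1, length]` into `n_bins` equal-width bins
#' (the last bin absorbs the integer-division remainder) and counts each
#' copy once, in the bin containing its midpoint — a copy straddling a bin
#' edge is never double-counted.
#'
#' @param tes TE-copy tibble, all on the one chromosome.
#' @param chrom_length Chromosome length in bp; may also be a one-row
#'   slice of a `genome_annotation` `chromosomes` tibble.
#' @param n_bins Number of bins (>= 1).
#' @param chrom Chromosome id (for error messages / consistency checks);
#'   defaults to the single chromosome present in `tes`.
#' @return A `binned_curve` tibble: `bin`, `bin_start`, `bin_end`, `count`.
#' @export
chromosome_distribution <- function(tes, chrom_length, n_bins = 100,
                                    chrom = NULL) {
  if (is.data.frame(chrom_length)) {
    chrom <- chrom %||% chrom_length$chrom[1]
    chrom_length <- chrom_length$length[1]
  }
  stopifnot(n_bins >= 1, chrom_length >= 1)
  n_bins <- as.integer(n_bins)
  if (nrow(tes) > 0) {
    chrom <- chrom %||% tes$chrom[1]
    off <- tes$chrom != chrom
    if (any(off)) {
      abort(sprintf("chromosome_distribution: %d cop(ies) on other chromosome(s): %s",
                    sum(off), paste(unique(tes$chrom[off]), collapse = ", ")))
    }
  }
  w <- chrom_length %/% n_bins
  if (w < 1) abort("chromosome_distribution: more bins than bases")
  bin_start <- 1L + (seq_len(n_bins) - 1L) * w
  bin_end <- c(bin_start[-1] - 1L, as.integer(chrom_length))
  counts <- integer(n_bins)
  if (nrow(tes) > 0) {
    mid <- (tes$start + tes$end) %/% 2
    idx <- pmin(n_bins, (mid - 1L) %/% w + 1L)
    tab <- table(factor(idx, levels = seq_len(n_bins)))
    counts <- as.integer(tab)
  }
  new_binned_curve(bin_start, bin_end, counts, axis = "position")
}

#' Genome frequency table of TE families
#'
#' For each chromosome and selected family: the copy count and the family
#' frequency, i.e. the chromosome's share of the family's genome-wide
#' copies as a percent (so each family's percentages sum to 100 over
#' chromosomes). Chromosome length shares of the genome are reported
#' alongside for comparison.
#'
#' @param tes TE-copy tibble (the selected families).
#' @param genome A `genome_annotation`.
#' @return A tibble with one row per (chromosome, family): `chrom`,
#'   `chrom_length`, `chrom_length_pct`, `family`, `n_copies`,
#'   `copy_pct`, `family_total`. Row order follows the genome's
#'   chromosome order, then family name.
#' @export
genome_frequency <- function(tes, genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  chroms <- genome$chromosomes
  unknown <- setdiff(unique(tes$chrom), chroms$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("TE copies on chromosome(s) absent from the annotation: %s",
                  paste(unknown, collapse = ", ")))
  }
  genome_len <- sum(chroms$length)
  fams <- sort(unique(tes$family))
  grid <- tidyr::expand_grid(chrom = chroms$chrom, family = fams)
  counts <- count(tes, .data$chrom, .data$family, name = "n_copies")
  out <- grid |>
    left_join(counts, by = c("chrom", "family")) |>
    mutate(n_copies = coalesce(.data$n_copies, 0L)) |>
    left_join(chroms, by = "chrom") |>
    mutate(chrom_length_pct = 100 * .data$length / genome_len) |>
    group_by(.data$family) |>
    mutate(family_total = sum(.data$n_copies),
           copy_pct = if_else(.data$family_total > 0,
                              100 * .data$n_copies / .data$family_total, NA_real_)) |>
    ungroup() |>
    rename(chrom_length = "length") |>
    select("chrom", "chrom_length", "chrom_length_pct", "family",
           "n_copies", "copy_pct", "family_total")
  out[order(match(out$chrom, chroms$chrom), out$family), ]
}

#' Histogram of TE copy sizes
#'
#' Bins span `[size_min, size_max]` (defaults: the observed minimum and
#' maximum copy length) in `n_intervals` equal-width intervals,
#' left-closed with a right-closed last interval; copies outside the
#' range are excluded.
#'
#' @param tes TE-copy tibble.
#' @param n_intervals Number of intervals (default 40).
#' @param size_min,size_max Optional range bounds in bp.
#' @return A `binned_curve` tibble over the size axis.
#' @export
size_histogram <- function(tes, n_intervals = 40, size_min = NULL,
                           size_max = NULL) {
  stopifnot(n_intervals >= 1)
  n_intervals <- as.integer(n_intervals)
  sizes <- if (nrow(tes) > 0) region_length(tes) else integer()
  size_min <- size_min %||% if (length(sizes) > 0) min(sizes) else 0
  size_max <- size_max %||% if (length(sizes) > 0) max(sizes) else 1
  if (size_min > size_max) abort("size_histogram: size_min > size_max")
  w <- (size_max - size_min) / n_intervals
  edges <- size_min + w * (0:n_intervals)
  counts <- integer(n_intervals)
  inside <- sizes[sizes >= size_min & sizes <= size_max]
  if (length(inside) > 0) {
    idx <- if (w == 0) rep(1L, length(inside)) else {
      pmin(n_intervals, as.integer(floor((inside - size_min) / w)) + 1L)
    }
    counts <- as.integer(table(factor(idx, levels = seq_len(n_intervals))))
  }
  new_binned_curve(edges[-length(edges)], edges[-1], counts, axis = "size")
}

#' Genome coverage proportions of genetic item classes
#'
#' For each requested item class, the number of distinct bases it covers
#' (union over possibly overlapping members, summed across chromosomes)
#' and that coverage as a percent of total genome length. Classes overlap
#' freely, so percentages need not sum to 100.
#'
#' Annotation classes are feature kinds (`gene`, `pseudogene`, `miscRNA`,
#' `exon`, `five_prime_UTR`, `three_prime_UTR`, or `UTRs` for both UTR
#' kinds pooled); `all_tes` covers every TE copy passed in `all_tes`; any
#' other class name is taken as a TE family name and covers that family's
#' copies in `tes`.
#'
#' @param genome A `genome_annotation`.
#' @param tes TE-copy tibble of the selected families.
#' @param classes Character vector of class names.
#' @param all_tes Optional TE-copy tibble of every copy in the repeat file
#'   (after filters, before family selection); required when `"all_tes"`
#'   is among `classes`.
#' @return A tibble: `class`, `covered_bp`, `pct`.
#' @export
size_proportions <- function(genome, tes, classes, all_tes = NULL) {
  stopifnot(inherits(genome, "genome_annotation"), length(classes) > 0)
  genome_len <- sum(genome$chromosomes$length)
  class_regions <- function(cl) {
    if (cl == "UTRs") {
      extract_features(genome, c("five_prime_UTR", "three_prime_UTR"))
    } else if (cl %in% te_feature_kinds) {
      extract_features(genome, cl)
    } else if (cl == "all_tes") {
      if (is.null(all_tes)) abort("size_proportions: class 'all_tes' requested but 'all_tes' not supplied")
      all_tes
    } else {
      filter(tes, .data$family == cl)
    }
  }
  rows <- map(classes, function(cl) {
    reg <- class_regions(cl)
    bp <- if (nrow(reg) == 0) 0 else {
      sum(map_dbl(split(reg, reg$chrom), union_length))
    }
    tibble(class = cl, covered_bp = bp, pct = 100 * bp / genome_len)
  })
  list_rbind(rows)
}
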