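#' Genomic regions and elementary interval arithmetic
#'
#' All coordinates in this package are 1-based and inclusive on both ends
#' (the GenBank/RepeatMasker convention), so a region `[start, end]` covers
#' `end - start + 1` bases. Regions are rows of a data frame with at least
#' the columns `chrom`, `start`, `end` (and usually `strand`).
#'
#' @name regions
NULL

.check_regions <- function(x, what = "region") {
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s table lacks column(s): %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(x$start < 1 | x$end < x$start)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s coordinates at row(s) %s: need 1 <= start <= end",
                  what, paste(head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Length of regions in base pairs
#'
#' @param x A data frame with `start` and `end` columns (1-based inclusive).
#' @return Integer vector of lengths, `end - start + 1`.
#' @export
region_length <- function(x) {
  as.integer(x$end - x$start + 1L)
}

#' Gap between two genomic regions
#'
#' Counts the bases strictly between two intervals on the same chromosome.
#' Overlapping or immediately adjacent regions have gap 0. Both arguments
#' are recycled row-wise in the usual vectorised way.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` (1-based
#'   inclusive). Rows are paired; one of the two may have a single row.
#' @return Non-negative integer vector of gap sizes in bp.
#' @examples
#' a <- tibble::tibble(chrom = "Chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "Chr1", start = 401, end = 600)
#' region_gap(a, b) # 200 bases lie strictly between
#' @export
region_gap <- function(a, b) {
  .check_regions(a, "first region")
  .check_regions(b, "second region")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), ]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), ]
  if (any(a$chrom != b$chrom)) {
    abort("region_gap: regions on different chromosomes are incomparable")
  }
  gap <- pmax(a$start, b$start) - pmin(a$end, b$end) - 1L
  as.integer(pmax(gap, 0L))
}

#' Number of distinct bases covered by a set of regions
#'
#' Overlapping and duplicated regions count each base once. All regions
#' must lie on a single chromosome.
#'
#' @param regions Data frame with `chrom`, `start`, `end`; may have 0 rows.
#' @return Covered length in bp (a single number).
#' @examples
#' r <- tibble::tibble(chrom = "c", start = c(1, 51), end = c(100, 150))
#' union_length(r) # 150
#' @export
union_length <- function(regions) {
  if (nrow(regions) == 0) return(0L)
  .check_regions(regions)
  if (length(unique(regions$chrom)) > 1) {
    abort("union_length: regions span more than one chromosome")
  }
  ir <- IRanges::IRanges(start = as.integer(regions$start),
                         end = as.integer(regions$end))
  sum(IRanges::width(IRanges::reduce(ir)))
}

#' Size and similarity filter settings
#'
#' Mirrors the two display sliders of the original interface: TE copies are
#' kept when their length lies in `[size_min, size_max]` and their percent
#' similarity to the family consensus lies in `[sim_min, sim_max]`, all
#' bounds inclusive. Similarity defaults to the 50--100% window; size
#' bounds default to the observed minimum and maximum of the copies being
#' filtered (`NULL` means "observed bound").
#'
#' @param size_min,size_max Copy length bounds in bp, or `NULL` for the
#'   observed bound.
#' @param sim_min,sim_max Percent similarity bounds in `[0, 100]`.
#' @return An object of class `te_filters`.
#' @export
te_filters <- function(size_min = NULL, size_max = NULL,
                       sim_min = 50, sim_max = 100) {
  if (sim_min > sim_max) abort("te_filters: sim_min > sim_max")
  if (sim_min < 0 || sim_max > 100) abort("te_filters: similarity bounds must lie in [0, 100]")
  if (!is.null(size_min) && !is.null(size_max) && size_min > size_max) {
    abort("te_filters: size_min > size_max")
  }
  structure(
    list(size_min = size_min, size_max = size_max,
         sim_min = sim_min, sim_max = sim_max),
    class = "te_filters"
  )
}

#' @export
print.te_filters <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "observed" else format(v)
  cat("<te_filters> size [", fmt(x$size_min), ", ", fmt(x$size_max),
      "] bp; similarity [", x$sim_min, ", ", x$sim_max, "] %\n", sep = "")
  invisible(x)
}

#' Filter TE copies by size and similarity
#'
#' @param tes A TE copy tibble (see [read_repeats()]).
#' @param filters A [te_filters()] object.
#' @return The filtered tibble, original row order preserved.
#' @export
apply_te_filters <- function(tes, filters = te_filters()) {
  stopifnot(inherits(filters, "te_filters"))
  if (nrow(tes) == 0) return(tes)
  len <- region_length(tes)
  smin <- filters$size_min %||% min(len)
  smax <- filters$size_max %||% max(len)
  if (smin > smax) abort("apply_te_filters: size_min > size_max")
  keep <- len >= smin & len <= smax &
    tes$similarity >= filters$sim_min & tes$similarity <= filters$sim_max
  tes[keep, , drop = FALSE]
}

#' Proximity and display configuration
#'
#' Parameters governing TE--gene proximity classification and the derived
#' summaries: `distance` is the proximal threshold in bp (a copy within
#' this many bases of a gene boundary is "Proximal Promoter" or
#' "Proximal 3' End", boundary inclusive); `region_bins` the number of
#' intervals of the within-region distance histograms; `family_limit` the
#' maximum number of selectable TE families per run; `display_threshold`
#' the fraction below which pie-chart slices are pooled as "other" (tables
#' stay itemised); `min_organisms` the minimum number of organisms a
#' TE--gene couple must occur in to be retained.
#'
#' @param distance Proximal distance threshold in bp (default 3000).
#' @param region_bins Number of histogram intervals (default 20).
#' @param family_limit Maximum selected families (default 20).
#' @param display_threshold Plot display threshold as a fraction (default 0.01).
#' @param min_organisms Minimum organisms per couple (default 1).
#' @param neighbor_kinds Feature kinds considered as "genes" in neighbor
#'   searches (default gene and pseudogene).
#' @return An object of class `proximity_config`.
#' @export
proximity_config <- function(distance = 3000, region_bins = 20,
                             family_limit = 20, display_threshold = 0.01,
                             min_organisms = 1,
                             neighbor_kinds = c("gene", "pseudogene")) {
  stopifnot(distance >= 0, region_bins >= 1, family_limit >= 1,
            display_threshold >= 0, display_threshold <= 1,
            min_organisms >= 1)
  bad <- setdiff(neighbor_kinds, te_feature_kinds)
  if (length(bad) > 0) {
    abort(sprintf("unknown neighbor kind(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(distance = distance, region_bins = as.integer(region_bins),
         family_limit = as.integer(family_limit),
         display_threshold = display_threshold,
         min_organisms = as.integer(min_organisms),
         neighbor_kinds = neighbor_kinds),
    class = "proximity_config"
  )
}

#' @export
print.proximity_config <- function(x, ...) {
  cat("<proximity_config> D =", x$distance, "bp;", x$region_bins,
      "region bins; <=", x$family_limit, "families; display >",
      sprintf("%.1f%%;", 100 * x$display_threshold),
      "couples in >=", x$min_organisms, "organism(s)\n")
  invisible(x)
}

# region category levels, in display order
te_categories <- c("ProximalPromoter", "Proximal3End", "ExonIntronUTR", "Intergenic")
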