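#' Repeat-hit input
#'
#' Parsers for repeat hit files in six dialects, all normalised to one
#' canonical TE-copy tibble with columns `chrom`, `start`, `end`, `strand`,
#' `family`, `superfamily`, `similarity` (percent identity to the family
#' consensus, in `[0, 100]`), `source` (dialect tag), `score` and
#' `class_hint` (the RepeatMasker class/family column, used as a
#' superfamily fallback). Hits are kept exactly as reported — overlapping
#' or nested copies are never merged, so fragmented copies stay visible.
#'
#' Per-dialect similarity: RepeatMasker reports divergence, converted with
#' [similarity_from_divergence()]; Censor reports a fraction, scaled by 100
#' when `<= 1`; BLAST dialects report percent identity directly; the native
#' TSV carries an explicit similarity column.
#'
#' Column maps for the tabular dialects:
#' * `repeatmasker` (.out): score, div, del, ins, query, qstart, qend,
#'   (left), strand `+`/`C`, family, class/family, ...
#' * `censor` (.map): query, qstart, qend, family, rstart, rend,
#'   direction `d`/`c`, similarity, then optional score columns
#' * `ncbiblast` (outfmt 6): qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore
#' * `abblast`: query, subject, score, pident, qstart, qend, strand
#' * `repet`: chrom, start, end, strand, family, identity
#' * `visualte`: chrom, start, end, strand, family, superfamily, similarity
#'
#' @name repeat_io
NULL

.te_cols <- function(chrom, start, end, strand, family, similarity, source,
                     score = NA_real_, superfamily = NA_character_,
                     class_hint = NA_character_) {
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
         strand = strand, family = family, superfamily = superfamily,
         similarity = similarity, source = source, score = score,
         class_hint = class_hint)
}

.num_or_fail <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    abort(sprintf("%s line %d: unparseable %s '%s'", path, lineno, what,
                  paste(x[is.na(v)], collapse = ", ")))
  }
  v
}

#' Convert RepeatMasker divergence to percent similarity
#'
#' RepeatMasker reports percent divergence from the consensus; the
#' analyses here use percent similarity, `100 - divergence`.
#'
#' @param div Percent divergence in `[0, 100]`.
#' @return Percent similarity.
#' @examples
#' similarity_from_divergence(10.5) # 89.5
#' @export
similarity_from_divergence <- function(div) {
  if (any(is.na(div)) || any(div < 0 | div > 100)) {
    abort("divergence must lie in [0, 100]")
  }
  100 - div
}

.parse_repeatmasker <- function(lines, path) {
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    # three-line header: starts with "SW" / "score" / blank separator
    if (grepl("^(SW|score)\\b", ln, ignore.case = TRUE)) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 11) {
      abort(sprintf("%s line %d: expected >= 11 RepeatMasker columns, got %d",
                    path, i, length(f)))
    }
    div <- .num_or_fail(f[2], path, i, "divergence")
    if (div < 0 || div > 100) {
      abort(sprintf("%s line %d: divergence %s outside [0, 100]", path, i, f[2]))
    }
    start <- .num_or_fail(f[6], path, i, "start")
    end <- .num_or_fail(f[7], path, i, "end")
    if (!f[9] %in% c("+", "C", "c", "-")) {
      abort(sprintf("%s line %d: unrecognizable strand '%s'", path, i, f[9]))
    }
    rows[[length(rows) + 1]] <- .te_cols(
      chrom = f[5], start = start, end = end,
      strand = if (f[9] == "+") "+" else "-",
      family = f[10], similarity = similarity_from_divergence(div),
      source = "repeatmasker", score = .num_or_fail(f[1], path, i, "score"),
      class_hint = f[11])
  }
  .bind_tes(rows)
}

.parse_censor <- function(lines, path) {
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^#", ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 8) {
      abort(sprintf("%s line %d: expected >= 8 Censor columns, got %d",
                    path, i, length(f)))
    }
    if (!f[7] %in% c("d", "c", "+", "-")) {
      abort(sprintf("%s line %d: unrecognizable direction '%s'", path, i, f[7]))
    }
    sim <- .num_or_fail(f[8], path, i, "similarity")
    if (sim <= 1) sim <- sim * 100
    if (sim < 0 || sim > 100) {
      abort(sprintf("%s line %d: similarity %s outside [0, 100] after conversion",
                    path, i, f[8]))
    }
    rows[[length(rows) + 1]] <- .te_cols(
      chrom = f[1],
      start = .num_or_fail(f[2], path, i, "start"),
      end = .num_or_fail(f[3], path, i, "end"),
      strand = if (f[7] %in% c("d", "+")) "+" else "-",
      family = f[4], similarity = sim, source = "censor")
  }
  .bind_tes(rows)
}

.parse_ncbiblast <- function(lines, path) {
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^#", ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 12) {
      abort(sprintf("%s line %d: expected 12 BLAST tabular columns, got %d",
                    path, i, length(f)))
    }
    pid <- .num_or_fail(f[3], path, i, "percent identity")
    if (pid < 0 || pid > 100) {
      abort(sprintf("%s line %d: pident %s outside [0, 100]", path, i, f[3]))
    }
    qs <- .num_or_fail(f[7], path, i, "qstart")
    qe <- .num_or_fail(f[8], path, i, "qend")
    ss <- .num_or_fail(f[9], path, i, "sstart")
    se <- .num_or_fail(f[10], path, i, "send")
    strand <- "+"
    if (qs > qe) { tmp <- qs; qs <- qe; qe <- tmp; strand <- "-" }
    else if (ss > se) strand <- "-"
    rows[[length(rows) + 1]] <- .te_cols(
      chrom = f[1], start = qs, end = qe, strand = strand, family = f[2],
      similarity = pid, source = "ncbiblast",
      score = .num_or_fail(f[12], path, i, "bitscore"))
  }
  .bind_tes(rows)
}

.parse_abblast <- function(lines, path) {
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^#", ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 7) {
      abort(sprintf("%s line %d: expected 7 AB-BLAST columns (query, subject, score, pident, qstart, qend, strand), got %d",
                    path, i, length(f)))
    }
    pid <- .num_or_fail(f[4], path, i, "percent identity")
    if (pid < 0 || pid > 100) {
      abort(sprintf("%s line %d: pident outside [0, 100]", path, i))
    }
    if (!f[7] %in% c("+", "-")) {
      abort(sprintf("%s line %d: unrecognizable strand '%s'", path, i, f[7]))
    }
    rows[[length(rows) + 1]] <- .te_cols(
      chrom = f[1], start = .num_or_fail(f[5], path, i, "start"),
      end = .num_or_fail(f[6], path, i, "end"), strand = f[7],
      family = f[2], similarity = pid, source = "abblast",
      score = .num_or_fail(f[3], path, i, "score"))
  }
  .bind_tes(rows)
}

.parse_repet <- function(lines, path) {
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^#", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) {
      abort(sprintf("%s line %d: expected 6 Repet columns (chrom, start, end, strand, family, identity), got %d",
                    path, i, length(f)))
    }
    pid <- .num_or_fail(f[6], path, i, "identity")
    if (pid <= 1) pid <- pid * 100
    if (pid < 0 || pid > 100) {
      abort(sprintf("%s line %d: identity outside [0, 100] after conversion",
                    path, i))
    }
    rows[[length(rows) + 1]] <- .te_cols(
      chrom = f[1], start = .num_or_fail(f[2], path, i, "start"),
      end = .num_or_fail(f[3], path, i, "end"),
      strand = .norm_strand(f[4]), family = f[5], similarity = pid,
      source = "repet")
  }
  .bind_tes(rows)
}

.parse_visualte_repeats <- function(lines, path) {
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^\\s*#", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 7) {
      abort(sprintf("%s line %d: expected 7 tab-separated columns (chrom, start, end, strand, family, superfamily, similarity), got %d",
                    path, i, length(f)))
    }
    sim <- .num_or_fail(f[7], path, i, "similarity")
    if (sim < 0 || sim > 100) {
      abort(sprintf("%s line %d: similarity outside [0, 100]", path, i))
    }
    rows[[length(rows) + 1]] <- .te_cols(
      chrom = f[1], start = .num_or_fail(f[2], path, i, "start"),
      end = .num_or_fail(f[3], path, i, "end"),
      strand = .norm_strand(f[4]), family = f[5],
      superfamily = if (f[6] %in% c("", ".", "NA")) NA_character_ else f[6],
      similarity = sim, source = "visualte")
  }
  .bind_tes(rows)
}

.bind_tes <- function(rows) {
  if (length(rows) == 0) return(.te_cols(character(), integer(), integer(),
                                         character(), character(), numeric(),
                                         character()))
  out <- list_rbind(rows)
  .check_regions(out, "TE copy")
  out
}

.sniff_repeat_dialect <- function(lines) {
  data_lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(data_lines) == 0) return("visualte")
  first <- trimws(data_lines[1])
  if (grepl("^(SW|score)\\b", first, ignore.case = TRUE)) return("repeatmasker")
  ws <- strsplit(first, "\\s+")[[1]]
  # a RepeatMasker data line: numeric score, numeric divergence, strand +/C at 9
  if (length(ws) >= 11 && !is.na(suppressWarnings(as.numeric(ws[1]))) &&
      !is.na(suppressWarnings(as.numeric(ws[2]))) && ws[9] %in% c("+", "C")) {
    return("repeatmasker")
  }
  if (length(ws) >= 8 && ws[7] %in% c("d", "c")) return("censor")
  if (length(ws) >= 12 && !is.na(suppressWarnings(as.numeric(ws[3])))) {
    return("ncbiblast")
  }
  "visualte"
}

#' Read a repeat-hit file into canonical TE copies
#'
#' @param path Path to the hit file.
#' @param dialect One of `"repeatmasker"`, `"censor"`, `"abblast"`,
#'   `"ncbiblast"`, `"repet"`, `"visualte"` or `"auto"`. Auto-detection
#'   recognises the RepeatMasker header or data-line shape, the Censor
#'   direction column, and the 12-column BLAST tabular layout; anything
#'   else is read as the native TSV. `abblast` and `repet` must be named
#'   explicitly.
#' @return A TE-copy tibble (one row per hit line; see [repeat_io]).
#' @export
read_repeats <- function(path,
                         dialect = c("auto", "repeatmasker", "censor",
                                     "abblast", "ncbiblast", "repet",
                                     "visualte")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("repeat file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") dialect <- .sniff_repeat_dialect(lines)
  switch(dialect,
    repeatmasker = .parse_repeatmasker(lines, path),
    censor = .parse_censor(lines, path),
    abblast = .parse_abblast(lines, path),
    ncbiblast = .parse_ncbiblast(lines, path),
    repet = .parse_repet(lines, path),
    visualte = .parse_visualte_repeats(lines, path)
  )
}

# ---- superfamilies ---------------------------------------------------------

#' Load a TE family-to-superfamily table
#'
#' A two-column tab-separated file (family, superfamily), `#` comments
#' allowed. Lookups are case-insensitive; families absent from the table
#' resolve to `"Unknown"`.
#'
#' @param path Path to the TSV file.
#' @param provenance Free-text provenance note stored on the object.
#' @return An object of class `superfamily_table`.
#' @export
load_superfamily_table <- function(path, provenance = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  fam <- character(); sup <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^\\s*#", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) {
      abort(sprintf("%s line %d: expected two tab-separated columns", path, i))
    }
    fam <- c(fam, f[1]); sup <- c(sup, f[2])
  }
  key <- tolower(fam)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- tapply(sup, key, function(s) length(unique(s)) > 1)
    if (any(conflict)) {
      abort(sprintf("conflicting superfamily assignments for: %s",
                    paste(names(conflict)[conflict], collapse = ", ")))
    }
  }
  tbl <- distinct(tibble(family = fam, superfamily = sup, key = key))
  structure(list(table = tbl, provenance = provenance),
            class = "superfamily_table")
}

#' @export
print.superfamily_table <- function(x, ...) {
  cat("<superfamily_table>", nrow(x$table), "families;",
      length(unique(x$table$superfamily)), "superfamilies;",
      "provenance:", x$provenance, "\n")
  invisible(x)
}

#' Look up superfamilies for family names
#'
#' @param table A `superfamily_table`.
#' @param family Character vector of family names (case-insensitive).
#' @return Character vector; unmapped families are `NA` (see
#'   [assign_superfamilies()] for the `"Unknown"` defaulting).
#' @export
superfamily_lookup <- function(table, family) {
  stopifnot(inherits(table, "superfamily_table"))
  idx <- match(tolower(family), table$table$key)
  table$table$superfamily[idx]
}

#' Attach superfamily labels to TE copies
#'
#' Resolution order per copy: the superfamily table (case-insensitive on
#' family name); then the RepeatMasker class/family column when present
#' (the token after the `/`, e.g. `DNA/Helitron` gives `Helitron`);
#' finally `"Unknown"`.
#'
#' @param tes A TE-copy tibble.
#' @param table A `superfamily_table`.
#' @return The tibble with the `superfamily` column filled.
#' @export
assign_superfamilies <- function(tes, table) {
  if (nrow(tes) == 0) return(tes)
  sf <- superfamily_lookup(table, tes$family)
  hint <- tes$class_hint %||% rep(NA_character_, nrow(tes))
  hint_sf <- ifelse(is.na(hint) | hint %in% c("", "."), NA_character_,
                    sub("^[^/]*/", "", hint))
  sf <- coalesce(sf, hint_sf, "Unknown")
  mutate(tes, superfamily = sf)
}
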