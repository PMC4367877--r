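#' Genome annotation input
#'
#' Parsers for genome annotation in GenBank flat-file, EMBL flat-file, or
#' the package's native tabular dialect. The result is a `genome_annotation`
#' object: a list with `organism` (character), `chromosomes` (tibble with
#' `chrom`, `length`) and `features` (tibble with `chrom`, `start`, `end`,
#' `strand`, `kind`, `feature_id`, `gene_name`, `gene_numeric_id`).
#'
#' Feature kinds form a closed set: gene, exon, pseudogene, miscRNA,
#' five_prime_UTR, three_prime_UTR. A gene's span is its outermost
#' annotated coordinates; `join(...)` compound locations are flattened to
#' the enclosing span, with each segment additionally emitted as an exon
#' for gene/mRNA features. `gene_numeric_id` is taken from a
#' `/db_xref="GeneID:n"` qualifier when present.
#'
#' @name annotation_io
NULL

.empty_features <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), kind = character(), feature_id = character(),
         gene_name = character(), gene_numeric_id = integer())
}

new_genome_annotation <- function(organism, chromosomes, features) {
  if (anyDuplicated(chromosomes$chrom)) {
    abort("duplicate chromosome ids within one genome")
  }
  .check_regions(features, "feature")
  known <- setNames(chromosomes$length, chromosomes$chrom)
  off <- features$chrom %in% names(known) & features$end > known[features$chrom]
  if (any(off)) {
    abort(sprintf("feature(s) extend past chromosome end: %s",
                  paste(head(features$feature_id[off], 3), collapse = ", ")))
  }
  structure(list(organism = organism,
                 chromosomes = as_tibble(chromosomes),
                 features = as_tibble(features)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$organism, ": ",
      nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$features), " feature(s)\n", sep = "")
  if (nrow(x$features) > 0) {
    print(count(x$features, .data$kind))
  }
  invisible(x)
}

# ---- location strings (GenBank/EMBL shared) --------------------------------

# Parse a feature location such as "complement(join(12..34,56..78))".
# Returns list(strand, span = c(start, end), segments = matrix with 2 cols).
.parse_location <- function(loc, context = "feature") {
  raw <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  s <- raw
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  s <- gsub("complement\\(([^()]*)\\)", "\\1", s)  # per-segment complements
  if (grepl("^(join|order)\\(", s)) {
    s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  seg <- matrix(NA_integer_, nrow = length(parts), ncol = 2)
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else {
      abort(sprintf("cannot parse location '%s' of %s", loc, context))
    }
    if (ab[2] < ab[1]) {
      abort(sprintf("coordinate error in %s: end %d < start %d",
                    context, ab[2], ab[1]))
    }
    seg[i, ] <- ab
  }
  list(strand = strand,
       span = c(min(seg[, 1]), max(seg[, 2])),
       segments = seg,
       compound = nrow(seg) > 1)
}

.qual_value <- function(quals, name) {
  hit <- grep(paste0("^/", name, "(=|$)"), quals, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  v <- sub(paste0("^/", name, "=?"), "", hit[1])
  gsub('^"|"$', "", v)
}

# Turn one raw feature (key, location, qualifiers) into 0+ feature rows.
.emit_feature <- function(key, loc_string, quals, chrom, counter_env) {
  kind <- switch(key,
    gene = "gene",
    exon = "exon",
    misc_RNA = "miscRNA",
    "5'UTR" = "five_prime_UTR",
    "3'UTR" = "three_prime_UTR",
    mRNA = "mRNA",
    NULL
  )
  if (is.null(kind)) return(NULL)
  if (kind == "gene" &&
      any(grepl("^/pseudo(gene)?(=|$)", quals))) kind <- "pseudogene"

  ctx <- sprintf("%s feature on %s", key, chrom)
  loc <- .parse_location(loc_string, ctx)
  gene_name <- .qual_value(quals, "gene")
  locus_tag <- .qual_value(quals, "locus_tag")
  name <- if (!is.na(gene_name)) gene_name else locus_tag
  fid <- if (!is.na(locus_tag)) locus_tag else name
  if (is.na(fid)) {
    counter_env$n <- counter_env$n + 1L
    fid <- sprintf("%s_%04d", key, counter_env$n)
  }
  dbx <- grep("^/db_xref=.*GeneID:", quals, value = TRUE)
  gid <- if (length(dbx) > 0) {
    as.integer(sub(".*GeneID:(\\d+).*", "\\1", dbx[1]))
  } else NA_integer_

  row <- function(kind, start, end) {
    tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
           strand = loc$strand, kind = kind, feature_id = fid,
           gene_name = if (is.na(name)) fid else name, gene_numeric_id = gid)
  }
  out <- list()
  if (kind != "mRNA") out[[1]] <- row(kind, loc$span[1], loc$span[2])
  # compound gene/mRNA locations contribute their segments as exons
  if (kind %in% c("gene", "mRNA") && loc$compound) {
    for (i in seq_len(nrow(loc$segments))) {
      out[[length(out) + 1]] <- row("exon", loc$segments[i, 1], loc$segments[i, 2])
    }
  }
  if (length(out) == 0) NULL else list_rbind(out)
}

# ---- GenBank ---------------------------------------------------------------

.read_genbank <- function(lines, path) {
  rec_breaks <- c(which(grepl("^//", lines)), length(lines) + 1L)
  starts <- which(grepl("^LOCUS", lines))
  if (length(starts) == 0) {
    abort(sprintf("%s: no LOCUS header found (line 1: '%s')",
                  path, substr(lines[1], 1, 60)))
  }
  organism <- NA_character_
  chroms <- list(); feats <- list()
  for (si in seq_along(starts)) {
    from <- starts[si]
    to <- min(rec_breaks[rec_breaks >= from]) - 1L
    rec <- lines[from:to]
    m <- regmatches(rec[1], regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp", rec[1]))[[1]]
    if (length(m) == 0) {
      abort(sprintf("%s line %d: unparseable LOCUS header '%s'",
                    path, from, rec[1]))
    }
    chrom <- m[2]; len <- as.integer(m[3])
    org <- grep("^\\s{1,4}ORGANISM\\s+", rec, value = TRUE)
    if (is.na(organism) && length(org) > 0) {
      organism <- trimws(sub("^\\s*ORGANISM\\s+", "", org[1]))
    }
    ftab <- .genbank_feature_block(rec)
    feats[[si]] <- .parse_feature_block(ftab, chrom)
    chroms[[si]] <- tibble(chrom = chrom, length = len)
  }
  new_genome_annotation(
    organism = organism %||% "unknown",
    chromosomes = list_rbind(chroms),
    features = .bind_features(feats)
  )
}

.genbank_feature_block <- function(rec) {
  f0 <- grep("^FEATURES", rec)
  if (length(f0) == 0) return(character())
  stop_at <- grep("^(ORIGIN|CONTIG|BASE COUNT)", rec)
  f1 <- if (length(stop_at) > 0) min(stop_at[stop_at > f0[1]]) - 1L else length(rec)
  if (f1 <= f0[1]) return(character())
  rec[(f0[1] + 1L):f1]
}

# Shared feature-table walker: lines are "  key  location" /
# "        /qualifier" / "        location-continuation".
.parse_feature_block <- function(block, chrom) {
  out <- list()
  counter <- new.env(); counter$n <- 0L
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      out[[length(out) + 1]] <<- .emit_feature(cur$key, cur$loc, cur$quals,
                                               chrom, counter)
    }
  }
  for (ln in block) {
    if (!nzchar(trimws(ln))) next
    body <- trimws(ln)
    is_new <- grepl("^\\s{1,10}\\S", ln) &&
      grepl("^\\S+\\s+(complement|join|order|<?\\d)", body)
    if (is_new) {
      flush()
      key <- sub("^(\\S+)\\s.*$", "\\1", body)
      loc <- sub("^\\S+\\s+", "", body)
      cur <- list(key = key, loc = loc, quals = character())
    } else if (grepl("^/", body)) {
      if (!is.null(cur)) cur$quals <- c(cur$quals, body)
    } else if (!is.null(cur) && length(cur$quals) == 0) {
      cur$loc <- paste0(cur$loc, body)   # wrapped location
    }
  }
  flush()
  .bind_features(out)
}

.bind_features <- function(lst) {
  lst <- compact(lst)
  if (length(lst) == 0) return(.empty_features())
  list_rbind(lst)
}

# ---- EMBL ------------------------------------------------------------------

.read_embl <- function(lines, path) {
  starts <- which(grepl("^ID\\s", lines))
  if (length(starts) == 0) {
    abort(sprintf("%s: no EMBL ID header found (line 1: '%s')",
                  path, substr(lines[1], 1, 60)))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  organism <- NA_character_
  chroms <- list(); feats <- list()
  for (si in seq_along(starts)) {
    rec <- lines[starts[si]:ends[si]]
    m <- regmatches(rec[1], regexec("^ID\\s+([^;\\s]+).*?(\\d+)\\s+BP", rec[1]))[[1]]
    if (length(m) == 0) {
      abort(sprintf("%s line %d: unparseable ID header '%s'",
                    path, starts[si], rec[1]))
    }
    chrom <- m[2]; len <- as.integer(m[3])
    os <- grep("^OS\\s+", rec, value = TRUE)
    if (is.na(organism) && length(os) > 0) {
      organism <- trimws(sub("^OS\\s+", "", os[1]))
    }
    ft <- grep("^FT\\s", rec, value = TRUE)
    sq <- grep("^SQ", rec)
    block <- sub("^FT", "  ", ft)
    feats[[si]] <- .parse_feature_block(block, chrom)
    chroms[[si]] <- tibble(chrom = chrom, length = len)
  }
  new_genome_annotation(
    organism = organism %||% "unknown",
    chromosomes = list_rbind(chroms),
    features = .bind_features(feats)
  )
}

# ---- native TSV ------------------------------------------------------------

# columns: chrom, start, end, strand, kind, gene_name, gene_numeric_id.
# rows with kind "chromosome" declare chromosome lengths (start=1, end=length);
# '#' starts a comment. Organism may be declared as "#!organism <name>".
.read_visualte_annotation <- function(lines, path) {
  org_line <- grep("^#!organism\\b", lines, value = TRUE)
  organism <- if (length(org_line) > 0) {
    trimws(sub("^#!organism", "", org_line[1]))
  } else "unknown"
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- list(); chroms <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 7) {
      abort(sprintf("%s line %d: expected 7 tab-separated columns, got %d",
                    path, i, length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("%s line %d: non-numeric coordinates", path, i))
    }
    if (f[5] == "chromosome") {
      chroms[[length(chroms) + 1]] <- tibble(chrom = f[1], length = end)
      next
    }
    if (!f[5] %in% te_feature_kinds) {
      abort(sprintf("%s line %d: unknown feature kind '%s' (valid: %s)",
                    path, i, f[5], paste(te_feature_kinds, collapse = ", ")))
    }
    if (end < start) {
      abort(sprintf("%s line %d: coordinate error, end < start for feature '%s'",
                    path, i, f[6]))
    }
    gid <- suppressWarnings(as.integer(f[7]))
    rows[[length(rows) + 1]] <- tibble(
      chrom = f[1], start = start, end = end, strand = .norm_strand(f[4]),
      kind = f[5], feature_id = f[6], gene_name = f[6], gene_numeric_id = gid)
  }
  features <- .bind_features(rows)
  chrom_tbl <- if (length(chroms) > 0) {
    distinct(list_rbind(chroms))
  } else {
    summarise(group_by(features, .data$chrom), length = max(.data$end),
              .groups = "drop")
  }
  new_genome_annotation(organism, chrom_tbl, features)
}

#' Read a genome annotation file
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"genbank"`, `"embl"`, `"visualte"` or `"auto"`.
#'   Auto-detection looks at the first header token: `LOCUS` means GenBank,
#'   `ID` means EMBL, anything else the native TSV dialect.
#' @return A `genome_annotation` object.
#' @examples
#' gb <- c("LOCUS       Chr1  5000 bp  DNA  linear  PLN",
#'         "FEATURES             Location/Qualifiers",
#'         "     gene            100..400",
#'         '                     /locus_tag="g1"',
#'         "//")
#' f <- tempfile(fileext = ".gb"); writeLines(gb, f)
#' read_annotation(f)
#' @export
read_annotation <- function(path, dialect = c("auto", "genbank", "embl", "visualte")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("annotation file is empty: %s", path))
  if (dialect == "auto") {
    first <- lines[which(nzchar(trimws(lines)) & !grepl("^#", lines))[1]]
    dialect <- if (grepl("^LOCUS\\s", first)) "genbank"
      else if (grepl("^ID\\s", first)) "embl"
      else "visualte"
  }
  switch(dialect,
    genbank = .read_genbank(lines, path),
    embl = .read_embl(lines, path),
    visualte = .read_visualte_annotation(lines, path)
  )
}

#' Extract features of given kinds, coordinate-sorted
#'
#' @param x A `genome_annotation` or a feature tibble.
#' @param kinds Character vector of feature kinds (subset of
#'   `r paste(te_feature_kinds, collapse = ", ")`).
#' @param chrom Optional chromosome id to restrict to.
#' @return A feature tibble sorted by (start, end).
#' @export
extract_features <- function(x, kinds = te_feature_kinds, chrom = NULL) {
  feats <- if (inherits(x, "genome_annotation")) x$features else as_tibble(x)
  if (length(kinds) == 0) abort("extract_features: 'kinds' must be non-empty")
  bad <- setdiff(kinds, te_feature_kinds)
  if (length(bad) > 0) {
    abort(sprintf("unknown feature kind(s): %s (valid: %s)",
                  paste(bad, collapse = ", "),
                  paste(te_feature_kinds, collapse = ", ")))
  }
  out <- filter(feats, .data$kind %in% kinds)
  if (!is.null(chrom)) out <- filter(out, .data$chrom %in% !!chrom)
  arrange(out, .data$chrom, .data$start, .data$end)
}
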