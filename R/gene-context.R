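#' TE-gene context: neighbors, proximity classes, GO distributions
#'
#' A TE copy's genomic context is summarised by its closest annotated
#' gene on each side and any genes it overlaps. Copies are classified
#' into four mutually exclusive region categories:
#'
#' * `ExonIntronUTR` — the copy overlaps a gene body (>= 1 bp);
#' * `ProximalPromoter` — within the proximal distance `D` (default
#'   3,000 bp, boundary inclusive) of the 5' side of its nearest gene;
#' * `Proximal3End` — likewise on the 3' side;
#' * `Intergenic` — farther than `D` from every gene.
#'
#' "Left"/"right" neighbors are chromosome-coordinate-based; promoter vs
#' 3'-end semantics apply the gene's strand at classification time
#' (unstranded genes are treated as forward). When the two flank genes
#' are exactly equidistant, the promoter interpretation wins.
#'
#' @name gene_context
NULL

.empty_neighbors <- function() {
  tibble(te_id = integer(), relation = character(), gene_name = character(),
         gene_start = integer(), gene_end = integer(), gene_strand = character(),
         gene_kind = character(), gene_numeric_id = integer(), gap = integer())
}

#' Nearest genes around TE copies
#'
#' For each TE copy: the nearest gene lying entirely to its left (gene
#' end < TE start), the nearest entirely to its right (gene start > TE
#' end), and all genes overlapping it. Gap is the number of bases
#' strictly between copy and gene (0 for adjacency or overlap). Ties on
#' equal gap are broken toward the gene with the smaller start
#' coordinate.
#'
#' @param tes TE-copy tibble, all on one chromosome.
#' @param genes Feature tibble on the same chromosome, sorted by
#'   (start, end) — see [extract_features()]. Unsorted input is an error.
#' @return A tibble with one row per (copy, neighbor): `te_id` (row index
#'   into `tes`), `relation` (`"left"`, `"right"` or `"within"`), gene
#'   columns and `gap`. Copies with no gene on the chromosome contribute
#'   no rows.
#' @export
nearest_genes <- function(tes, genes) {
  if (nrow(genes) > 1 && is.unsorted(genes$start)) {
    abort("nearest_genes: genes must be sorted by start (see extract_features)")
  }
  if (nrow(tes) == 0 || nrow(genes) == 0) return(.empty_neighbors())
  chrom <- unique(c(tes$chrom, genes$chrom))
  if (length(chrom) > 1) {
    abort("nearest_genes: copies and genes must share one chromosome")
  }
  gene_row <- function(i, te_id, relation, gap) {
    tibble(te_id = te_id, relation = relation,
           gene_name = genes$gene_name[i], gene_start = genes$start[i],
           gene_end = genes$end[i], gene_strand = genes$strand[i],
           gene_kind = genes$kind[i],
           gene_numeric_id = genes$gene_numeric_id[i],
           gap = as.integer(gap))
  }
  out <- vector("list", nrow(tes))
  for (t in seq_len(nrow(tes))) {
    ts <- tes$start[t]; te <- tes$end[t]
    rows <- list()
    ov <- which(genes$start <= te & genes$end >= ts)
    for (i in ov) rows[[length(rows) + 1]] <- gene_row(i, t, "within", 0L)
    left <- which(genes$end < ts)
    if (length(left) > 0) {
      m <- max(genes$end[left])
      cand <- left[genes$end[left] == m]
      i <- cand[which.min(genes$start[cand])]
      rows[[length(rows) + 1]] <- gene_row(i, t, "left", ts - m - 1L)
    }
    right <- which(genes$start > te)
    if (length(right) > 0) {
      m <- min(genes$start[right])
      cand <- right[genes$start[right] == m]
      i <- cand[which.min(genes$end[cand])]
      rows[[length(rows) + 1]] <- gene_row(i, t, "right", m - te - 1L)
    }
    out[[t]] <- if (length(rows) > 0) list_rbind(rows) else NULL
  }
  .bind_features_or(out, .empty_neighbors())
}

# promoter/3'-end semantics for a flank neighbor given gene strand
.side_category <- function(relation, gene_strand) {
  fwd <- gene_strand != "-"
  if_else(
    (relation == "right" & fwd) | (relation == "left" & !fwd),
    "ProximalPromoter", "Proximal3End")
}

#' Classify TE copies into gene-region categories
#'
#' Classification precedence per copy: any overlapped gene makes it
#' `ExonIntronUTR`; otherwise, among flank genes with gap `<= D`
#' (inclusive), the one with the smallest gap decides between
#' `ProximalPromoter` and `Proximal3End` by which side of the gene
#' (strand-aware) the copy lies on, a promoter interpretation winning an
#' exact-gap tie; otherwise `Intergenic`.
#'
#' @param tes TE-copy tibble (any chromosomes).
#' @param genome A `genome_annotation`.
#' @param config A [proximity_config()]; `config$neighbor_kinds` selects
#'   which feature kinds count as genes.
#' @return `tes` with added columns `te_id`, `category`, and the deciding
#'   neighbor's `near_gene_name`/`near_gene_start`/`near_gene_end`/
#'   `near_gene_strand`/`near_gap` (`NA` for intergenic copies).
#' @export
classify_te <- function(tes, genome, config = proximity_config()) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(config, "proximity_config"))
  tes <- mutate(tes, te_id = dplyr::row_number())
  nb <- te_neighbors(tes, genome, config)
  D <- config$distance
  cls <- rep("Intergenic", nrow(tes))
  near <- tibble(near_gene_name = rep(NA_character_, nrow(tes)),
                 near_gene_start = NA_integer_, near_gene_end = NA_integer_,
                 near_gene_strand = NA_character_, near_gap = NA_integer_)
  if (nrow(nb) > 0) {
    within_ids <- unique(nb$te_id[nb$relation == "within"])
    cls[within_ids] <- "ExonIntronUTR"
    pick_within <- nb |>
      filter(.data$relation == "within") |>
      distinct(.data$te_id, .keep_all = TRUE)
    flank <- nb |>
      filter(.data$relation != "within", .data$gap <= D,
             !.data$te_id %in% within_ids) |>
      mutate(side_cat = .side_category(.data$relation, .data$gene_strand))
    if (nrow(flank) > 0) {
      flank <- flank |>
        group_by(.data$te_id) |>
        filter(.data$gap == min(.data$gap)) |>
        # promoter wins an exact tie between equally distant flank genes
        arrange(.data$side_cat != "ProximalPromoter", .by_group = TRUE) |>
        slice(1) |>
        ungroup()
    }
    cls[flank$te_id] <- flank$side_cat
    fill_near <- function(picked) {
      near$near_gene_name[picked$te_id] <<- picked$gene_name
      near$near_gene_start[picked$te_id] <<- picked$gene_start
      near$near_gene_end[picked$te_id] <<- picked$gene_end
      near$near_gene_strand[picked$te_id] <<- picked$gene_strand
      near$near_gap[picked$te_id] <<- picked$gap
    }
    fill_near(pick_within)
    fill_near(flank)
  }
  bind_cols(tes, tibble(category = cls), near)
}

# all neighbor rows (left/right/within) across chromosomes
te_neighbors <- function(tes, genome, config = proximity_config()) {
  genes <- extract_features(genome, config$neighbor_kinds)
  if (!"te_id" %in% names(tes)) tes <- mutate(tes, te_id = dplyr::row_number())
  parts <- map(split(tes, tes$chrom), function(chunk) {
    g <- filter(genes, .data$chrom == chunk$chrom[1])
    nb <- nearest_genes(chunk, g)
    nb$te_id <- chunk$te_id[nb$te_id]
    nb
  })
  .bind_features_or(unname(parts), .empty_neighbors())
}

#' Distribution of TE copies over region categories
#'
#' @inheritParams classify_te
#' @return A tibble `category`, `n`, `proportion` covering the four
#'   categories present (zero copies give a zero-row tibble).
#' @export
category_distribution <- function(tes, genome, config = proximity_config()) {
  if (nrow(tes) == 0) {
    return(tibble(category = character(), n = integer(), proportion = double()))
  }
  cls <- classify_te(tes, genome, config)
  cls |>
    count(category = factor(.data$category, levels = te_categories),
          .drop = FALSE, name = "n") |>
    mutate(category = as.character(.data$category),
           proportion = .data$n / sum(.data$n))
}

#' Histogram of gap distances within a proximal category
#'
#' Bins the classifying-gene gap distances of the copies in one proximal
#' category over `[0, D]` in `config$region_bins` equal intervals,
#' left-closed with a right-closed last interval. Bin 0 is nearest the
#' gene boundary (the gene start for promoters, the gene end for 3'
#' ends).
#'
#' @param classified Output of [classify_te()] (or a TE tibble, in which
#'   case `genome` must be given and classification is run first).
#' @param category `"ProximalPromoter"` or `"Proximal3End"`; the other
#'   two categories have no distance axis and are an error.
#' @param config A [proximity_config()].
#' @param genome Optional `genome_annotation` when `classified` is raw.
#' @return A `binned_curve` over the gap-distance axis.
#' @export
region_position_histogram <- function(classified, category,
                                      config = proximity_config(),
                                      genome = NULL) {
  if (!category %in% c("ProximalPromoter", "Proximal3End")) {
    abort(sprintf("no distance axis for category '%s' (only proximal categories)",
                  category))
  }
  if (!"category" %in% names(classified)) {
    if (is.null(genome)) abort("supply classify_te() output or a genome")
    classified <- classify_te(classified, genome, config)
  }
  gaps <- classified$near_gap[classified$category == category]
  D <- config$distance
  nb <- config$region_bins
  w <- D / nb
  counts <- integer(nb)
  if (length(gaps) > 0) {
    idx <- if (w == 0) rep(1L, length(gaps)) else {
      pmin(nb, as.integer(floor(gaps / w)) + 1L)
    }
    counts <- as.integer(table(factor(idx, levels = seq_len(nb))))
  }
  new_binned_curve(w * (0:(nb - 1)), w * (1:nb), counts, axis = "gap")
}

#' GO slim distribution of TE-neighboring genes
#'
#' Collects each TE copy's flank neighbors and overlapped genes, projects
#' each gene's GO annotation onto the slim (set semantics per gene), and
#' tallies slim-term assignments. Genes lacking a numeric id or any
#' slim-mapped annotation fall into an explicit `"unannotated"` bucket,
#' so proportions always sum to 1.
#'
#' @param tes TE-copy tibble.
#' @param genome A `genome_annotation`.
#' @param go_map A `gene_go_map` from [read_gene2go()].
#' @param dag A `go_dag`.
#' @param slim A `slim_set`.
#' @param config A [proximity_config()].
#' @return A `go_distribution` tibble: `term`, `label`, `n`,
#'   `proportion`; the display threshold is carried as an attribute and
#'   applied only in plots ([autoplot.go_distribution()]) and never in
#'   the table itself.
#' @export
neighbor_go_distribution <- function(tes, genome, go_map, dag, slim,
                                     config = proximity_config()) {
  nb <- te_neighbors(tes, genome, config)
  .go_tally(nb$gene_numeric_id, go_map, dag, slim, config$display_threshold)
}

#' GO slim distribution of a gene set (baseline)
#'
#' The all-genes baseline of [neighbor_go_distribution()]: every feature
#' in `genes` counts once.
#'
#' @param genes Feature tibble (e.g. all `gene` features of the genome).
#' @inheritParams neighbor_go_distribution
#' @export
gene_go_distribution <- function(genes, go_map, dag, slim,
                                 config = proximity_config()) {
  .go_tally(genes$gene_numeric_id, go_map, dag, slim,
            config$display_threshold)
}

.go_tally <- function(gene_ids, go_map, dag, slim, display_threshold) {
  gs <- .gene_slim_table(go_map, dag, slim)
  term_names <- setNames(dag$terms$name, dag$terms$id)
  slim_of <- split(gs$slim_id, gs$gene_id)
  counts <- list()
  bump <- function(term) counts[[term]] <<- (counts[[term]] %||% 0L) + 1L
  for (gid in gene_ids) {
    terms <- if (!is.na(gid)) slim_of[[as.character(gid)]] else NULL
    if (is.null(terms) || length(terms) == 0) bump("unannotated")
    else for (s in terms) bump(s)
  }
  if (length(counts) == 0) {
    out <- tibble(term = character(), label = character(), n = integer(),
                  proportion = double())
  } else {
    out <- tibble(term = names(counts), n = unname(unlist(counts))) |>
      mutate(label = if_else(.data$term == "unannotated", "unannotated",
                             coalesce(term_names[.data$term], .data$term)),
             proportion = .data$n / sum(.data$n)) |>
      arrange(desc(.data$proportion), .data$term) |>
      select("term", "label", "n", "proportion")
  }
  structure(out, class = c("go_distribution", class(out)),
            display_threshold = display_threshold, slim = slim$name)
}

#' Count TE-gene couples across organisms
#'
#' A couple is the triple (TE family, neighboring gene name, relation
#' side), gene names matched case-insensitively — or, when an ortholog
#' map is given, by ortholog group. `X` is the number of distinct
#' organisms in which the couple occurs at least once.
#'
#' @param feature_tables A feature table ([build_feature_table()]) or a
#'   list of them (one per organism); each must carry an `organism`
#'   column.
#' @param ortholog_map Optional two-column data frame or TSV path
#'   (`gene_name`, `ortholog_group`) overriding name matching.
#' @return A tibble `family`, `gene_key`, `relation`, `organisms`
#'   (list-column), `X`.
#' @export
count_couples <- function(feature_tables, ortholog_map = NULL) {
  tbl <- if (is.data.frame(feature_tables)) feature_tables
         else list_rbind(feature_tables)
  if (nrow(tbl) == 0) {
    return(tibble(family = character(), gene_key = character(),
                  relation = character(), organisms = list(), X = integer()))
  }
  if (is.character(ortholog_map)) {
    ortholog_map <- readr::read_tsv(ortholog_map, comment = "#",
                                    col_names = c("gene_name", "ortholog_group"),
                                    col_types = "cc")
  }
  tbl <- tbl |>
    filter(!is.na(.data$gene_name)) |>
    mutate(gene_key = tolower(.data$gene_name))
  if (!is.null(ortholog_map)) {
    om <- mutate(as_tibble(ortholog_map), gene_lc = tolower(.data$gene_name))
    idx <- match(tbl$gene_key, om$gene_lc)
    tbl$gene_key <- if_else(is.na(idx), tbl$gene_key,
                            tolower(om$ortholog_group[idx]))
  }
  tbl |>
    group_by(family = .data$te_family, .data$gene_key, .data$relation) |>
    summarise(organisms = list(sort(unique(.data$organism))),
              X = length(unique(.data$organism)), .groups = "drop")
}

#' Build the master TE-gene feature table
#'
#' One row per (TE copy, neighbor): at least two rows per copy when both
#' flanks carry a gene, plus one row per overlapped gene; a copy on a
#' gene-free chromosome yields a single placeholder row with
#' `relation = "none"`. Columns, in order: organism, chrom, te_family,
#' te_start, te_end, te_strand, superfamily, similarity, gene_name,
#' gene_start, gene_end, gene_strand, relation, distance,
#' region_category, go_terms (semicolon-joined slim ids), ortholog_X.
#'
#' @param tes TE-copy tibble.
#' @param genome A `genome_annotation`.
#' @param config A [proximity_config()].
#' @param go_map,dag,slim Optional ontology resources; when omitted the
#'   `go_terms` column is empty.
#' @param organism Organism label (defaults to the genome's).
#' @return A tibble with the fixed column order above. `ortholog_X` is 1
#'   for gene rows of a single-organism run; use [count_couples()] +
#'   [annotate_couples()] across organisms to recompute it.
#' @export
build_feature_table <- function(tes, genome, config = proximity_config(),
                                go_map = NULL, dag = NULL, slim = NULL,
                                organism = genome$organism) {
  cls <- classify_te(tes, genome, config)
  nb <- te_neighbors(cls, genome, config)
  gs <- if (!is.null(go_map) && !is.null(dag) && !is.null(slim)) {
    .gene_slim_table(go_map, dag, slim)
  } else tibble(gene_id = integer(), slim_id = character())
  slim_join <- gs |>
    group_by(.data$gene_id) |>
    summarise(go_terms = paste(sort(.data$slim_id), collapse = ";"))
  te_part <- cls |>
    select("te_id", "chrom", te_family = "family", te_start = "start",
           te_end = "end", te_strand = "strand", "superfamily",
           "similarity", region_category = "category")
  rows <- nb |>
    left_join(te_part, by = "te_id") |>
    left_join(slim_join, by = c(gene_numeric_id = "gene_id")) |>
    mutate(go_terms = coalesce(.data$go_terms, ""),
           distance = .data$gap)
  orphan_ids <- setdiff(cls$te_id, nb$te_id)
  if (length(orphan_ids) > 0) {
    orphans <- te_part |>
      filter(.data$te_id %in% orphan_ids) |>
      mutate(gene_name = NA_character_, gene_start = NA_integer_,
             gene_end = NA_integer_, gene_strand = NA_character_,
             relation = "none", distance = NA_integer_, go_terms = "")
    rows <- bind_rows(rows, orphans)
  }
  out <- rows |>
    mutate(organism = organism, ortholog_X = if_else(is.na(.data$gene_name),
                                                     NA_integer_, 1L)) |>
    arrange(.data$te_id, match(.data$relation, c("left", "right", "within", "none")),
            .data$gene_start) |>
    select("organism", "chrom", "te_family", "te_start", "te_end",
           "te_strand", "superfamily", "similarity", "gene_name",
           "gene_start", "gene_end", "gene_strand", "relation", "distance",
           "region_category", "go_terms", "ortholog_X")
  out
}

#' Annotate a feature table with cross-organism couple counts
#'
#' @param table A feature table from [build_feature_table()].
#' @param couples Output of [count_couples()] over all organisms.
#' @param min_organisms Keep only rows whose couple occurs in at least
#'   this many organisms (placeholder rows without a gene are kept when
#'   `min_organisms == 1`).
#' @param ortholog_map Optional ortholog map, as in [count_couples()].
#' @return The table with `ortholog_X` recomputed and filtered.
#' @export
annotate_couples <- function(table, couples, min_organisms = 1,
                             ortholog_map = NULL) {
  key <- tolower(table$gene_name)
  if (is.character(ortholog_map)) {
    ortholog_map <- readr::read_tsv(ortholog_map, comment = "#",
                                    col_names = c("gene_name", "ortholog_group"),
                                    col_types = "cc")
  }
  if (!is.null(ortholog_map)) {
    om <- mutate(as_tibble(ortholog_map), gene_lc = tolower(.data$gene_name))
    idx <- match(key, om$gene_lc)
    key <- if_else(is.na(idx), key, tolower(om$ortholog_group[idx]))
  }
  idx <- match(paste(table$te_family, key, table$relation),
               paste(couples$family, couples$gene_key, couples$relation))
  table$ortholog_X <- if_else(is.na(table$gene_name), NA_integer_,
                              couples$X[idx])
  keep <- is.na(table$gene_name) & min_organisms <= 1 |
    (!is.na(table$ortholog_X) & table$ortholog_X >= min_organisms)
  table[keep, ]
}
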