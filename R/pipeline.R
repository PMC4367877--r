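#' End-to-end landscape run
#'
#' [run_te_landscape()] wires the whole analysis: parse annotation and
#' repeat files, attach superfamilies, apply size/similarity filters,
#' select families, and emit every panel as a TSV (plus a BED track and
#' a JSON manifest) under an output directory.
#'
#' @name cli_report
NULL

#' Configuration of a landscape run
#'
#' @param annotation Character vector of annotation file paths (>= 1);
#'   each file is one organism/genome.
#' @param repeats Character vector of repeat file paths, recycled against
#'   `annotation`.
#' @param families Character vector of selected TE family names (>= 1, at
#'   most `config$family_limit`).
#' @param annotation_format,repeat_format Dialects (see
#'   [read_annotation()], [read_repeats()]).
#' @param chromosomes `"all"` or a character vector of chromosome ids.
#' @param filters A [te_filters()].
#' @param config A [proximity_config()].
#' @param superfamily_table Optional path to a family-superfamily TSV.
#' @param gene2go,obo Optional ontology file paths; both are required for
#'   the GO outputs.
#' @param slim `"generic"` (the packaged synthetic generic slim),
#'   `"level1"`, `"level2"`, or a path to a custom slim list.
#' @param taxon Optional taxon filter for gene2go.
#' @param ortholog_map Optional ortholog-map TSV path.
#' @param out_dir Output directory.
#' @param n_bins Bins of the per-chromosome occurrence curves.
#' @param size_intervals Intervals of the size histogram.
#' @param window Optional `c(start, end)` coordinate window restricting
#'   the BED track and occurrence curves.
#' @param plots Also write PNG plots of each panel.
#' @return A `run_config` list.
#' @export
run_config <- function(annotation, repeats, families,
                       annotation_format = "auto", repeat_format = "auto",
                       chromosomes = "all",
                       filters = te_filters(), config = proximity_config(),
                       superfamily_table = NULL,
                       gene2go = NULL, obo = NULL, slim = "generic",
                       taxon = NULL, ortholog_map = NULL,
                       out_dir = "telandscape_out",
                       n_bins = 100, size_intervals = 40,
                       window = NULL, plots = FALSE) {
  if (length(annotation) < 1 || length(repeats) < 1) {
    abort("need at least one annotation and one repeat file")
  }
  families <- unique(families)
  if (length(families) < 1) abort("need at least one TE family name")
  if (length(families) > config$family_limit) {
    abort(sprintf("%d families selected; at most %d allowed",
                  length(families), config$family_limit))
  }
  if (!is.null(window) && (length(window) != 2 || window[1] > window[2])) {
    abort("window must be c(start, end) with start <= end")
  }
  structure(
    list(annotation = annotation, repeats = repeats, families = families,
         annotation_format = annotation_format, repeat_format = repeat_format,
         chromosomes = chromosomes, filters = filters, config = config,
         superfamily_table = superfamily_table, gene2go = gene2go,
         obo = obo, slim = slim, taxon = taxon, ortholog_map = ortholog_map,
         out_dir = out_dir, n_bins = as.integer(n_bins),
         size_intervals = as.integer(size_intervals), window = window,
         plots = plots),
    class = "run_config")
}

.load_slim <- function(choice, dag) {
  if (identical(choice, "level1")) return(derive_tree_level_slim(dag, 1))
  if (identical(choice, "level2")) return(derive_tree_level_slim(dag, 2))
  path <- if (identical(choice, "generic")) goslim_generic_synthetic_path()
          else choice
  suppressWarnings(read_slim_terms(path, name = if (identical(choice, "generic"))
    "GenericEBI-synthetic" else "custom", dag = dag))
}

.write_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  path
}

#' Run the full TE landscape analysis
#'
#' Per genome, writes: `tracks.bed`, `distribution_<chrom>.tsv`,
#' `frequency.tsv`, `size_histogram.tsv`, `size_proportions.tsv`,
#' `distance_categories.tsv`, `region_histogram_<category>.tsv`,
#' `go_distribution_<scope>.tsv` (when ontology inputs are given),
#' `te_gene_features.tsv`, and a `manifest.json` listing every artifact
#' and the parameters used. Counts at every stage (parsed, filtered,
#' selected, classified) are reported via messages.
#'
#' @param cfg A [run_config()].
#' @return An object of class `te_landscape` holding every result table,
#'   the manifest, and the inputs used; also written to `cfg$out_dir`.
#' @export
run_te_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  n_org <- length(cfg$annotation)
  repeats <- rep_len(cfg$repeats, n_org)

  sft <- if (!is.null(cfg$superfamily_table)) {
    load_superfamily_table(cfg$superfamily_table)
  } else NULL
  onto <- NULL
  if (!is.null(cfg$gene2go) || !is.null(cfg$obo)) {
    if (is.null(cfg$gene2go) || is.null(cfg$obo)) {
      abort("GO outputs need both 'gene2go' and 'obo'")
    }
    dag <- read_go_obo(cfg$obo)
    onto <- list(go_map = read_gene2go(cfg$gene2go, taxon = cfg$taxon),
                 dag = dag, slim = .load_slim(cfg$slim, dag))
  }

  per_genome <- vector("list", n_org)
  for (oi in seq_len(n_org)) {
    per_genome[[oi]] <- .run_one_genome(
      cfg, oi, cfg$annotation[oi], repeats[oi], sft, onto)
  }
  feature_tables <- map(per_genome, "features_table")
  couples <- count_couples(feature_tables, ortholog_map = cfg$ortholog_map)
  for (oi in seq_len(n_org)) {
    annotated <- annotate_couples(per_genome[[oi]]$features_table, couples,
                                  min_organisms = cfg$config$min_organisms,
                                  ortholog_map = cfg$ortholog_map)
    per_genome[[oi]]$features_table <- annotated
    .write_tsv(annotated, per_genome[[oi]]$manifest$outputs$te_gene_features)
  }
  manifest <- list(
    parameters = list(
      families = cfg$families, chromosomes = cfg$chromosomes,
      sim_min = cfg$filters$sim_min, sim_max = cfg$filters$sim_max,
      size_min = cfg$filters$size_min, size_max = cfg$filters$size_max,
      distance = cfg$config$distance, region_bins = cfg$config$region_bins,
      n_bins = cfg$n_bins, size_intervals = cfg$size_intervals,
      min_organisms = cfg$config$min_organisms,
      slim = if (is.null(onto)) NULL else onto$slim$name),
    genomes = map(per_genome, "manifest"))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  structure(
    list(config = cfg, genomes = per_genome, couples = couples,
         manifest = manifest, manifest_path = manifest_path),
    class = "te_landscape")
}

.run_one_genome <- function(cfg, oi, ann_path, rep_path, sft, onto) {
  genome <- read_annotation(ann_path, dialect = cfg$annotation_format)
  if (!identical(cfg$chromosomes, "all")) {
    keep <- genome$chromosomes$chrom %in% cfg$chromosomes
    if (!any(keep)) abort("no selected chromosome exists in the annotation")
    genome$chromosomes <- genome$chromosomes[keep, ]
    genome$features <- filter(genome$features,
                              .data$chrom %in% cfg$chromosomes)
  }
  all_tes <- read_repeats(rep_path, dialect = cfg$repeat_format)
  inform(sprintf("[%s] parsed %d features, %d repeat hits",
                 genome$organism, nrow(genome$features), nrow(all_tes)))
  if (!is.null(sft)) all_tes <- assign_superfamilies(all_tes, sft)
  all_tes <- mutate(all_tes,
                    superfamily = coalesce(.data$superfamily, "Unknown"))
  all_tes <- filter(all_tes, .data$chrom %in% genome$chromosomes$chrom)
  all_tes <- apply_te_filters(all_tes, cfg$filters)

  known <- unique(all_tes$family)
  missing <- setdiff(cfg$families, known)
  if (length(missing) > 0) {
    warn(sprintf("family name(s) not found in repeat data: %s",
                 paste(missing, collapse = ", ")))
  }
  selected <- intersect(cfg$families, known)
  if (length(selected) == 0) {
    abort(sprintf(
      "none of the selected family names occur in %s; available families: %s",
      rep_path, paste(sort(known), collapse = ", ")))
  }
  tes <- filter(all_tes, .data$family %in% selected)
  inform(sprintf("[%s] %d copies after filters across %d selected families",
                 genome$organism, nrow(tes), length(selected)))

  gdir <- if (length(cfg$annotation) > 1) {
    d <- file.path(cfg$out_dir, sprintf("genome%02d", oi))
    dir.create(d, showWarnings = FALSE)
    d
  } else cfg$out_dir
  out <- function(f) file.path(gdir, f)
  outputs <- list()

  win_tes <- tes
  if (!is.null(cfg$window)) {
    win_tes <- filter(tes, .data$end >= cfg$window[1],
                      .data$start <= cfg$window[2])
  }
  outputs$tracks <- export_bed(win_tes, out("tracks.bed"))

  curves <- list()
  for (ch in genome$chromosomes$chrom) {
    bc <- chromosome_distribution(filter(win_tes, .data$chrom == ch),
                                  genome$chromosomes[genome$chromosomes$chrom == ch, ],
                                  n_bins = cfg$n_bins)
    curves[[ch]] <- bc
    outputs[[paste0("distribution_", ch)]] <-
      .write_tsv(bc, out(sprintf("distribution_%s.tsv", ch)))
  }
  freq <- genome_frequency(tes, genome)
  outputs$frequency <- .write_tsv(freq, out("frequency.tsv"))

  sizes <- size_histogram(tes, n_intervals = cfg$size_intervals,
                          size_min = cfg$filters$size_min,
                          size_max = cfg$filters$size_max)
  outputs$size_histogram <- .write_tsv(sizes, out("size_histogram.tsv"))

  prop_classes <- c(selected, "all_tes", "gene", "pseudogene", "miscRNA",
                    "exon", "UTRs")
  props <- size_proportions(genome, tes, prop_classes, all_tes = all_tes)
  outputs$size_proportions <- .write_tsv(props, out("size_proportions.tsv"))

  classified <- classify_te(tes, genome, cfg$config)
  inform(sprintf("[%s] classified %d copies", genome$organism, nrow(classified)))
  cats <- classified |>
    count(category = factor(.data$category, levels = te_categories),
          .drop = FALSE, name = "n") |>
    mutate(category = as.character(.data$category),
           proportion = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_)
  outputs$distance_categories <- .write_tsv(cats, out("distance_categories.tsv"))
  region_hists <- list()
  for (cat in c("ProximalPromoter", "Proximal3End")) {
    rh <- region_position_histogram(classified, cat, cfg$config)
    region_hists[[cat]] <- rh
    outputs[[paste0("region_histogram_", cat)]] <-
      .write_tsv(rh, out(sprintf("region_histogram_%s.tsv", cat)))
  }

  go_dists <- list()
  if (!is.null(onto)) {
    go_dists$selected <- neighbor_go_distribution(
      tes, genome, onto$go_map, onto$dag, onto$slim, cfg$config)
    sf_names <- unique(classified$superfamily)
    sf_tes <- filter(all_tes, .data$superfamily %in% setdiff(sf_names, "Unknown"))
    if (nrow(sf_tes) > 0) {
      go_dists$superfamily <- neighbor_go_distribution(
        sf_tes, genome, onto$go_map, onto$dag, onto$slim, cfg$config)
    }
    go_dists$all_genes <- gene_go_distribution(
      extract_features(genome, cfg$config$neighbor_kinds),
      onto$go_map, onto$dag, onto$slim, cfg$config)
    for (scope in names(go_dists)) {
      outputs[[paste0("go_distribution_", scope)]] <-
        .write_tsv(go_dists[[scope]], out(sprintf("go_distribution_%s.tsv", scope)))
    }
  }

  ftab <- build_feature_table(
    tes, genome, cfg$config,
    go_map = onto$go_map, dag = onto$dag, slim = onto$slim)
  outputs$te_gene_features <- out("te_gene_features.tsv")
  .write_tsv(ftab, outputs$te_gene_features)

  if (isTRUE(cfg$plots)) {
    .write_plots(gdir, curves, freq, sizes, cats, region_hists, go_dists)
  }
  list(organism = genome$organism, genome = genome, all_tes = all_tes,
       tes = tes, classified = classified, curves = curves,
       frequency = freq, size_histogram = sizes, size_proportions = props,
       categories = cats, region_histograms = region_hists,
       go_distributions = go_dists, features_table = ftab,
       manifest = list(organism = genome$organism, outputs = outputs))
}

.write_plots <- function(dir, curves, freq, sizes, cats, region_hists, go_dists) {
  save <- function(p, name) {
    ggplot2::ggsave(file.path(dir, paste0(name, ".png")), p,
                    width = 7, height = 4, dpi = 120)
  }
  for (ch in names(curves)) {
    save(ggplot2::autoplot(curves[[ch]]), paste0("distribution_", ch))
  }
  save(plot_genome_frequency(freq), "frequency")
  save(ggplot2::autoplot(sizes), "size_histogram")
  save(plot_category_distribution(cats), "distance_categories")
  for (cat in names(region_hists)) {
    save(ggplot2::autoplot(region_hists[[cat]]), paste0("region_histogram_", cat))
  }
  for (scope in names(go_dists)) {
    save(ggplot2::autoplot(go_dists[[scope]]), paste0("go_distribution_", scope))
  }
}

#' Export TE copies as a BED6 track
#'
#' Coordinates are converted from 1-based inclusive to BED's 0-based
#' half-open convention; the score column is `round(similarity * 10)`
#' (0--1000). Lines are sorted by chromosome, then start.
#'
#' @param tes TE-copy tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_bed <- function(tes, path) {
  header <- "# BED6: chrom, start (0-based), end, family, similarity x 10, strand"
  tes <- arrange(tes, .data$chrom, .data$start, .data$end)
  lines <- if (nrow(tes) == 0) character() else {
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", tes$chrom, tes$start - 1L, tes$end,
            tes$family, as.integer(round(tes$similarity * 10)),
            if_else(tes$strand == "*", ".", tes$strand))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' List TE family names available in a repeat file
#'
#' @param path Repeat file path.
#' @param dialect Dialect, as in [read_repeats()].
#' @return A tibble `family`, `n_copies`, sorted by decreasing count.
#' @export
list_families <- function(path, dialect = "auto") {
  read_repeats(path, dialect = dialect) |>
    count(.data$family, name = "n_copies", sort = TRUE)
}

#' @export
print.te_landscape <- function(x, ...) {
  cat("<te_landscape>", length(x$genomes), "genome(s);",
      "families:", paste(x$config$families, collapse = ", "), "\n")
  for (g in x$genomes) {
    cat("  ", g$organism, ": ", nrow(g$tes), " copies, ",
        nrow(g$features_table), " feature-table rows\n", sep = "")
  }
  invisible(x)
}

#' Tidy the result of a landscape run
#'
#' @param x A `te_landscape`.
#' @param ... Unused.
#' @return The master TE-gene feature table over all genomes (one row
#'   per TE-copy/neighbor pair).
#' @export
tidy.te_landscape <- function(x, ...) {
  list_rbind(map(x$genomes, "features_table"))
}

#' One-row summary of a landscape run
#'
#' @param x A `te_landscape`.
#' @param ... Unused.
#' @return A one-row tibble: genome/copy counts and the pooled category
#'   proportions.
#' @export
glance.te_landscape <- function(x, ...) {
  cls <- list_rbind(map(x$genomes, "classified"))
  props <- prop.table(table(factor(cls$category, levels = te_categories)))
  tibble(
    n_genomes = length(x$genomes),
    n_families = length(x$config$families),
    n_copies = nrow(cls),
    n_feature_rows = nrow(tidy(x)),
    prop_within = unname(props["ExonIntronUTR"]),
    prop_promoter = unname(props["ProximalPromoter"]),
    prop_three_prime = unname(props["Proximal3End"]),
    prop_intergenic = unname(props["Intergenic"]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
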