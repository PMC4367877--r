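#' Deterministic synthetic genomes with planted ground truth
#'
#' Generates an annotated genome, TE hit files, and toy ontology
#' resources whose analysis results are known by construction, so the
#' whole pipeline can be exercised without downloads. TE copies are
#' placed constructively, not rejection-sampled: each copy is put at
#' coordinates that realise its intended region category exactly, and
#' genes are spaced widely enough (more than twice the proximal distance
#' plus the largest copy size apart) that the intended nearest gene is
#' always the true nearest gene. Planted category proportions are
#' therefore recovered exactly, with no sampling tolerance.
#'
#' One pseudo-random stream per content kind (gene layout, TE placement,
#' GO assignment), each derived from the single seed, so the same seed
#' and spec always give byte-identical files.
#'
#' @name fixtures
NULL

#' Specification of a synthetic genome
#'
#' Defaults describe the standard test genome: 2 chromosomes of 2 Mb,
#' 100 genes each, three Helitron-like families of 200 copies with sizes
#' 150--1200 bp and similarities 55--100%, and planted category
#' proportions 0.10 within / 0.25 promoter-proximal / 0.25
#' 3'-end-proximal / 0.40 intergenic.
#'
#' @param seed Integer seed; same seed + spec means byte-identical files.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length(s) in bp (recycled).
#' @param genes_per_chrom Genes per chromosome (recycled).
#' @param gene_length Two-element uniform bounds on gene length (bp).
#' @param pseudogene_fraction Fraction of genes planted as pseudogenes.
#' @param families Tibble with columns `name`, `superfamily`, `n_copies`,
#'   `size_min`, `size_max`, `sim_min`, `sim_max`.
#' @param proportions Named numeric, summing to 1: `within`, `promoter`,
#'   `three_prime`, `intergenic`.
#' @param distance Proximal distance D in bp used when planting.
#' @param taxon Taxon id written to the synthetic gene2go.
#' @param go Toy ontology shape: `n_level1`, `n_level2` term counts,
#'   `annotation_prob` per-gene annotation probability, `max_terms`
#'   maximum terms per annotated gene.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 42L,
                           n_chromosomes = 2,
                           chrom_length = 2e6,
                           genes_per_chrom = 100,
                           gene_length = c(1000, 3000),
                           pseudogene_fraction = 0.05,
                           families = NULL,
                           proportions = c(within = 0.10, promoter = 0.25,
                                           three_prime = 0.25, intergenic = 0.40),
                           distance = 3000,
                           taxon = 9001L,
                           go = list(n_level1 = 6, n_level2 = 12,
                                     annotation_prob = 0.8, max_terms = 3)) {
  families <- families %||% tibble(
    name = c("synREP1", "synREP2", "synREP3"),
    superfamily = "Helitron",
    n_copies = 200L, size_min = 150L, size_max = 1200L,
    sim_min = 55, sim_max = 100)
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("planted category proportions must sum to 1")
  }
  if (any(proportions < 0) || any(families$n_copies < 0)) {
    abort("counts and proportions must be non-negative")
  }
  need <- c("within", "promoter", "three_prime", "intergenic")
  if (!all(need %in% names(proportions))) {
    abort(sprintf("proportions must be named: %s", paste(need, collapse = ", ")))
  }
  structure(
    list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
         chrom_length = as.integer(rep_len(chrom_length, n_chromosomes)),
         genes_per_chrom = as.integer(rep_len(genes_per_chrom, n_chromosomes)),
         gene_length = as.integer(gene_length),
         pseudogene_fraction = pseudogene_fraction,
         families = as_tibble(families),
         proportions = proportions[need], distance = distance,
         taxon = as.integer(taxon), go = go),
    class = "synthetic_spec")
}

# integer allocation by largest remainder, preserving sum(n)
.allocate <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.lay_out_genes <- function(spec) {
  max_te <- max(spec$families$size_max)
  min_gap <- 2L * (spec$distance + max_te) + max_te + 600L
  id0 <- 0L
  feats <- list()
  for (ci in seq_len(spec$n_chromosomes)) {
    chrom <- sprintf("Chr%d", ci)
    C <- spec$chrom_length[ci]
    n <- spec$genes_per_chrom[ci]
    if (n == 0) next
    len <- sample(spec$gene_length[1]:spec$gene_length[2], n, replace = TRUE)
    slack <- C - sum(len) - (n + 1L) * min_gap
    if (slack < 0) {
      abort(sprintf(
        "chromosome %s too crowded to place %d genes with clear flanks; use larger chromosomes",
        chrom, n))
    }
    u <- stats::runif(n + 1)
    extra <- floor(slack * u / sum(u))
    extra[n + 1] <- extra[n + 1] + (slack - sum(extra))
    gaps <- min_gap + extra
    starts <- integer(n); pos <- 0L
    for (i in seq_len(n)) {
      pos <- pos + gaps[i]
      starts[i] <- pos + 1L
      pos <- pos + len[i]
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_pseudo <- round(n * spec$pseudogene_fraction)
    kind <- rep("gene", n)
    if (n_pseudo > 0) kind[sample.int(n, n_pseudo)] <- "pseudogene"
    ids <- id0 + seq_len(n)
    id0 <- id0 + n
    g <- tibble(chrom = chrom, start = starts, end = starts + len - 1L,
                strand = strand, kind = kind,
                feature_id = sprintf("SYN%dG%04d", ci, seq_len(n)),
                gene_name = sprintf("SYN%dG%04d", ci, seq_len(n)),
                gene_numeric_id = as.integer(100000L + ids))
    # two exons per gene, flanking an internal gap
    third <- pmax(1L, len %/% 3L)
    ex <- bind_rows(
      mutate(g, kind = "exon", end = .data$start + third - 1L),
      mutate(g, kind = "exon", start = .data$end - third + 1L))
    feats[[ci]] <- bind_rows(g, ex)
  }
  list_rbind(feats)
}

.place_tes <- function(spec, genes) {
  D <- spec$distance
  max_te <- max(spec$families$size_max)
  margin <- D + max_te + 200L
  chrom_tbl <- tibble(chrom = sprintf("Chr%d", seq_len(spec$n_chromosomes)),
                      length = spec$chrom_length)
  genes_sorted <- genes |>
    filter(.data$kind %in% c("gene", "pseudogene")) |>
    arrange(.data$chrom, .data$start)
  g_by_chrom <- split(genes_sorted, genes_sorted$chrom)
  rows <- list()
  for (fi in seq_len(nrow(spec$families))) {
    fam <- spec$families[fi, ]
    n <- fam$n_copies
    if (n == 0) next
    cat_n <- .allocate(n, spec$proportions)
    categories <- rep(c("ExonIntronUTR", "ProximalPromoter", "Proximal3End",
                        "Intergenic"), times = cat_n)
    chroms <- sample(chrom_tbl$chrom, n, replace = TRUE,
                     prob = chrom_tbl$length)
    sizes <- sample(fam$size_min:fam$size_max, n, replace = TRUE)
    sims <- round(stats::runif(n, fam$sim_min, fam$sim_max), 1)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (k in seq_len(n)) {
      ch <- chroms[k]; size <- sizes[k]; cat <- categories[k]
      g <- g_by_chrom[[ch]]
      C <- chrom_tbl$length[chrom_tbl$chrom == ch]
      if (is.null(g) || nrow(g) == 0) {
        if (cat != "Intergenic") {
          abort(sprintf("cannot place a '%s' copy on gene-free %s", cat, ch))
        }
      }
      placed <- switch(cat,
        ExonIntronUTR = {
          host <- which(region_length(g) >= size)
          if (length(host) == 0) {
            abort("no gene long enough to contain a planted copy; enlarge gene_length")
          }
          i <- host[sample.int(length(host), 1)]
          s <- g$start[i] + sample.int(g$end[i] - g$start[i] - size + 2L, 1) - 1L
          list(start = s, gene = i, gap = 0L)
        },
        ProximalPromoter = ,
        Proximal3End = {
          i <- sample.int(nrow(g), 1)
          gap <- sample.int(D + 1L, 1) - 1L
          five_prime_side <- (cat == "ProximalPromoter") == (g$strand[i] != "-")
          s <- if (five_prime_side) g$start[i] - gap - size
               else g$end[i] + gap + 1L
          list(start = s, gene = i, gap = gap)
        },
        Intergenic = {
          ng <- if (is.null(g)) 0L else nrow(g)
          bounds_lo <- c(1L, if (ng > 0) g$end + margin)
          bounds_hi <- c(if (ng > 0) g$start - margin - size, C - size + 1L)
          widths <- pmax(0L, bounds_hi - bounds_lo + 1L)
          if (all(widths == 0)) {
            abort(sprintf("no room for an intergenic copy on %s; use larger chromosomes", ch))
          }
          z <- sample.int(ng + 1L, 1, prob = widths)
          s <- bounds_lo[z] + sample.int(widths[z], 1) - 1L
          list(start = s, gene = NA_integer_, gap = NA_integer_)
        })
      rows[[length(rows) + 1]] <- tibble(
        chrom = ch, start = as.integer(placed$start),
        end = as.integer(placed$start + size - 1L),
        strand = strands[k], family = fam$name,
        superfamily = fam$superfamily, similarity = sims[k],
        source = "planted", score = NA_real_,
        class_hint = paste0("DNA/", fam$superfamily),
        category = cat,
        near_gene = if (is.na(placed$gene)) NA_character_
                    else g$gene_name[placed$gene],
        near_gap = placed$gap)
    }
  }
  tes <- list_rbind(rows)
  if (any(tes$start < 1) || any(tes$end > chrom_tbl$length[match(tes$chrom, chrom_tbl$chrom)])) {
    abort("planted copy falls off the chromosome; use larger chromosomes")
  }
  tes
}

.make_toy_ontology <- function(spec, genes) {
  roots <- tibble(
    id = c("GO:0008150", "GO:0003674", "GO:0005575"),
    name = c("biological_process", "molecular_function", "cellular_component"),
    namespace = c("biological_process", "molecular_function", "cellular_component"),
    parent = NA_character_)
  n1 <- spec$go$n_level1; n2 <- spec$go$n_level2
  lvl1 <- tibble(
    id = sprintf("GO:%07d", 1000000L + seq_len(n1)),
    name = sprintf("broad process %d", seq_len(n1)),
    namespace = roots$namespace[(seq_len(n1) - 1L) %% 3L + 1L],
    parent = roots$id[(seq_len(n1) - 1L) %% 3L + 1L])
  lvl2 <- tibble(
    id = sprintf("GO:%07d", 2000000L + seq_len(n2)),
    name = sprintf("specific process %d", seq_len(n2)),
    namespace = lvl1$namespace[(seq_len(n2) - 1L) %% n1 + 1L],
    parent = lvl1$id[(seq_len(n2) - 1L) %% n1 + 1L])
  terms <- bind_rows(roots, lvl1, lvl2)

  ann_genes <- distinct(filter(genes, .data$kind %in% c("gene", "pseudogene")),
                        .data$gene_numeric_id, .keep_all = TRUE)
  ann <- list()
  for (i in seq_len(nrow(ann_genes))) {
    if (stats::runif(1) <= spec$go$annotation_prob) {
      k <- sample.int(spec$go$max_terms, 1)
      picks <- sample(lvl2$id, min(k, n2))
      ann[[length(ann) + 1]] <- tibble(
        gene_id = ann_genes$gene_numeric_id[i], go_id = picks)
    }
  }
  gene2go <- .bind_features_or(ann, tibble(gene_id = integer(), go_id = character()))
  slim_parent <- setNames(lvl2$parent, lvl2$id)
  list(terms = terms, lvl1 = lvl1, lvl2 = lvl2, gene2go = gene2go,
       slim_parent = slim_parent)
}

# neighbor genes of every planted copy, by direct arithmetic on the layout
.planted_neighbors <- function(tes, genes) {
  out <- vector("list", 0)
  for (ch in unique(tes$chrom)) {
    g <- arrange(filter(genes, .data$chrom == ch), .data$start)
    tt <- filter(tes, .data$chrom == ch)
    if (nrow(g) == 0) next
    li <- findInterval(tt$start - 1L, g$end)           # last gene ending before
    ri <- findInterval(tt$end, g$start) + 1L           # first gene starting after
    for (j in seq_len(nrow(tt))) {
      ids <- c(if (li[j] >= 1) g$gene_numeric_id[li[j]],
               if (ri[j] <= nrow(g)) g$gene_numeric_id[ri[j]],
               if (tt$category[j] == "ExonIntronUTR")
                 g$gene_numeric_id[match(tt$near_gene[j], g$gene_name)])
      out[[length(out) + 1]] <- tibble(family = tt$family[j], gene_id = ids)
    }
  }
  .bind_features_or(out, tibble(family = character(), gene_id = integer()))
}

#' Generate a synthetic genome with planted ground truth
#'
#' Writes, under `out_dir`: `annotation.gb`, `annotation.embl`,
#' `annotation.visualte.tsv`, `repeats.out` (RepeatMasker),
#' `repeats.visualte.tsv`, `gene2go.tsv`, `go.obo`, `slim_toy.txt`
#' (the toy level-1 slim), `superfamilies.tsv` and `ground_truth.json`.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of class `te_simulation`: `paths` (named
#'   file paths), `genome` (the `genome_annotation`), `tes` (planted
#'   copies with `category`, `near_gene`, `near_gap`), `ontology`
#'   (toy DAG pieces) and `ground_truth` (expected summaries: category
#'   counts, per-family frequency, neighbor GO distribution).
#' @examples
#' \donttest{
#' sim <- simulate_te_genome(synthetic_spec(seed = 1, chrom_length = 3e5,
#'                                          genes_per_chrom = 10),
#'                           tempfile("sim"))
#' table(sim$tes$category)
#' }
#' @export
simulate_te_genome <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(spec$proportions[c("within", "promoter", "three_prime")] > 0) &&
      sum(spec$genes_per_chrom) == 0) {
    abort("cannot plant gene-linked categories in a genome with 0 genes")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- withr::with_seed(spec$seed + 1L, .lay_out_genes(spec))
  tes <- withr::with_seed(spec$seed + 2L, .place_tes(spec, genes))
  onto <- withr::with_seed(spec$seed + 3L, .make_toy_ontology(spec, genes))

  genome <- new_genome_annotation(
    organism = "Synthetica exemplaris",
    chromosomes = tibble(chrom = sprintf("Chr%d", seq_len(spec$n_chromosomes)),
                         length = spec$chrom_length),
    features = genes)

  p <- function(f) file.path(out_dir, f)
  paths <- c(genbank = p("annotation.gb"), embl = p("annotation.embl"),
             visualte_annotation = p("annotation.visualte.tsv"),
             repeatmasker = p("repeats.out"),
             visualte_repeats = p("repeats.visualte.tsv"),
             gene2go = p("gene2go.tsv"), obo = p("go.obo"),
             slim = p("slim_toy.txt"), superfamilies = p("superfamilies.tsv"),
             ground_truth = p("ground_truth.json"))
  write_genbank(genome, paths[["genbank"]])
  write_embl(genome, paths[["embl"]])
  write_visualte_annotation(genome, paths[["visualte_annotation"]])
  write_repeatmasker(tes, genome, paths[["repeatmasker"]])
  write_visualte_repeats(tes, paths[["visualte_repeats"]])
  .write_gene2go(onto$gene2go, spec$taxon, paths[["gene2go"]])
  .write_obo(onto$terms, paths[["obo"]])
  writeLines(c("# toy level-1 slim", onto$lvl1$id), paths[["slim"]])
  writeLines(c("# family\tsuperfamily",
               sprintf("%s\t%s", spec$families$name, spec$families$superfamily)),
             paths[["superfamilies"]])

  gt <- .ground_truth(spec, genome, tes, onto)
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(structure(
    list(paths = paths, spec = spec, genome = genome, tes = tes,
         ontology = onto, ground_truth = gt),
    class = "te_simulation"))
}

.ground_truth <- function(spec, genome, tes, onto) {
  genes <- genome$features
  cat_counts <- tes |>
    count(.data$family, .data$category) |>
    tidyr::complete(family = spec$families$name, category = te_categories,
                    fill = list(n = 0L))
  overall <- tes |>
    count(.data$category) |>
    tidyr::complete(category = te_categories, fill = list(n = 0L)) |>
    mutate(proportion = .data$n / sum(.data$n))
  freq <- tes |>
    count(.data$family, .data$chrom) |>
    tidyr::complete(family = spec$families$name,
                    chrom = genome$chromosomes$chrom, fill = list(n = 0L))
  # expected neighbor GO distribution, from layout arithmetic
  nb <- .planted_neighbors(tes, filter(genes, .data$kind %in% c("gene", "pseudogene")))
  slim_sets <- map(split(onto$gene2go$go_id, onto$gene2go$gene_id),
                   ~ unique(unname(onto$slim_parent[.x])))
  tally <- list()
  for (gid in nb$gene_id) {
    terms <- slim_sets[[as.character(gid)]]
    if (is.null(terms)) terms <- "unannotated"
    for (s in terms) tally[[s]] <- (tally[[s]] %||% 0L) + 1L
  }
  go_dist <- tibble(term = names(tally), n = unlist(unname(tally))) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    arrange(desc(.data$proportion), .data$term)
  list(
    organism = genome$organism,
    seed = spec$seed,
    chromosomes = genome$chromosomes,
    n_genes = sum(genes$kind %in% c("gene", "pseudogene")),
    tes = select(tes, "chrom", "start", "end", "strand", "family",
                 "superfamily", "similarity", "category", "near_gene",
                 "near_gap"),
    category_counts = cat_counts,
    category_proportions = overall,
    frequency = freq,
    gene2go = onto$gene2go,
    neighbor_go_distribution = go_dist)
}

# ---- writers ---------------------------------------------------------------

.gb_feature_lines <- function(f, key_width = 16) {
  key <- switch(f$kind, gene = "gene", pseudogene = "gene",
                miscRNA = "misc_RNA", exon = "exon",
                five_prime_UTR = "5'UTR", three_prime_UTR = "3'UTR")
  loc <- sprintf("%d..%d", f$start, f$end)
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  quals <- c(sprintf("/gene=\"%s\"", f$gene_name),
             sprintf("/locus_tag=\"%s\"", f$feature_id))
  if (f$kind == "pseudogene") quals <- c(quals, "/pseudo")
  if (!is.na(f$gene_numeric_id)) {
    quals <- c(quals, sprintf("/db_xref=\"GeneID:%d\"", f$gene_numeric_id))
  }
  c(sprintf("     %-15s %s", key, loc),
    sprintf("                     %s", quals))
}

#' Write a genome annotation as a GenBank flat file
#' @param genome A `genome_annotation`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ci in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$chrom[ci]
    len <- genome$chromosomes$length[ci]
    writeLines(c(
      sprintf("LOCUS       %s %d bp    DNA     linear   UNA 01-JAN-2000",
              ch, len),
      sprintf("DEFINITION  %s chromosome %s, synthetic annotation.",
              genome$organism, ch),
      sprintf("ACCESSION   %s", ch),
      "SOURCE      synthetic",
      sprintf("  ORGANISM  %s", genome$organism),
      "FEATURES             Location/Qualifiers",
      sprintf("     %-15s %s", "source", sprintf("1..%d", len))), con)
    feats <- filter(genome$features, .data$chrom == ch)
    for (i in seq_len(nrow(feats))) {
      writeLines(.gb_feature_lines(feats[i, ]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a genome annotation as an EMBL flat file
#' @inheritParams write_genbank
#' @export
write_embl <- function(genome, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ci in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$chrom[ci]
    len <- genome$chromosomes$length[ci]
    writeLines(c(
      sprintf("ID   %s; SV 1; linear; genomic DNA; STD; UNC; %d BP.", ch, len),
      "XX",
      sprintf("OS   %s", genome$organism),
      "XX",
      "FH   Key             Location/Qualifiers",
      "FH"), con)
    feats <- filter(genome$features, .data$chrom == ch)
    for (i in seq_len(nrow(feats))) {
      gb <- .gb_feature_lines(feats[i, ])
      writeLines(paste0("FT", substring(gb, 3)), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a genome annotation in the native TSV dialect
#' @inheritParams write_genbank
#' @export
write_visualte_annotation <- function(genome, path) {
  strand_out <- function(s) if_else(s == "*", ".", s)
  lines <- c(
    sprintf("#!organism %s", genome$organism),
    "# chrom\tstart\tend\tstrand\tkind\tgene_name\tgene_numeric_id",
    sprintf("%s\t1\t%d\t.\tchromosome\t%s\tNA",
            genome$chromosomes$chrom, genome$chromosomes$length,
            genome$chromosomes$chrom),
    with(genome$features,
         sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s", chrom, start, end,
                 strand_out(strand), kind, gene_name,
                 if_else(is.na(gene_numeric_id), "NA",
                         as.character(gene_numeric_id)))))
  writeLines(lines, path)
  invisible(path)
}

#' Write TE copies as a RepeatMasker .out file
#'
#' Divergence is written as `100 - similarity` with one decimal, so
#' similarities recorded to 0.1% round-trip exactly.
#'
#' @param tes TE-copy tibble.
#' @param genome A `genome_annotation` (for the "(left)" columns); may be
#'   `NULL`, in which case 0 is written.
#' @param path Output path.
#' @export
write_repeatmasker <- function(tes, genome = NULL, path) {
  lens <- if (!is.null(genome)) {
    setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  } else NULL
  header <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  size <- region_length(tes)
  left <- if (!is.null(lens)) lens[tes$chrom] - tes$end else rep(0L, nrow(tes))
  lines <- sprintf(
    "%6.0f %5.1f  0.0  0.0  %-10s %8d %8d (%.0f) %s %-14s %-20s %6d %6d (0) %5d",
    if_else(is.na(tes$score), 1000, tes$score),
    100 - tes$similarity, tes$chrom, tes$start, tes$end, left,
    if_else(tes$strand == "-", "C", "+"), tes$family,
    coalesce(tes$class_hint, "Unknown"), 1L, size, seq_len(nrow(tes)))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write TE copies in the native TSV repeat dialect
#' @param tes TE-copy tibble.
#' @param path Output path.
#' @export
write_visualte_repeats <- function(tes, path) {
  lines <- c(
    "# chrom\tstart\tend\tstrand\tfamily\tsuperfamily\tsimilarity",
    sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
            tes$chrom, tes$start, tes$end,
            if_else(tes$strand == "*", ".", tes$strand),
            tes$family, coalesce(tes$superfamily, "."),
            formatC(tes$similarity, format = "fg")))
  writeLines(lines, path)
  invisible(path)
}

.write_gene2go <- function(gene2go, taxon, path) {
  lines <- c(
    "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
    if (nrow(gene2go) > 0)
      sprintf("%d\t%d\t%s\tIEA\t-\t-\t-\tProcess",
              taxon, gene2go$gene_id, gene2go$go_id))
  writeLines(lines, path)
  invisible(path)
}

.write_obo <- function(terms, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: go-toy"), con)
  for (i in seq_len(nrow(terms))) {
    writeLines(c("", "[Term]",
                 sprintf("id: %s", terms$id[i]),
                 sprintf("name: %s", terms$name[i]),
                 sprintf("namespace: %s", terms$namespace[i]),
                 if (!is.na(terms$parent[i]))
                   sprintf("is_a: %s ! parent", terms$parent[i])), con)
  }
  invisible(path)
}
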