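# shared builders and independent oracles

te_tbl <- function(start, end, chrom = "Chr1", strand = "+", family = "famA",
                   similarity = 90, superfamily = NA_character_,
                   source = "test") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, family = family,
                 superfamily = superfamily, similarity = similarity,
                 source = source, score = NA_real_,
                 class_hint = NA_character_)
}

gene_tbl <- function(start, end, chrom = "Chr1", strand = "+", kind = "gene",
                     name = NULL, id = NULL) {
  n <- length(start)
  name <- name %||% sprintf("g%03d", seq_len(n))
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, kind = kind,
                 feature_id = name, gene_name = name,
                 gene_numeric_id = as.integer(id %||% seq_len(n)))
}

toy_genome <- function(features, lengths = NULL, organism = "toy") {
  chroms <- unique(features$chrom)
  lengths <- lengths %||%
    stats::setNames(sapply(chroms, function(ch)
      max(features$end[features$chrom == ch]) + 10000L), chroms)
  telandscape:::new_genome_annotation(
    organism,
    tibble::tibble(chrom = names(lengths), length = unname(lengths)),
    features)
}

# base-by-base boolean-marking oracle for covered length
union_length_oracle <- function(regions) {
  if (nrow(regions) == 0) return(0L)
  hit <- logical(max(regions$end))
  for (i in seq_len(nrow(regions))) {
    hit[regions$start[i]:regions$end[i]] <- TRUE
  }
  sum(hit)
}

# exhaustive per-copy scan oracle for nearest-gene search
nearest_oracle <- function(te_start, te_end, genes) {
  res <- list(left = NULL, right = NULL, within = integer())
  best_l <- -Inf; best_r <- Inf
  for (i in seq_len(nrow(genes))) {
    gs <- genes$start[i]; ge <- genes$end[i]
    if (gs <= te_end && ge >= te_start) {
      res$within <- c(res$within, i)
    } else if (ge < te_start) {
      if (ge > best_l ||
          (ge == best_l && gs < genes$start[res$left])) {
        best_l <- ge; res$left <- i
      }
    } else if (gs > te_end) {
      if (gs < best_r ||
          (gs == best_r && genes$end[i] < genes$end[res$right])) {
        best_r <- gs; res$right <- i
      }
    }
  }
  res$left_gap <- if (!is.null(res$left)) te_start - best_l - 1L
  res$right_gap <- if (!is.null(res$right)) best_r - te_end - 1L
  res
}

# random non-degenerate gene layouts for property tests
random_genes <- function(n, max_coord = 10000L) {
  s <- sort(sample.int(max_coord - 50L, n))
  gene_tbl(start = s, end = pmin(max_coord, s + sample.int(40L, n)),
           strand = sample(c("+", "-"), n, replace = TRUE))
}

# OBO text for a parent-table DAG (cols: id, parents list; optional name,
# namespace)
write_toy_obo <- function(terms, path = tempfile(fileext = ".obo")) {
  nm <- if ("name" %in% names(terms)) terms$name else terms$id
  ns <- if ("namespace" %in% names(terms)) terms$namespace
        else rep("biological_process", nrow(terms))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(terms))) {
    writeLines(c("", "[Term]", sprintf("id: %s", terms$id[i]),
                 sprintf("name: %s", nm[i]),
                 sprintf("namespace: %s", ns[i]),
                 sprintf("is_a: %s", terms$parents[[i]])), con)
  }
  path
}

go_id <- function(i) sprintf("GO:%07d", i)

# igraph reachability oracle for slim projection
slim_oracle <- function(dag, terms, slim) {
  edges <- purrr::imap(dag$parents, function(p, id) {
    p <- intersect(p, dag$terms$id)
    if (length(p) == 0) NULL else cbind(id, p)
  })
  edges <- do.call(rbind, purrr::compact(edges))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), vertices = dag$terms$id, directed = TRUE)
  reach <- unique(unlist(lapply(intersect(terms, dag$terms$id), function(t)
    names(igraph::subcomponent(g, t, mode = "out")))))
  intersect(slim$terms, reach)
}

small_spec <- function(seed, n_chromosomes = 1, chrom_length = 3e5,
                       genes_per_chrom = 10, n_copies = 30L) {
  synthetic_spec(
    seed = seed, n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    genes_per_chrom = genes_per_chrom,
    families = tibble::tibble(name = c("famA", "famB"),
                              superfamily = "Helitron",
                              n_copies = n_copies, size_min = 150L,
                              size_max = 900L, sim_min = 55, sim_max = 100))
}

.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 7, spec = NULL) {
  key <- paste0("s", seed, if (!is.null(spec)) "custom")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_te_genome(spec %||% small_spec(seed),
                                            tempfile("sim"))
  }
  .sim_cache[[key]]
}
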