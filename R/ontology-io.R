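#' Gene Ontology input and slim projection
#'
#' Loads NCBI `gene2go` mappings and an OBO 1.2 ontology graph, derives
#' the level-based slim vocabularies, and projects detailed annotations
#' onto a slim via the ancestor closure over `is_a` and `part_of` edges.
#'
#' @name ontology_io
NULL

.go_id_re <- "^GO:[0-9]{7}$"

#' Read an NCBI gene2go mapping
#'
#' Expects the NCBI tab-separated layout with columns tax_id, GeneID,
#' GO_ID (further columns ignored); lines starting with `#` are skipped.
#' Duplicate (gene, term) pairs are collapsed.
#'
#' @param path Path to the gene2go file.
#' @param taxon Optional numeric taxon id; when given, only that taxon's
#'   rows are kept.
#' @return A tibble with columns `tax_id`, `gene_id`, `go_id`, of class
#'   `gene_go_map`; the taxon filter is recorded as an attribute.
#' @export
read_gene2go <- function(path, taxon = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^#", lines))
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("%s line %d: expected >= 3 tab-separated columns", path, i))
    }
    if (!grepl(.go_id_re, f[3])) {
      abort(sprintf("%s line %d: malformed GO id '%s'", path, i, f[3]))
    }
    rows[[j]] <- tibble(tax_id = as.integer(f[1]),
                        gene_id = as.integer(f[2]), go_id = f[3])
  }
  out <- if (length(rows) == 0) {
    tibble(tax_id = integer(), gene_id = integer(), go_id = character())
  } else distinct(list_rbind(rows))
  if (!is.null(taxon)) out <- filter(out, .data$tax_id == as.integer(taxon))
  structure(out, class = c("gene_go_map", class(out)), taxon = taxon)
}

#' Read a GO ontology graph from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, keeping id, name, namespace, the obsolete
#' flag, and parent links via `is_a:` and `relationship: part_of`. The
#' parent graph must be acyclic.
#'
#' @param path Path to the OBO file.
#' @return An object of class `go_dag`: list with `terms` (tibble: `id`,
#'   `name`, `namespace`, `obsolete`) and `parents` (named list of parent
#'   id vectors).
#' @export
read_go_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  stanza_starts <- which(grepl("^\\[", lines))
  ids <- character(); names_ <- character(); ns <- character(); obs <- logical()
  parents <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    block <- lines[(s + 1):(if (length(nxt) > 0) min(nxt) - 1 else length(lines))]
    get1 <- function(tag) {
      hit <- grep(paste0("^", tag, ": "), block, value = TRUE)
      if (length(hit) == 0) NA_character_
      else sub(" !.*$", "", sub(paste0("^", tag, ": "), "", hit[1]))
    }
    id <- get1("id")
    if (is.na(id)) next
    isa <- sub(" !.*$", "", sub("^is_a: ", "", grep("^is_a: ", block, value = TRUE)))
    po <- grep("^relationship: part_of ", block, value = TRUE)
    po <- sub(" !.*$", "", sub("^relationship: part_of ", "", po))
    ids <- c(ids, id)
    names_ <- c(names_, get1("name"))
    ns <- c(ns, get1("namespace"))
    obs <- c(obs, identical(get1("is_obsolete"), "true"))
    parents[[id]] <- unique(c(isa, po))
  }
  if (length(ids) == 0) abort(sprintf("%s: no [Term] stanzas found", path))
  dag <- structure(
    list(terms = tibble(id = ids, name = names_, namespace = ns, obsolete = obs),
         parents = parents),
    class = "go_dag")
  .check_acyclic(dag)
  dag
}

# Kahn's algorithm over parent links; cycles are a format error.
.check_acyclic <- function(dag) {
  ids <- dag$terms$id
  par <- map(dag$parents[ids], ~ intersect(.x, ids))
  indeg <- lengths(par)
  children <- new.env(parent = emptyenv())
  for (id in ids) {
    for (p in par[[id]]) {
      assign(p, c(get0(p, envir = children, ifnotfound = character()), id),
             envir = children)
    }
  }
  queue <- ids[indeg == 0]
  seen <- 0L
  indeg <- setNames(indeg, ids)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in get0(v, envir = children, ifnotfound = character())) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) abort("ontology graph contains a cycle")
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag>", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete ),",
      sum(lengths(x$parents)), "parent links\n")
  invisible(x)
}

.dag_roots <- function(dag) {
  known <- dag$terms$id[!dag$terms$obsolete]
  has_parent <- map_int(dag$parents[known],
                        ~ length(intersect(.x, dag$terms$id))) > 0
  known[!has_parent]
}

.dag_children <- function(dag, of) {
  known <- dag$terms$id[!dag$terms$obsolete]
  known[map_int(dag$parents[known], ~ length(intersect(.x, of))) > 0]
}

#' A slim vocabulary (set of broad GO terms)
#'
#' @param terms Character vector of GO term ids.
#' @param name Slim name, e.g. `"GenericEBI"`, `"TreeLevel1"`,
#'   `"TreeLevel2"` or `"custom"`.
#' @param dag Optional `go_dag`; when given, ids absent from the graph are
#'   reported with a warning (and kept, flagged as missing).
#' @return An object of class `slim_set`.
#' @export
slim_set <- function(terms, name = "custom", dag = NULL) {
  terms <- unique(terms)
  if (length(terms) == 0) {
    warn(sprintf("slim '%s' is empty", name))
  }
  bad <- terms[!grepl(.go_id_re, terms)]
  if (length(bad) > 0) {
    abort(sprintf("malformed GO id(s) in slim: %s", paste(bad, collapse = ", ")))
  }
  missing <- character()
  if (!is.null(dag)) {
    missing <- setdiff(terms, dag$terms$id)
    if (length(missing) > 0) {
      warn(sprintf("%d slim term(s) absent from the ontology graph: %s",
                   length(missing), paste(head(missing, 5), collapse = ", ")))
    }
  }
  structure(list(name = name, terms = terms, missing = missing),
            class = "slim_set")
}

#' @export
print.slim_set <- function(x, ...) {
  cat("<slim_set>", x$name, "-", length(x$terms), "terms\n")
  invisible(x)
}

#' Read a slim term list (one GO id per line, `#` comments)
#'
#' @inheritParams slim_set
#' @param path Path to the list file.
#' @export
read_slim_terms <- function(path, name = "custom", dag = NULL) {
  lines <- readLines(path, warn = FALSE)
  ids <- trimws(lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)])
  slim_set(ids, name = name, dag = dag)
}

#' Derive the level-1 or level-2 slim from the ontology tree
#'
#' Level 1 is the set of direct children of the namespace roots (terms
#' with no parents); level 2 the children of level-1 terms, excluding
#' roots and level-1 terms themselves. Obsolete terms never appear.
#'
#' @param dag A `go_dag`.
#' @param level 1 or 2.
#' @return A `slim_set` named `TreeLevel1` or `TreeLevel2`.
#' @export
derive_tree_level_slim <- function(dag, level = 1) {
  stopifnot(level %in% c(1, 2))
  roots <- .dag_roots(dag)
  level1 <- setdiff(.dag_children(dag, roots), roots)
  ids <- if (level == 1) level1 else {
    setdiff(.dag_children(dag, level1), c(roots, level1))
  }
  if (length(ids) == 0) {
    warn(sprintf("TreeLevel%d slim is empty (graph has only roots?)", level))
  }
  structure(list(name = paste0("TreeLevel", level), terms = ids,
                 missing = character()),
            class = "slim_set")
}

#' Ancestor closure of GO terms (including the terms themselves)
#'
#' @param dag A `go_dag`.
#' @param terms Character vector of GO ids.
#' @return Character vector of all ancestors-or-self reachable via
#'   `is_a`/`part_of` parent links. Unknown ids are skipped with a warning.
#' @export
go_ancestors <- function(dag, terms) {
  unknown <- setdiff(terms, dag$terms$id)
  if (length(unknown) > 0) {
    warn(sprintf("skipping %d GO id(s) absent from the ontology graph: %s",
                 length(unknown), paste(head(unknown, 5), collapse = ", ")))
  }
  frontier <- intersect(terms, dag$terms$id)
  seen <- character()
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    up <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(intersect(up, dag$terms$id), seen)
  }
  unique(seen)
}

#' Project GO terms onto a slim
#'
#' Returns every slim term that is an ancestor-or-self of at least one of
#' the input terms.
#'
#' @param dag A `go_dag`.
#' @param terms Character vector of annotated GO ids.
#' @param slim A `slim_set`.
#' @return Character vector of slim term ids (possibly empty).
#' @export
map_to_slim <- function(dag, terms, slim) {
  stopifnot(inherits(slim, "slim_set"))
  if (length(terms) == 0) return(character())
  intersect(slim$terms, go_ancestors(dag, terms))
}

# per-gene slim projection with set semantics: one row per (gene, slim term)
.gene_slim_table <- function(go_map, dag, slim) {
  if (nrow(go_map) == 0) {
    return(tibble(gene_id = integer(), slim_id = character()))
  }
  by_gene <- split(go_map$go_id, go_map$gene_id)
  rows <- imap(by_gene, function(terms, gid) {
    s <- suppressWarnings(map_to_slim(dag, unique(terms), slim))
    if (length(s) == 0) NULL else tibble(gene_id = as.integer(gid), slim_id = s)
  })
  out <- .bind_features_or(rows, tibble(gene_id = integer(), slim_id = character()))
  out
}

.bind_features_or <- function(lst, empty) {
  lst <- compact(lst)
  if (length(lst) == 0) empty else list_rbind(lst)
}

#' Path to the packaged synthetic generic slim
#'
#' The package ships `goslim_generic_synthetic.txt`, a synthetic stand-in
#' for the EBI generic GO-slim list: a curated set of broad, real GO
#' accessions usable as a default slim when no project-specific list is
#' supplied. For faithful work against the current EBI generic slim,
#' download that list and pass it to [read_slim_terms()].
#'
#' @return Path to the packaged file.
#' @export
goslim_generic_synthetic_path <- function() {
  system.file("extdata", "goslim_generic_synthetic.txt",
              package = "telandscape", mustWork = TRUE)
}
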