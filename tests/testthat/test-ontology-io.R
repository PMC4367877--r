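write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# root -> {A, B}; A -> {C}; diamond D under A and B
toy_dag <- function() {
  terms <- tibble::tibble(
    id = c(go_id(1), go_id(2), go_id(3), go_id(4), go_id(5)),
    parents = list(character(), go_id(1), go_id(1), go_id(2),
                   c(go_id(2), go_id(3))))
  read_go_obo(write_toy_obo(terms))
}

test_that("gene2go parses, filters by taxon, and deduplicates", {
  f <- write_tmp(c(
    "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
    "3702\t839580\tGO:0032196\tIEA\t-\ttransposition\t-\tProcess",
    "3702\t839580\tGO:0032196\tISS\t-\ttransposition\t-\tProcess",
    "9606\t1234\tGO:0008150\tIEA\t-\t-\t-\tProcess"))
  m <- read_gene2go(f, taxon = 3702)
  expect_equal(nrow(m), 1)
  expect_equal(m$gene_id, 839580L)
  expect_equal(m$go_id, "GO:0032196")
  expect_equal(nrow(read_gene2go(f, taxon = 9606)), 1)
  expect_equal(nrow(read_gene2go(f)), 2)
  expect_error(read_gene2go(write_tmp("1\t2\tGO:12")), "line 1")
})

test_that("OBO terms, parent links and obsolete flags are read; cycles rejected", {
  dag <- toy_dag()
  expect_equal(nrow(dag$terms), 5)
  expect_setequal(dag$parents[[go_id(5)]], c(go_id(2), go_id(3)))
  cyc <- tibble::tibble(id = c(go_id(1), go_id(2)),
                        parents = list(go_id(2), go_id(1)))
  expect_error(read_go_obo(write_toy_obo(cyc)), "cycle")
})

test_that("tree-level slims are children-of-roots and their children, disjoint", {
  dag <- toy_dag()
  l1 <- derive_tree_level_slim(dag, 1)
  l2 <- derive_tree_level_slim(dag, 2)
  expect_setequal(l1$terms, c(go_id(2), go_id(3)))
  expect_setequal(l2$terms, c(go_id(4), go_id(5)))
  expect_length(intersect(l1$terms, l2$terms), 0)
  roots_only <- read_go_obo(write_toy_obo(tibble::tibble(
    id = go_id(1), parents = list(character()))))
  expect_warning(empty <- derive_tree_level_slim(roots_only, 1), "empty")
  expect_length(empty$terms, 0)
})

test_that("slim projection follows ancestor paths, including diamonds", {
  dag <- toy_dag()
  slimA <- slim_set(go_id(2))
  expect_equal(map_to_slim(dag, go_id(4), slimA), go_id(2))      # single path
  expect_equal(map_to_slim(dag, go_id(2), slimA), go_id(2))      # self
  diamond <- slim_set(c(go_id(2), go_id(3)))
  expect_setequal(map_to_slim(dag, go_id(5), diamond),
                  c(go_id(2), go_id(3)))
  expect_equal(map_to_slim(dag, character(), diamond), character())
  expect_warning(out <- map_to_slim(dag, "GO:9999999", diamond), "absent")
  expect_length(out, 0)
})

test_that("slim projection is monotone in the annotated term set", {
  dag <- toy_dag()
  slim <- slim_set(c(go_id(2), go_id(3)))
  small <- map_to_slim(dag, go_id(4), slim)
  big <- map_to_slim(dag, c(go_id(4), go_id(5)), slim)
  expect_true(all(small %in% big))
})

test_that("slim projection matches igraph reachability on random DAGs", {
  skip_if_not_installed("igraph")
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(5:50, 1)
      parents <- lapply(seq_len(n), function(i) {
        if (i == 1) character()
        else go_id(sample.int(i - 1, min(i - 1, sample.int(2, 1))))
      })
      dag <- read_go_obo(write_toy_obo(
        tibble::tibble(id = go_id(seq_len(n)), parents = parents)))
      slim <- slim_set(go_id(sample.int(n, min(n, 8))))
      terms <- go_id(sample.int(n, min(n, 5)))
      expect_setequal(map_to_slim(dag, terms, slim),
                      slim_oracle(dag, terms, slim))
    }
  })
})

test_that("part_of edges participate in the ancestor closure", {
  obo <- c("format-version: 1.2", "", "[Term]", paste0("id: ", go_id(1)),
           "name: whole", "namespace: biological_process", "",
           "[Term]", paste0("id: ", go_id(2)), "name: part",
           "namespace: biological_process",
           paste0("relationship: part_of ", go_id(1)))
  dag <- read_go_obo(write_tmp(obo, ".obo"))
  expect_setequal(go_ancestors(dag, go_id(2)), c(go_id(1), go_id(2)))
})

test_that("the packaged synthetic generic slim loads as valid GO ids", {
  s <- read_slim_terms(goslim_generic_synthetic_path(),
                       name = "GenericEBI-synthetic")
  expect_gt(length(s$terms), 40)
  expect_true(all(grepl("^GO:[0-9]{7}$", s$terms)))
  expect_true("GO:0032196" %in% s$terms)
})
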