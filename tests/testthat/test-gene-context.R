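test_that("nearest flank genes and gaps match direct arithmetic", {
  genes <- gene_tbl(c(100, 4000), c(400, 6000))
  nb <- nearest_genes(te_tbl(1000, 1500), genes)
  left <- nb[nb$relation == "left", ]
  right <- nb[nb$relation == "right", ]
  expect_equal(left$gene_start, 100L)
  expect_equal(left$gap, 599L)     # 1000 - 400 - 1
  expect_equal(right$gene_start, 4000L)
  expect_equal(right$gap, 2499L)   # 4000 - 1500 - 1
})

test_that("overlapping genes are reported as within, not flanks", {
  genes <- gene_tbl(c(100, 900, 5000), c(400, 2000, 6000))
  nb <- nearest_genes(te_tbl(1000, 1500), genes)
  expect_equal(nb$relation[nb$gene_start == 900], "within")
  expect_equal(nb$gap[nb$relation == "within"], 0L)
  # a spanning gene fully containing the copy
  nb2 <- nearest_genes(te_tbl(1000, 1500), gene_tbl(500, 3000))
  expect_equal(nb2$relation, "within")
})

test_that("no genes means no neighbor rows; unsorted input errors", {
  expect_equal(nrow(nearest_genes(te_tbl(10, 20), gene_tbl(integer(), integer()))), 0)
  expect_error(nearest_genes(te_tbl(10, 20),
                             gene_tbl(c(500, 100), c(900, 300))), "sorted")
})

test_that("nearest-gene search agrees with the exhaustive scan oracle", {
  withr::with_seed(17, {
    for (rep in 1:30) {
      genes <- random_genes(sample.int(15, 1))
      s <- sample.int(9500, 5)
      tes <- te_tbl(s, s + sample.int(300, 5))
      nb <- nearest_genes(tes, genes)
      for (t in seq_len(nrow(tes))) {
        oracle <- nearest_oracle(tes$start[t], tes$end[t], genes)
        got <- nb[nb$te_id == t, ]
        expect_setequal(got$gene_start[got$relation == "within"],
                        genes$start[oracle$within])
        if (is.null(oracle$left)) {
          expect_equal(sum(got$relation == "left"), 0)
        } else {
          expect_equal(got$gap[got$relation == "left"], oracle$left_gap)
        }
        if (is.null(oracle$right)) {
          expect_equal(sum(got$relation == "right"), 0)
        } else {
          expect_equal(got$gap[got$relation == "right"], oracle$right_gap)
        }
      }
    }
  })
})

test_that("the proximal distance rule is inclusive at D and strict above", {
  # forward gene to the right: copy is on its 5' side
  genome_at <- function(gene_start) toy_genome(gene_tbl(gene_start, gene_start + 2000))
  cfg <- proximity_config(distance = 3000)
  at_gap <- function(gap) {
    classify_te(te_tbl(1000, 1500), genome_at(1500 + gap + 1), cfg)$category
  }
  expect_equal(at_gap(2499), "ProximalPromoter")
  expect_equal(at_gap(3000), "ProximalPromoter")
  expect_equal(at_gap(3001), "Intergenic")
})

test_that("strand decides promoter vs 3' end on both flanks", {
  cfg <- proximity_config()
  cls <- function(gene) classify_te(te_tbl(10000, 10500), toy_genome(gene), cfg)$category
  expect_equal(cls(gene_tbl(12000, 14000, strand = "+")), "ProximalPromoter")
  expect_equal(cls(gene_tbl(12000, 14000, strand = "-")), "Proximal3End")
  expect_equal(cls(gene_tbl(7000, 9000, strand = "+")), "Proximal3End")
  expect_equal(cls(gene_tbl(7000, 9000, strand = "-")), "ProximalPromoter")
})

test_that("overlap precedence and the promoter tie-break hold", {
  cfg <- proximity_config()
  # copy overlaps a gene while another is proximal
  g <- dplyr::bind_rows(gene_tbl(900, 1200, name = "in"),
                        gene_tbl(1600, 3000, name = "near"))
  expect_equal(classify_te(te_tbl(1000, 1500), toy_genome(g), cfg)$category,
               "ExonIntronUTR")
  # equal gaps left and right; the right gene (forward) gives promoter
  tie <- dplyr::bind_rows(gene_tbl(1000, 2000, strand = "+", name = "l"),
                          gene_tbl(4001, 5000, strand = "+", name = "r"))
  cls <- classify_te(te_tbl(2501, 3500), toy_genome(tie), cfg)
  expect_equal(cls$category, "ProximalPromoter")
  expect_equal(cls$near_gene_name, "r")
})

test_that("category distribution recovers planted proportions exactly", {
  sim <- cached_sim(7)
  cd <- category_distribution(
    dplyr::select(sim$tes, -category, -near_gene, -near_gap),
    sim$genome)
  gt <- sim$ground_truth$category_proportions
  expect_equal(sum(cd$proportion), 1, tolerance = 1e-12)
  m <- merge(cd, gt, by = "category")
  expect_equal(m$n.x, as.integer(m$n.y))
  empty <- category_distribution(te_tbl(integer(), integer()), sim$genome)
  expect_equal(nrow(empty), 0)
})

test_that("copies on a gene-free chromosome are all intergenic", {
  genome <- telandscape:::new_genome_annotation(
    "toy", tibble::tibble(chrom = "ChrZ", length = 100000L),
    gene_tbl(integer(), integer(), chrom = character()))
  cd <- category_distribution(te_tbl(c(10, 5000), c(200, 5400), chrom = "ChrZ"),
                              genome)
  expect_equal(cd$proportion[cd$category == "Intergenic"], 1)
})

test_that("raising D never demotes proximal copies to intergenic", {
  sim <- cached_sim(7)
  tes <- dplyr::select(sim$tes, -category, -near_gene, -near_gap)
  small <- classify_te(tes, sim$genome, proximity_config(distance = 1000))
  big <- classify_te(tes, sim$genome, proximity_config(distance = 5000))
  was_prox <- small$category %in% c("ProximalPromoter", "Proximal3End")
  expect_false(any(big$category[was_prox] == "Intergenic"))
  expect_identical(small$category == "ExonIntronUTR",
                   big$category == "ExonIntronUTR")
})

test_that("region position histograms bin gap distances from the gene boundary", {
  cls <- tibble::tibble(category = "ProximalPromoter",
                        near_gap = c(0L, 149L, 150L))
  cfg <- proximity_config(distance = 3000, region_bins = 20)
  h <- region_position_histogram(cls, "ProximalPromoter", cfg)
  expect_equal(h$count[1:2], c(2L, 1L))
  expect_equal(sum(h$count), 3)
  all_at_D <- tibble::tibble(category = "Proximal3End",
                             near_gap = rep(3000L, 4))
  h2 <- region_position_histogram(all_at_D, "Proximal3End", cfg)
  expect_equal(h2$count[20], 4L)
  h3 <- region_position_histogram(cls[0, ], "ProximalPromoter", cfg)
  expect_equal(sum(h3$count), 0)
  expect_error(region_position_histogram(cls, "Intergenic", cfg),
               "distance axis")
})

go_fixture <- function(gene_terms) {
  # linear DAG: root(1) -> S1(2), S2(3); leaves 4..5 under S1/S2
  terms <- tibble::tibble(
    id = go_id(1:5),
    parents = list(character(), go_id(1), go_id(1), go_id(2), go_id(3)))
  dag <- read_go_obo(write_toy_obo(terms))
  slim <- slim_set(c(go_id(2), go_id(3)))
  rows <- purrr::imap(gene_terms, function(tt, gid)
    tibble::tibble(tax_id = 1L, gene_id = as.integer(gid), go_id = tt))
  map <- structure(purrr::list_rbind(rows),
                   class = c("gene_go_map", "tbl_df", "tbl", "data.frame"))
  list(dag = dag, slim = slim, map = map)
}

test_that("neighbor GO distributions count slim assignments per gene", {
  fx <- go_fixture(list(`1` = go_id(4)))
  genome <- toy_genome(gene_tbl(5000, 6000, id = 1))
  d <- neighbor_go_distribution(te_tbl(1000, 1500), genome,
                                fx$map, fx$dag, fx$slim)
  expect_equal(d$term, go_id(2))
  expect_equal(d$proportion, 1)

  # two neighbor genes with slim sets {S1} and {S1, S2}
  fx2 <- go_fixture(list(`1` = go_id(4), `2` = c(go_id(4), go_id(5))))
  genome2 <- toy_genome(gene_tbl(c(100, 5000), c(400, 6000), id = c(1, 2)))
  d2 <- neighbor_go_distribution(te_tbl(1000, 1500), genome2,
                                 fx2$map, fx2$dag, fx2$slim)
  expect_equal(d2$proportion[d2$term == go_id(2)], 2 / 3)
  expect_equal(d2$proportion[d2$term == go_id(3)], 1 / 3)
  expect_equal(sum(d2$proportion), 1, tolerance = 1e-12)
})

test_that("genes without GO annotation land in an explicit unannotated bucket", {
  fx <- go_fixture(list(`1` = go_id(4)))
  genome <- toy_genome(gene_tbl(c(100, 5000), c(400, 6000), id = c(1, 99)))
  d <- neighbor_go_distribution(te_tbl(1000, 1500), genome,
                                fx$map, fx$dag, fx$slim)
  expect_setequal(d$term, c(go_id(2), "unannotated"))
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  base <- gene_go_distribution(extract_features(genome, "gene"),
                               fx$map, fx$dag, fx$slim)
  expect_equal(sum(base$proportion), 1, tolerance = 1e-12)
})

test_that("couples are keyed per organism, case-insensitively", {
  row <- function(org, fam = "AtREP1", gene = "geneZ", rel = "left") {
    tibble::tibble(organism = org, te_family = fam, gene_name = gene,
                   relation = rel)
  }
  cc <- count_couples(dplyr::bind_rows(row("O1"), row("O2", gene = "GENEZ")))
  expect_equal(cc$X, 2L)
  cc2 <- count_couples(dplyr::bind_rows(row("O1"), row("O1")))
  expect_equal(cc2$X, 1L)
})

test_that("the feature table has two flank rows plus one per containing gene", {
  cfg <- proximity_config()
  genes2 <- gene_tbl(c(100, 4000), c(400, 6000), id = c(1, 2))
  t2 <- build_feature_table(te_tbl(1000, 1500), toy_genome(genes2), cfg)
  expect_equal(nrow(t2), 2)
  expect_setequal(t2$relation, c("left", "right"))
  genes3 <- dplyr::bind_rows(genes2, gene_tbl(900, 2000, name = "host", id = 3))
  t3 <- build_feature_table(te_tbl(1000, 1500), toy_genome(genes3), cfg)
  expect_equal(nrow(t3), 3)
  expect_equal(sum(t3$relation == "within"), 1)
  expect_equal(unique(t3$region_category), "ExonIntronUTR")
  expect_equal(names(t2), c("organism", "chrom", "te_family", "te_start",
                            "te_end", "te_strand", "superfamily", "similarity",
                            "gene_name", "gene_start", "gene_end",
                            "gene_strand", "relation", "distance",
                            "region_category", "go_terms", "ortholog_X"))
})

test_that("copies on gene-free chromosomes get a placeholder row", {
  genome <- telandscape:::new_genome_annotation(
    "toy", tibble::tibble(chrom = "ChrZ", length = 50000L),
    gene_tbl(integer(), integer(), chrom = character()))
  ft <- build_feature_table(te_tbl(100, 500, chrom = "ChrZ"), genome)
  expect_equal(nrow(ft), 1)
  expect_equal(ft$relation, "none")
  expect_true(is.na(ft$gene_name))
})

test_that("couple counts and the min-organisms filter propagate to tables", {
  cfg <- proximity_config()
  genes <- gene_tbl(c(100, 4000), c(400, 6000), name = c("gA", "gB"))
  g1 <- toy_genome(genes, organism = "O1")
  g2 <- toy_genome(genes, organism = "O2")
  t1 <- build_feature_table(te_tbl(1000, 1500), g1, cfg, organism = "O1")
  t2 <- build_feature_table(te_tbl(1100, 1600), g2, cfg, organism = "O2")
  cc <- count_couples(list(t1, t2))
  expect_true(all(cc$X == 2))
  kept <- annotate_couples(t1, cc, min_organisms = 2)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$ortholog_X == 2))
  none <- annotate_couples(t1, count_couples(t1), min_organisms = 3)
  expect_equal(nrow(none), 0)
})
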