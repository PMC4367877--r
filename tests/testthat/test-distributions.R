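test_that("occurrence curve places copies by midpoint, once each", {
  tes <- te_tbl(c(45, 945), c(55, 955))  # midpoints 50 and 950
  bc <- chromosome_distribution(tes, 1000, n_bins = 10)
  expect_equal(bc$count, c(1L, rep(0L, 8), 1L))
  expect_equal(nrow(bc), 10)
  expect_equal(chromosome_distribution(tes[0, ], 1000, 10)$count, rep(0L, 10))
  expect_error(chromosome_distribution(te_tbl(1, 5, chrom = c("a", "b"),
                                              start = c(1, 1), end = c(5, 5)),
                                       1000, 10), "other chromosome")
})

test_that("occurrence and size histograms conserve the copy count", {
  withr::with_seed(13, {
    s <- sample.int(9000, 100)
    tes <- te_tbl(s, pmin(10000L, s + sample.int(500, 100)))
  })
  expect_equal(sum(chromosome_distribution(tes, 10000, 7)$count), 100)
  expect_equal(sum(size_histogram(tes, 40)$count), 100)
})

test_that("size histogram bin edges are left-closed with right-closed last bin", {
  tes <- te_tbl(c(1, 1, 1), c(100, 100, 900))  # sizes 100, 100, 900
  h <- size_histogram(tes, 2, size_min = 100, size_max = 900)
  expect_equal(h$count, c(2L, 1L))
  one <- size_histogram(te_tbl(1, 500), 1)
  expect_equal(sum(one$count), 1)
  expect_error(size_histogram(tes, 2, size_min = 10, size_max = 5), "size_min")
  # copies outside the range are excluded
  h2 <- size_histogram(tes, 2, size_min = 150, size_max = 1000)
  expect_equal(sum(h2$count), 1)
})

test_that("genome frequency normalises per family and orders by chromosome", {
  feats <- gene_tbl(10, 20)
  genome <- telandscape:::new_genome_annotation(
    "toy", tibble::tibble(chrom = c("Chr1", "Chr2"),
                          length = c(60000L, 40000L)), feats)
  tes <- te_tbl(c(1, 100, 200, 300), c(50, 150, 250, 350),
                chrom = c("Chr1", "Chr1", "Chr1", "Chr2"))
  fr <- genome_frequency(tes, genome)
  expect_equal(unique(fr$chrom_length_pct[fr$chrom == "Chr1"]), 60)
  expect_equal(unique(fr$chrom_length_pct[fr$chrom == "Chr2"]), 40)
  expect_equal(fr$copy_pct, c(75, 25))
  expect_equal(sum(fr$copy_pct), 100, tolerance = 1e-9)
  expect_error(genome_frequency(te_tbl(1, 5, chrom = "ChrX"), genome),
               "ChrX")
})

test_that("frequency percentages sum to 100 per family on random data", {
  withr::with_seed(31, {
    tes <- te_tbl(start = sample.int(5e4, 60), end = sample.int(5e4, 60) + 100,
                  chrom = sample(c("Chr1", "Chr2"), 60, replace = TRUE),
                  family = sample(c("f1", "f2", "f3"), 60, replace = TRUE))
  })
  tes$end <- tes$start + 100L
  genome <- telandscape:::new_genome_annotation(
    "toy", tibble::tibble(chrom = c("Chr1", "Chr2"),
                          length = c(60000L, 60000L)), gene_tbl(10, 20))
  fr <- genome_frequency(tes, genome)
  sums <- tapply(fr$copy_pct, fr$family, sum)
  expect_equal(as.numeric(sums), rep(100, 3), tolerance = 1e-9)
  expect_equal(sum(unique(fr[c("chrom", "chrom_length_pct")])$chrom_length_pct),
               100, tolerance = 1e-9)
})

test_that("coverage proportions use union lengths over the genome", {
  feats <- gene_tbl(c(1, 51), c(100, 150))
  genome <- telandscape:::new_genome_annotation(
    "toy", tibble::tibble(chrom = "Chr1", length = 1000L), feats)
  sp <- size_proportions(genome, te_tbl(1, 10), "gene")
  expect_equal(sp$pct, 15)   # union [1,150] of overlapping genes
  expect_equal(size_proportions(genome, te_tbl(1, 10), "miscRNA")$pct, 0)
  both <- size_proportions(genome, te_tbl(c(1, 1), c(10, 10), family = "famA"),
                           c("famA", "gene", "all_tes"),
                           all_tes = te_tbl(1, 200))
  expect_true(all(both$pct >= 0 & both$pct <= 100))
  expect_equal(both$pct[both$class == "all_tes"], 20)
})

test_that("coverage never increases when features are removed", {
  withr::with_seed(8, {
    s <- sample.int(900, 30)
    feats <- gene_tbl(s, pmin(1000L, s + sample.int(100, 30)))
  })
  genome_all <- telandscape:::new_genome_annotation(
    "toy", tibble::tibble(chrom = "Chr1", length = 1000L), feats)
  genome_half <- telandscape:::new_genome_annotation(
    "toy", tibble::tibble(chrom = "Chr1", length = 1000L), feats[1:15, ])
  p_all <- size_proportions(genome_all, te_tbl(1, 5), "gene")$pct
  p_half <- size_proportions(genome_half, te_tbl(1, 5), "gene")$pct
  expect_lte(p_half, p_all)
  expect_lte(p_all, 100)
})

test_that("uniformly placed copies give multinomial-consistent bin counts", {
  n_bins <- 10; n <- 200
  pvals <- sapply(1:20, function(seed) {
    withr::with_seed(seed, {
      mid <- sample.int(100000, n)
      tes <- te_tbl(mid, mid)  # degenerate 1-bp copies at the midpoint
    })
    counts <- chromosome_distribution(tes, 100000, n_bins)$count
    suppressWarnings(chisq.test(counts, p = rep(1 / n_bins, n_bins))$p.value)
  })
  expect_true(all(pvals > 0.001))
})
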