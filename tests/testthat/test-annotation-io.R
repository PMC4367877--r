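minimal_gb <- function(features = "     gene            100..400",
                       quals = '                     /locus_tag="g1"') {
  c("LOCUS       Chr1 5000 bp    DNA     linear   UNA 01-JAN-2000",
    "DEFINITION  toy record.",
    "SOURCE      toy",
    "  ORGANISM  Toyus minimus",
    "FEATURES             Location/Qualifiers",
    features, quals, "//")
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("a minimal GenBank record parses with length, organism and one gene", {
  g <- read_annotation(write_tmp(minimal_gb()), dialect = "genbank")
  expect_equal(g$chromosomes$chrom, "Chr1")
  expect_equal(g$chromosomes$length, 5000)
  expect_equal(g$organism, "Toyus minimus")
  expect_equal(nrow(g$features), 1)
  expect_equal(g$features$kind, "gene")
  expect_equal(g$features$start, 100L)
  expect_equal(g$features$end, 400L)
  expect_equal(g$features$strand, "+")
})

test_that("the same content in EMBL dialect yields an identical annotation", {
  embl <- c("ID   Chr1; SV 1; linear; genomic DNA; STD; UNC; 5000 BP.",
            "OS   Toyus minimus",
            "FH   Key             Location/Qualifiers",
            "FT   gene            100..400",
            'FT                   /locus_tag="g1"',
            "//")
  a <- read_annotation(write_tmp(minimal_gb()), dialect = "genbank")
  b <- read_annotation(write_tmp(embl), dialect = "embl")
  expect_equal(a$features, b$features)
  expect_equal(a$chromosomes, b$chromosomes)
  expect_equal(a$organism, b$organism)
})

test_that("complement locations give reverse strand with unchanged coordinates", {
  g <- read_annotation(write_tmp(minimal_gb(
    "     gene            complement(200..900)")), dialect = "genbank")
  expect_equal(g$features$strand, "-")
  expect_equal(c(g$features$start, g$features$end), c(200L, 900L))
})

test_that("join locations flatten to the span plus per-segment exons", {
  g <- read_annotation(write_tmp(minimal_gb(
    "     gene            join(100..200,400..600)")), dialect = "genbank")
  expect_equal(g$features$kind, c("gene", "exon", "exon"))
  expect_equal(g$features$start[g$features$kind == "gene"], 100L)
  expect_equal(g$features$end[g$features$kind == "gene"], 600L)
  expect_equal(g$features$start[g$features$kind == "exon"], c(100L, 400L))
})

test_that("pseudo qualifier, GeneID db_xref and misc_RNA key are recognised", {
  gb <- c("LOCUS       Chr1 9000 bp    DNA     linear   UNA 01-JAN-2000",
          "FEATURES             Location/Qualifiers",
          "     gene            100..400",
          '                     /locus_tag="p1"',
          "                     /pseudo",
          "     gene            1000..2000",
          '                     /gene="abc"',
          '                     /db_xref="GeneID:839580"',
          "     misc_RNA        3000..3100",
          '                     /locus_tag="r1"',
          "//")
  g <- read_annotation(write_tmp(gb), dialect = "genbank")
  expect_equal(g$features$kind, c("pseudogene", "gene", "miscRNA"))
  expect_equal(g$features$gene_numeric_id, c(NA, 839580L, NA))
  expect_equal(g$features$gene_name[2], "abc")
})

test_that("an empty feature table gives a chromosome with zero features", {
  gb <- c("LOCUS       Chr9 1234 bp    DNA     linear   UNA 01-JAN-2000",
          "FEATURES             Location/Qualifiers", "//")
  g <- read_annotation(write_tmp(gb), dialect = "genbank")
  expect_equal(nrow(g$features), 0)
  expect_equal(g$chromosomes$length, 1234)
})

test_that("header and coordinate errors are reported with context", {
  expect_error(read_annotation(write_tmp(c("LOCUS garbage", "//")),
                               dialect = "genbank"), "LOCUS")
  expect_error(read_annotation(write_tmp(minimal_gb(
    "     gene            400..100")), dialect = "genbank"), "end")
  expect_error(read_annotation(tempfile(), dialect = "genbank"), "not found")
})

test_that("dialect auto-detection distinguishes the three formats", {
  gb <- write_tmp(minimal_gb())
  expect_equal(read_annotation(gb)$chromosomes$chrom, "Chr1")
  tsv <- write_tmp(c("#!organism toy",
                     "Chr2\t1\t8000\t.\tchromosome\tChr2\tNA",
                     "Chr2\t10\t50\t+\tgene\tgX\t77"))
  g <- read_annotation(tsv)
  expect_equal(g$chromosomes$length, 8000)
  expect_equal(g$features$gene_numeric_id, 77L)
})

test_that("extract_features selects kinds, sorted, and validates kind names", {
  feats <- dplyr::bind_rows(
    gene_tbl(c(500, 100), c(900, 300), name = c("b", "a")),
    gene_tbl(c(50, 700, 120), c(80, 820, 200), kind = "exon",
             name = c("e1", "e2", "e3")))
  g <- toy_genome(feats)
  genes <- extract_features(g, "gene")
  expect_equal(genes$gene_name, c("a", "b"))
  expect_false(is.unsorted(genes$start))
  expect_equal(nrow(extract_features(g, te_feature_kinds)), 5)
  expect_equal(nrow(extract_features(g, "five_prime_UTR")), 0)
  expect_error(extract_features(g, "enhancer"), "valid")
})

test_that("multi-record files give one chromosome per record with unique ids", {
  two <- c(minimal_gb(),
           sub("Chr1", "Chr2", minimal_gb()))
  g <- read_annotation(write_tmp(two), dialect = "genbank")
  expect_equal(g$chromosomes$chrom, c("Chr1", "Chr2"))
  expect_equal(nrow(g$features), 2)
})
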