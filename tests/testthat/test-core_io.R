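test_that("expression bundle round-trips through TSV files", {
  dir <- withr::local_tempdir()
  sim <- generate_bundle(sim_config(n_genes = 50, n_mirnas = 10, rng_seed = 3))
  paths <- file.path(dir, c("v.tsv", "d.tsv", "s.tsv"))
  write_expression_bundle(sim$mrna, paths[1], paths[2], paths[3])
  back <- read_expression_bundle(paths[1], paths[2], paths[3], "gene")
  expect_equal(back$values, sim$mrna$values, tolerance = 1e-12)
  expect_identical(back$detection, sim$mrna$detection)
  expect_identical(
    dplyr::arrange(back$design, sample_id),
    dplyr::arrange(sim$mrna$design, sample_id)
  )
  expect_identical(back$scale, "raw")
})

test_that("bundle construction enforces pairing, dimensions and unique ids", {
  v <- matrix(1:8 + 0, 2, 4,
    dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4"))
  )
  d <- matrix(TRUE, 2, 4, dimnames = dimnames(v))
  design <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    patient_id = c("P1", "P1", "P2", "P2"),
    tissue = c("tumor", "normal", "tumor", "normal")
  )
  b <- expression_bundle(v, d, design)
  expect_s3_class(b, "expression_bundle")
  expect_equal(nrow(bundle_pairs(b)), 2)

  bad <- design
  bad$tissue <- c("tumor", "tumor", "tumor", "normal") # P1 twice tumor
  expect_error(expression_bundle(v, d, bad), "unpaired design")
  expect_error(expression_bundle(v, d[, 1:3], design), "dimension mismatch")
  v2 <- v; rownames(v2) <- c("g1", "G1") # collide after normalization
  expect_error(expression_bundle(v2, d, design), "duplicate feature ids")
  v3 <- v; v3[1, 1] <- 0
  expect_error(expression_bundle(v3, d, design), "strictly positive")
})

test_that("target pair reader de-duplicates, handles headers, empties and bad rows", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "pairs.tsv")
  writeLines(c("hsa-miR-1\tTP53", "hsa-mir-1\ttp53", "hsa-miR-2\tKRAS"), f)
  map <- suppressMessages(read_target_pairs(f, "toy"))
  expect_equal(nrow(map), 2) # duplicate collapses after normalization
  expect_identical(predictor_label(map), "toy")

  writeLines(c("mirna_id\tgene_id", "hsa-miR-1\tTP53"), f)
  expect_equal(nrow(suppressMessages(read_target_pairs(f, "toy"))), 1)

  writeLines(character(0), f)
  expect_warning(m0 <- read_target_pairs(f, "toy"), "empty")
  expect_equal(nrow(m0), 0)

  writeLines(c("hsa-miR-1\tTP53", "brokenrow"), f)
  expect_error(read_target_pairs(f, "toy"), "line 2")
})

test_that("generator-emitted pair tables round-trip losslessly", {
  dir <- withr::local_tempdir()
  sim <- generate_bundle(sim_config(n_genes = 300, n_mirnas = 60, rng_seed = 5))
  f <- file.path(dir, "pairs.tsv")
  write_target_pairs(sim$targets, f)
  back <- suppressMessages(read_target_pairs(f, "planted"))
  key <- function(m) sort(paste(m$mirna_id, m$gene_id))
  expect_identical(key(back), key(sim$targets))
})

test_that("FASTA promoter reader normalizes, validates and round-trips", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "prom.fa")
  writeLines(c(">geneA", "acgtacgt", ">geneB", "NNACGT"), f)
  tab <- read_fasta_promoters(f)
  expect_identical(tab$gene_id, c("GENEA", "GENEB"))
  expect_identical(tab$sequence[1], "ACGTACGT")
  expect_identical(unique(tab$cpg_class), "unclassified")

  writeLines(c(">geneA", "ACGT", ">GENEA", "TTTT"), f)
  expect_error(read_fasta_promoters(f), "duplicate")

  proms <- generate_promoters(sim_config(
    promoter_counts = c(HCG = 2, ICG = 2, LCG = 2), rng_seed = 2
  ))
  write_fasta_promoters(proms, f)
  back <- read_fasta_promoters(f)
  expect_identical(back$sequence, proms$sequence)
  expect_identical(back$gene_id, proms$gene_id)
})

test_that("identifier normalization is idempotent and joins readers consistently", {
  x <- c(" hsa-miR-96 ", "HSA-MIR-96")
  expect_identical(normalize_mirna_id(x), c("hsa-mir-96", "hsa-mir-96"))
  expect_identical(
    normalize_mirna_id(normalize_mirna_id(x)), normalize_mirna_id(x)
  )
  g <- c(" tp53", "Tp53 ")
  expect_identical(normalize_gene_id(g), c("TP53", "TP53"))
  expect_identical(normalize_gene_id(normalize_gene_id(g)), normalize_gene_id(g))
})

test_that("detection p-values convert to boolean calls at the threshold", {
  p <- matrix(c(0.01, 0.05, 0.049, NA), 2, 2)
  d <- detection_from_pvalues(p, 0.05)
  expect_identical(as.vector(d), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(detection_from_pvalues(matrix(1.2)), "\\[0, 1\\]")
})
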