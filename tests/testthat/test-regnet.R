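toy_map <- function(pairs, label = "toy") {
  target_map(
    tibble::tibble(
      mirna_id = vapply(pairs, `[[`, character(1), 1),
      gene_id = vapply(pairs, `[[`, character(1), 2)
    ),
    label
  )
}

test_that("restriction to expressed genes matches a brute-force set filter", {
  map <- toy_map(list(
    c("hsa-mir-1", "G1"), c("hsa-mir-1", "G2"), c("hsa-mir-2", "G2")
  ))
  out <- restrict_to_expressed(map, "G1")
  expect_identical(out$gene_id, "G1")
  expect_identical(out$mirna_id, "hsa-mir-1") # mir-2 lost all targets

  expect_equal(nrow(restrict_to_expressed(map, character(0))), 0)

  set.seed(31)
  for (i in 1:5) {
    pairs <- tibble::tibble(
      mirna_id = sprintf("hsa-mir-%d", sample(1:10, 200, TRUE)),
      gene_id = sprintf("G%03d", sample(1:100, 200, TRUE))
    )
    map <- target_map(pairs, "rand")
    expressed <- sprintf("G%03d", sample(1:100, 40))
    got <- restrict_to_expressed(map, expressed)
    want <- dplyr::filter(tibble::as_tibble(map), gene_id %in% expressed)
    expect_identical(
      sort(paste(got$mirna_id, got$gene_id)),
      sort(paste(want$mirna_id, want$gene_id))
    )
  }
})

test_that("pair overlap reports shared counts and percentages of each predictor", {
  a <- toy_map(list(c("m1", "G1"), c("m1", "G2"), c("m2", "G3")), "a")
  b <- toy_map(list(c("m1", "G2"), c("m2", "G3"), c("m2", "G4")), "b")
  ov <- pair_overlap(a, b)
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$pct_of_a, percent_of(2, 3))

  same <- pair_overlap(a, a)
  expect_equal(same$pct_of_a, 100)
  expect_equal(same$pct_of_b, 100)

  disj <- pair_overlap(a, toy_map(list(c("m9", "G9")), "c"))
  expect_equal(disj$n_shared, 0)
  expect_equal(disj$pct_of_a, 0)

  expect_error(
    pair_overlap(a, toy_map(list(), "empty")),
    "non-empty"
  )
})

test_that("regulation values follow the variation-over-targets formula", {
  expect_equal(mirna_regulation_value(2, 4), 0.5)
  expect_equal(mirna_regulation_value(-1.5, 3), -0.5)
  expect_error(mirna_regulation_value(1, 0), "no expressed targets")

  expect_equal(gene_regulation_value(0.5), 0.5)
  expect_equal(gene_regulation_value(c(0.5, -0.5)), 0)
  expect_true(is.na(gene_regulation_value(numeric(0))))
})

test_that("gene classification follows the sign-concordance rule", {
  expect_identical(classify_gene(0.3, "down"), "anti_correlated")
  expect_identical(classify_gene(0.3, "up"), "correlated")
  expect_identical(classify_gene(-0.3, "up"), "anti_correlated")
  expect_identical(classify_gene(-0.3, "down"), "correlated")
  expect_identical(classify_gene(NA_real_, "up"), "others")
  expect_identical(classify_gene(0, "down"), "others")
  expect_identical(classify_gene(0.05, "up", epsilon = 0.1), "others")
  expect_error(classify_gene(1, "sideways"), "direction")
})

test_that("classification depends only on signs: scaling delta_e changes nothing", {
  set.seed(41)
  mirna_de <- tibble::tibble(
    feature_id = sprintf("hsa-mir-%d", 1:6),
    direction = sample(c("up", "down"), 6, TRUE),
    mean_delta = rnorm(6, sd = 2)
  )
  mirna_de$mean_delta <- abs(mirna_de$mean_delta) *
    ifelse(mirna_de$direction == "up", 1, -1)
  gene_de <- tibble::tibble(
    feature_id = sprintf("G%03d", 1:30),
    direction = sample(c("up", "down"), 30, TRUE),
    mean_delta = rnorm(30)
  )
  pairs <- tibble::tibble(
    mirna_id = sample(mirna_de$feature_id, 60, TRUE),
    gene_id = sample(gene_de$feature_id, 60, TRUE)
  )
  map <- target_map(pairs, "rand")
  expressed <- gene_de$feature_id

  base <- gene_regulation(
    gene_de, mirna_regulation(mirna_de, map, expressed), map
  )
  scaled_de <- dplyr::mutate(mirna_de, mean_delta = mean_delta * 7.3)
  scaled <- gene_regulation(
    gene_de, mirna_regulation(scaled_de, map, expressed), map
  )
  expect_identical(base$reg_class, scaled$reg_class)
})

test_that("summary table partitions the DE set and reproduces printed percentages", {
  gene_reg <- tibble::tibble(
    gene_id = sprintf("G%04d", 1:1878),
    direction = c(rep("up", 581), rep("down", 1297)),
    reg_class = c(
      rep("anti_correlated", 26), rep("correlated", 50), rep("others", 505),
      rep("anti_correlated", 171), rep("correlated", 140), rep("others", 986)
    )
  )
  s <- classification_summary(gene_reg)
  expect_equal(sum(s$n_total), 1878)
  expect_equal(sum(s$n_up), 581)
  expect_equal(sum(s$n_down), 1297)
  anti <- s[s$reg_class == "anti_correlated", ]
  expect_equal(anti$pct_down, 13.18)
  expect_equal(anti$pct_up, 4.48)
  expect_equal(s$pct_down[s$reg_class == "correlated"], 10.79)
  expect_equal(s$pct_up[s$reg_class == "others"], 86.92)
  expect_equal(s$pct_down[s$reg_class == "others"], 76.02)

  toy <- tibble::tibble(
    gene_id = sprintf("G%d", 1:5),
    direction = c("up", "up", "down", "down", "down"),
    reg_class = "others"
  )
  st <- classification_summary(toy)
  expect_equal(st$n_total[st$reg_class == "others"], 5)
  expect_equal(st$pct_up[st$reg_class == "others"], 100)
  expect_equal(st$pct_down[st$reg_class == "others"], 100)

  bad <- toy; bad$reg_class[1] <- NA
  expect_error(classification_summary(bad), "unclassified")
})

test_that("planted repression with zero noise classifies every target anti-correlated", {
  sim <- generate_bundle(sim_config(
    n_genes = 400, n_mirnas = 40, noise_sd = 0, rng_seed = 23
  ))
  fit_g <- suppressMessages(diff_expression(sim$mrna))
  fit_m <- suppressMessages(diff_expression(sim$mirna))
  expressed <- rownames(detection_filter(sim$mrna)$values)
  mr <- mirna_regulation(tidy(fit_m), sim$targets, expressed)
  gr <- gene_regulation(tidy(fit_g), mr, sim$targets)
  planted <- sim$truth$genes[sim$truth$genes$planted_class == "anti_correlated", ]
  got <- gr[gr$gene_id %in% planted$gene_id, ]
  expect_equal(nrow(got), nrow(planted))
  expect_true(all(got$reg_class == "anti_correlated"))
})
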