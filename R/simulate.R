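#' Configuration for the synthetic paired-study generator
#'
#' The generator emulates a small paired tumor/normal microarray study: six
#' patient pairs, log-normal baseline intensities, Gaussian noise on the log2
#' scale, a planted set of consistently shifted genes and miRNAs, and a
#' planted bipartite repression network in which each differentially
#' expressed miRNA shifts its targets in the opposite direction, scaled by
#' `repression_effect / t` for a miRNA with `t` targets (so target shifts
#' mirror the regulation-value statistic).
#'
#' @param n_patients Number of tumor/normal pairs (default 6).
#' @param n_genes,n_mirnas Feature counts (defaults 2000 and 150).
#' @param frac_genes_up,frac_genes_down Fractions of genes planted with a
#'   consistent up/down shift (defaults 0.03 / 0.06, echoing the roughly
#'   1:2 up:down imbalance seen in paired tumor studies).
#' @param frac_mirnas_up,frac_mirnas_down Fractions of miRNAs planted
#'   up/down (defaults 0.08 each).
#' @param targets_per_mirna Integer range (length 2) of expressed targets
#'   drawn per planted miRNA (default `c(3, 8)`).
#' @param de_effect Log2 shift magnitude of planted differential features
#'   (default 2, i.e. four-fold).
#' @param repression_effect Log2 target shift per unit regulator shift,
#'   before division by the regulator's target count (default 2).
#' @param noise_sd Gaussian noise sd on the log2 scale (default 0.1).
#' @param baseline_log2_mean,baseline_log2_sd Baseline intensity
#'   distribution on the log2 scale (defaults 8 and 2).
#' @param frac_undetected Fraction of genes planted below the detection
#'   floor in every sample (default 0.02).
#' @param detect_floor_log2 Detection floor on the log2 scale (default 2).
#' @param planted_term_size Size of the planted annotation term
#'   (default 100).
#' @param planted_enrichment_fraction Fraction of the planted term drawn
#'   from the planted up-regulated genes (default 0.5).
#' @param n_terms Total number of annotation terms (default 20).
#' @param promoter_counts Named integer vector of promoters to generate per
#'   CpG class (default 20 of each of HCG, ICG, LCG).
#' @param rng_seed Integer seed; identical seeds give identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 6, n_genes = 2000, n_mirnas = 150,
                       frac_genes_up = 0.03, frac_genes_down = 0.06,
                       frac_mirnas_up = 0.08, frac_mirnas_down = 0.08,
                       targets_per_mirna = c(3, 8),
                       de_effect = 2, repression_effect = 2, noise_sd = 0.1,
                       baseline_log2_mean = 8, baseline_log2_sd = 2,
                       frac_undetected = 0.02, detect_floor_log2 = 2,
                       planted_term_size = 100,
                       planted_enrichment_fraction = 0.5, n_terms = 20,
                       promoter_counts = c(HCG = 20, ICG = 20, LCG = 20),
                       rng_seed = 17L) {
  fracs <- c(frac_genes_up, frac_genes_down, frac_mirnas_up, frac_mirnas_down,
             frac_undetected, planted_enrichment_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1].")
  if (n_patients < 2 || n_genes < 1 || n_mirnas < 1) {
    abort("counts must be positive (and n_patients >= 2).")
  }
  if (length(targets_per_mirna) != 2 || targets_per_mirna[1] < 1 ||
      targets_per_mirna[2] < targets_per_mirna[1]) {
    abort("`targets_per_mirna` must be an increasing integer range of length 2.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    as.list(environment()),
    class = "sim_config"
  )
}

sim_gene_ids <- function(n) sprintf("GENE%05d", seq_len(n))
sim_mirna_ids <- function(n) sprintf("hsa-mir-%04d", seq_len(n))

# planted shifts, slightly jittered in magnitude, fixed in sign
planted_shifts <- function(n_up, n_down, n_total, effect) {
  s <- numeric(n_total)
  if (n_up > 0) s[seq_len(n_up)] <- effect * runif(n_up, 0.8, 1.25)
  if (n_down > 0) s[n_up + seq_len(n_down)] <- -effect * runif(n_down, 0.8, 1.25)
  s
}

build_bundle <- function(ids, baseline, shift, config, feature_type) {
  n_pat <- config$n_patients
  patients <- sprintf("P%02d", seq_len(n_pat))
  samples <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  tumor <- outer(baseline + shift, rep(1, n_pat)) +
    matrix(rnorm(length(ids) * n_pat, 0, config$noise_sd), ncol = n_pat)
  normal <- outer(baseline, rep(1, n_pat)) +
    matrix(rnorm(length(ids) * n_pat, 0, config$noise_sd), ncol = n_pat)
  log2v <- cbind(tumor, normal)
  dimnames(log2v) <- list(ids, samples)
  detection <- log2v >= config$detect_floor_log2
  design <- tibble::tibble(
    sample_id = samples,
    patient_id = rep(patients, 2),
    tissue = rep(c("tumor", "normal"), each = n_pat)
  )
  expression_bundle(2^log2v, detection, design,
    scale = "raw", feature_type = feature_type
  )
}

#' Generate a synthetic paired study with a planted regulatory network
#'
#' Produces paired tumor/normal mRNA and miRNA bundles, a miRNA-target map,
#' and truth tables describing what was planted. Planted differential genes
#' and miRNAs receive a consistent log2 shift in every tumor sample; each
#' planted miRNA additionally represses a drawn set of target genes, shifting
#' them by `-repression_effect * shift / t` per edge, so those targets are
#' anti-correlated with their regulators by construction. Truth tables are
#' derived from the realized edges and are never consumed by the analysis.
#'
#' @param config A [sim_config()].
#' @return A list: `mrna` and `mirna` (`expression_bundle`s), `targets`
#'   (`target_map`, label `"planted"`), and `truth` (list of tibbles
#'   `genes`, `mirnas`, `edges`).
#' @export
generate_bundle <- function(config = sim_config()) {
  set.seed(config$rng_seed)
  n_g <- config$n_genes
  n_m <- config$n_mirnas
  gene_ids <- sim_gene_ids(n_g)
  mirna_ids <- sim_mirna_ids(n_m)

  n_g_up <- round(config$frac_genes_up * n_g)
  n_g_down <- round(config$frac_genes_down * n_g)
  n_m_up <- round(config$frac_mirnas_up * n_m)
  n_m_down <- round(config$frac_mirnas_down * n_m)
  n_undet <- round(config$frac_undetected * n_g)

  gene_shift <- planted_shifts(n_g_up, n_g_down, n_g, config$de_effect)
  mirna_shift <- planted_shifts(n_m_up, n_m_down, n_m, config$de_effect)

  # gene index layout: [up | down | target pool | free | undetected at end]
  n_de <- n_g_up + n_g_down
  de_mirna_idx <- seq_len(n_m_up + n_m_down)
  t_range <- config$targets_per_mirna
  pool_size <- min(
    max(2 * (n_m_up + n_m_down) * t_range[2], t_range[2]),
    n_g - n_de - n_undet
  )
  pool_idx <- n_de + seq_len(pool_size)
  undet_idx <- if (n_undet > 0) n_g - n_undet + seq_len(n_undet) else integer(0)

  edges <- purrr::map_dfr(de_mirna_idx, function(m) {
    t_m <- sample(seq(t_range[1], t_range[2]), 1)
    t_m <- min(t_m, length(pool_idx))
    tibble::tibble(
      mirna_id = mirna_ids[m],
      gene_idx = sample(pool_idx, t_m),
      t_expressed = t_m,
      regulator_shift = mirna_shift[m]
    )
  })
  # repression: target shift opposite in sign to its regulator's shift
  per_gene <- edges |>
    dplyr::group_by(.data$gene_idx) |>
    dplyr::summarise(
      shift = -config$repression_effect *
        sum(.data$regulator_shift / .data$t_expressed),
      true_R = sum(.data$regulator_shift / .data$t_expressed)
    )
  gene_shift[per_gene$gene_idx] <- per_gene$shift

  # decoy edges from non-variable miRNAs to free genes: present in the target
  # map but carrying no expression signal
  free_idx <- setdiff(seq_len(n_g), c(seq_len(n_de), pool_idx, undet_idx))
  null_mirnas <- setdiff(seq_len(n_m), de_mirna_idx)
  decoys <- purrr::map_dfr(null_mirnas, function(m) {
    t_m <- sample(seq(t_range[1], t_range[2]), 1)
    tibble::tibble(
      mirna_id = mirna_ids[m],
      gene_idx = sample(free_idx, min(t_m, length(free_idx)))
    )
  })

  baseline <- rnorm(n_g, config$baseline_log2_mean, config$baseline_log2_sd)
  # planted variable features live in the upper intensity stratum: they are
  # well-measured, and neither they nor their shifted values cross the null
  # median, so array medians stay comparable across tissues
  planted_g <- unique(c(seq_len(n_de), per_gene$gene_idx))
  baseline[planted_g] <- runif(
    length(planted_g),
    config$baseline_log2_mean + 3.5, config$baseline_log2_mean + 5.5
  )
  if (n_undet > 0) {
    baseline[undet_idx] <- rnorm(n_undet, config$detect_floor_log2 - 4, 0.3)
    gene_shift[undet_idx] <- 0
  }
  mirna_baseline <- rnorm(n_m, config$baseline_log2_mean, config$baseline_log2_sd)
  planted_m <- which(mirna_shift != 0)
  mirna_baseline[planted_m] <- runif(
    length(planted_m),
    config$baseline_log2_mean + 3.5, config$baseline_log2_mean + 5.5
  )

  mrna <- build_bundle(gene_ids, baseline, gene_shift, config, "gene")
  mirna <- build_bundle(mirna_ids, mirna_baseline, mirna_shift, config, "mirna")

  all_edges <- dplyr::bind_rows(
    dplyr::transmute(edges,
      mirna_id = .data$mirna_id, gene_id = gene_ids[.data$gene_idx]
    ),
    dplyr::transmute(decoys,
      mirna_id = .data$mirna_id, gene_id = gene_ids[.data$gene_idx]
    )
  )
  targets <- target_map(all_edges, "planted")

  truth_genes <- tibble::tibble(
    gene_id = normalize_gene_id(gene_ids),
    planted_direction = dplyr::case_when(
      gene_shift > 0 ~ "up",
      gene_shift < 0 ~ "down",
      TRUE ~ "none"
    ),
    planted_class = dplyr::case_when(
      seq_len(n_g) %in% per_gene$gene_idx & gene_shift != 0 ~ "anti_correlated",
      gene_shift != 0 ~ "others",
      TRUE ~ "none"
    ),
    detected = !(seq_len(n_g) %in% undet_idx)
  )
  truth_mirnas <- tibble::tibble(
    mirna_id = normalize_mirna_id(mirna_ids),
    planted_direction = dplyr::case_when(
      mirna_shift > 0 ~ "up",
      mirna_shift < 0 ~ "down",
      TRUE ~ "none"
    )
  )
  truth_edges <- dplyr::transmute(edges,
    mirna_id = normalize_mirna_id(.data$mirna_id),
    gene_id = normalize_gene_id(gene_ids[.data$gene_idx]),
    regulator_shift = .data$regulator_shift,
    t_expressed = .data$t_expressed
  )

  list(
    mrna = mrna, mirna = mirna, targets = targets,
    truth = list(genes = truth_genes, mirnas = truth_mirnas, edges = truth_edges)
  )
}

sample_promoter <- function(class, length_bp) {
  emit <- function(units, probs, n_units) {
    paste(sample(units, n_units, replace = TRUE, prob = probs), collapse = "")
  }
  n_units <- ceiling(length_bp / 1.3)
  s <- switch(class,
    # CpG-dense and GC-rich throughout
    HCG = emit(c("CG", "C", "G", "A", "T"),
               c(0.25, 0.15, 0.15, 0.225, 0.225), n_units),
    # moderate CpG (keeps O/E up) but AT-rich (keeps GC below the HCG floor)
    ICG = emit(c("CG", "A", "T", "G", "C"),
               c(0.10, 0.38, 0.38, 0.07, 0.07), n_units),
    # CpG-free: every C-before-G adjacency is broken afterwards
    LCG = {
      x <- emit(c("A", "T", "G", "C"), c(0.3, 0.3, 0.2, 0.2), length_bp)
      gsub("CG", "CA", x, fixed = TRUE)
    },
    abort("unknown CpG class.")
  )
  substr(s, 1, length_bp)
}

#' Generate promoter sequences of each CpG class
#'
#' Constructs random promoter sequences engineered to fall into the
#' requested HCG/ICG/LCG classes under the given thresholds; every emitted
#' sequence is verified with [classify_promoter()] (and redrawn if a random
#' draw misses its class).
#'
#' @param config A [sim_config()] (uses `promoter_counts` and `rng_seed`).
#' @param length_bp Sequence length (default 700).
#' @param cpg A [cpg_config()] used for verification.
#' @return Tibble: `gene_id`, `sequence`, `true_class`.
#' @export
generate_promoters <- function(config = sim_config(), length_bp = 700,
                               cpg = cpg_config()) {
  set.seed(config$rng_seed + 1L)
  counts <- config$promoter_counts
  rows <- purrr::imap(as.list(counts), function(n, class) {
    if (n == 0) return(NULL)
    seqs <- character(n)
    for (i in seq_len(n)) {
      for (try in 1:50) {
        s <- sample_promoter(class, length_bp)
        if (classify_promoter(s, cpg)$cpg_class == class) break
        s <- NA_character_
      }
      if (is.na(s)) abort(sprintf("could not construct a %s promoter.", class))
      seqs[i] <- s
    }
    tibble::tibble(true_class = class, sequence = seqs)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
    gene_id = sprintf("PROM%04d", seq_len(nrow(out))),
    .before = 1
  )
}

#' Generate a gene-to-term annotation with one planted enriched term
#'
#' The first term draws `planted_enrichment_fraction` of its genes from
#' `planted_genes` (the planted up-regulated set) and the rest at random, so
#' it is over-represented in that set; the remaining terms are random draws
#' from the universe.
#'
#' @param config A [sim_config()] (uses `planted_term_size`, `n_terms`,
#'   `planted_enrichment_fraction`, `rng_seed`).
#' @param universe Character vector of gene ids.
#' @param planted_genes Gene ids the planted term is enriched in.
#' @return Tibble: `gene_id`, `term_id`, `term_name`; the planted term is
#'   `TERM0001` ("planted process").
#' @export
generate_annotation <- function(config, universe, planted_genes) {
  if (config$n_terms < 1) abort("`n_terms` must be >= 1.")
  set.seed(config$rng_seed + 2L)
  universe <- unique(normalize_gene_id(universe))
  planted_genes <- intersect(unique(normalize_gene_id(planted_genes)), universe)
  size <- min(config$planted_term_size, length(universe))
  n_planted <- min(
    round(config$planted_enrichment_fraction * size),
    length(planted_genes)
  )
  planted_members <- unique(c(
    sample(planted_genes, n_planted),
    sample(setdiff(universe, planted_genes), size - n_planted)
  ))
  other <- purrr::map_dfr(seq_len(config$n_terms - 1), function(i) {
    sz <- sample(50:200, 1)
    tibble::tibble(
      gene_id = sample(universe, min(sz, length(universe))),
      term_id = sprintf("TERM%04d", i + 1),
      term_name = sprintf("random process %d", i)
    )
  })
  dplyr::bind_rows(
    tibble::tibble(
      gene_id = planted_members,
      term_id = "TERM0001", term_name = "planted process"
    ),
    other
  )
}

#' Write a complete synthetic study to disk
#'
#' Emits every input format the pipeline consumes (expression matrices with
#' detection flags and design, target pairs, promoter FASTA, annotation TSV)
#' plus truth tables under `truth/`, which the pipeline never reads.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_study <- function(config = sim_config(), out_dir) {
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  sim <- generate_bundle(config)
  write_expression_bundle(sim$mrna,
    p("mrna_values.tsv"), p("mrna_detection.tsv"), p("mrna_design.tsv")
  )
  write_expression_bundle(sim$mirna,
    p("mirna_values.tsv"), p("mirna_detection.tsv"), p("mirna_design.tsv")
  )
  write_target_pairs(sim$targets, p("target_pairs.tsv"))
  proms <- generate_promoters(config)
  write_fasta_promoters(proms, p("promoters.fa"))
  ann <- generate_annotation(
    config,
    universe = sim$truth$genes$gene_id[sim$truth$genes$detected],
    planted_genes = sim$truth$genes$gene_id[
      sim$truth$genes$planted_direction == "up"
    ]
  )
  write_annotation(ann, p("annotation.tsv"))
  readr::write_tsv(sim$truth$genes, p("truth", "genes.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$mirnas, p("truth", "mirnas.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$edges, p("truth", "edges.tsv"), progress = FALSE)
  readr::write_tsv(
    dplyr::select(proms, "gene_id", "true_class"),
    p("truth", "promoters.tsv"), progress = FALSE
  )
  invisible(list(
    mrna_values = p("mrna_values.tsv"),
    mrna_detection = p("mrna_detection.tsv"),
    mrna_design = p("mrna_design.tsv"),
    mirna_values = p("mirna_values.tsv"),
    mirna_detection = p("mirna_detection.tsv"),
    mirna_design = p("mirna_design.tsv"),
    target_pairs = p("target_pairs.tsv"),
    promoters = p("promoters.fa"),
    annotation = p("annotation.tsv"),
    truth_dir = p("truth")
  ))
}
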