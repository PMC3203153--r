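#' Configuration for the end-to-end pipeline
#'
#' Collects the input paths and stage parameters for [run_pipeline()]. Target
#' pair tables are given as a named list of paths; the names are the
#' predictor labels.
#'
#' @param mrna_values,mrna_detection,mrna_design mRNA bundle file paths.
#' @param mirna_values,mirna_detection,mirna_design miRNA bundle file paths.
#' @param target_pairs Named list/vector of target-pair TSV paths (names =
#'   predictor labels).
#' @param promoters Optional promoter FASTA path.
#' @param annotation Optional annotation TSV path.
#' @param out_dir Report directory.
#' @param sam A [sam_config()].
#' @param cpg A [cpg_config()].
#' @param epsilon Null band for [classify_gene()] (default 0).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mrna_values, mrna_detection, mrna_design,
                            mirna_values, mirna_detection, mirna_design,
                            target_pairs, promoters = NULL, annotation = NULL,
                            out_dir, sam = sam_config(), cpg = cpg_config(),
                            epsilon = 0) {
  if (is.null(names(target_pairs)) || any(names(target_pairs) == "")) {
    abort("`target_pairs` must be named by predictor label.")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the integrated miRNA-mRNA analysis end to end
#'
#' Executes every stage on the configured inputs and writes a report
#' directory: differential-expression tables for mRNA and miRNA, per-predictor
#' regulation tables and three-class summaries, pairwise predictor overlap
#' (when two or more predictors are given), promoter CpG classes with a
#' CpG-class by regulation-class cross-table, term-enrichment tables for the
#' up- and down-regulated gene sets, and a run log echoing every parameter.
#' Deterministic given the configured seeds.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  log_lines <- c(
    sprintf("mirreg %s pipeline run", as.character(utils::packageVersion("mirreg"))),
    sprintf("sam: s0_percentile=%g n_permutations=%d fdr=%g seed=%d",
            config$sam$s0_percentile, config$sam$n_permutations,
            config$sam$fdr_threshold, config$sam$rng_seed),
    sprintf("cpg: window=%d step=%d gc_min=%g oe_min=%g oe_max=%g",
            config$cpg$window_bp, config$cpg$step_bp, config$cpg$hcg_gc_min,
            config$cpg$hcg_oe_min, config$cpg$lcg_oe_max),
    sprintf("epsilon=%g", config$epsilon)
  )

  mrna <- run_stage("read_mrna", read_expression_bundle(
    config$mrna_values, config$mrna_detection, config$mrna_design, "gene"
  ))
  mirna <- run_stage("read_mirna", read_expression_bundle(
    config$mirna_values, config$mirna_detection, config$mirna_design, "mirna"
  ))
  maps <- run_stage("read_targets", purrr::imap(
    as.list(config$target_pairs),
    function(path, label) suppressMessages(read_target_pairs(path, label))
  ))

  fit_mrna <- run_stage("diffexp_mrna", diff_expression(mrna, config$sam))
  fit_mirna <- run_stage("diffexp_mirna", diff_expression(mirna, config$sam))
  readr::write_tsv(tidy(fit_mrna), p("diffexp_mrna.tsv"), progress = FALSE)
  readr::write_tsv(tidy(fit_mirna), p("diffexp_mirna.tsv"), progress = FALSE)
  gm <- glance(fit_mrna); gi <- glance(fit_mirna)
  log_lines <- c(log_lines,
    sprintf("mrna: %d features, %d up, %d down, %d at q<%g",
            gm$n_features, gm$n_up, gm$n_down, gm$n_significant,
            config$sam$fdr_threshold),
    sprintf("mirna: %d features, %d up, %d down, %d at q<%g",
            gi$n_features, gi$n_up, gi$n_down, gi$n_significant,
            config$sam$fdr_threshold)
  )

  expressed_genes <- rownames(detection_filter(mrna)$values)
  gene_de <- de_features(fit_mrna)

  regnet <- run_stage("regnet", purrr::imap(maps, function(map, label) {
    mr <- mirna_regulation(tidy(fit_mirna), map, expressed_genes)
    gr <- gene_regulation(tidy(fit_mrna), mr, map, config$epsilon)
    cs <- classification_summary(gr)
    readr::write_tsv(mr, p(sprintf("mirna_regulation_%s.tsv", label)),
      progress = FALSE)
    readr::write_tsv(gr, p(sprintf("gene_regulation_%s.tsv", label)),
      progress = FALSE)
    readr::write_tsv(cs, p(sprintf("class_summary_%s.tsv", label)),
      progress = FALSE)
    list(mirna_regulation = mr, gene_regulation = gr, summary = cs)
  }))

  overlaps <- NULL
  if (length(maps) >= 2) {
    combos <- utils::combn(names(maps), 2, simplify = FALSE)
    overlaps <- run_stage("overlap", purrr::map_dfr(
      combos, function(x) pair_overlap(maps[[x[1]]], maps[[x[2]]])
    ))
    readr::write_tsv(overlaps, p("predictor_overlap.tsv"), progress = FALSE)
  }

  cpg_classes <- NULL
  if (!is.null(config$promoters)) {
    cpg_classes <- run_stage("cpg", {
      proms <- read_fasta_promoters(config$promoters)
      classify_promoters(proms, config$cpg)
    })
    readr::write_tsv(cpg_classes, p("cpg_classes.tsv"), progress = FALSE)
    # CpG class x regulation class cross-table, first predictor
    gr1 <- regnet[[1]]$gene_regulation
    cross <- gr1 |>
      dplyr::inner_join(cpg_classes, by = "gene_id") |>
      dplyr::count(.data$reg_class, .data$cpg_class) |>
      tidyr::pivot_wider(
        names_from = "cpg_class", values_from = "n", values_fill = 0L
      )
    readr::write_tsv(cross, p("cpg_by_reg_class.tsv"), progress = FALSE)
  }

  enrichments <- NULL
  if (!is.null(config$annotation)) {
    enrichments <- run_stage("enrichment", {
      ann <- read_annotation(config$annotation)
      list(
        up = enrich(gene_de$feature_id[gene_de$direction == "up"],
                    ann, expressed_genes),
        down = enrich(gene_de$feature_id[gene_de$direction == "down"],
                      ann, expressed_genes)
      )
    })
    readr::write_tsv(enrichments$up, p("enrichment_up.tsv"), progress = FALSE)
    readr::write_tsv(enrichments$down, p("enrichment_down.tsv"), progress = FALSE)
  }

  writeLines(log_lines, p("run_log.txt"))
  invisible(list(
    out_dir = config$out_dir,
    fit_mrna = fit_mrna, fit_mirna = fit_mirna,
    regnet = regnet, overlaps = overlaps,
    cpg_classes = cpg_classes, enrichments = enrichments
  ))
}
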