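#' miRNA regulation value
#'
#' The regulation value of a differentially expressed miRNA is its expression
#' variation (mean per-pair log2 tumor - normal difference) divided by its
#' number of expressed targets. A miRNA with many targets spreads a given
#' expression change thinly; one with few targets is assumed to press harder
#' on each.
#'
#' @param delta_e Expression variation(s) of the miRNA(s).
#' @param t_expressed Count(s) of the miRNA's targets among expressed genes
#'   (must be >= 1).
#' @return `delta_e / t_expressed`, vectorized.
#' @export
#' @examples
#' mirna_regulation_value(2, 4)    # 0.5
#' mirna_regulation_value(-1.5, 3) # -0.5
mirna_regulation_value <- function(delta_e, t_expressed) {
  if (any(t_expressed < 1)) abort("no expressed targets: `t_expressed` must be >= 1.")
  delta_e / t_expressed
}

#' Per-miRNA regulation values for a differential expression result
#'
#' Joins the consistent-direction miRNA list against a target map restricted
#' to expressed genes and computes each variable miRNA's regulation value.
#' miRNAs with no expressed target are dropped (they cannot regulate anything
#' measurable).
#'
#' @param mirna_de Tibble with `feature_id`, `direction`, `mean_delta` (e.g.
#'   `tidy()` of a miRNA `sam_fit`); only rows with direction `up`/`down` are
#'   used.
#' @param map A `target_map`.
#' @param expressed_gene_ids Genes surviving the detection filter.
#' @return Tibble: `mirna_id`, `direction`, `delta_e`, `t_expressed`,
#'   `r_value`.
#' @export
mirna_regulation <- function(mirna_de, map, expressed_gene_ids) {
  restricted <- restrict_to_expressed(map, expressed_gene_ids)
  counts <- dplyr::count(tibble::as_tibble(restricted), .data$mirna_id,
    name = "t_expressed"
  )
  mirna_de |>
    dplyr::filter(.data$direction %in% c("up", "down")) |>
    dplyr::transmute(
      mirna_id = normalize_mirna_id(.data$feature_id),
      direction = .data$direction,
      delta_e = .data$mean_delta
    ) |>
    dplyr::inner_join(counts, by = "mirna_id") |>
    dplyr::mutate(r_value = mirna_regulation_value(.data$delta_e, .data$t_expressed))
}

#' Gene regulation value
#'
#' A gene's regulation value is the sum of the regulation values of all
#' variable miRNAs predicted to target it; a gene with no such regulator has
#' a null (NA) regulation value.
#'
#' @param r_values Numeric vector of regulator regulation values (possibly
#'   empty).
#' @return The sum, or `NA_real_` for an empty vector.
#' @export
gene_regulation_value <- function(r_values) {
  if (length(r_values) == 0) return(NA_real_)
  sum(r_values)
}

#' Classify a gene by sign concordance with its miRNA regulation
#'
#' A gene whose regulation value is null (no variable regulator) or within
#' `epsilon` of zero is `others`. Otherwise the gene is `anti_correlated`
#' when the sign of its summed regulation value is opposite to its own
#' expression direction (positive regulation with a down gene, or negative
#' with an up gene), and `correlated` when the signs agree.
#'
#' @param R_g Summed regulation value(s); `NA` means null.
#' @param direction Gene direction(s), `"up"` or `"down"`.
#' @param epsilon Non-negative half-width of the "null" band (default 0:
#'   only exact cancellation or no regulator gives `others`).
#' @return Character vector in
#'   `c("anti_correlated", "correlated", "others")`.
#' @export
classify_gene <- function(R_g, direction, epsilon = 0) {
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  if (!all(direction %in% c("up", "down"))) {
    abort("`direction` must be 'up' or 'down'.")
  }
  dir_sign <- ifelse(direction == "up", 1, -1)
  out <- ifelse(sign(R_g) == dir_sign, "correlated", "anti_correlated")
  out[is.na(R_g) | R_g == 0 | abs(R_g) < epsilon] <- "others"
  out
}

#' Regulation values and classes for differentially expressed genes
#'
#' For every consistent-direction gene, sums the regulation values of its
#' variable miRNA regulators (under the given target map) and classifies the
#' gene as correlated / anti-correlated / others.
#'
#' @param gene_de Tibble with `feature_id`, `direction`, `mean_delta`; only
#'   `up`/`down` rows are classified.
#' @param mirna_reg Output of [mirna_regulation()].
#' @param map The same `target_map` used for `mirna_reg`.
#' @param epsilon Passed to [classify_gene()].
#' @return Tibble: `gene_id`, `direction`, `mean_delta`, `n_regulators`,
#'   `R_g`, `reg_class`.
#' @export
gene_regulation <- function(gene_de, mirna_reg, map, epsilon = 0) {
  de <- gene_de |>
    dplyr::filter(.data$direction %in% c("up", "down")) |>
    dplyr::transmute(
      gene_id = normalize_gene_id(.data$feature_id),
      direction = .data$direction,
      mean_delta = .data$mean_delta
    )
  reg_sums <- tibble::as_tibble(map) |>
    dplyr::inner_join(
      dplyr::select(mirna_reg, "mirna_id", "r_value"),
      by = "mirna_id"
    ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_regulators = dplyr::n(), R_g = sum(.data$r_value))
  de |>
    dplyr::left_join(reg_sums, by = "gene_id") |>
    dplyr::mutate(
      n_regulators = dplyr::coalesce(.data$n_regulators, 0L),
      reg_class = classify_gene(.data$R_g, .data$direction, epsilon)
    )
}

#' Summarize regulation classes with up/down percentages
#'
#' Builds the three-class summary table: per class, the total gene count, the
#' up-regulated count with its percentage of all up-regulated genes, and the
#' down-regulated count with its percentage of all down-regulated genes.
#' Class totals partition the differentially expressed gene set.
#'
#' @param gene_reg Output of [gene_regulation()]; every row must carry a
#'   valid `reg_class`.
#' @param n_up_total,n_down_total Denominators; default to the up/down counts
#'   in `gene_reg`.
#' @return Tibble: `reg_class`, `n_total`, `n_up`, `pct_up`, `n_down`,
#'   `pct_down`.
#' @export
classification_summary <- function(gene_reg,
                                   n_up_total = sum(gene_reg$direction == "up"),
                                   n_down_total = sum(gene_reg$direction == "down")) {
  classes <- c("anti_correlated", "correlated", "others")
  if (any(is.na(gene_reg$reg_class)) || !all(gene_reg$reg_class %in% classes)) {
    abort("unclassified gene present in `gene_reg`.")
  }
  gene_reg |>
    dplyr::mutate(reg_class = factor(.data$reg_class, levels = classes)) |>
    dplyr::group_by(.data$reg_class, .drop = FALSE) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down")
    ) |>
    dplyr::mutate(
      reg_class = as.character(.data$reg_class),
      pct_up = percent_of(.data$n_up, n_up_total),
      pct_down = percent_of(.data$n_down, n_down_total),
      .after = "n_up"
    ) |>
    dplyr::relocate("pct_up", .after = "n_up") |>
    dplyr::relocate("pct_down", .after = "n_down")
}

#' Bar chart of the regulation-class summary
#'
#' @param summary Output of [classification_summary()].
#' @return A ggplot object: up/down gene counts per regulation class.
#' @export
plot_classification <- function(summary) {
  long <- summary |>
    dplyr::select("reg_class", "n_up", "n_down") |>
    tidyr::pivot_longer(c("n_up", "n_down"),
      names_to = "direction", values_to = "n"
    ) |>
    dplyr::mutate(direction = sub("^n_", "", .data$direction))
  ggplot2::ggplot(long, ggplot2::aes(.data$reg_class, .data$n,
    fill = .data$direction
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "#d73027", down = "#4575b4")) +
    ggplot2::labs(
      x = "regulation class", y = "differentially expressed genes",
      fill = "gene direction"
    ) +
    ggplot2::theme_minimal()
}
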