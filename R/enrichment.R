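#' Hypergeometric upper-tail probability
#'
#' P(X >= O) for X ~ hypergeometric: drawing `n` genes without replacement
#' from a universe of `N` genes of which `C` belong to the category. This is
#' the raw enrichment p-value for observing `O` or more category genes in the
#' gene set.
#'
#' @param N Universe size.
#' @param n Gene-set (draw) size.
#' @param C Category size in the universe.
#' @param O Observed overlap, `0 <= O <= min(n, C)`.
#' @return The upper-tail probability.
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 3) # 66/252
hypergeom_upper_tail <- function(N, n, C, O) {
  if (any(c(N, n, C, O) < 0) || O > min(n, C) || max(n, C) > N) {
    abort("inconsistent counts: need 0 <= O <= min(n, C) <= N.")
  }
  stats::phyper(O - 1, C, N - C, n, lower.tail = FALSE)
}

#' Expected overlap and enrichment ratio
#'
#' `E = C * n / N` is the overlap expected by chance; `R = O / E` is the
#' ratio of enrichment. Both are reported rounded half-up to two decimals, as
#' in enrichment report tables.
#'
#' @inheritParams hypergeom_upper_tail
#' @return One-row tibble with columns `E` and `R` (two decimals).
#' @export
expected_and_ratio <- function(C, n, N, O) {
  if (N <= 0 || n <= 0) abort("`N` and `n` must be positive.")
  E <- C * n / N
  if (E == 0 && O > 0) abort("expected count is 0 but overlap is positive.")
  tibble::tibble(
    E = round_half_up(E, 2),
    R = if (E == 0) NA_real_ else round_half_up(O / E, 2)
  )
}

#' Enrichment ratio from reported O and E
#'
#' @param O Observed overlap.
#' @param E Expected overlap (> 0).
#' @return `O / E` rounded half-up to two decimals.
#' @export
#' @examples
#' enrichment_ratio(21, 6.49) # 3.24
enrichment_ratio <- function(O, E) {
  if (any(E <= 0)) abort("`E` must be positive.")
  round_half_up(O / E, 2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of raw p-values: sort ascending,
#' multiply `p_(i)` by `m/i`, enforce monotonicity from the largest rank
#' down, cap at 1, and restore the input order.
#'
#' @param pvalues Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`.
#' @return Tibble with normalized gene ids, duplicates collapsed.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "term_id", "term_name") %in% names(ann))) {
    abort("annotation needs columns gene_id, term_id, term_name.")
  }
  ann |>
    dplyr::mutate(gene_id = normalize_gene_id(.data$gene_id)) |>
    dplyr::distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
}

#' Write an annotation table
#' @param annotation Tibble with `gene_id`, `term_id`, `term_name`.
#' @param path Output TSV path.
#' @return Invisibly, the annotation.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[, c("gene_id", "term_id", "term_name")], path,
    progress = FALSE
  )
  invisible(annotation)
}

#' Hypergeometric term enrichment of a gene set
#'
#' For every annotation term with at least one gene-set member, reports the
#' category size in the reference (`C`), the observed overlap (`O`), the
#' expected overlap (`E = C * n / N`), the enrichment ratio (`R = O / E`),
#' the hypergeometric upper-tail p-value (`rawP`) and its
#' Benjamini-Hochberg adjustment (`adjP`). The reference universe `N` is the
#' set of `universe` genes carrying at least one annotation term, and `n` is
#' the number of gene-set members inside that mapped universe.
#'
#' @param gene_set Character vector of gene ids (subset of `universe`).
#' @param annotation Tibble with `gene_id`, `term_id`, `term_name`.
#' @param universe Character vector of measured gene ids.
#' @param p_cutoff Terms with `adjP < p_cutoff` are flagged `enriched`
#'   (default 0.001).
#' @return Tibble sorted by `rawP`: `term_id`, `term_name`, `C`, `O`, `E`,
#'   `R`, `rawP`, `adjP`, `enriched`.
#' @export
enrich <- function(gene_set, annotation, universe, p_cutoff = 0.001) {
  universe <- unique(normalize_gene_id(universe))
  if (length(universe) == 0) abort("empty universe.")
  gene_set <- unique(normalize_gene_id(gene_set))
  if (!all(gene_set %in% universe)) {
    abort("`gene_set` must be a subset of `universe`.")
  }
  ann <- annotation |>
    dplyr::mutate(gene_id = normalize_gene_id(.data$gene_id)) |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
  N <- length(unique(ann$gene_id))
  mapped_set <- intersect(gene_set, unique(ann$gene_id))
  n <- length(mapped_set)
  rows <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      C = dplyr::n(),
      O = sum(.data$gene_id %in% mapped_set),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$O >= 1)
  if (nrow(rows) == 0 || n == 0) {
    return(tibble::tibble(
      term_id = character(), term_name = character(), C = integer(),
      O = integer(), E = numeric(), R = numeric(), rawP = numeric(),
      adjP = numeric(), enriched = logical()
    ))
  }
  rows |>
    dplyr::mutate(
      E = round_half_up(.data$C * n / N, 2),
      R = enrichment_ratio(.data$O, .data$C * n / N),
      rawP = purrr::map2_dbl(.data$C, .data$O, function(C, O) {
        hypergeom_upper_tail(N, n, C, O)
      }),
      adjP = bh_adjust(.data$rawP),
      enriched = .data$adjP < p_cutoff
    ) |>
    dplyr::arrange(.data$rawP)
}

#' Dot plot of an enrichment result
#'
#' @param enrichment Output of [enrich()].
#' @param top Number of top terms (by rawP) to show (default 15).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 15) {
  df <- head(enrichment, top)
  ggplot2::ggplot(df, ggplot2::aes(
    .data$R, stats::reorder(.data$term_name, .data$R),
    size = .data$O, colour = -log10(.data$adjP)
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "enrichment ratio (O/E)", y = NULL,
      size = "overlap O", colour = "-log10 adjP"
    ) +
    ggplot2::theme_minimal()
}
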