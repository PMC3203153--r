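#' Build a miRNA-target map
#'
#' A target map is a tibble of unique (mirna_id, gene_id) pairs predicted by
#' one target-prediction method, carrying the predictor label as an attribute.
#' Identifiers are normalized (miRNAs lower-cased, genes upper-cased) so the
#' map joins cleanly against expression features.
#'
#' @param pairs Data frame with columns `mirna_id` and `gene_id`.
#' @param predictor_label Short label of the prediction source (e.g.
#'   `"targetscan"`, `"miranda"`, `"conserved"`).
#' @return A tibble of class `target_map` with attribute `predictor_label`.
#' @export
target_map <- function(pairs, predictor_label) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("mirna_id", "gene_id") %in% names(pairs))) {
    abort("`pairs` needs columns mirna_id and gene_id.")
  }
  out <- pairs |>
    dplyr::transmute(
      mirna_id = normalize_mirna_id(.data$mirna_id),
      gene_id = normalize_gene_id(.data$gene_id)
    ) |>
    dplyr::distinct()
  attr(out, "predictor_label") <- as.character(predictor_label)
  class(out) <- c("target_map", class(out))
  out
}

#' Predictor label of a target map
#' @param map A `target_map`.
#' @return The predictor label string.
#' @export
predictor_label <- function(map) attr(map, "predictor_label")

#' Read a two-column miRNA-target pair table
#'
#' Parses a tab-separated file of (mirna_id, gene_id) rows, with an optional
#' header line. Duplicate rows are collapsed; the unique-pair count is
#' reported via a message.
#'
#' @param path Path to the TSV.
#' @param predictor_label Label for the prediction source.
#' @return A `target_map`.
#' @export
read_target_pairs <- function(path, predictor_label) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) {
    warn(sprintf("'%s' is empty; returning an empty target map.", path))
    return(target_map(
      tibble::tibble(mirna_id = character(), gene_id = character()),
      predictor_label
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  # optional header: first line whose columns look like names, not identifiers
  start <- 1L
  if (grepl("mirna|mir_id|gene", lines[1], ignore.case = TRUE) &&
      grepl("gene|target", lines[1], ignore.case = TRUE)) {
    start <- 2L
    bad <- setdiff(bad, 1L)
  }
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed row at line %d of '%s': expected 2 tab-separated columns.",
      bad[1], path
    ))
  }
  if (start > length(lines)) {
    warn(sprintf("'%s' has a header but no rows; returning an empty target map.", path))
    return(target_map(
      tibble::tibble(mirna_id = character(), gene_id = character()),
      predictor_label
    ))
  }
  body <- fields[seq(start, length(fields))]
  map <- target_map(
    tibble::tibble(
      mirna_id = vapply(body, `[[`, character(1), 1),
      gene_id = vapply(body, `[[`, character(1), 2)
    ),
    predictor_label
  )
  inform(sprintf(
    "read %d unique %s miRNA-target pairs from '%s'.",
    nrow(map), predictor_label, path
  ))
  map
}

#' Write a miRNA-target pair table
#'
#' @param map A `target_map`.
#' @param path Output TSV path (header `mirna_id`/`gene_id` included).
#' @return Invisibly, the map.
#' @export
write_target_pairs <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map)[, c("mirna_id", "gene_id")], path,
    progress = FALSE
  )
  invisible(map)
}

#' Restrict a target map to expressed genes
#'
#' Keeps only pairs whose target gene survived the detection filter; miRNAs
#' that lose all their targets drop out of the map. The per-miRNA pair counts
#' of the restricted map are the "number of expressed targets" denominator of
#' the regulation-value statistic.
#'
#' @param map A `target_map`.
#' @param expressed_gene_ids Character vector of expressed gene ids.
#' @return A restricted `target_map`.
#' @export
restrict_to_expressed <- function(map, expressed_gene_ids) {
  expressed <- normalize_gene_id(expressed_gene_ids)
  out <- dplyr::filter(tibble::as_tibble(map), .data$gene_id %in% expressed)
  target_map(out, predictor_label(map))
}

#' Overlap between two predictors' target-pair sets
#'
#' Counts pairs present in both maps and expresses the shared count as a
#' percentage of each map (two decimals, half-up).
#'
#' @param map_a,map_b `target_map` objects (non-empty).
#' @return A one-row tibble: `predictor_a`, `predictor_b`, `n_a`, `n_b`,
#'   `n_shared`, `pct_of_a`, `pct_of_b`.
#' @export
pair_overlap <- function(map_a, map_b) {
  if (nrow(map_a) == 0 || nrow(map_b) == 0) {
    abort("pair_overlap requires two non-empty target maps.")
  }
  key <- function(m) paste(m$mirna_id, m$gene_id, sep = "\r")
  n_shared <- length(intersect(key(map_a), key(map_b)))
  tibble::tibble(
    predictor_a = predictor_label(map_a),
    predictor_b = predictor_label(map_b),
    n_a = nrow(map_a),
    n_b = nrow(map_b),
    n_shared = n_shared,
    pct_of_a = percent_of(n_shared, nrow(map_a)),
    pct_of_b = percent_of(n_shared, nrow(map_b))
  )
}
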