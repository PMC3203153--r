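#' Configuration for promoter CpG-density classification
#'
#' Defaults follow the established windowed CpG-island criteria: a promoter
#' is high-CpG (HCG) when some 500-bp window has GC fraction >= 0.55 and
#' CpG observed/expected ratio >= 0.75; low-CpG (LCG) when no window reaches
#' an O/E of 0.48; intermediate (ICG) otherwise.
#'
#' @param window_bp Sliding-window width in bp (default 500, must be >= 2).
#' @param step_bp Window step in bp (default 1).
#' @param hcg_gc_min Minimum window GC fraction for HCG (default 0.55).
#' @param hcg_oe_min Minimum window CpG O/E for HCG (default 0.75).
#' @param lcg_oe_max Windows all below this O/E give LCG (default 0.48).
#' @return A list of class `cpg_config`.
#' @export
cpg_config <- function(window_bp = 500, step_bp = 1, hcg_gc_min = 0.55,
                       hcg_oe_min = 0.75, lcg_oe_max = 0.48) {
  if (window_bp < 2) abort("`window_bp` must be >= 2.")
  if (step_bp < 1) abort("`step_bp` must be >= 1.")
  if (!(lcg_oe_max > 0 && lcg_oe_max < hcg_oe_min)) {
    abort("need 0 < lcg_oe_max < hcg_oe_min.")
  }
  structure(
    list(
      window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
      hcg_gc_min = hcg_gc_min, hcg_oe_min = hcg_oe_min,
      lcg_oe_max = lcg_oe_max
    ),
    class = "cpg_config"
  )
}

seq_chars <- function(seq) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (!all(s %in% c("A", "C", "G", "T", "N"))) {
    abort("sequence must be over the alphabet {A, C, G, T, N}.")
  }
  s
}

#' GC fraction of a sequence
#'
#' `(#C + #G) / effective length`, where N positions are excluded from both
#' counts and the effective length.
#'
#' @param seq A DNA string over `{A, C, G, T, N}`.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  s <- seq_chars(seq)
  eff <- sum(s != "N")
  if (eff == 0) abort("effective (non-N) length is 0.")
  sum(s %in% c("C", "G")) / eff
}

#' CpG observed/expected ratio of a sequence
#'
#' `(#CpG dinucleotides x effective length) / (#C x #G)`, with N positions
#' excluded from all counts and from the effective length (a dinucleotide
#' containing N does not count). By convention the ratio is 0 when the
#' sequence contains no C or no G.
#'
#' @param seq A DNA string over `{A, C, G, T, N}`.
#' @return The O/E ratio (>= 0).
#' @export
#' @examples
#' cpg_oe_ratio("CGCGCG") # 2
cpg_oe_ratio <- function(seq) {
  s <- seq_chars(seq)
  eff <- sum(s != "N")
  if (eff < 2) abort("effective (non-N) length must be >= 2.")
  n_c <- sum(s == "C")
  n_g <- sum(s == "G")
  if (n_c == 0 || n_g == 0) return(0)
  n_cg <- sum(s[-length(s)] == "C" & s[-1] == "G")
  n_cg * eff / (n_c * n_g)
}

# per-window GC fraction and CpG O/E via cumulative sums
window_stats <- function(s, config) {
  L <- length(s)
  w <- min(config$window_bp, L)
  is_c <- as.integer(s == "C")
  is_g <- as.integer(s == "G")
  is_n <- as.integer(s == "N")
  is_cg <- c(as.integer(s[-L] == "C" & s[-1] == "G"), 0L)
  cum <- function(x) c(0, cumsum(x))
  cc <- cum(is_c); cg <- cum(is_g); cn <- cum(is_n); ccg <- cum(is_cg)
  starts <- seq.int(1L, L - w + 1L, by = config$step_bp)
  ends <- starts + w - 1L
  n_c <- cc[ends + 1] - cc[starts]
  n_g <- cg[ends + 1] - cg[starts]
  n_n <- cn[ends + 1] - cn[starts]
  n_cg <- ccg[ends] - ccg[starts] # dinucleotides fully inside the window
  eff <- w - n_n
  gc <- ifelse(eff > 0, (n_c + n_g) / eff, NA_real_)
  oe <- ifelse(eff >= 2 & n_c > 0 & n_g > 0, n_cg * eff / (n_c * n_g), 0)
  oe[eff < 2] <- NA_real_
  tibble::tibble(start = starts, gc = gc, oe = oe)
}

#' Classify one promoter sequence by CpG density
#'
#' Slides a window over the sequence: HCG if any window simultaneously
#' reaches the GC and O/E thresholds; LCG if no window reaches the lower O/E
#' threshold; ICG otherwise. A sequence shorter than the window is classified
#' from a single whole-sequence window (a message notes the fallback).
#'
#' @param seq A DNA string over `{A, C, G, T, N}`.
#' @param config A [cpg_config()].
#' @return One-row tibble: `best_window_gc`, `best_window_oe` (the maximum-O/E
#'   window's statistics), `cpg_class` in `c("HCG", "ICG", "LCG")`.
#' @export
classify_promoter <- function(seq, config = cpg_config()) {
  s <- seq_chars(seq)
  if (length(s) < config$window_bp) {
    inform(sprintf(
      "sequence (%d bp) shorter than window (%d bp); classifying it as a single window.",
      length(s), config$window_bp
    ))
  }
  ws <- window_stats(s, config)
  ws <- ws[!is.na(ws$oe) & !is.na(ws$gc), , drop = FALSE]
  if (nrow(ws) == 0) abort("no window with effective length >= 2.")
  cls <- if (any(ws$gc >= config$hcg_gc_min & ws$oe >= config$hcg_oe_min)) {
    "HCG"
  } else if (all(ws$oe < config$lcg_oe_max)) {
    "LCG"
  } else {
    "ICG"
  }
  best <- which.max(ws$oe)
  tibble::tibble(
    best_window_gc = ws$gc[best],
    best_window_oe = ws$oe[best],
    cpg_class = cls
  )
}

#' Classify a table of promoters
#'
#' @param promoters Tibble with columns `gene_id` and `sequence` (e.g. from
#'   [read_fasta_promoters()]).
#' @param config A [cpg_config()].
#' @return Tibble: `gene_id`, `best_window_gc`, `best_window_oe`,
#'   `cpg_class`.
#' @export
classify_promoters <- function(promoters, config = cpg_config()) {
  res <- purrr::map(promoters$sequence, classify_promoter, config = config)
  dplyr::bind_cols(
    tibble::tibble(gene_id = promoters$gene_id),
    dplyr::bind_rows(res)
  )
}

#' Read promoter sequences from FASTA
#'
#' Record ids are taken as gene ids (first whitespace-delimited token,
#' upper-cased); sequences are upper-cased. Duplicate gene ids and empty
#' sequences are errors.
#'
#' @param path FASTA file path.
#' @return Tibble: `gene_id`, `sequence`, `cpg_class` (`"unclassified"`).
#' @export
read_fasta_promoters <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- normalize_gene_id(sub("\\s.*$", "", names(set)))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate gene id in '%s': %s", path, ids[duplicated(ids)][1]
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("empty sequence for '%s'.", ids[nchar(seqs) == 0][1]))
  }
  tibble::tibble(
    gene_id = ids, sequence = unname(seqs), cpg_class = "unclassified"
  )
}

#' Write promoter sequences to FASTA
#'
#' @param promoters Tibble with `gene_id` and `sequence`.
#' @param path Output FASTA path.
#' @return Invisibly, `promoters`.
#' @export
write_fasta_promoters <- function(promoters, path) {
  set <- Biostrings::DNAStringSet(setNames(
    promoters$sequence, promoters$gene_id
  ))
  Biostrings::writeXStringSet(set, path)
  invisible(promoters)
}

#' Bar chart of CpG classes, optionally split by a grouping column
#'
#' @param cpg_classes Output of [classify_promoters()], optionally with an
#'   extra `group` column (e.g. regulation class).
#' @return A ggplot object.
#' @export
plot_cpg_classes <- function(cpg_classes) {
  has_group <- "group" %in% names(cpg_classes)
  aes <- if (has_group) {
    ggplot2::aes(.data$group, fill = .data$cpg_class)
  } else {
    ggplot2::aes(.data$cpg_class, fill = .data$cpg_class)
  }
  ggplot2::ggplot(cpg_classes, aes) +
    ggplot2::geom_bar(position = if (has_group) "fill" else "stack") +
    ggplot2::labs(
      x = if (has_group) "group" else "CpG class",
      y = if (has_group) "fraction of promoters" else "promoters",
      fill = "CpG class"
    ) +
    ggplot2::theme_minimal()
}
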