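#' Round half-up to a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as used for every reported proportion in
#' the package's summary tables. Base R's `round()` rounds half to even, which
#' disagrees with how percentages are conventionally printed in expression
#' studies (e.g. 4.475 -> 4.48, not 4.47).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(4.475, 2) # 4.48
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small relative guard against binary representation of exact decimal halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, reported to two decimals
#'
#' Computes `100 * k / n` rounded half-up to two decimals, the convention used
#' for every proportion in the package's report tables. Cross-set percentages
#' (k drawn from a different set than n, so possibly k > n) are permitted.
#'
#' @param k Numerator count(s), non-negative.
#' @param n Denominator count, strictly positive.
#' @return Numeric percentage(s) on the 0-100 scale, two decimals.
#' @export
#' @examples
#' percent_of(13, 581)   # 2.24
#' percent_of(171, 1297) # 13.18
percent_of <- function(k, n) {
  if (length(n) != 1 || !is.finite(n) || n <= 0) {
    abort("`n` must be a single positive count.")
  }
  if (any(!is.finite(k)) || any(k < 0)) {
    abort("`k` must be non-negative count(s).")
  }
  round_half_up(100 * k / n, 2)
}

#' Normalize miRNA identifiers
#'
#' Mature-miRNA names ("hsa-miR-96") are case-inconsistent across sources;
#' all readers lower-case and trim them so pair tables join correctly against
#' expression features. Idempotent.
#'
#' @param x Character vector of miRNA names.
#' @return Normalized character vector.
#' @export
normalize_mirna_id <- function(x) tolower(trimws(x))

#' Normalize gene identifiers
#'
#' Gene symbols are upper-cased and trimmed in every reader. Idempotent.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized character vector.
#' @export
normalize_gene_id <- function(x) toupper(trimws(x))

normalize_feature_id <- function(x, feature_type) {
  switch(feature_type,
    gene  = normalize_gene_id(x),
    mirna = normalize_mirna_id(x),
    abort("unknown feature type")
  )
}

# standard error of the mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
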