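#' Construct a paired expression bundle
#'
#' An expression bundle holds an intensity matrix (features x samples), a
#' same-shaped logical detection matrix, and a paired tumor/normal design.
#' It is the container every differential-expression operation consumes.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param detection Logical matrix, same dimensions and dimnames as `values`;
#'   TRUE where the feature was called detected in that sample.
#' @param design Data frame with columns `sample_id`, `patient_id`, `tissue`
#'   (`"tumor"` or `"normal"`); every patient must appear exactly once with
#'   each tissue.
#' @param scale Either `"raw"` (positive intensities) or `"log2_centered"`.
#' @param feature_type `"gene"` or `"mirna"`; controls identifier
#'   normalization (genes upper-cased, miRNAs lower-cased).
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(values, detection, design,
                              scale = c("raw", "log2_centered"),
                              feature_type = c("gene", "mirna")) {
  scale <- match.arg(scale)
  feature_type <- match.arg(feature_type)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (!is.matrix(detection) || !is.logical(detection)) {
    abort("`detection` must be a logical matrix.")
  }
  if (!identical(dim(values), dim(detection))) {
    abort("dimension mismatch between `values` and `detection`.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry feature ids as rownames and sample ids as colnames.")
  }
  rownames(values) <- normalize_feature_id(rownames(values), feature_type)
  if (anyDuplicated(rownames(values))) {
    abort(paste0(
      "duplicate feature ids after normalization: ",
      paste(head(unique(rownames(values)[duplicated(rownames(values))]), 3),
            collapse = ", ")
    ))
  }
  dimnames(detection) <- dimnames(values)

  design <- tibble::as_tibble(design)
  req <- c("sample_id", "patient_id", "tissue")
  if (!all(req %in% names(design))) {
    abort("`design` needs columns sample_id, patient_id, tissue.")
  }
  design <- dplyr::mutate(design,
    sample_id = as.character(.data$sample_id),
    patient_id = as.character(.data$patient_id),
    tissue = as.character(.data$tissue)
  )
  if (!all(design$tissue %in% c("tumor", "normal"))) {
    abort("`tissue` must be 'tumor' or 'normal'.")
  }
  if (!setequal(design$sample_id, colnames(values)) ||
      anyDuplicated(design$sample_id)) {
    abort("design sample ids must match the value matrix columns exactly.")
  }
  counts <- dplyr::count(design, .data$patient_id, .data$tissue)
  per_patient <- tidyr::pivot_wider(counts,
    names_from = "tissue", values_from = "n", values_fill = 0L
  )
  ok <- "tumor" %in% names(per_patient) && "normal" %in% names(per_patient) &&
    all(per_patient$tumor == 1L) && all(per_patient$normal == 1L)
  if (!ok) abort("unpaired design: every patient needs exactly one tumor and one normal sample.")
  if (scale == "raw" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "raw-scale values must be strictly positive (feature '%s', sample '%s').",
      rownames(values)[bad[1]], colnames(values)[bad[2]]
    ))
  }

  structure(
    list(values = values, detection = detection,
         design = design[order(design$patient_id, design$tissue), ],
         scale = scale, feature_type = feature_type),
    class = "expression_bundle"
  )
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf(
    "<expression_bundle> %d %s features x %d samples (%d patient pairs), scale=%s\n",
    nrow(x$values), x$feature_type, ncol(x$values),
    length(unique(x$design$patient_id)), x$scale
  ))
  invisible(x)
}

#' @export
dim.expression_bundle <- function(x) dim(x$values)

#' Patient pairing of a bundle
#'
#' @param bundle An `expression_bundle`.
#' @return A tibble with one row per patient: `patient_id`, `tumor_sample`,
#'   `normal_sample`.
#' @export
bundle_pairs <- function(bundle) {
  wide <- tidyr::pivot_wider(bundle$design,
    names_from = "tissue", values_from = "sample_id"
  )
  tibble::tibble(
    patient_id = wide$patient_id,
    tumor_sample = wide$tumor,
    normal_sample = wide$normal
  )
}

#' Per-patient tumor-normal differences
#'
#' @param bundle An `expression_bundle` (log2-centered scale for meaningful
#'   log-ratios).
#' @return Numeric matrix, features x patients, of tumor minus normal values.
#' @export
paired_deltas <- function(bundle) {
  pr <- bundle_pairs(bundle)
  d <- bundle$values[, pr$tumor_sample, drop = FALSE] -
    bundle$values[, pr$normal_sample, drop = FALSE]
  colnames(d) <- pr$patient_id
  d
}

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read a paired expression bundle from tab-separated files
#'
#' @param values_path TSV of intensities: first column feature ids, header row
#'   sample ids.
#' @param detection_path TSV of detection calls (logical or 0/1), same layout.
#' @param design_path TSV with columns `sample_id`, `patient_id`, `tissue`.
#' @param feature_type `"gene"` or `"mirna"`.
#' @return An `expression_bundle` with `scale = "raw"`.
#' @export
read_expression_bundle <- function(values_path, detection_path, design_path,
                                   feature_type = c("gene", "mirna")) {
  feature_type <- match.arg(feature_type)
  values <- read_matrix_tsv(values_path)
  storage.mode(values) <- "double"
  det <- read_matrix_tsv(detection_path)
  detection <- matrix(as.logical(det), nrow = nrow(det), dimnames = dimnames(det))
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  if (!identical(rownames(values), rownames(detection))) {
    abort("feature ids differ between values and detection files.")
  }
  expression_bundle(values, detection, design,
    scale = "raw", feature_type = feature_type
  )
}

#' Write a paired expression bundle to tab-separated files
#'
#' Inverse of [read_expression_bundle()]; the round trip is lossless up to
#' numeric text precision.
#'
#' @inheritParams read_expression_bundle
#' @param bundle An `expression_bundle`.
#' @return Invisibly, the bundle.
#' @export
write_expression_bundle <- function(bundle, values_path, detection_path,
                                    design_path) {
  write_m <- function(m, path, transform = identity) {
    df <- tibble::as_tibble(transform(m), rownames = "feature_id")
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_m(bundle$values, values_path)
  write_m(bundle$detection, detection_path, function(m) {
    matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  })
  readr::write_tsv(bundle$design, design_path, progress = FALSE)
  invisible(bundle)
}

#' Convert detection p-values to detection calls
#'
#' Array platforms report a per-spot detection p-value; the pipeline's
#' detection filter wants boolean calls. A spot is called detected when its
#' detection p-value is below `alpha`.
#'
#' @param p_matrix Numeric matrix of detection p-values.
#' @param alpha Detection threshold (default 0.05).
#' @return Logical matrix of the same shape.
#' @export
detection_from_pvalues <- function(p_matrix, alpha = 0.05) {
  if (any(p_matrix < 0 | p_matrix > 1, na.rm = TRUE)) {
    abort("detection p-values must lie in [0, 1].")
  }
  m <- p_matrix < alpha
  m[is.na(m)] <- FALSE
  m
}
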