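#' Drop features not detected in any sample
#'
#' The first filtering step of the analysis: a feature is kept when its
#' detection call is TRUE in at least one sample; everything else is removed.
#' Feature order is preserved.
#'
#' @param bundle An `expression_bundle`.
#' @return The filtered `expression_bundle` (possibly with zero features).
#' @export
detection_filter <- function(bundle) {
  keep <- rowSums(bundle$detection) > 0
  if (!any(keep)) {
    inform("detection_filter: no feature detected in any sample; empty bundle returned.")
  }
  expression_bundle(
    bundle$values[keep, , drop = FALSE],
    bundle$detection[keep, , drop = FALSE],
    bundle$design,
    scale = bundle$scale, feature_type = bundle$feature_type
  )
}

#' Log2-transform and median-center each array
#'
#' Transforms raw intensities to log2 and subtracts each sample column's
#' median, so that every array has median exactly zero. This is the standard
#' normalization applied before the paired analysis.
#'
#' @param bundle A raw-scale `expression_bundle` with strictly positive values.
#' @return The bundle on the `log2_centered` scale.
#' @export
log2_median_center <- function(bundle) {
  if (bundle$scale != "raw") abort("bundle is already log2-centered.")
  v <- log2(bundle$values)
  v <- sweep(v, 2, apply(v, 2, stats::median), "-")
  expression_bundle(v, bundle$detection, bundle$design,
    scale = "log2_centered", feature_type = bundle$feature_type
  )
}

#' Consistent-direction differential expression filter
#'
#' With only a handful of patient pairs, a conservative filter is used before
#' any significance testing: a feature is called `up` only if its tumor minus
#' normal log2 difference is positive in every patient pair, `down` only if
#' negative in every pair, and `none` otherwise. An exact-zero difference in
#' any pair breaks consistency.
#'
#' @param bundle A log2-centered `expression_bundle`.
#' @return A tibble with columns `feature_id`, `direction`
#'   (`up`/`down`/`none`) and `mean_delta` (mean per-pair difference).
#' @export
consistent_direction <- function(bundle) {
  if (bundle$scale != "log2_centered") {
    abort("consistent_direction expects a log2-centered bundle.")
  }
  d <- paired_deltas(bundle)
  direction <- rep("none", nrow(d))
  direction[rowSums(d > 0) == ncol(d)] <- "up"
  direction[rowSums(d < 0) == ncol(d)] <- "down"
  tibble::tibble(
    feature_id = rownames(d),
    direction = direction,
    mean_delta = unname(rowMeans(d))
  )
}

#' Configuration for the SAM-style paired analysis
#'
#' @param s0_percentile Percentile (0-100) of the feature-wise standard-error
#'   distribution used as the fudge factor s0 (default 5).
#' @param n_permutations Number of sign-flip permutations (default 1000).
#'   When `2^n_pairs <= n_permutations` the exhaustive set of sign patterns is
#'   used instead.
#' @param fdr_threshold FDR used when flagging significant features
#'   (default 0.1).
#' @param rng_seed Integer seed for the permutation draw.
#' @return A list of class `sam_config`.
#' @export
sam_config <- function(s0_percentile = 5, n_permutations = 1000,
                       fdr_threshold = 0.1, rng_seed = 1L) {
  if (s0_percentile < 0 || s0_percentile > 100) {
    abort("`s0_percentile` must lie in [0, 100].")
  }
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    abort("`fdr_threshold` must lie in (0, 1).")
  }
  structure(
    list(
      s0_percentile = s0_percentile,
      n_permutations = as.integer(n_permutations),
      fdr_threshold = fdr_threshold,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sam_config"
  )
}

#' SAM-style paired d-statistic
#'
#' `d = mean(deltas) / (se(deltas) + s0)` where `se` is the standard error of
#' the mean (sample sd over sqrt(n)) and `s0` is a small positive fudge factor
#' that damps features with tiny scatter. With `s0 = 0` this is the one-sample
#' t statistic on the paired differences.
#'
#' @param deltas Numeric vector of per-patient paired differences (n >= 2).
#' @param s0 Non-negative fudge factor.
#' @return The d statistic (scalar).
#' @export
sam_paired_d <- function(deltas, s0) {
  if (length(deltas) < 2) abort("need at least 2 paired differences.")
  denom <- se_mean(deltas) + s0
  if (denom == 0) abort("degenerate scatter: se + s0 = 0.")
  mean(deltas) / denom
}

# s0 as a percentile of the feature-wise standard errors
sam_s0 <- function(delta_matrix, s0_percentile) {
  se <- apply(delta_matrix, 1, se_mean)
  unname(stats::quantile(se, s0_percentile / 100, type = 7))
}

sign_patterns <- function(n_pairs, config) {
  exhaustive <- 2^n_pairs <= config$n_permutations
  if (exhaustive) {
    s <- as.matrix(expand.grid(rep(list(c(1, -1)), n_pairs)))
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(config$rng_seed)
    s <- matrix(sample(c(1, -1), n_pairs * config$n_permutations, replace = TRUE),
      ncol = n_pairs
    )
  }
  dimnames(s) <- NULL
  list(patterns = s, exhaustive = exhaustive)
}

# d with the degenerate-scatter convention of the matrix path: a feature
# whose mean and scatter are both zero gets d = 0; a constant nonzero delta
# with zero scatter and s0 = 0 gets +/-Inf (maximally significant)
d_from_mean_se <- function(m, se, s0) {
  denom <- se + s0
  d <- ifelse(denom > 0, m / denom, sign(m) * Inf)
  d[m == 0 & denom == 0] <- 0
  d
}

# d statistics for every column of sign-flipped deltas; vectorized over
# permutations: squared deviations are sign-invariant, only the mean moves.
perm_d_stats <- function(delta_matrix, signs, s0) {
  n <- ncol(delta_matrix)
  ss <- rowSums(delta_matrix^2)
  m <- (delta_matrix %*% t(signs)) / n   # features x permutations
  v <- (ss - n * m^2) / (n - 1)
  v[v < 0] <- 0
  d_from_mean_se(m, sqrt(v / n), s0)
}

#' Sign-flip permutation FDR for the paired d-statistic
#'
#' For each feature, the q-value is the median over permutations of the count
#' of null |d| values at least as large as the observed |d|, divided by the
#' number of observed |d| at least as large, capped at 1 and monotonized so
#' that q never decreases as |d| decreases. Permutations flip the sign of each
#' patient's delta vector; when all `2^n_pairs` patterns fit inside
#' `n_permutations` the exhaustive set is used (and a message notes the
#' switch).
#'
#' @param delta_matrix Numeric matrix of per-patient differences
#'   (features x patients).
#' @param config A [sam_config()].
#' @return A list: `d` (observed statistics), `q` (q-values), `s0`,
#'   `n_permutations` used, `exhaustive` flag.
#' @export
sam_permutation_test <- function(delta_matrix, config = sam_config()) {
  n <- ncol(delta_matrix)
  if (n < 2) abort("need at least 2 patient pairs.")
  s0 <- sam_s0(delta_matrix, config$s0_percentile)
  d_obs <- d_from_mean_se(
    rowMeans(delta_matrix),
    apply(delta_matrix, 1, se_mean), s0
  )

  sp <- sign_patterns(n, config)
  if (sp$exhaustive && config$n_permutations != nrow(sp$patterns)) {
    inform(sprintf(
      "using exhaustive enumeration of %d sign patterns (<= %d requested permutations).",
      nrow(sp$patterns), config$n_permutations
    ))
  }
  d_null <- perm_d_stats(delta_matrix, sp$patterns, s0)

  abs_obs <- abs(d_obs)
  sorted_obs <- sort(abs_obs)
  n_feat <- length(d_obs)
  # #(values >= x): total minus count strictly below (exact, tie-safe)
  n_at_least <- function(x, sorted_vals) {
    length(sorted_vals) - findInterval(x, sorted_vals, left.open = TRUE)
  }
  obs_count <- n_at_least(abs_obs, sorted_obs)

  null_counts <- vapply(seq_len(ncol(d_null)), function(b) {
    n_at_least(abs_obs, sort(abs(d_null[, b])))
  }, numeric(n_feat))
  med_null <- apply(null_counts, 1, stats::median)

  q <- pmin(med_null / obs_count, 1)
  # monotone: larger |d| never gets a larger q
  ord_dec <- order(abs_obs, decreasing = TRUE)
  q[ord_dec] <- cummax(q[ord_dec])

  list(
    d = d_obs, q = q, s0 = s0,
    n_permutations = nrow(sp$patterns), exhaustive = sp$exhaustive
  )
}

#' Paired differential expression analysis
#'
#' Runs the full differential-expression stage on a raw bundle: detection
#' filtering, log2 median-centering, the consistent-direction filter, and the
#' SAM-style paired statistic with sign-flip permutation FDR.
#'
#' @param bundle A raw-scale `expression_bundle` (a log2-centered bundle is
#'   accepted and used as-is).
#' @param config A [sam_config()].
#' @return An object of class `sam_fit`. `tidy()` returns the per-feature
#'   table (`feature_id`, `direction`, `mean_delta`, `d_stat`, `q_value`);
#'   `glance()` returns one-row counts.
#' @export
diff_expression <- function(bundle, config = sam_config()) {
  bundle <- detection_filter(bundle)
  if (bundle$scale == "raw") bundle <- log2_median_center(bundle)
  cd <- consistent_direction(bundle)
  deltas <- paired_deltas(bundle)
  pt <- sam_permutation_test(deltas, config)
  structure(
    list(
      table = dplyr::mutate(cd, d_stat = unname(pt$d), q_value = unname(pt$q)),
      s0 = pt$s0,
      n_pairs = ncol(deltas),
      n_permutations = pt$n_permutations,
      exhaustive = pt$exhaustive,
      config = config,
      feature_type = bundle$feature_type
    ),
    class = "sam_fit"
  )
}

#' @export
print.sam_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sam_fit> %d %s features, %d pairs; %d up / %d down (consistent); %d at q < %g (s0 = %.4g, %d %s permutations)\n",
    g$n_features, x$feature_type, x$n_pairs, g$n_up, g$n_down,
    g$n_significant, x$config$fdr_threshold, x$s0, x$n_permutations,
    if (x$exhaustive) "exhaustive" else "sampled"
  ))
  invisible(x)
}

#' @rdname diff_expression
#' @param x A `sam_fit`.
#' @param ... Unused.
#' @export
tidy.sam_fit <- function(x, ...) x$table

#' @rdname diff_expression
#' @export
glance.sam_fit <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$table),
    n_up = sum(x$table$direction == "up"),
    n_down = sum(x$table$direction == "down"),
    n_significant = sum(x$table$q_value < x$config$fdr_threshold),
    s0 = x$s0,
    n_pairs = x$n_pairs,
    n_permutations = x$n_permutations,
    exhaustive = x$exhaustive
  )
}

#' @rdname diff_expression
#' @param object A `sam_fit`.
#' @export
autoplot.sam_fit <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(.data$mean_delta, .data$d_stat,
    colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d73027", down = "#4575b4", none = "grey60")
    ) +
    ggplot2::labs(
      x = "mean per-pair log2(tumor) - log2(normal)",
      y = "paired d statistic", colour = "direction"
    ) +
    ggplot2::theme_minimal()
}

#' Differentially expressed features of a fit
#'
#' @param fit A `sam_fit`.
#' @param fdr_significant If TRUE, additionally require
#'   `q_value < fdr_threshold`; by default only the consistent-direction
#'   filter is applied (the two layers are reported distinctly).
#' @return Tibble of features with direction `up` or `down`.
#' @export
de_features <- function(fit, fdr_significant = FALSE) {
  out <- dplyr::filter(fit$table, .data$direction != "none")
  if (fdr_significant) {
    out <- dplyr::filter(out, .data$q_value < fit$config$fdr_threshold)
  }
  out
}
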