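#' Read a Ct-value table
#'
#' @param path TSV with columns `sample_id`, `group` (`case`/`control`),
#'   optional `pair_id`, `target`, `ct_target`, `ct_reference`.
#' @return Tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "group", "target", "ct_target", "ct_reference")
  if (!all(req %in% names(ct))) {
    abort(paste("Ct table needs columns:", paste(req, collapse = ", ")))
  }
  if (!all(ct$group %in% c("case", "control"))) {
    abort("`group` must be 'case' or 'control'.")
  }
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)) ||
      any(ct$ct_target <= 0) || any(ct$ct_reference <= 0)) {
    abort("Ct values must be finite and positive.")
  }
  ct
}

#' Relative fold change by the delta-delta-Ct method
#'
#' Each record's delta-Ct is `ct_target - ct_reference` (target normalized to
#' the internal reference assay, e.g. U6 snRNA for miRNA or GAPDH for mRNA);
#' the delta-delta-Ct is the case delta-Ct minus the control delta-Ct, and
#' the fold change is `2^(-ddCt)`.
#'
#' @param ct_target_case,ct_reference_case Case Ct values (vectorized).
#' @param ct_target_control,ct_reference_control Control Ct values.
#' @return Fold change(s) `2^(-ddCt)`.
#' @export
#' @examples
#' ddct_fold_change(20, 18, 24, 20) # ddCt = -2 -> 4
ddct_fold_change <- function(ct_target_case, ct_reference_case,
                             ct_target_control, ct_reference_control) {
  args <- list(ct_target_case, ct_reference_case,
               ct_target_control, ct_reference_control)
  if (any(vapply(args, function(x) any(!is.finite(x)), logical(1)))) {
    abort("missing or non-finite Ct value.")
  }
  ddct <- (ct_target_case - ct_reference_case) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Per-sample fold changes for a Ct table
#'
#' Technical replicate Ct values (same sample, target and group) are averaged
#' before delta-Ct. When every case record has a `pair_id` matching a control
#' record, the fold change is computed pair-wise; otherwise each case sample
#' is referenced to the mean control delta-Ct (the convention for serum
#' panels normalized to cancer-free controls).
#'
#' @param ct Tibble of Ct records (see [read_ct_table()]).
#' @return Tibble: `target`, `sample_id` (case sample), `dct_case`,
#'   `dct_control`, `fold_change`, `paired`.
#' @export
qpcr_fold_changes <- function(ct) {
  dct <- ct |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("target", "group", "sample_id", "pair_id")
    ))) |>
    dplyr::summarise(
      dct = mean(.data$ct_target) - mean(.data$ct_reference),
      .groups = "drop"
    )
  cases <- dplyr::filter(dct, .data$group == "case")
  controls <- dplyr::filter(dct, .data$group == "control")
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    abort("need both case and control records.")
  }
  paired <- "pair_id" %in% names(dct) &&
    !any(is.na(cases$pair_id)) &&
    all(paste(cases$target, cases$pair_id) %in%
          paste(controls$target, controls$pair_id))
  if (paired) {
    out <- dplyr::inner_join(
      cases, controls,
      by = c("target", "pair_id"), suffix = c("_case", "_control")
    ) |>
      dplyr::transmute(
        target = .data$target, sample_id = .data$sample_id_case,
        dct_case = .data$dct_case, dct_control = .data$dct_control
      )
  } else {
    ref <- controls |>
      dplyr::group_by(.data$target) |>
      dplyr::summarise(dct_control = mean(.data$dct))
    out <- cases |>
      dplyr::inner_join(ref, by = "target") |>
      dplyr::transmute(
        target = .data$target, sample_id = .data$sample_id,
        dct_case = .data$dct, dct_control = .data$dct_control
      )
  }
  dplyr::mutate(out,
    fold_change = 2^(-(.data$dct_case - .data$dct_control)),
    paired = paired
  )
}

#' Compare case and control groups with a t-test
#'
#' Reports each group's mean and standard error, and a paired t-test (equal
#' lengths, matched order) or Welch two-sample t-test. If the paired
#' differences are all zero the test is degenerate; `t = 0`, `p = 1` are
#' reported with a warning.
#'
#' @param values_case,values_control Numeric vectors (n >= 2 each), e.g.
#'   relative expression values or delta-Ct values.
#' @param paired Use a paired test (requires equal lengths)?
#' @return An object of class `qpcr_test`; see `tidy()` and `glance()`.
#' @export
group_compare <- function(values_case, values_control, paired = FALSE) {
  if (length(values_case) < 2 || length(values_control) < 2) {
    abort("each group needs at least 2 values.")
  }
  if (paired && length(values_case) != length(values_control)) {
    abort("paired comparison requires equal group sizes.")
  }
  degenerate <- paired && all(values_case - values_control == 0)
  if (!paired && sd(values_case) == 0 && sd(values_control) == 0 &&
      mean(values_case) == mean(values_control)) {
    degenerate <- TRUE
  }
  if (degenerate) {
    warn("degenerate comparison (no variation in differences); reporting t = 0, p = 1.")
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_), p.value = 1)
  } else {
    tt <- stats::t.test(values_case, values_control, paired = paired)
  }
  structure(
    list(
      mean_case = mean(values_case), se_case = se_mean(values_case),
      mean_control = mean(values_control), se_control = se_mean(values_control),
      n_case = length(values_case), n_control = length(values_control),
      t_statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, paired = paired
    ),
    class = "qpcr_test"
  )
}

#' @export
print.qpcr_test <- function(x, ...) {
  cat(sprintf(
    "<qpcr_test> case %.3g +/- %.3g (n=%d) vs control %.3g +/- %.3g (n=%d); %s t = %.3g, p = %.3g\n",
    x$mean_case, x$se_case, x$n_case, x$mean_control, x$se_control,
    x$n_control, if (x$paired) "paired" else "Welch", x$t_statistic, x$p_value
  ))
  invisible(x)
}

#' @rdname group_compare
#' @param x,object A `qpcr_test`.
#' @param ... Unused.
#' @export
tidy.qpcr_test <- function(x, ...) {
  tibble::tibble(
    mean_case = x$mean_case, se_case = x$se_case,
    mean_control = x$mean_control, se_control = x$se_control,
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    method = if (x$paired) "paired t-test" else "Welch t-test"
  )
}

#' @rdname group_compare
#' @export
glance.qpcr_test <- function(x, ...) {
  tibble::tibble(
    n_case = x$n_case, n_control = x$n_control,
    paired = x$paired, p_value = x$p_value
  )
}

#' Bar chart of mean fold change per target with standard errors
#'
#' @param fold_changes Output of [qpcr_fold_changes()].
#' @return A ggplot object (mean +/- SE per target).
#' @export
plot_fold_changes <- function(fold_changes) {
  df <- fold_changes |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      mean_fc = mean(.data$fold_change),
      se_fc = se_mean(.data$fold_change)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$mean_fc)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_fc - .data$se_fc,
        ymax = .data$mean_fc + .data$se_fc
      ),
      width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "relative expression (fold change, mean +/- SE)") +
    ggplot2::theme_minimal()
}
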