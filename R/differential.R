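#' Group means and log2 fold change with a stabilizing pseudocount
#'
#' `log2fc = log2((mean(case) + pseudocount) / (mean(control) + pseudocount))`
#' using arithmetic group means of RPKM; the symmetric pseudocount (default
#' 0.5 RPKM) keeps the ratio finite and unbiased at zero coverage.
#'
#' @param case_values,control_values Non-empty numeric vectors (RPKM).
#' @param pseudocount Small positive stabilizer, in RPKM units.
#' @return One-row tibble: `mean_case`, `mean_control`, `log2fc`.
#' @export
fold_change <- function(case_values, control_values, pseudocount = 0.5) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    abort("Both groups must be non-empty.")
  }
  mc <- mean(case_values)
  mn <- mean(control_values)
  tibble::tibble(
    mean_case = mc,
    mean_control = mn,
    log2fc = log2((mc + pseudocount) / (mn + pseudocount))
  )
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p by the rank-sum null distribution when the smaller group has at
#' most `exact_max_n` observations and the data are tie-free; otherwise the
#' normal approximation with tie and continuity corrections. Two samples
#' with all values identical give p = 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max_n Largest min-group size for which the exact
#'   distribution is used.
#' @return A p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    return(1)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= exact_max_n
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)$p.value
  )
  min(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on the sorted scale
#' `adj_(i) = min over j >= i of (p_(j) * m / j)`, capped at 1, mapped back
#' to the input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values in the input order (empty in, empty out).
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric(0))
  }
  p.adjust(p_values, method = "BH")
}

#' Differential promoter-coverage testing between cohorts
#'
#' The per-TSS procedure: (1) group means and pseudocounted log2 fold change
#' for every TSS; (2) a fold-change prefilter keeps TSSs with
#' `max(ratio, 1/ratio) > fc_threshold`; (3) a two-sided Wilcoxon rank-sum
#' test per retained TSS; (4) Benjamini-Hochberg FDR across the tested set
#' (optionally across all TSSs); (5) a TSS is called `up`/`down` (promoter
#' coverage in cases relative to controls) only when all three criteria
#' hold: `p_value < alpha`, `|log2fc| >= log2(fc_threshold)` and
#' `fdr < fdr_threshold`. Untested TSSs keep their log2fc with `NA`
#' p-value/FDR and call `ns`.
#'
#' @param rpkm A `tss_rpkm` long tibble from [rpkm_matrix()].
#' @param sample_sheet Tibble with `sample_id` and `cohort`; samples
#'   labelled `control_label` form the control group, all others the case
#'   group. Each group needs at least 2 samples.
#' @param fc_threshold Fold-change gate (> 1).
#' @param alpha p-value threshold.
#' @param fdr_threshold FDR threshold.
#' @param pseudocount Passed to [fold_change()].
#' @param fdr_scope `"tested"` (BH over the prefiltered set, the default
#'   order of operations) or `"all"`.
#' @param prefilter Set `FALSE` to test every TSS regardless of fold change
#'   (e.g. to study type-I error); calls still require all three criteria.
#' @param control_label Cohort label identifying controls.
#' @return A tibble of class `tss_diff`: `gene_id`, `mean_case`,
#'   `mean_control`, `log2fc`, `tested`, `p_value`, `fdr`, `call`.
#' @export
differential_tss <- function(rpkm, sample_sheet,
                             fc_threshold = 1.5, alpha = 0.05,
                             fdr_threshold = 0.2, pseudocount = 0.5,
                             fdr_scope = c("tested", "all"),
                             prefilter = TRUE,
                             control_label = "control") {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(fc_threshold > 1, alpha > 0, alpha < 1, fdr_threshold > 0, fdr_threshold < 1)
  dat <- dplyr::inner_join(
    tibble::as_tibble(rpkm),
    dplyr::select(sample_sheet, "sample_id", "cohort"),
    by = "sample_id"
  )
  dat$group <- ifelse(dat$cohort == control_label, "control", "case")
  n_per <- table(unique(dat[, c("sample_id", "group")])$group)
  if (length(n_per) < 2 || any(n_per < 2)) {
    abort("Both cohorts need at least 2 samples.")
  }
  split_vals <- dplyr::summarise(
    dplyr::group_by(dat, .data$gene_id),
    case_values = list(.data$rpkm[.data$group == "case"]),
    control_values = list(.data$rpkm[.data$group == "control"]),
    .groups = "drop"
  )
  res <- dplyr::mutate(
    split_vals,
    mean_case = purrr::map_dbl(.data$case_values, mean),
    mean_control = purrr::map_dbl(.data$control_values, mean),
    log2fc = log2((.data$mean_case + pseudocount) / (.data$mean_control + pseudocount)),
    tested = if (prefilter) {
      pmax(2^.data$log2fc, 2^-.data$log2fc) > fc_threshold
    } else {
      rep(TRUE, dplyr::n())
    },
    p_value = NA_real_
  )
  idx <- which(res$tested)
  res$p_value[idx] <- purrr::map2_dbl(
    res$case_values[idx], res$control_values[idx], wilcoxon_rank_sum
  )
  res$fdr <- NA_real_
  if (fdr_scope == "tested") {
    res$fdr[idx] <- benjamini_hochberg(res$p_value[idx])
  } else {
    # BH over all TSSs: untested ones enter at p = 1
    p_all <- ifelse(is.na(res$p_value), 1, res$p_value)
    fdr_all <- benjamini_hochberg(p_all)
    res$fdr[idx] <- fdr_all[idx]
  }
  res$call <- "ns"
  hit <- res$tested &
    !is.na(res$p_value) & res$p_value < alpha &
    abs(res$log2fc) >= log2(fc_threshold) &
    !is.na(res$fdr) & res$fdr < fdr_threshold
  res$call[hit] <- ifelse(res$log2fc[hit] > 0, "up", "down")
  out <- dplyr::select(res, -"case_values", -"control_values")
  attr(out, "params") <- list(
    fc_threshold = fc_threshold, alpha = alpha, fdr_threshold = fdr_threshold,
    pseudocount = pseudocount, fdr_scope = fdr_scope, prefilter = prefilter
  )
  class(out) <- c("tss_diff", class(out))
  out
}

#' @describeIn differential_tss The differential table as a plain tibble.
#' @param x A `tss_diff` object.
#' @param ... Unused.
#' @export
tidy.tss_diff <- function(x, ...) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "params") <- NULL
  x
}

#' @describeIn differential_tss One-row summary (TSS counts, thresholds).
#' @export
glance.tss_diff <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_tss = nrow(x),
    n_tested = sum(x$tested),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    fc_threshold = p$fc_threshold,
    alpha = p$alpha,
    fdr_threshold = p$fdr_threshold
  )
}

#' Volcano-plot table
#'
#' One row per tested TSS: `gene_id`, `log2fc`, `neg_log10_p`, `call`.
#' Untested TSSs are excluded.
#'
#' @param records A `tss_diff` tibble.
#' @return A tibble ready for a volcano plot.
#' @export
volcano_table <- function(records) {
  tested <- records[records$tested, , drop = FALSE]
  tibble::tibble(
    gene_id = tested$gene_id,
    log2fc = tested$log2fc,
    neg_log10_p = -log10(tested$p_value),
    call = tested$call
  )
}

#' @describeIn differential_tss Volcano plot of the tested TSSs.
#' @param object A `tss_diff` object.
#' @export
autoplot.tss_diff <- function(object, ...) {
  tab <- volcano_table(object)
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc, .data$neg_log10_p, colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d73027", down = "#4575b4", ns = "grey60")
    ) +
    ggplot2::labs(
      x = expression(log[2] ~ "fold change (case / control)"),
      y = expression(-log[10] ~ italic(p)),
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap matrix of called TSSs
#'
#' RPKM values restricted to differential TSSs, z-scored per TSS (the usual
#' clustered-heatmap display convention).
#'
#' @param rpkm A `tss_rpkm` tibble.
#' @param records A `tss_diff` tibble.
#' @param z_score Z-score each TSS across samples?
#' @return Numeric matrix, samples in rows, called TSSs in columns.
#' @export
heatmap_matrix <- function(rpkm, records, z_score = TRUE) {
  called <- records$gene_id[records$call != "ns"]
  if (length(called) == 0) {
    abort("No differential TSSs to display.")
  }
  m <- rpkm_wide(rpkm)[, called, drop = FALSE]
  if (z_score) {
    m <- apply(m, 2, function(v) {
      s <- sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    })
  }
  m
}
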