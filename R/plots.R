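#' Mean promoter metaplot data for several gene sets
#'
#' Convenience wrapper around [geneset_mean_profile()] for a table of gene
#' sets (e.g. the top/bottom split from [select_top_bottom()]).
#'
#' @param profiles Long raw profile tibble from [sample_profiles()].
#' @param sets Tibble with columns `set` (or `set_name`) and `gene_id`.
#' @param flank_frac Passed to [relative_profile()].
#' @return Tibble: `set`, `offset`, `mean_depth`, `sd_depth`, ...
#' @export
metaplot_data <- function(profiles, sets, flank_frac = 0.75) {
  set_col <- if ("set" %in% names(sets)) "set" else "set_name"
  groups <- split(sets$gene_id, sets[[set_col]])
  dplyr::bind_rows(purrr::imap(groups, function(genes, nm) {
    out <- geneset_mean_profile(profiles, genes, flank_frac = flank_frac)
    dplyr::mutate(out, set = nm, .before = 1)
  }))
}

#' TSS metaplot (relative depth around the TSS, per gene set)
#'
#' @param data Output of [metaplot_data()].
#' @param ribbon Show +/- 1 SD (across genes) ribbons?
#' @return A ggplot.
#' @export
plot_metaplot <- function(data, ribbon = TRUE) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(.data$offset, .data$mean_depth, colour = .data$set, fill = .data$set)
  )
  if (ribbon) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_depth - .data$sd_depth,
        ymax = .data$mean_depth + .data$sd_depth
      ),
      alpha = 0.15, colour = NA
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "distance from TSS (bp, 5' to 3')",
      y = "relative depth", colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of differential TSS coverage (tile plot)
#'
#' ggplot rendering of [heatmap_matrix()], rows ordered by the sample
#' dendrogram when a clustering is supplied.
#'
#' @param m Matrix from [heatmap_matrix()].
#' @param clust Optional `tss_clust` used to order the samples.
#' @return A ggplot.
#' @export
plot_heatmap <- function(m, clust = NULL) {
  if (!is.null(clust)) {
    m <- m[clust$leaf_order, , drop = FALSE]
  }
  long <- tibble::tibble(
    sample_id = factor(rep(rownames(m), ncol(m)), levels = rownames(m)),
    gene_id = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$gene_id, .data$sample_id, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white", high = "#d73027") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
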