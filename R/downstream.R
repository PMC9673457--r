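#' PCA of samples over TSS profiles
#'
#' Columns (TSSs) are centered (and by default z-scored; constant TSSs are
#' set to zero), and scores are computed by singular value decomposition.
#' Explained-variance fractions are non-increasing and sum to at most 1.
#'
#' @param rpkm A `tss_rpkm` tibble from [rpkm_matrix()], or a numeric matrix
#'   with samples in rows.
#' @param n_components Number of components to keep.
#' @param z_score Unit-scale each TSS before the SVD?
#' @return An object of class `tss_pca` with elements `scores` (tibble,
#'   one row per sample), `explained` (variance fractions), `rotation`.
#' @export
pca_samples <- function(rpkm, n_components = 2, z_score = TRUE) {
  m <- if (is.matrix(rpkm)) rpkm else rpkm_wide(rpkm)
  if (nrow(m) < 2) {
    abort("PCA needs at least 2 samples.")
  }
  n_components <- min(n_components, nrow(m), ncol(m))
  if (z_score) {
    m <- apply(m, 2, function(v) {
      s <- sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    })
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2) / (nrow(m) - 1)
  if (total_var == 0) {
    scores <- matrix(0, nrow(m), n_components)
    explained <- rep(0, n_components)
    rotation <- matrix(0, ncol(m), n_components)
  } else {
    fit <- prcomp(m, center = TRUE, scale. = FALSE)
    k <- seq_len(min(n_components, ncol(fit$x)))
    scores <- fit$x[, k, drop = FALSE]
    explained <- (fit$sdev^2 / sum(fit$sdev^2))[k]
    rotation <- fit$rotation[, k, drop = FALSE]
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(m) %||% paste0("s", seq_len(nrow(m)))),
        tibble::as_tibble(scores)
      ),
      explained = explained,
      rotation = rotation
    ),
    class = "tss_pca"
  )
}

#' @export
print.tss_pca <- function(x, ...) {
  cat(sprintf(
    "<tss_pca> %d samples, %d components (%.1f%% variance in PC1)\n",
    nrow(x$scores), length(x$explained), 100 * x$explained[1]
  ))
  invisible(x)
}

#' @describeIn pca_samples Per-sample component scores.
#' @param x A `tss_pca` object.
#' @param ... Unused.
#' @export
tidy.tss_pca <- function(x, ...) {
  x$scores
}

#' @describeIn pca_samples One-row summary with explained-variance fractions.
#' @export
glance.tss_pca <- function(x, ...) {
  out <- tibble::tibble(n_samples = nrow(x$scores), n_components = length(x$explained))
  for (i in seq_along(x$explained)) {
    out[[paste0("var_explained_pc", i)]] <- x$explained[i]
  }
  out
}

#' @describeIn pca_samples Score plot of the first two components, optionally
#'   coloured by cohort.
#' @param object A `tss_pca` object.
#' @param sample_sheet Optional tibble with `sample_id` and `cohort`.
#' @export
autoplot.tss_pca <- function(object, sample_sheet = NULL, ...) {
  sc <- object$scores
  if (!is.null(sample_sheet)) {
    sc <- dplyr::left_join(sc,
      dplyr::select(sample_sheet, "sample_id", "cohort"),
      by = "sample_id"
    )
  }
  aes <- if ("cohort" %in% names(sc)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$cohort)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples over (by default z-scored) TSS
#' columns, typically restricted to the differential TSSs via `records`.
#' Deterministic given the input order; defaults mirror the common
#' clustered-heatmap setup (Euclidean distance, complete linkage).
#'
#' @param rpkm A `tss_rpkm` tibble or a numeric matrix (samples in rows).
#' @param records Optional `tss_diff` result; restricts the matrix to
#'   called TSSs.
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Linkage method for [stats::hclust()].
#' @param z_score Z-score each TSS first?
#' @return An object of class `tss_clust` wrapping the `hclust` tree, with
#'   leaf order, cophenetic distances and the settings used.
#' @export
cluster_samples <- function(rpkm, records = NULL, metric = "euclidean",
                            linkage = "complete", z_score = TRUE) {
  m <- if (is.matrix(rpkm)) rpkm else rpkm_wide(rpkm)
  if (!is.null(records)) {
    called <- records$gene_id[records$call != "ns"]
    if (length(called) == 0) {
      abort("No differential TSSs to cluster on.")
    }
    m <- m[, intersect(colnames(m), called), drop = FALSE]
  }
  if (nrow(m) < 2) {
    abort("Clustering needs at least 2 samples.")
  }
  if (z_score) {
    m <- apply(m, 2, function(v) {
      s <- sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    })
  }
  d <- dist(m, method = metric)
  if (any(!is.finite(d))) {
    abort("Distance matrix contains non-finite values.")
  }
  tree <- hclust(d, method = linkage)
  structure(
    list(
      tree = tree,
      leaf_order = tree$labels[tree$order],
      cophenetic = cophenetic(tree),
      metric = metric,
      linkage = linkage
    ),
    class = "tss_clust"
  )
}

#' @export
print.tss_clust <- function(x, ...) {
  cat(sprintf(
    "<tss_clust> %d samples, %s distance, %s linkage\n",
    length(x$leaf_order), x$metric, x$linkage
  ))
  invisible(x)
}

#' @describeIn cluster_samples Merge table of the dendrogram (one row per
#'   merge, with heights).
#' @param x A `tss_clust` object.
#' @param ... Unused.
#' @export
tidy.tss_clust <- function(x, ...) {
  tibble::tibble(
    merge = seq_len(nrow(x$tree$merge)),
    left = x$tree$merge[, 1],
    right = x$tree$merge[, 2],
    height = x$tree$height
  )
}

#' @describeIn cluster_samples One-row summary.
#' @export
glance.tss_clust <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$leaf_order),
    metric = x$metric,
    linkage = x$linkage,
    max_height = max(x$tree$height)
  )
}

#' Cut a sample dendrogram and score cohort purity
#'
#' Cuts the tree into `k` clusters and returns the label purity: the
#' fraction of samples whose cohort is the majority cohort of their cluster.
#'
#' @param clust A `tss_clust` object.
#' @param labels Named vector (or vector aligned with the tree labels) of
#'   cohort labels.
#' @param k Number of clusters.
#' @return Purity in (0, 1].
#' @export
cluster_purity <- function(clust, labels, k = 2) {
  cl <- cutree(clust$tree, k = k)
  if (!is.null(names(labels))) {
    labels <- labels[names(cl)]
  }
  sum(tapply(labels, cl, function(l) max(table(l)))) / length(cl)
}

#' Export a sample dendrogram as Newick
#'
#' @param clust A `tss_clust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clust, path) {
  ape::write.tree(ape::as.phylo(clust$tree), file = path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, tests whether the selected genes overlap it more than
#' expected by chance given the population (background), with the
#' upper-tail hypergeometric probability P(X >= k); BH-adjusted across the
#' tested sets. Sets with no member in the population are skipped. The
#' background should be the genes the selection was made from (e.g. all
#' profiled TSS genes), not the whole genome.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `population`; genes outside it are dropped with a warning).
#' @param gene_sets Tibble with columns `set_name`, `gene_id` (see
#'   [read_gene_sets()]).
#' @param population Character vector: the background gene universe.
#' @return A tibble, one row per tested set: `set_name`, `population_size`,
#'   `annotated` (K), `selected` (n), `overlap` (k), `p_value`, `fdr`,
#'   `overlap_genes` (list column).
#' @export
hypergeom_enrich <- function(selected, gene_sets, population) {
  population <- unique(population)
  if (length(population) == 0) {
    abort("`population` is empty.")
  }
  outside <- setdiff(selected, population)
  if (length(outside) > 0) {
    warn(sprintf("%d selected gene(s) outside the population were dropped.", length(outside)))
  }
  selected <- unique(intersect(selected, population))
  N <- length(population)
  n <- length(selected)
  sets <- split(gene_sets$gene_id, gene_sets$set_name)
  rows <- purrr::imap(sets, function(genes, nm) {
    members <- unique(intersect(genes, population))
    K <- length(members)
    if (K == 0) {
      return(NULL)
    }
    hit <- sort(intersect(members, selected))
    k <- length(hit)
    tibble::tibble(
      set_name = nm,
      population_size = N,
      annotated = K,
      selected = n,
      overlap = k,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      overlap_genes = list(hit)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) > 0) {
    out$fdr <- benjamini_hochberg(out$p_value)
    out <- dplyr::relocate(dplyr::arrange(out, .data$p_value), "fdr", .after = "p_value")
  }
  out
}

#' Intersect differential genes with a reference gene list
#'
#' Set intersection of the called (non-`ns`) genes with a user-supplied
#' list (e.g. an immune-gene list), annotated with each gene's coverage
#' direction and log2 fold change, in deterministic (lexicographic) order.
#'
#' @param records A `tss_diff` tibble.
#' @param reference_list Character vector of gene ids.
#' @return Tibble: `gene_id`, `call`, `log2fc`.
#' @export
intersect_gene_list <- function(records, reference_list) {
  called <- records[records$call != "ns", , drop = FALSE]
  hit <- dplyr::arrange(
    called[called$gene_id %in% reference_list, c("gene_id", "call", "log2fc")],
    .data$gene_id
  )
  tibble::as_tibble(hit)
}
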