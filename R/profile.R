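#' Weighted fragment counts in promoter windows
#'
#' Counts (sums of GC-correction weights of) fragments overlapping the
#' window `[pos - W, pos + W + 1)` around each TSS by at least 1 bp.
#'
#' @param fragments Fragment tibble (0-based half-open, with `weight`).
#' @param tss TSS tibble (one or more rows).
#' @param window_halfwidth Half-window W in bp.
#' @return A tibble with columns `gene_id`, `count`.
#' @export
window_count <- function(fragments, tss, window_halfwidth = 1000) {
  assert_tss(tss)
  fragments <- complete_fragments(assert_fragments(fragments))
  W <- window_halfwidth
  counts <- rep(0, nrow(tss))
  for (cn in unique(tss$chrom)) {
    ti <- which(tss$chrom == cn)
    fr <- fragments[fragments$chrom == cn, , drop = FALSE]
    if (nrow(fr) == 0) next
    win <- IRanges::IRanges(start = tss$pos[ti] - W + 1L, end = tss$pos[ti] + W + 1L)
    frg <- IRanges::IRanges(start = fr$start + 1L, end = fr$end)
    hits <- IRanges::findOverlaps(win, frg)
    w_sum <- tapply(
      fr$weight[S4Vectors::subjectHits(hits)],
      factor(S4Vectors::queryHits(hits), levels = seq_along(ti)),
      sum
    )
    w_sum[is.na(w_sum)] <- 0
    counts[ti] <- as.numeric(w_sum)
  }
  tibble::tibble(gene_id = tss$gene_id, count = counts)
}

#' Strand-oriented per-base depth profile around TSSs
#'
#' For each TSS, `depth[x]` is the summed fragment weight covering genomic
#' position `pos + x` (plus strand) or `pos - x` (minus strand), for
#' strand-oriented offsets x in -W..+W, so offsets always run 5' to 3' of
#' the gene.
#'
#' @inheritParams window_count
#' @return A long tibble: `gene_id`, `offset`, `depth`, with attribute
#'   `normalization = "raw"`.
#' @export
per_base_profile <- function(fragments, tss, window_halfwidth = 1000) {
  assert_tss(tss)
  fragments <- complete_fragments(assert_fragments(fragments))
  W <- as.integer(window_halfwidth)
  offs <- -W:W
  out <- purrr::map(unique(tss$chrom), function(cn) {
    ti <- which(tss$chrom == cn)
    fr <- fragments[fragments$chrom == cn, , drop = FALSE]
    chrom_len <- max(tss$pos[ti] + W + 1L, if (nrow(fr)) max(fr$end) else 0L)
    cov <- coverage_vector(fr, chrom_len)
    purrr::map(ti, function(k) {
      gpos <- tss$pos[k] + if (tss$strand[k] == "+") offs else -offs
      depth <- rep(0, length(offs))
      ok <- gpos >= 0L & gpos < chrom_len
      depth[ok] <- cov[gpos[ok] + 1L]
      tibble::tibble(gene_id = tss$gene_id[k], offset = offs, depth = depth)
    })
  })
  res <- dplyr::bind_rows(purrr::list_flatten(out))
  attr(res, "normalization") <- "raw"
  attr(res, "window_halfwidth") <- W
  res
}

#' Per-base profiles for every sample of a study
#'
#' @param samples Sample tibble with `sample_id` and a `fragments` list
#'   column (as produced by [simulate_cohorts()] or assembled from
#'   [read_fragments()]).
#' @inheritParams window_count
#' @param genes Optional subset of gene ids to profile.
#' @return Long tibble: `sample_id`, `gene_id`, `offset`, `depth`.
#' @export
sample_profiles <- function(samples, tss, window_halfwidth = 1000, genes = NULL) {
  if (!is.null(genes)) {
    tss <- tss[tss$gene_id %in% genes, , drop = FALSE]
  }
  res <- purrr::map2(samples$sample_id, samples$fragments, function(id, fr) {
    p <- per_base_profile(fr, tss, window_halfwidth)
    p$sample_id <- id
    p
  })
  out <- dplyr::bind_rows(res)
  attr(out, "window_halfwidth") <- as.integer(window_halfwidth)
  dplyr::relocate(out, "sample_id")
}

#' Relative (flank-normalized) profile depth
#'
#' Divides each profile by its mean depth over the flank offsets
#' (`|x| >= flank_frac * W`), the convention used for "relative depth" in
#' TSS metaplots; a profile whose flank mean is 1 is unchanged in shape and
#' its flank mean becomes exactly 1. Profiles with zero flank coverage get
#' `NA` depths.
#'
#' @param profiles Long profile tibble with columns `gene_id`, `offset`,
#'   `depth` (optionally `sample_id`).
#' @param flank_frac Fraction of W where the flank begins.
#' @return The tibble with `depth` replaced by relative depth.
#' @export
relative_profile <- function(profiles, flank_frac = 0.75) {
  W <- max(abs(profiles$offset))
  grp <- intersect(c("sample_id", "gene_id"), names(profiles))
  out <- dplyr::mutate(
    dplyr::group_by(profiles, dplyr::across(dplyr::all_of(grp))),
    .flank = mean(.data$depth[abs(.data$offset) >= flank_frac * W]),
    depth = ifelse(.data$.flank > 0, .data$depth / .data$.flank, NA_real_)
  )
  out <- dplyr::select(dplyr::ungroup(out), -".flank")
  attr(out, "normalization") <- "relative"
  out
}

#' Mean relative profile over a gene set
#'
#' Cohort-level TSS metaplot for one gene set. Two normalization orders are
#' offered:
#'
#' * `"aggregate"` (default): average the raw depth over samples per gene,
#'   then over the genes of the set, and flank-normalize the aggregate
#'   profile. This is the standard metaplot convention and is stable at low
#'   coverage, where a single gene's flank holds only a handful of
#'   fragments and per-profile ratios are heavy-tailed.
#' * `"per_gene"`: flank-normalize every (sample, gene) profile first, then
#'   average over genes and samples. Faithful to per-profile relative
#'   depth, but noisy below roughly 1X coverage.
#'
#' Dispersion is in both cases the offset-wise standard deviation across
#' genes of the per-gene (across-sample mean, flank-normalized) profiles.
#'
#' @param profiles Long raw profile tibble from [sample_profiles()] (columns
#'   `sample_id`, `gene_id`, `offset`, `depth`).
#' @param gene_set Character vector of gene ids (must all be profiled).
#' @param flank_frac Passed to [relative_profile()].
#' @param normalize Normalization order, see above.
#' @return Tibble: `offset`, `mean_depth`, `sd_depth`, `n_genes`, `n_samples`.
#' @export
geneset_mean_profile <- function(profiles, gene_set, flank_frac = 0.75,
                                 normalize = c("aggregate", "per_gene")) {
  normalize <- match.arg(normalize)
  if (length(gene_set) == 0) {
    abort("`gene_set` is empty.")
  }
  missing <- setdiff(gene_set, unique(profiles$gene_id))
  if (length(missing) > 0) {
    abort(sprintf(
      "%d gene(s) of the set are not profiled (e.g. %s).",
      length(missing), missing[1]
    ))
  }
  sel <- profiles[profiles$gene_id %in% gene_set, , drop = FALSE]
  ns <- if ("sample_id" %in% names(sel)) dplyr::n_distinct(sel$sample_id) else 1L
  W <- max(abs(sel$offset))

  # per-gene profile, averaged over samples, for the dispersion band
  per_gene_raw <- dplyr::summarise(
    dplyr::group_by(sel, .data$gene_id, .data$offset),
    depth = mean(.data$depth),
    .groups = "drop"
  )
  per_gene_rel <- relative_profile(per_gene_raw, flank_frac = flank_frac)
  disp <- dplyr::summarise(
    dplyr::group_by(per_gene_rel, .data$offset),
    sd_depth = sd(.data$depth, na.rm = TRUE),
    .groups = "drop"
  )

  if (normalize == "aggregate") {
    agg <- dplyr::summarise(
      dplyr::group_by(per_gene_raw, .data$offset),
      depth = mean(.data$depth),
      .groups = "drop"
    )
    flank <- mean(agg$depth[abs(agg$offset) >= flank_frac * W])
    agg$mean_depth <- if (flank > 0) agg$depth / flank else NA_real_
    out <- dplyr::select(agg, "offset", "mean_depth")
  } else {
    rel <- relative_profile(sel, flank_frac = flank_frac)
    per_gene <- dplyr::summarise(
      dplyr::group_by(rel, .data$gene_id, .data$offset),
      depth = mean(.data$depth, na.rm = TRUE),
      .groups = "drop"
    )
    out <- dplyr::summarise(
      dplyr::group_by(per_gene, .data$offset),
      mean_depth = mean(.data$depth, na.rm = TRUE),
      .groups = "drop"
    )
  }
  out <- dplyr::left_join(out, disp, by = "offset")
  out$n_genes <- length(unique(sel$gene_id))
  out$n_samples <- ns
  out
}

#' RPKM-normalized promoter-window matrix
#'
#' For every sample and (by default primary) TSS, the weighted window count
#' is normalized as reads per kilobase per million mapped fragments:
#' `rpkm = 1e9 * count / (region_length * total_mapped_fragments)`, with
#' `region_length = 2 * window_halfwidth` (the 2 kb promoter window).
#'
#' @param samples Sample tibble with `sample_id`, `total_mapped_fragments`
#'   and a `fragments` list column.
#' @inheritParams window_count
#' @param primary_only Restrict to primary TSSs (one per gene)?
#' @return A long tibble of class `tss_rpkm`: `sample_id`, `gene_id`,
#'   `count`, `rpkm`; attributes `window_halfwidth`, `region_length`.
#' @export
rpkm_matrix <- function(samples, tss, window_halfwidth = 1000,
                        primary_only = TRUE) {
  assert_tss(tss)
  if (any(samples$total_mapped_fragments <= 0)) {
    abort("Every sample needs total_mapped_fragments > 0.")
  }
  if (primary_only && "is_primary" %in% names(tss)) {
    tss <- tss[tss$is_primary, , drop = FALSE]
  }
  region_length <- 2 * window_halfwidth
  res <- purrr::pmap(
    list(samples$sample_id, samples$fragments, samples$total_mapped_fragments),
    function(id, fr, total) {
      wc <- window_count(fr, tss, window_halfwidth)
      tibble::tibble(
        sample_id = id,
        gene_id = wc$gene_id,
        count = wc$count,
        rpkm = 1e9 * wc$count / (region_length * total)
      )
    }
  )
  out <- dplyr::bind_rows(res)
  attr(out, "window_halfwidth") <- window_halfwidth
  attr(out, "region_length") <- region_length
  class(out) <- c("tss_rpkm", class(out))
  out
}

#' Wide matrix view of a [rpkm_matrix()] result
#'
#' @param rpkm A `tss_rpkm` tibble.
#' @param value Which column to spread (`"rpkm"` or `"count"`).
#' @return Numeric matrix, samples in rows, TSS genes in columns.
#' @export
rpkm_wide <- function(rpkm, value = "rpkm") {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(rpkm), "sample_id", "gene_id",
      dplyr::all_of(value)),
    names_from = "gene_id", values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

#' Randomly pool low-coverage control samples
#'
#' Shuffles the control samples with the given seed (within strata when
#' `stratify_by` is given, e.g. integer gestational-age weeks), partitions
#' each stratum into groups of exactly `pool_size`, discards leftovers with
#' a warning, and concatenates each group's fragments into one pseudo-sample
#' whose `total_mapped_fragments` is the member sum. 140 controls pooled 4
#' at a time therefore give 35 pools.
#'
#' @param samples Control-sample tibble with `sample_id`,
#'   `total_mapped_fragments` and a `fragments` list column.
#' @param pool_size Samples per pool.
#' @param seed Seed for the random shuffle.
#' @param stratify_by Optional name of a column whose values define strata
#'   (discretize continuous covariates first, e.g.
#'   `mutate(week = floor(gestational_age))`).
#' @return A sample tibble of pools (`sample_id` = pool id, `members` list
#'   column of member sample ids).
#' @export
pool_controls <- function(samples, pool_size = 4, seed = NULL,
                          stratify_by = NULL) {
  stopifnot(pool_size >= 1)
  strata <- if (is.null(stratify_by)) {
    rep("all", nrow(samples))
  } else {
    as.character(samples[[stratify_by]])
  }
  groups <- split(seq_len(nrow(samples)), strata)
  if (all(lengths(groups) < pool_size)) {
    abort(sprintf("No stratum holds at least pool_size = %d samples.", pool_size))
  }
  assignment <- with_seed_if(seed, {
    purrr::map(groups, function(idx) {
      idx <- idx[sample.int(length(idx))]
      n_pools <- length(idx) %/% pool_size
      list(
        pools = if (n_pools > 0) {
          split(idx[seq_len(n_pools * pool_size)], rep(seq_len(n_pools), each = pool_size))
        } else {
          list()
        },
        n_left = length(idx) - n_pools * pool_size
      )
    })
  })
  n_left <- sum(purrr::map_int(assignment, "n_left"))
  if (n_left > 0) {
    warn(sprintf("Discarded %d leftover sample(s) not filling a pool.", n_left))
  }
  pools <- purrr::list_flatten(purrr::map(assignment, "pools"))
  res <- purrr::imap(pools, function(idx, nm) {
    frags <- dplyr::arrange(
      dplyr::bind_rows(samples$fragments[idx]),
      .data$chrom, .data$start, .data$end
    )
    tibble::tibble(
      cohort = samples$cohort[idx][1],
      gestational_age = mean(samples$gestational_age[idx]),
      total_mapped_fragments = sum(samples$total_mapped_fragments[idx]),
      members = list(samples$sample_id[idx]),
      fragments = list(frags)
    )
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(out,
    sample_id = sprintf("pool%03d", dplyr::row_number()),
    .before = 1
  )
  out
}

#' Split genes into the most- and least-expressed sets
#'
#' Ranks genes by an expression (or expression-proxy) level and returns the
#' `top_n` highest and `top_n` lowest, the gene sets contrasted in
#' Top500/Bottom500 promoter metaplots. Ties are broken by gene id
#' (lexicographic) so the split is deterministic.
#'
#' @param expression Tibble with columns `gene_id` and `expression`.
#' @param top_n Set size (default 500).
#' @return Tibble with columns `set` (`"top"`/`"bottom"`) and `gene_id`;
#'   the two sets are disjoint.
#' @export
select_top_bottom <- function(expression, top_n = 500) {
  stopifnot(all(c("gene_id", "expression") %in% names(expression)))
  if (nrow(expression) < 2 * top_n) {
    abort(sprintf(
      "Need at least %d genes to pick disjoint top/bottom %d.", 2 * top_n, top_n
    ))
  }
  ranked <- dplyr::arrange(expression, dplyr::desc(.data$expression), .data$gene_id)
  dplyr::bind_rows(
    tibble::tibble(set = "top", gene_id = head(ranked$gene_id, top_n)),
    tibble::tibble(set = "bottom", gene_id = rev(utils::tail(ranked$gene_id, top_n)))
  )
}
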