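#' Annotate fragments with their GC fraction
#'
#' Computes `gc_fraction = (#G + #C) / (#unambiguous bases)` over each
#' fragment's reference span. Ambiguous bases (N etc.) are excluded from
#' numerator and denominator; a fragment spanning only ambiguous bases gets
#' `NA` and is left untouched by the correction.
#'
#' @param fragments Fragment tibble (0-based half-open).
#' @param reference A [ref_genome].
#' @return The fragments with `gc_fraction` filled in.
#' @export
annotate_gc <- function(fragments, reference) {
  assert_fragments(fragments)
  fragments <- complete_fragments(fragments)
  if (nrow(fragments) == 0) {
    return(fragments)
  }
  out <- dplyr::group_split(fragments, .data$chrom, .keep = TRUE)
  out <- purrr::map(out, function(fr) {
    chr <- ref_chrom(reference, fr$chrom[1])
    bad <- fr$start < 0 | fr$end > chr$length
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "Fragment %s:%d-%d lies outside the reference (length %d).",
        fr$chrom[i], fr$start[i], fr$end[i], chr$length
      ))
    }
    fr$gc_fraction <- interval_gc(chr, fr$start, fr$end)
    fr
  })
  dplyr::bind_rows(out)
}

#' Estimate a GC sampling-bias model
#'
#' Histograms the GC fraction of the observed fragments into `gc_bins` equal
#' bins on [0, 1] and compares it with the GC distribution of random genomic
#' positions (lengths resampled from the observed fragment lengths), rescaled
#' to the same total. The per-bin correction weight is `expected / observed`;
#' bins with no observed or no expected mass, or with fewer than
#' `min_bin_count` observed fragments, keep weight 1, and weights are capped
#' to `weight_cap` for robustness against sparse GC tails.
#'
#' For real genomes a precomputed expected histogram (e.g. mappability-aware)
#' can be supplied via `expected`.
#'
#' @param fragments Fragments with `gc_fraction` (see [annotate_gc()]).
#' @param reference A [ref_genome]; ignored when `expected` is given.
#' @param gc_bins Number of GC bins.
#' @param n_expected_draws Random positions used to build the expected
#'   histogram.
#' @param seed Seed for the expected-position draws.
#' @param min_bin_count Minimum observed fragments for a bin to be corrected.
#' @param weight_cap Length-2 numeric, lower/upper weight bounds.
#' @param expected Optional precomputed expected counts per bin (length
#'   `gc_bins`; any scale, it is rescaled internally).
#' @return An object of class `gc_bias_model`.
#' @export
estimate_gc_bias <- function(fragments, reference, gc_bins = 100,
                             n_expected_draws = 1e5, seed = NULL,
                             min_bin_count = 50, weight_cap = c(0.1, 10),
                             expected = NULL) {
  assert_fragments(fragments)
  if (nrow(fragments) == 0) {
    abort("Cannot estimate GC bias from an empty fragment set.")
  }
  if (!"gc_fraction" %in% names(fragments) || all(is.na(fragments$gc_fraction))) {
    abort("Fragments carry no gc_fraction; run annotate_gc() first.")
  }
  edges <- seq(0, 1, length.out = gc_bins + 1)
  gc <- fragments$gc_fraction[!is.na(fragments$gc_fraction)]
  observed <- bin_counts(gc, edges)

  if (is.null(expected)) {
    lens <- fragments$end - fragments$start
    chrom_lens <- chrom_lengths(reference)
    expected_gc <- with_seed_if(seed, {
      draw_len <- sample(lens, n_expected_draws, replace = TRUE)
      draw_chr <- sample(names(chrom_lens), n_expected_draws,
        replace = TRUE, prob = chrom_lens
      )
      gc_all <- numeric(0)
      for (cn in unique(draw_chr)) {
        l <- draw_len[draw_chr == cn]
        chr <- ref_chrom(reference, cn)
        start <- floor(runif(length(l), 0, chr$length - l))
        gc_all <- c(gc_all, interval_gc(chr, start, start + l))
      }
      gc_all
    })
    expected <- bin_counts(expected_gc[!is.na(expected_gc)], edges)
  }
  if (length(expected) != gc_bins) {
    abort(sprintf("`expected` must have %d bins.", gc_bins))
  }
  expected <- expected * sum(observed) / sum(expected)

  weight <- rep(1, gc_bins)
  usable <- observed >= min_bin_count & expected > 0
  weight[usable] <- expected[usable] / observed[usable]
  weight <- pmin(weight_cap[2], pmax(weight_cap[1], weight))

  structure(
    list(
      bin_edges = edges, observed = observed, expected = expected,
      weight = weight, n_fragments = length(gc)
    ),
    class = "gc_bias_model"
  )
}

bin_counts <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(edges) - 1)
}

#' @export
print.gc_bias_model <- function(x, ...) {
  cat(sprintf(
    "<gc_bias_model> %d bins, %d fragments; weight range [%.3f, %.3f]\n",
    length(x$weight), x$n_fragments, min(x$weight), max(x$weight)
  ))
  invisible(x)
}

#' @describeIn estimate_gc_bias One row per GC bin (bin_lo, bin_hi, observed,
#'   expected, weight).
#' @param x A `gc_bias_model`.
#' @param ... Unused.
#' @export
tidy.gc_bias_model <- function(x, ...) {
  nb <- length(x$weight)
  tibble::tibble(
    bin_lo = x$bin_edges[-(nb + 1)],
    bin_hi = x$bin_edges[-1],
    observed = x$observed,
    expected = x$expected,
    weight = x$weight
  )
}

#' @describeIn estimate_gc_bias One-row model summary.
#' @export
glance.gc_bias_model <- function(x, ...) {
  corrected <- which(x$weight != 1)
  tibble::tibble(
    n_fragments = x$n_fragments,
    n_bins = length(x$weight),
    n_bins_corrected = length(corrected),
    max_weight = max(x$weight),
    min_weight = min(x$weight)
  )
}

#' Apply a GC-bias model to fragments
#'
#' Multiplies each fragment's weight by the correction weight of its GC bin.
#' Fragments without a GC fraction keep their weight; order and coordinates
#' are unchanged.
#'
#' @param fragments Fragments with `gc_fraction`.
#' @param model A `gc_bias_model` from [estimate_gc_bias()].
#' @return The fragments with updated `weight`.
#' @export
apply_gc_correction <- function(fragments, model) {
  assert_fragments(fragments)
  fragments <- complete_fragments(fragments)
  stopifnot(inherits(model, "gc_bias_model"))
  gc <- fragments$gc_fraction
  has_gc <- !is.na(gc)
  idx <- findInterval(gc[has_gc], model$bin_edges,
    rightmost.closed = TRUE, all.inside = TRUE
  )
  fragments$weight[has_gc] <- fragments$weight[has_gc] * model$weight[idx]
  fragments
}

#' Serialize / restore a GC-bias model as TSV
#'
#' @param model A `gc_bias_model`.
#' @param path TSV path.
#' @return `path` (write) or the model (read).
#' @export
write_gc_model <- function(model, path) {
  write_table(tidy(model), path)
}

#' @rdname write_gc_model
#' @export
read_gc_model <- function(path) {
  tab <- read_table_tsv(path)
  structure(
    list(
      bin_edges = c(tab$bin_lo, tab$bin_hi[nrow(tab)]),
      observed = tab$observed, expected = tab$expected,
      weight = tab$weight, n_fragments = sum(tab$observed)
    ),
    class = "gc_bias_model"
  )
}

#' @describeIn estimate_gc_bias Observed vs expected GC histograms and the
#'   per-bin correction weight.
#' @param object A `gc_bias_model`.
#' @export
autoplot.gc_bias_model <- function(object, ...) {
  tab <- tidy(object)
  tab$gc <- (tab$bin_lo + tab$bin_hi) / 2
  long <- tidyr::pivot_longer(tab, c("observed", "expected"),
    names_to = "which", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$gc, .data$count, colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fragment GC fraction", y = "fragments", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Window-level GC and weighted fragment counts
#'
#' Tiles each chromosome with non-overlapping windows and reports the window
#' GC fraction alongside the summed fragment weight (fragments assigned by
#' midpoint). The Spearman correlation between the two columns is the usual
#' diagnostic of residual GC bias: positive before correction on GC-biased
#' data, near zero after.
#'
#' @param fragments Fragment tibble (weights used as-is).
#' @param reference A [ref_genome].
#' @param window_size Window size in bp.
#' @return Tibble: `chrom`, `window_start`, `gc`, `count`.
#' @export
window_gc_counts <- function(fragments, reference, window_size = 2000) {
  assert_fragments(fragments)
  fragments <- complete_fragments(fragments)
  out <- purrr::imap(reference$chroms, function(chr, cn) {
    n_win <- chr$length %/% window_size
    if (n_win == 0) {
      return(NULL)
    }
    start <- (seq_len(n_win) - 1L) * window_size
    gc <- interval_gc(chr, start, start + window_size)
    count <- rep(0, n_win)
    fr <- fragments[fragments$chrom == cn, , drop = FALSE]
    if (nrow(fr) > 0) {
      bin <- ((fr$start + fr$end) %/% 2L) %/% window_size + 1L
      keep <- bin >= 1 & bin <= n_win
      sums <- rowsum(fr$weight[keep], bin[keep])
      count[as.integer(rownames(sums))] <- sums[, 1]
    }
    tibble::tibble(chrom = cn, window_start = start, gc = gc, count = count)
  })
  dplyr::bind_rows(purrr::compact(out))
}
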