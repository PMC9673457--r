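# Shared fixture builders; everything is generated in code at test time.

# Small study spec used across module tests: 50 genes on 200 kb.
tiny_spec <- function(...) {
  synthetic_spec(
    genome_length = 2e5, n_genes = 50, mean_depth = 1,
    ...
  )
}

# A reference built from a literal sequence, for hand-checkable GC tests.
literal_ref <- function(seq, chrom = "chr1") {
  ref_genome(setNames(seq, chrom))
}

# Fragment tibble from 0-based half-open (start, end) pairs.
frags <- function(start, end, weight = 1, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    weight = weight, gc_fraction = NA_real_
  )
}

# One-row TSS tibble.
tss_row <- function(pos, strand = "+", gene_id = "gA", chrom = "chr1") {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, pos = as.integer(pos),
    strand = strand, is_primary = TRUE
  )
}

# Independent brute-force two-sided Wilcoxon rank-sum p-value by complete
# enumeration of all rank assignments (tie-free data only).
enum_wilcox_p <- function(x, y) {
  m <- length(x)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(m)])
  mu <- m * (m + length(y) + 1) / 2
  combos <- utils::combn(m + length(y), m)
  all_ranks <- seq_len(m + length(y))
  w_all <- apply(combos, 2, function(idx) sum(all_ranks[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Independent step-up BH implementation (sorted-scale running minimum).
manual_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force per-base depth over a window: loop positions, count covering
# fragments by weight (0-based half-open fragments).
brute_depth <- function(fragments, positions) {
  vapply(positions, function(p) {
    sum(fragments$weight[fragments$start <= p & p < fragments$end])
  }, numeric(1))
}
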