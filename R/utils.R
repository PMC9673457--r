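# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards. All randomized steps in the package route
# through this so identical seeds give identical outputs.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive a stage seed from a global one; fixed offsets keep stages
# independently reproducible. Kept below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483587L)
}

assert_fragments <- function(fragments, arg = "fragments") {
  needed <- c("chrom", "start", "end")
  if (!is.data.frame(fragments) || !all(needed %in% names(fragments))) {
    abort(sprintf("`%s` must be a data frame with columns chrom, start, end.", arg))
  }
  invisible(fragments)
}

# Ensure optional fragment columns exist with their defaults
# (weight = 1 before GC correction, gc_fraction absent).
complete_fragments <- function(fragments) {
  if (!"weight" %in% names(fragments)) {
    fragments$weight <- 1
  }
  if (!"gc_fraction" %in% names(fragments)) {
    fragments$gc_fraction <- NA_real_
  }
  tibble::as_tibble(fragments)
}

assert_tss <- function(tss, arg = "tss") {
  needed <- c("gene_id", "chrom", "pos", "strand")
  if (!is.data.frame(tss) || !all(needed %in% names(tss))) {
    abort(sprintf("`%s` must be a data frame with columns gene_id, chrom, pos, strand.", arg))
  }
  bad <- setdiff(unique(tss$strand), c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("Invalid strand value(s): %s (must be '+' or '-').", paste(bad, collapse = ", ")))
  }
  invisible(tss)
}

# Weighted per-base coverage of one chromosome as a numeric vector of
# length `chrom_len`, from 0-based half-open fragment intervals.
coverage_vector <- function(fragments, chrom_len) {
  if (nrow(fragments) == 0) {
    return(numeric(chrom_len))
  }
  ir <- IRanges::IRanges(start = fragments$start + 1L, end = fragments$end)
  cov <- IRanges::coverage(ir, weight = fragments$weight, width = chrom_len)
  as.numeric(cov)
}
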