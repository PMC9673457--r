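#' Reference genome container with precomputed GC structure
#'
#' Wraps one or more chromosome sequences together with cumulative GC and
#' unambiguous-base counts, so per-fragment GC fractions and sliding-window
#' GC can be computed in O(1) per query. Ambiguous bases (anything outside
#' ACGT, e.g. N) are excluded from both the GC numerator and the denominator.
#'
#' @param seqs Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `ref_genome`.
#' @export
ref_genome <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("Reference sequences must be named (chromosome names).")
  }
  chroms <- purrr::map(seqs, function(s) {
    raw <- charToRaw(s)
    is_gc <- raw %in% charToRaw("GCgc")
    is_ok <- raw %in% charToRaw("ACGTacgt")
    list(
      length = length(raw),
      # leading 0 so counts over 0-based half-open [s, e) are cum[e+1] - cum[s+1]
      gc_cum = cumsum(c(0L, as.integer(is_gc))),
      ok_cum = cumsum(c(0L, as.integer(is_ok))),
      seq = s
    )
  })
  structure(list(chroms = chroms), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  lens <- purrr::map_int(x$chroms, "length")
  cat("<ref_genome> ", length(lens), " sequence(s), ",
    format(sum(lens), big.mark = ","), " bp total\n",
    sep = ""
  )
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [ref_genome] object.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ref_genome(seqs)
}

#' Write a reference genome to FASTA
#'
#' @param reference A [ref_genome] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(purrr::map_chr(reference$chroms, "seq"))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Chromosome lengths of a reference
#'
#' @param reference A [ref_genome] object.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(reference) {
  purrr::map_int(reference$chroms, "length")
}

ref_chrom <- function(reference, chrom) {
  chr <- reference$chroms[[chrom]]
  if (is.null(chr)) {
    abort(sprintf("Chromosome '%s' not present in the reference.", chrom))
  }
  chr
}

# GC fraction over 0-based half-open intervals on one chromosome;
# NA when the span contains no unambiguous base.
interval_gc <- function(chr, start, end) {
  gc <- chr$gc_cum[end + 1L] - chr$gc_cum[start + 1L]
  ok <- chr$ok_cum[end + 1L] - chr$ok_cum[start + 1L]
  ifelse(ok > 0, gc / ok, NA_real_)
}
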