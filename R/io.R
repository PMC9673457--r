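#' Read cfDNA fragment intervals from BED or BAM
#'
#' Reads aligned cfDNA fragments as 0-based half-open intervals and applies a
#' fragment-length filter. BED3 input (`chrom`, `start`, `end`, no header) is
#' read directly; for BAM input a fragment is the outer span of a properly
#' paired read pair, or the read span for single-end data (the low-coverage
#' cfDNA platforms this pipeline targets sequence 150-160 bp inserts
#' single-end).
#'
#' Malformed intervals (`end <= start`) are skipped with a warning; the
#' number of records read and filtered is attached as attributes
#' `n_read` / `n_filtered`.
#'
#' @param path Path to a `.bed` (or any tab-separated chrom/start/end) file,
#'   or a coordinate-sorted `.bam` file (requires the Rsamtools package).
#' @param min_length,max_length Inclusive fragment-length bounds in bp.
#'   Defaults are permissive; the synthetic generator emits 150-160 bp.
#' @return A tibble with columns `chrom`, `start`, `end`, `weight` (1 before
#'   GC correction) and `gc_fraction` (NA until [annotate_gc()]).
#' @export
read_fragments <- function(path, min_length = 100, max_length = 300) {
  if (!file.exists(path)) {
    abort(sprintf("Fragment file not found: %s", path))
  }
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    raw <- read_fragments_bam(path)
  } else {
    raw <- readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end"),
      col_types = readr::cols_only(
        chrom = readr::col_character(),
        start = readr::col_double(),
        end = readr::col_double()
      ),
      progress = FALSE
    )
  }
  n_read <- nrow(raw)
  bad <- !is.finite(raw$start) | !is.finite(raw$end) | raw$end <= raw$start
  if (any(bad)) {
    warn(sprintf("Skipped %d malformed interval(s) with end <= start.", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
  }
  len <- raw$end - raw$start
  keep <- len >= min_length & len <= max_length
  out <- complete_fragments(raw[keep, , drop = FALSE])
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  attr(out, "n_read") <- n_read
  attr(out, "n_filtered") <- n_read - nrow(out)
  out
}

read_fragments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Reading BAM requires the Rsamtools package; supply BED instead.")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "isize", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  paired <- bitwAnd(b$flag, 1L) > 0L
  proper <- bitwAnd(b$flag, 2L) > 0L
  # paired data: outer span from the leftmost properly-paired mate;
  # single-end data: the read span itself
  use_pair <- paired & proper & !is.na(b$isize) & b$isize > 0L
  use_single <- !paired
  start1 <- c(b$pos[use_pair], b$pos[use_single])
  width <- c(b$isize[use_pair], b$qwidth[use_single])
  tibble::tibble(
    chrom = as.character(c(b$rname[use_pair], b$rname[use_single])),
    start = start1 - 1, # BAM pos is 1-based
    end = start1 - 1 + width
  )
}

#' Write fragments as BED3 (plus optional weight column)
#'
#' @param fragments Fragment tibble (0-based half-open coordinates).
#' @param path Output path.
#' @param weights Write the GC-correction weight as a 4th column?
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path, weights = FALSE) {
  assert_fragments(fragments)
  cols <- c("chrom", "start", "end", if (weights) "weight")
  out <- complete_fragments(fragments)[, cols]
  if (weights) {
    out$weight <- formatC(out$weight, format = "fg", digits = 6)
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Accepts a tab-separated table with header columns `gene_id`, `chrom`,
#' `pos`, `strand` and optional `is_primary`, or a BED6 file (`.bed`
#' extension; gene id taken from the name column, TSS from the
#' strand-appropriate interval end). Coordinates are 0-based.
#'
#' When no `is_primary` column is given, the first TSS listed per gene is
#' marked as the primary TSS (pTSS) used for per-gene promoter testing.
#' Duplicate (gene_id, pos, strand) rows are collapsed with a warning; an
#' invalid strand is an error.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `gene_id`, `chrom`, `pos`, `strand`,
#'   `is_primary`.
#' @export
read_tss_table <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
      col_types = "cddcdc",
      progress = FALSE
    )
    tss <- tibble::tibble(
      gene_id = bed$gene_id,
      chrom = bed$chrom,
      pos = ifelse(bed$strand == "+", bed$start, bed$end - 1),
      strand = bed$strand
    )
  } else {
    tss <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    needed <- c("gene_id", "chrom", "pos", "strand")
    if (!all(needed %in% names(tss))) {
      abort("TSS table must have columns gene_id, chrom, pos, strand.")
    }
  }
  assert_tss(tss)
  tss$pos <- as.integer(tss$pos)
  if (any(tss$pos < 0)) {
    abort("TSS positions must be >= 0.")
  }
  dup <- duplicated(tss[, c("gene_id", "pos", "strand")])
  if (any(dup)) {
    warn(sprintf("Collapsed %d duplicate TSS row(s).", sum(dup)))
    tss <- tss[!dup, , drop = FALSE]
  }
  if (!"is_primary" %in% names(tss)) {
    tss <- dplyr::mutate(
      dplyr::group_by(tss, .data$gene_id),
      is_primary = dplyr::row_number() == 1L
    )
    tss <- dplyr::ungroup(tss)
  } else {
    tss$is_primary <- as.logical(tss$is_primary)
    n_primary <- dplyr::count(dplyr::filter(tss, .data$is_primary), .data$gene_id)
    if (any(n_primary$n > 1)) {
      abort("At most one primary TSS per gene_id is allowed.")
    }
  }
  tibble::as_tibble(tss)
}

#' Read a sample sheet
#'
#' Tab-separated with header: `sample_id`, `cohort` (one of the declared
#' labels, controls labelled `control`), `gestational_age` (weeks) and
#' `fragment_path` (per-sample fragment file).
#'
#' @param path Path to the sample sheet.
#' @param cohort_labels Allowed cohort labels.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path,
                              cohort_labels = c("control", "case", "T21", "T18", "T13")) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("sample_id", "cohort", "gestational_age")
  if (!all(needed %in% names(sheet))) {
    abort("Sample sheet must have columns sample_id, cohort, gestational_age.")
  }
  bad <- setdiff(unique(sheet$cohort), cohort_labels)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown cohort label(s): %s (allowed: %s).",
      paste(bad, collapse = ", "), paste(cohort_labels, collapse = ", ")
    ))
  }
  tibble::as_tibble(sheet)
}

#' Read gene sets
#'
#' Accepts GMT (`set<TAB>description<TAB>gene1<TAB>gene2...`), two-column
#' (`set_name`, `gene_id`) TSV, or a plain one-gene-per-line list (the set is
#' then named after the file).
#'
#' @param path Path to the gene-set file.
#' @param format One of `"auto"`, `"gmt"`, `"tsv"`, `"list"`.
#' @return A tibble with columns `set_name`, `gene_id`.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv", "list")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "gmt") {
    rows <- purrr::map(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) {
        abort("GMT lines need set name, description and at least one gene.")
      }
      tibble::tibble(set_name = f[1], gene_id = f[-(1:2)])
    })
    return(dplyr::bind_rows(rows))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (format == "list" || all(n_fields == 1)) {
    set <- sub("\\.[^.]*$", "", basename(path))
    return(tibble::tibble(set_name = set, gene_id = vapply(fields, `[`, "", 1)))
  }
  tibble::tibble(
    set_name = vapply(fields, `[`, "", 1),
    gene_id = vapply(fields, `[`, "", 2)
  )
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), header included, doubles serialized
#' at a fixed precision so write/read round-trips are stable.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @param digits Significant digits for double columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, digits = 8) {
  out <- dplyr::mutate(
    tibble::as_tibble(records),
    dplyr::across(dplyr::where(is.double), ~ signif(.x, digits))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
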