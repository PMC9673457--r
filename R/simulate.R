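#' Specification for the synthetic cfDNA generator
#'
#' Bundles every parameter of the synthetic study: genome composition
#' (isochore-like smooth GC variation around `gc_target`), gene content,
#' the promoter nucleosome model (a Gaussian nucleosome-depleted region at
#' active TSSs plus decaying downstream nucleosome phasing), sequencing
#' depth and fragment-length regime, GC sampling bias, and the planted
#' case/control differences.
#'
#' @param genome_length Genome size in bp.
#' @param gc_target Mean genome GC fraction in (0, 1).
#' @param gc_amplitude Amplitude of the smooth (sinusoidal) GC modulation
#'   around `gc_target`; emulates isochore-scale compositional structure so
#'   GC bias is detectable at the window level.
#' @param gc_period Period of the GC modulation in bp.
#' @param n_genes Number of genes (one TSS each).
#' @param active_fraction Fraction of genes simulated as expressed.
#' @param ndr_depth Fractional coverage reduction at the TSS of active genes,
#'   in [0, 1).
#' @param ndr_sigma Width (bp) of the Gaussian promoter dip.
#' @param phasing_amplitude Relative amplitude of the downstream nucleosome
#'   oscillation.
#' @param phasing_period Nucleosome repeat length in bp.
#' @param phasing_decay Gaussian decay length (bp) of the phasing envelope,
#'   so the multiplier returns to 1 away from the TSS.
#' @param frag_len_range Inclusive fragment-length range in bp.
#' @param mean_depth Target haploid coverage (e.g. 1.0 for cases, 0.25 for
#'   low-coverage controls).
#' @param n_diff_genes Number of genes whose promoter signal differs between
#'   cohorts.
#' @param diff_log2fc Planted |log2| promoter-coverage ratio for differential
#'   genes (scale mode).
#' @param gc_bias_strength Slope of the fragment-sampling bias versus
#'   fragment GC.
#' @param window_halfwidth Promoter half-window W in bp (profiles span -W..+W).
#' @param seed Integer seed for all randomized steps (NULL inherits the
#'   caller's RNG stream).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 1e6,
                           gc_target = 0.5,
                           gc_amplitude = 0.1,
                           gc_period = 2e4,
                           n_genes = 200,
                           active_fraction = 0.5,
                           ndr_depth = 0.5,
                           ndr_sigma = 150,
                           phasing_amplitude = 0.1,
                           phasing_period = 190,
                           phasing_decay = 500,
                           frag_len_range = c(150L, 160L),
                           mean_depth = 1,
                           n_diff_genes = 0,
                           diff_log2fc = 1,
                           gc_bias_strength = 0,
                           window_halfwidth = 1000,
                           seed = NULL) {
  spec <- as.list(environment())
  stopifnot(
    spec$genome_length > 0,
    spec$gc_target > 0, spec$gc_target < 1,
    spec$n_genes >= 1,
    spec$active_fraction >= 0, spec$active_fraction <= 1,
    spec$ndr_depth >= 0, spec$ndr_depth < 1,
    spec$phasing_period > 0,
    length(spec$frag_len_range) == 2,
    spec$frag_len_range[1] > 0,
    spec$frag_len_range[2] >= spec$frag_len_range[1],
    spec$frag_len_range[2] < spec$genome_length,
    spec$mean_depth > 0,
    spec$n_diff_genes >= 0, spec$n_diff_genes <= spec$n_genes,
    spec$window_halfwidth > 0
  )
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %s bp genome, %d genes (%.0f%% active), depth %gX, NDR depth %.2f\n",
    format(x$genome_length, big.mark = ","), x$n_genes,
    100 * x$active_fraction, x$mean_depth, x$ndr_depth
  ))
  invisible(x)
}

#' Simulate a reference genome and its TSS annotation
#'
#' Bases are drawn independently with position-dependent GC probability
#' `gc_target + gc_amplitude * sin(2*pi*i/gc_period)`; the genome-wide mean
#' GC therefore equals `gc_target`. TSSs are placed on alternating strands,
#' evenly spaced, at least `2*window_halfwidth` from the chromosome ends and
#' at least `4*window_halfwidth` apart so promoter windows never overlap.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `reference` (a [ref_genome]) and `tss`
#'   (a TSS tibble, one primary TSS per gene).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$genome_length
  W <- spec$window_halfwidth
  n <- spec$n_genes
  min_len <- n * 4 * W
  if (L < min_len) {
    abort(sprintf(
      "genome_length %s cannot pack %d non-overlapping promoter windows; need at least %s bp.",
      format(L, big.mark = ","), n, format(min_len, big.mark = ",")
    ))
  }
  with_seed_if(spec$seed, {
    i <- seq_len(L)
    p_gc <- pmin(0.99, pmax(
      0.01,
      spec$gc_target + spec$gc_amplitude * sin(2 * pi * i / spec$gc_period)
    ))
    is_gc <- runif(L) < p_gc
    pick <- runif(L) < 0.5
    # index into A/T/C/G as raw bytes; rawToChar avoids a length-L character vector
    seq <- rawToChar(charToRaw("ATCG")[1L + is_gc * 2L + pick])

    step <- if (n > 1) (L - 4 * W) / (n - 1) else 0
    pos <- as.integer(round(2 * W + (seq_len(n) - 1) * step))
    tss <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = "chr1",
      pos = pos,
      strand = rep_len(c("+", "-"), n),
      is_primary = TRUE
    )
    list(reference = ref_genome(c(chr1 = seq)), tss = tss)
  })
}

#' Promoter protection landscape
#'
#' Per-base sampling-rate multiplier around a TSS. For an active gene,
#' with x the strand-oriented offset from the TSS:
#'
#' m(x) = 1 - ndr_depth * exp(-x^2 / (2 ndr_sigma^2))
#'          + phasing_amplitude * sin(2 pi x / phasing_period)
#'            * (1 - exp(-x^2 / (2 ndr_sigma^2)))
#'            * exp(-x^2 / (2 phasing_decay^2))
#'
#' clipped at 0. The Gaussian term is the nucleosome-depleted region; the
#' damped sinusoid is phased-nucleosome oscillation that fades with distance
#' (the decay envelope makes the multiplier return to 1 far from the TSS).
#' For an inactive gene m(x) = 1 everywhere.
#'
#' @param spec A [synthetic_spec()].
#' @param offsets Strand-oriented offsets (bp) at which to evaluate.
#' @param active Is the gene simulated as expressed?
#' @return A tibble with columns `offset`, `multiplier`.
#' @export
protection_landscape <- function(spec, offsets = -2000:2000, active = TRUE) {
  tibble::tibble(
    offset = offsets,
    multiplier = protection_multiplier(offsets, spec, active)
  )
}

protection_multiplier <- function(x, spec, active = TRUE) {
  if (!active) {
    return(rep(1, length(x)))
  }
  ndr <- exp(-x^2 / (2 * spec$ndr_sigma^2))
  m <- 1 - spec$ndr_depth * ndr +
    spec$phasing_amplitude * sin(2 * pi * x / spec$phasing_period) *
      (1 - ndr) * exp(-x^2 / (2 * spec$phasing_decay^2))
  pmax(m, 0)
}

# Per-position fragment-midpoint sampling rate over the whole genome:
# protection landscape of every gene (strand-oriented), optional planted
# promoter-window scaling, and the GC sampling bias evaluated on the GC of
# a mean-length fragment centred at each position.
sampling_rate <- function(spec, reference, tss, activity, promoter_scale = NULL) {
  chr <- ref_chrom(reference, tss$chrom[1])
  L <- chr$length
  rate <- rep(1, L)

  cut <- as.integer(ceiling(max(4 * spec$ndr_sigma, 4 * spec$phasing_decay,
                                spec$phasing_period)))
  off <- -cut:cut
  m_plus <- protection_multiplier(off, spec, active = TRUE)
  m_minus <- rev(m_plus)
  for (k in seq_len(nrow(tss))) {
    gene <- tss$gene_id[k]
    if (!isTRUE(activity[[gene]])) next
    idx <- tss$pos[k] + 1L + off
    ok <- idx >= 1L & idx <= L
    m <- if (tss$strand[k] == "+") m_plus else m_minus
    rate[idx[ok]] <- rate[idx[ok]] * m[ok]
  }
  if (!is.null(promoter_scale)) {
    W <- spec$window_halfwidth
    for (gene in names(promoter_scale)) {
      k <- match(gene, tss$gene_id)
      if (is.na(k)) next
      idx <- max(1L, tss$pos[k] + 1L - W):min(L, tss$pos[k] + 1L + W)
      rate[idx] <- rate[idx] * promoter_scale[[gene]]
    }
  }
  if (spec$gc_bias_strength != 0) {
    flen <- as.integer(round(mean(spec$frag_len_range)))
    half <- flen %/% 2L
    m0 <- seq_len(L) - 1L
    s0 <- pmax(0L, m0 - half)
    e0 <- pmin(L, m0 + (flen - half))
    gc <- interval_gc(chr, s0, e0)
    fac <- pmax(0, 1 + spec$gc_bias_strength * (gc - spec$gc_target))
    fac[is.na(fac)] <- 1
    rate <- rate * fac
  }
  rate
}

#' Simulate one cfDNA sample
#'
#' Draws `N ~ Poisson(mean_depth * genome_length / mean fragment length)`
#' fragment midpoints with probability proportional to the protection
#' landscape times the GC sampling bias, assigns lengths uniformly on
#' `frag_len_range`, and returns a one-row sample tibble with the fragments
#' as a list column and `total_mapped_fragments` set to the realized N.
#'
#' @param spec A [synthetic_spec()].
#' @param reference A [ref_genome] from [simulate_genome()].
#' @param tss TSS tibble from [simulate_genome()].
#' @param activity Named logical vector: is each gene expressed?
#' @param sample_id,cohort Sample identity for the sample sheet row.
#' @param gestational_age Weeks (drawn uniformly on [12, 28] when NA).
#' @param seed Seed (NULL inherits the caller's RNG stream).
#' @param rate Optional precomputed [sampling rate]; pass when simulating many
#'   samples that share a genome and activity state.
#' @param promoter_scale Optional named per-gene multiplier applied to the
#'   sampling rate over the promoter window (planted differences).
#' @return One-row tibble: `sample_id`, `cohort`, `gestational_age`,
#'   `total_mapped_fragments`, `fragments` (list column).
#' @export
simulate_sample <- function(spec, reference, tss, activity,
                            sample_id = "sample1", cohort = "case",
                            gestational_age = NA_real_, seed = NULL,
                            rate = NULL, promoter_scale = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  assert_tss(tss)
  if (is.null(rate)) {
    rate <- sampling_rate(spec, reference, tss, activity, promoter_scale)
  }
  if (sum(rate) <= 0) {
    abort("Total fragment sampling mass is zero; check the simulation parameters.")
  }
  chrom <- tss$chrom[1]
  L <- ref_chrom(reference, chrom)$length
  with_seed_if(seed, {
    if (is.na(gestational_age)) {
      gestational_age <- runif(1, 12, 28)
    }
    n_target <- spec$mean_depth * L / mean(spec$frag_len_range)
    n <- rpois(1, n_target)
    mids <- sample.int(L, n, replace = TRUE, prob = rate)
    lens <- sample.int(
      spec$frag_len_range[2] - spec$frag_len_range[1] + 1L, n,
      replace = TRUE
    ) + spec$frag_len_range[1] - 1L
    start <- mids - 1L - lens %/% 2L
    start <- pmax(0L, pmin(start, L - lens))
    ord <- order(start, lens)
    frag_start <- as.integer(start[ord])
    frag_end <- as.integer(start[ord] + lens[ord])
    frags <- tibble::tibble(
      chrom = chrom,
      start = frag_start,
      end = frag_end,
      weight = 1,
      gc_fraction = NA_real_
    )
    tibble::tibble(
      sample_id = sample_id,
      cohort = cohort,
      gestational_age = gestational_age,
      total_mapped_fragments = n,
      fragments = list(frags)
    )
  })
}

#' Simulate a case/control cfDNA study
#'
#' Generates (or reuses) a shared genome and TSS set, assigns baseline
#' activity states, plants `n_diff_genes` case/control differences, and
#' simulates both cohorts. Differences are planted either by scaling the
#' case promoter-window sampling rate by `2^(+/- diff_log2fc)` (mode
#' `"scale"`, a controlled planted log2 fold change with random sign) or by
#' flipping the gene's activity state in cases (mode `"flip"`; flipping an
#' active gene to inactive removes the promoter dip, so its promoter
#' coverage is higher in cases). Gestational ages are drawn uniformly on
#' [12, 28] weeks in both cohorts.
#'
#' @param spec_case Spec for the case cohort.
#' @param spec_control Spec for the control cohort (defaults to `spec_case`
#'   with its own `mean_depth`); must agree with `spec_case` on the genome
#'   and gene content.
#' @param n_case,n_control Cohort sizes.
#' @param reference,tss Optional pre-simulated genome (both or neither).
#' @param diff_mode `"scale"` or `"flip"` (see above).
#' @param case_label,control_label Cohort labels for the sample sheet.
#' @param seed Seed governing genome, activity assignment, planting and all
#'   fragment draws.
#' @return An object of class `cohort_sim`: list with `samples` (sample
#'   tibble with fragments list column), `reference`, `tss`, `truth`
#'   (per-gene ground truth) and the two specs.
#' @export
simulate_cohorts <- function(spec_case, spec_control = NULL,
                             n_case = 20, n_control = 20,
                             reference = NULL, tss = NULL,
                             diff_mode = c("scale", "flip"),
                             case_label = "case", control_label = "control",
                             seed = NULL) {
  diff_mode <- match.arg(diff_mode)
  spec_control <- spec_control %||% spec_case
  stopifnot(
    spec_case$genome_length == spec_control$genome_length,
    spec_case$n_genes == spec_control$n_genes
  )
  if (is.null(reference) != is.null(tss)) {
    abort("Supply both `reference` and `tss`, or neither.")
  }
  with_seed_if(seed, {
    if (is.null(reference)) {
      genome_spec <- spec_case
      genome_spec$seed <- NULL # inherit the seeded stream set up here
      g <- simulate_genome(genome_spec)
      reference <- g$reference
      tss <- g$tss
    }
    genes <- tss$gene_id
    n_active <- round(spec_case$active_fraction * length(genes))
    active_genes <- sample(genes, n_active)
    activity_control <- setNames(genes %in% active_genes, genes)

    n_diff <- spec_case$n_diff_genes
    diff_genes <- if (n_diff > 0) sample(genes, n_diff) else character(0)
    activity_case <- activity_control
    promoter_scale <- NULL
    planted <- setNames(rep(0, length(genes)), genes)
    if (n_diff > 0) {
      if (diff_mode == "scale") {
        signs <- sample(c(-1, 1), n_diff, replace = TRUE)
        planted[diff_genes] <- signs * abs(spec_case$diff_log2fc)
        promoter_scale <- setNames(2^planted[diff_genes], diff_genes)
      } else {
        activity_case[diff_genes] <- !activity_case[diff_genes]
        planted[diff_genes] <- NA_real_ # direction set by the NDR, not a fixed ratio
      }
    }
    truth <- tibble::tibble(
      gene_id = genes,
      active_control = unname(activity_control),
      active_case = unname(activity_case),
      planted_log2fc = unname(planted),
      is_differential = genes %in% diff_genes
    )

    rate_case <- sampling_rate(spec_case, reference, tss, activity_case, promoter_scale)
    rate_control <- sampling_rate(spec_control, reference, tss, activity_control)

    cases <- purrr::map(seq_len(n_case), function(i) {
      simulate_sample(spec_case, reference, tss, activity_case,
        sample_id = sprintf("%s%03d", case_label, i), cohort = case_label,
        rate = rate_case
      )
    })
    controls <- purrr::map(seq_len(n_control), function(i) {
      simulate_sample(spec_control, reference, tss, activity_control,
        sample_id = sprintf("%s%03d", control_label, i), cohort = control_label,
        rate = rate_control
      )
    })
    structure(
      list(
        samples = dplyr::bind_rows(c(cases, controls)),
        reference = reference,
        tss = tss,
        truth = truth,
        spec_case = spec_case,
        spec_control = spec_control
      ),
      class = "cohort_sim"
    )
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  tab <- table(x$samples$cohort)
  cat(
    "<cohort_sim> ", nrow(x$tss), " genes; samples: ",
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    "; ", sum(x$truth$is_differential), " planted differential gene(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the reference FASTA, TSS table, per-sample fragment BEDs, the
#' sample sheet (with fragment paths) and the ground-truth table.
#'
#' @param sim A `cohort_sim` from [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return Named list of the paths written, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    tss = file.path(dir, "tss.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_reference(sim$reference, paths$reference)
  write_table(sim$tss, paths$tss)
  write_table(sim$truth, paths$truth)
  frag_paths <- purrr::map2_chr(
    sim$samples$sample_id, sim$samples$fragments,
    function(id, fr) {
      p <- file.path(dir, paste0(id, ".bed"))
      write_fragments_bed(fr, p)
      p
    }
  )
  sheet <- dplyr::mutate(
    dplyr::select(sim$samples, -"fragments"),
    fragment_path = frag_paths
  )
  write_table(sheet, paths$samples)
  paths$fragments <- frag_paths
  invisible(paths)
}
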