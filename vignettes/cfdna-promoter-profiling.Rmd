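---
title: "Methods: cfDNA nucleosome-footprint profiling at transcription start sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA nucleosome-footprint profiling at transcription start sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftss)
library(dplyr)
```

## The biological signal

Plasma cell-free DNA (cfDNA) is released mainly by apoptotic cells, and the
nuclease digestion that fragments it spares nucleosome-bound DNA while
degrading exposed linker and naked DNA. Sequencing coverage of cfDNA
therefore traces nucleosome occupancy in the tissues of origin. At the
promoters of transcriptionally *active* genes the nucleosome-depleted
region (NDR) around the transcription start site (TSS) leaves a coverage
dip, flanked downstream by phased nucleosomes; inactive promoters stay
occupied and flat. Comparing per-promoter coverage between cohorts is thus
an indirect read-out of differential gene activity — usable even at the
very low sequencing depths (0.25–1X) typical of non-invasive prenatal
testing (NIPT) libraries.

`cftss` implements this analysis end to end: fragment input, GC-bias
correction by fragment reweighting, strand-aware per-base TSS profiles and
RPKM promoter matrices, random pooling of low-coverage controls, a
Wilcoxon/Benjamini–Hochberg differential-coverage test with a fold-change
gate, and downstream PCA, clustering and gene-set over-representation.
Because suitable clinical data cannot be redistributed, the package ships a
first-class synthetic generator that encodes the study conditions, so every
stage is testable offline against a known ground truth.

## The differential procedure

For sample $s$ and (primary) TSS $t$, the promoter signal is the
RPKM-normalized weighted fragment count in the window $\pm W$ around the
TSS ($W = 1000$ bp by default, so the region length is a conventional
2 kb):

$$\mathrm{RPKM}_{st} = \frac{10^9 \, c_{st}}{2W \cdot N_s},$$

where $c_{st}$ sums the GC-correction weights of fragments overlapping
$[\mathrm{pos}-W,\ \mathrm{pos}+W+1)$ by at least 1 bp and $N_s$ is the
sample's total mapped fragments. A fragment either overlaps or it does
not; no midpoint assignment is used, which is the simplest defensible
reading of region read counting.

Per TSS, the test between cohorts proceeds in the stated order:

1. group means and $\log_2$ fold change with a symmetric pseudocount
   ($\log_2\frac{\bar x_\text{case} + c}{\bar x_\text{ctrl} + c}$,
   $c = 0.5$ RPKM, which keeps the ratio finite at zero coverage);
2. a prefilter keeps TSSs with two-sided fold change $> 1.5$
   (i.e. $\max(r, 1/r) > 1.5$ on the pseudocounted means — the strict
   ratio gate and the $|\log_2\mathrm{FC}| \ge \log_2 1.5$ call criterion
   coincide only under this two-sided reading, which is the one adopted);
3. a two-sided Wilcoxon rank-sum test per retained TSS — exact when the
   smaller group has at most 8 tie-free observations, otherwise the normal
   approximation with tie and continuity corrections;
4. Benjamini–Hochberg adjustment **across the tested set only**, matching
   the stated order of operations (gate first, then correction);
   `fdr_scope = "all"` is available for comparison;
5. a TSS is called `up`/`down` only when all three criteria hold:
   $p < 0.05$, $|\log_2\mathrm{FC}| \ge \log_2 1.5$, FDR $< 0.2$.

Calls are reported as **coverage** direction (`up` = more promoter
coverage in cases). The mapping from coverage to expression direction
(active promoters are *depleted*) is deliberately left to the analyst,
since the sign convention is ambiguous in parts of the motivating
literature.

Low-coverage controls are first merged into pseudo-samples:
`pool_controls()` shuffles the controls under a seed (optionally within
strata, e.g. integer gestational-age weeks), takes $\lfloor n/4 \rfloor$
groups of exactly 4 and concatenates their fragments, so 140 controls at
~0.25X become 35 pools at ~1X. Leftover samples are discarded with a
warning.

## GC-bias model

Library preparation and sequencing over- or under-sample fragments as a
smooth function of their GC content. `estimate_gc_bias()` reimplements the
classic observed/expected histogram approach: the observed fragment-GC
histogram (100 bins on $[0,1]$) is compared with the GC of random genomic
positions whose lengths are resampled from the observed fragment lengths,
and each bin receives weight $\mathrm{expected}/\mathrm{observed}$.
Correction is by *fragment reweighting*, not resampling: deterministic,
information-preserving, and composable with every downstream weighted
count. Three numerical guards matter in the tails: bins with fewer than 50
observed fragments keep weight 1, bins with zero observed or expected mass
keep weight 1, and weights are capped to $[0.1, 10]$. The expected
histogram assumes a fully mappable genome (true for synthetic references);
for real genomes a precomputed, mappability-aware expected histogram can
be supplied directly.

## What the synthetic generator encodes

`synthetic_spec()` bundles the study conditions; the defaults *are* the
simulated study and are not tuned per analysis.

| parameter | default | meaning |
|---|---|---|
| `mean_depth` | 1 (cases), 0.25 (controls) | haploid coverage of the two depth regimes |
| `frag_len_range` | 150–160 bp | cfDNA fragment lengths, drawn uniformly |
| `ndr_depth` | 0.5 | fractional coverage loss at active TSSs |
| `ndr_sigma` | 150 bp | width of the Gaussian NDR dip |
| `phasing_amplitude`, `phasing_period` | 0.1, 190 bp | downstream nucleosome oscillation |
| `phasing_decay` | 500 bp | Gaussian envelope returning the landscape to 1 |
| `gc_target`, `gc_amplitude`, `gc_period` | 0.5, 0.1, 20 kb | mean GC and smooth isochore-like modulation |
| `gc_bias_strength` | 0 | slope of sampling bias vs fragment GC |
| `n_diff_genes`, `diff_log2fc` | 0, 1 | planted case/control promoter differences |

The promoter model is generative, not estimated: active TSSs multiply the
fragment-midpoint sampling rate by

$$m(x) = 1 - a\,e^{-x^2/2\sigma^2}
  + A \sin\!\left(\tfrac{2\pi x}{P}\right)
    \left(1 - e^{-x^2/2\sigma^2}\right) e^{-x^2/2 d^2},$$

with $x$ the strand-oriented offset. The final Gaussian envelope
($d$ = `phasing_decay`) is a deliberate model choice: without it the
sinusoidal term would oscillate at full amplitude arbitrarily far from the
TSS, which is neither biological (phasing decays within a few nucleosome
repeats) nor consistent with a landscape that must return to 1 between
genes. Inactive promoters have $m \equiv 1$.

Genome composition is drawn base-by-base with
$P(\mathrm{GC}) = \texttt{gc\_target} + \texttt{gc\_amplitude}\,
\sin(2\pi i/\texttt{gc\_period})$. The sinusoidal modulation emulates
isochore-scale compositional structure: on a strictly i.i.d. genome the GC
of a 2 kb window varies by only ~1%, and no realistic per-fragment GC bias
would ever be detectable at the window level. The genome-wide mean GC
still equals `gc_target` (whole periods fit in the genome many times
over).

Fragment counts are Poisson around
$\texttt{mean\_depth} \times L / \overline{\ell}$ (sequencing shot noise);
midpoints are drawn from the product of the protection landscape and the
clipped GC factor $1 + \beta(\mathrm{GC}_\text{frag} - \mathrm{GC}_0)$;
lengths are uniform on the range. Planted differences default to scaling
the case promoter-window rate by $2^{\pm \texttt{diff\_log2fc}}$ with
random sign, which produces a *controlled* planted log2 fold change;
flipping the activity state (`diff_mode = "flip"`) is also available and
produces a direction (higher case coverage when an active gene
deactivates) but not a fixed effect size. Gestational ages are drawn
uniformly on 12–28 weeks in both cohorts and carry no simulated effect;
they exist so covariate-stratified pooling is exercisable.

What the generator does **not** emulate: mappability and alignment
artefacts, sequencing error, fragment-size differences between fetal and
maternal cfDNA, fetal-fraction mixtures, copy-number changes (including
the trisomic chromosome itself), and correlated biological variation
between promoters. Passing tests therefore demonstrate that the *pipeline*
recovers what its model class plants under realistic noise and depth — not
that any particular clinical signal exists.

## Numerical and design choices

* **Coordinates** are 0-based half-open throughout (BED convention);
  1-based inputs are converted at read time.
* **Profiles** span $2W + 1$ strand-oriented offsets; minus-strand
  profiles are flipped so offsets run 5′→3′ of the gene. RPKM uses region
  length $2W$, keeping the denominator a round 2 kb.
* **Relative depth** divides by the mean over the flank offsets
  ($|x| \ge 0.75W$). For gene-set metaplots the default normalizes the
  *aggregate* profile (mean over samples, then genes) rather than each
  (sample, gene) profile: at 0.25X a single gene's flank holds roughly one
  fragment, so per-profile ratios are heavy-tailed and their mean is
  unstable, whereas the aggregate flank pools hundreds of fragments. The
  per-profile order remains available as `normalize = "per_gene"`.
* **Primary TSSs**: when the annotation does not flag one, the first TSS
  listed per gene is taken as primary — a stand-in rule, stated as such.
* **Ties**: top/bottom expression sets break ties lexicographically by
  gene id from a single ranking, so the two sets are always disjoint and
  deterministic; Wilcoxon falls back to the corrected normal
  approximation whenever ties are present.
* **Degenerate inputs**: identical cohorts yield no tested TSSs and no
  calls; constant matrices give zero-variance PCA scores rather than
  errors; zero-flank profiles propagate `NA` rather than infinities.
* **Seeds**: every random step (genome, fragments, pooling, expected-GC
  draws) flows through an explicit seed; `run_pipeline()` fans one global
  seed out to the stages by fixed offsets so each stage is independently
  reproducible.
* **Enrichment background** defaults to the profiled genes, not the whole
  genome — the selection was made among profiled promoters, and the
  hypergeometric test must condition on that universe.

## Problem sizes used by the test suite

The packaged checks simulate at sizes chosen to make their statistical
targets measurable while staying desk-sized: 2 000 genes on an 8 Mb genome
with 15 v 15 (null) and 20 v 20 (100 planted effects at
$|\log_2\mathrm{FC}| = 1$) cohorts at 1X for the differential
characteristics; 150 genes on 1 Mb at 0.25X for the TSS-dip contrast;
2 000 windows of 2 kb at bias strength 2 for GC flattening; and 140
controls pooled 4-fold for the pooling analogue. The differential cohorts
are simulated directly at 1X in both arms — the pooling stage that lifts
real 0.25X controls to ~1X is exercised separately — and with
`gc_bias_strength = 0`, since GC correction is assessed on its own.

## Known limitations

* The promoter landscape is a two-term parametric form; real metaplots
  show asymmetric NDRs and upstream −1 nucleosomes it does not model.
* The expected-GC model assumes uniform mappability; supply a precomputed
  expected histogram for real genomes.
* No covariate-adjusted testing (e.g. gestational-age regression) — the
  design follows the two-group comparison of the motivating analysis.
* Headline gene counts from any particular clinical cohort are not
  reproducible from synthetic data and are not targets of the test suite;
  the suite checks operating characteristics (type-I error, sensitivity,
  FDR, direction, flattening, separation) instead.
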