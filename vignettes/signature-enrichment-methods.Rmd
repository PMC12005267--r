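---
title: "Methods: mutation curation, spectra, and trinucleotide signature enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation curation, spectra, and trinucleotide signature enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimspect)
```

This vignette documents the statistical model behind the package, the
conventions that had to be fixed where more than one reasonable choice
exists, and what the synthetic-data generators do and do not emulate. It is
the reference for every numerical decision in the code; the README shows
the user-facing workflow.

## The experimental design being modeled

The package analyses acute mutagen-exposure experiments in haploid yeast.
Each genotype contributes two arms of independent cultures, treated and
untreated. Two readouts are modeled:

* **Plating assays.** Per culture, resistant and viable colony counts per
  mL. The per-culture mutation frequency is their ratio; viability is the
  treated viable count relative to the untreated arm of the same genotype
  (untreated cultures define 100 % by convention).
* **Whole-genome sequencing of surviving isolates.** Per isolate, a table
  of single-nucleotide variants with variant allele frequencies (VAF),
  called against a reference genome. Because a haploid isolate carries a
  real mutation in essentially every cell, true calls cluster near VAF 1;
  subclonal noise and contamination sit lower.

## Curation of variant tables

Three rules, applied in a fixed precedence (VAF, then baseline, then
sharing), with each record assigned exactly one fate so the filter report
always partitions the input:

1. **VAF filter.** Keep records with VAF ≥ 0.90. The boundary is
   *inclusive*: a call at exactly 90 % is kept, since the cutoff's purpose
   is to keep homozygous-like calls, not to exclude the boundary case.
2. **Baseline subtraction.** A mutation identity — the tuple
   (contig, position, ref, alt); different alt alleles at one site are
   distinct events — present in the sequenced pre-treatment culture is
   preexisting, and removed from every carrier.
3. **Shared-mutation removal.** An identity carried by ≥ 2 distinct
   samples of the batch is preexisting (it predates the single-cell
   bottleneck of isolate picking), and removed from every carrier.
   Duplicate records *within* one sample do not trigger this rule.

Sharing is counted after the VAF filter, so a sub-threshold record does not
make its partner "shared". Curation is idempotent: re-curating its own
output changes nothing, which the test suite asserts as a property.

## Strand-collapsed spectra

Substitutions are reported as the six pyrimidine classes (C>A, C>G, C>T,
T>A, T>C, T>G). A purine reference is reverse-complemented together with
its trinucleotide context, so a G>T with plus-strand context `aGc` is
counted as C>A in `gCt`. Contexts are written with lowercase flanks and an
uppercase center. Per-cohort summaries are arithmetic means of per-isolate
class counts.

Records at a contig edge or with an `N` in the trinucleotide cannot be
classified. They are flagged and counted, never silently dropped, and are
excluded from all context-dependent statistics — both from the mutation
side and from the background windows of the enrichment statistic.

## The enrichment statistic

For one cohort (pooled across isolates) with target class C>A and motif
`gCn`:

* `mut_all` — the number of strand-collapsed C>A mutations;
* `mut_sig` — those whose context matches the motif;
* `ctx_all` — summed over the ±20 bp windows of those same mutations, the
  number of cytosines on both strands (plus-strand C plus plus-strand G);
* `ctx_sig` — likewise, the number of motif cytosines on both strands.

Enrichment is the ratio of proportions
`(mut_sig/mut_all) / (ctx_sig/ctx_all)`; the one-sided (greater) Fisher's
exact test runs on the 2×2 table with disjoint cells
`[[mut_sig, mut_all − mut_sig], [ctx_sig, ctx_all − ctx_sig]]`. Across the
cohorts of one call, p-values are Benjamini–Hochberg adjusted; that call
defines the BH family.

Conventions fixed here, each a genuine free choice:

* **Windows are symmetric, include the mutated position, and are truncated
  at contig ends.** Truncation beats exclusion because short contigs would
  otherwise lose their mutations entirely.
* **Motif membership is a genome property, not a window property.** A
  cytosine at the window edge is a `gCn` cytosine if its 5′ guanine lies
  just outside the window; conversely the count formula is dinucleotide
  based — position *i* counts when (base *i* is C and *i*−1 is G) or
  (base *i* is G and *i*+1 is C) — so a `GC` dinucleotide fully inside a
  window contributes 2, mirroring the strand collapse applied to
  mutations. A missing neighbor at a contig end behaves like `N`: only the
  unconstrained flank code `n` matches it, so a C with no 5′ neighbor is
  never a `gCn` cytosine.
* **Backgrounds are drawn around the counted C>A mutations only**, keeping
  numerator and denominator on the same residue set, and are summed over
  windows rather than taken genome-wide, so local composition (GC islands,
  repeats) cancels between the two.
* **No pseudocounts.** A cohort with no C>A mutations yields explicit
  `NA` markers (excluded from the BH family); `mut_sig = 0` gives
  enrichment 0; `ctx_sig = 0` with `mut_sig > 0` gives `Inf`. Transparent
  degenerate values beat smoothed estimates at these cohort sizes.
* **Generic motifs.** Any central-pyrimidine motif with lowercase IUPAC
  flanks is accepted (e.g. `tCw`), with the same machinery.

Because the window is centered on the mutated residue, the mutation itself
(and, for a motif cytosine, its 5′ guanine partner) contributes to its own
background. This couples numerator and denominator slightly: under
placement of C>A mutations uniformly over cytosines, the expected
enrichment is a little below 1 (about 0.96–0.97 at yeast-like GC content),
and the one-sided test is correspondingly conservative. The test suite
measures exactly this null behavior.

## Synthetic-data generators

The generators produce every input the pipeline consumes, with ground-truth
labels, so correctness is checkable exactly rather than plausibly.

**Genomes** are i.i.d. base draws at a target GC content (default 0.38, the
budding-yeast value). They deliberately lack chromatin structure, repeats,
and compositional heterogeneity; conclusions from passing tests concern the
statistics, not the biology of real genomes.

**Signature-spiked cohorts.** `target_enrichment` is expressed on the scale
of the windowed statistic itself. The generator enumerates every candidate
cytosine (both strands, interior, N-free trinucleotide), computes each
candidate's window motif/cytosine content from prefix sums, and solves the
quadratic

```
p (p·C̄_M + (1−p)·C̄_N) = E (p·Ḡ_M + (1−p)·Ḡ_N)
```

for the motif-placement probability `p`, where `C̄`/`Ḡ` are mean window
cytosine/motif counts over the motif (M) and non-motif (N) candidate pools
and `E` is the target. The naive alternative — multiplying the
motif/non-motif *odds* by `E` — does not put the parameter on the
estimator's scale: at yeast-like GC (motif fraction ≈ 0.19 among
cytosines) odds-placement yields a measured enrichment well below the
nominal target, both because odds and proportion ratios diverge when the
motif fraction is not small and because motif-centered windows carry their
own motif in the background. The calibrated sampler makes the estimator
consistent by construction, which is what a generator whose parameter
claims to *be* the enrichment owes its users. A `placement = "uniform"`
mode places target-class mutations over candidates in proportion to
abundance, ignoring the target — the classical null of an unbiased
mutagen, used for calibration studies. Unattainable targets (placement
probability outside [0, 1]) are a hard error, not a silent cap.

Within a sample, positions are disjoint; across samples they are drawn
independently, so occasional coincident keys arise by chance — as in real
cohorts — and are legitimately removed by the shared-mutation rule. The
contamination generator therefore labels such accidental duplicates
`shared` in its ground truth, alongside its deliberate injections of
baseline-resident keys, cross-sample duplicated keys, and sub-threshold
VAFs (drawn uniformly on 0.3–0.89).

**Plating assays** combine lognormal culture-to-culture variation on both
the per-culture frequency (σ = 0.5) and the viable count (σ = 0.2) with
Poisson sampling of resistant-colony counts, since plating is a count
process riding on culture variation. Defaults encode the conditions of an
NER-deficient strain under acute acetaldehyde exposure: a 2.5-fold
frequency increase, 56 % viability loss, cultures at ~2×10⁷ viable
cells/mL, untreated frequencies near 5×10⁻⁷ (so a 12-culture arm sees
Poisson means around 10 resistant colonies). The generator does not model
jackpot cultures (early mutation events inflating single cultures beyond
lognormal tails) or plating dilution error.

## Hypothesis tests

Arm comparisons use the two-sided Mann–Whitney U test: exact null
enumeration when both arms have ≤ 8 values and no ties, otherwise the
tie-corrected normal approximation with continuity correction. Sidedness
is deliberately two-sided — the conservative default when either direction
of effect would be reported. Fold changes are ratios of medians because
medians are what the assay summaries plot and are robust to single
jackpot-like cultures; a zero untreated median yields an explicit `NA`
rather than infinity. Viability comparisons expose both baselines —
against the wild-type strain's viability percentages (the screen
convention) and against the genotype's own untreated arm — since published
analyses use the former for survival and the latter phrasing for
frequency.

qPCR folds follow the ΔΔCt convention: ΔCt normalizes the target gene to
the reference channel per strain; ΔΔCt subtracts the wild-type ΔCt *of the
same growth condition* (plain vs doxycycline), and the fold is 2^−ΔΔCt.
Replicate wells are averaged on the ΔCt scale. A condition without a
wild-type measurement is a pairing error, not a silent skip.

## Problem sizes used in validation

The shipped validation suite uses a 100 kb single-contig genome at GC 0.38;
1,000 replicate cohorts of 500 uniformly placed C>A mutations for null
calibration (mean enrichment within 1 ± 0.05, rejection ≤ 6 % at α = 0.05);
recovery of targets 1.5/2/3 from 2,000-mutation cohorts to within 10 %;
four-cohort study-design simulations at 250 C>A mutations per cohort; and
200–500 replicate plating assays at 12 cultures per arm. These sizes put
Monte-Carlo error well below the tolerances being asserted while keeping
the whole suite in the low minutes on one CPU.

## Known limitations

* The enrichment estimator's small null bias (window-center coupling) is
  documented rather than corrected; at cohort sizes where it matters the
  test is conservative, never anti-conservative.
* Backgrounds are windowed sums; a genome-wide background variant is not
  implemented.
* Per-isolate signature calls are intentionally not exposed in the
  pipeline driver: at realistic per-isolate mutation counts they are
  noise.
* The VCF reader handles plain per-isolate VCFs (one sample column,
  VarScan-style `FREQ` or `INFO/AF` for VAF); multi-sample VCFs are
  rejected by design.
* Indels and multi-nucleotide variants are out of scope throughout; they
  are counted and skipped at load time.
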