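---
title: "Mutation calling, clonal correction and spectrum comparison for NGS-sequenced transgenic rodent assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation calling, clonal correction and spectrum comparison for NGS-sequenced transgenic rodent assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgrspectra)
library(dplyr)
```

## The assay and the analysis problem

The transgenic rodent (TGR) mutation assay scores in vivo mutagenicity by
recovering a reporter transgene — here lacZ, carried by MutaMouse animals —
from any tissue and selecting mutant copies as plaques in a bacterial
host. The mutant frequency (MF) for an animal is mutant plaques divided by
total plaque-forming units (pfu). Sequencing the pooled mutant plaques
adds two things the plaque counts alone cannot give:

1. **Clonal correction.** A premeiotic mutation in a spermatogonial stem
   cell is copied into many descendant germ cells, so one mutational
   event can surface as many mutant plaques. The sequenced pool reveals
   how many plaques share the identical change, letting the MF be
   deflated to independent events.
2. **A high-resolution mutation spectrum.** With every mutant plaque
   sequenced at depth, each independent mutation is classified,
   annotated with sequence context, and compared across treatment groups
   and tissues.

`tgrspectra` implements the full path from per-position pileup counts of
pooled plaques to statistically compared spectra, together with a
simulator that generates pools with known ground truth. The `analysis/`
scripts in the repository run the pipeline end to end; every computation
they use lives in the package and is unit-tested.

## Calling model

For each animal, the pooled mutant plaques are amplified and sequenced in
**duplicate**, giving two pileups: read counts supporting each alternate
event (substitution to one of three bases; insertions and deletions of
1-2 bp) at each reference position, with total depth per position.

- **Error correction.** Wildtype (titre) plaques carry no true mutations,
  so their pooled deviant proportion at a (position, event) estimates the
  false mutation proportion (FMP) of the PCR + sequencing process there.
  The corrected proportion in a mutant pool is `max(0, raw - FMP)`.
  Subtraction (rather than, say, a per-site binomial test) is the
  simplest rule consistent with describing calls as "corrected for" the
  error proportion; it is unbiased when the error landscape is shared
  between wildtype and mutant libraries, which holds when they come from
  one platform and run.
- **Threshold.** A mutation present in one of the N pooled plaques is
  expected at deviant proportion at least 1/N, so the calling threshold
  is `1/N`, compared inclusively (`>=`), and a call requires the
  corrected proportion to reach threshold in **both** replicates.
- **Indel filter.** Homopolymer slippage makes indel error both large and
  unstable from run to run on semiconductor platforms, so indel events
  whose FMP exceeds the *highest substitution FMP* are discarded before
  thresholding. This only behaves sensibly because substitution FMP
  varies across sites with a heavy tail; the maximum is set by a few
  error-prone sites, and only indel events noisier than the noisiest
  substitution are dropped.

## Clone counts and clonality

A mutation carried by k of N pooled plaques has expected corrected
proportion k/N, so the **raw clone estimate** is the replicate-mean
corrected proportion divided by the threshold. Quantification near the
limit of detection is imprecise, so the estimate passes through a
limit-of-detection/linear rule: raw values at or below `lod_bound`
(default 1.5) count as one clone; above it, `slope * raw + intercept`
is rounded half-up (the defaults, slope 1 and intercept 0, reduce to
plain rounding). Rounding is half-up, not banker's, so a raw estimate of
2.5 becomes 3.

When template recovery from the pool is incomplete — the realistic case;
boiling plaques and taking an aliquot loses a fraction of templates —
every raw estimate is inflated by the common factor N/M, where M is the
number of plaques that actually contributed template. `estimate_clones(
calibrate = TRUE)` estimates that factor per animal from the smallest
raw estimate, because the singleton cluster (clone count 1, the most
common value at any realistic clonality) marks the proportion one
template contributes. With complete recovery the scale is ~1 and the
calibrated rule coincides with the default one.

Mutations recurring within an animal collapse to one **independent**
mutation per (position, event); clones never span animals. Per-animal
clonality is `1 - independent / identified`, with identified the sum of
adjusted clone counts; an animal with no passed calls has *undefined*
(not zero) clonality. The clonally corrected mutant frequency is
`MF x (1 - clonality)`, which reproduces every per-animal corrected
value in the bundled case-study table at its printed precision.

## The simulator

`simulate_pools()` generates the raw material the pipeline consumes, at
the scale of the emulated assay: 144 plaques pooled per animal,
duplicate replicates, ~2700-fold depth per recovered lacZ copy.
Independent mutations are drawn per animal with classes following a
configurable spectrum (defaults: the case study's exposed-group
proportions) and placed only at bases compatible with their class; each
expands to a clone count from a **zero-truncated geometric**
distribution. That family was chosen as the simplest one-parameter
distribution spanning the observed per-animal clonality range
(~5-60%); no empirical clone-size distribution is available to fit, and
conclusions that depend on the tail of clone sizes should be checked
against other families.

Three modelling points deserve explanation:

- **Template recovery** (`recovery_rate`, default 0.702, the emulated
  assay's recovered/input mutant ratio). Each pooled plaque contributes
  template independently with this probability. Mutations losing all
  copies vanish; survivors are *enriched*: a surviving singleton sits at
  expected proportion 1/M > 1/N, which is precisely what makes the 1/N
  threshold conservative and singleton calls reliable. Without this
  (recovery 1), a singleton's expectation sits exactly at the threshold
  and sampling noise rejects about half of its replicates — a structural
  limit, not an implementation artifact. The clone-size parameter is
  calibrated in closed form (q = c / (1 - (1-c)(1-rho))) so the
  *recovered* pool hits the clonality target in expectation.
- **Error landscape.** Substitution error rates are drawn per
  (position, alternate base) from a Gamma distribution (mean 2e-3, shape
  0.3 — a heavy tail) and fixed for the experiment: error is
  sequence-context driven, so the wildtype and every mutant pool share
  the landscape (`error_seed`), which is what makes FMP subtraction
  work. Indel error is 5e-4 at ordinary positions and 20-fold higher
  within or adjacent to homopolymer runs (>= 3 identical bases, the
  same convention the annotation module uses), with a mean-preserving
  lognormal jitter (sdlog 0.3) applied independently per library
  replicate: slippage is unstable between amplifications, and that
  instability is what creates false indel calls for the FMP filter to
  suppress. At the full-scale threshold (1/144) a few unstable indel
  events per animal still slip through; the step-2 analysis script
  reports the resulting precision rather than hiding it.
- **Noise-free limit** (`exact_counts = TRUE`). Read counts are set to
  their expectations instead of binomial draws. Large depth alone never
  reaches this limit at the threshold boundary (the probability of a
  binomial proportion meeting its own mean stays near 1/2), so the
  idealized setting used in tests is explicit: zero error rates,
  complete recovery, exact counts.

Per-animal plaque-assay counts (mutant plaques out of `total_pfu` at the
configured true MF) accompany each pool so the frequency analysis can be
exercised on synthetic data.

What the simulator does **not** emulate: read-level errors and alignment
(the pipeline consumes pileup counts by design), Ion Torrent flow-space
artifacts beyond the homopolymer rate multiplier, positional hotspots in
the error landscape beyond the Gamma tail, the positive-selection
biology of the plaque assay (every simulated mutation is assumed
selectable), and structural deletions larger than 2 bp. Passing tests on
simulated pools therefore validate the arithmetic and decision rules of
the pipeline, not the upstream wet-lab and alignment stages.

## Spectrum and context conventions

Substitutions are reported by reference basepair, purine-normalized:
C>A is the same class as G>T (G:C>T:A). Indels form two further classes.
Context flags:

- `at_gc`: the reference basepair is G:C.
- `cpg`: the position, or a position within `cpg_radius` (default 1) of
  it, participates in a 5'-CG-3' dinucleotide. The neighbourhood
  definition (rather than strict membership) reflects that adduct-driven
  mutation at methylated CpG affects the immediate vicinity, and a
  strict definition cannot reproduce published CpG-context fractions of
  G:C sites in lacZ under any composition.
- `homopolymer`: inside or within 1 base of a run of >= 3 identical
  bases. Three is the shortest run meaningfully called a repeat; the
  1-base adjacency mirrors "within or adjacent to".
- `dipyrimidine`: the pyrimidine of the mutated basepair has a
  same-strand pyrimidine neighbour (checked on the bottom strand when
  the top-strand reference base is a purine).

Edge positions use whichever neighbours exist. Hotspots are positions
mutated in more than one animal of a dose group (recurrences within an
animal count once). Codon consequences translate the affected codon with
the standard code: stop gain is nonsense, preserved residue silent,
otherwise missense; all 1-2 bp indels are frameshifts; positions outside
the reading frame are intergenic.

Spectrum tables carry counts and within-group proportions over the eight
classes, optionally weighted by group MF (proportion x MF), which puts
groups with different mutational burdens on one frequency scale.

## Statistical machinery

- `monte_carlo_chi2()` compares groups over joint (position, class)
  cells — tables far too sparse for asymptotic chi-squared theory — by
  referring Pearson's X2 to its exact null over tables with both margins
  fixed, sampled by Patefield's algorithm. The p-value uses the add-one
  estimator (1 + #extreme)/(1 + n_sim), never zero, and is reproducible
  given a seed. The joint position-by-class table is used (rather than
  position or type alone) as the literal reading of comparing spectra
  "considering both position and type".
- `fisher_type_spectrum()` is exact for 2x2 tables and for R x C tables
  up to 5 non-empty classes and 200 observations (Freeman-Halton via
  `fisher.test`); beyond that it Monte Carlo-estimates the same
  probability-ordering p with fixed margins. Both paths agree with a
  full-enumeration hypergeometric oracle in the test suite. Two-sided
  p-values sum the probabilities of tables no more probable than the
  observed one — the convention that reproduces published CpG (0.287)
  and dipyrimidine (0.066) benchmark values.
- `per_type_subtables()` screens each class against all others pooled in
  2x2 tables, Bonferroni-adjusted by the number of classes with nonzero
  total (classes absent everywhere are skipped and logged, not counted).
- `induced_spectrum()` corrects a treated spectrum for background and
  burden: induced frequency per class is
  `MF_t x p_t(c) - MF_c x p_c(c)`, clipped at zero with a warning
  (classes the exposure does not elevate), renormalized to induced
  proportions. The unclipped variant is available (`clip = FALSE`).
  This difference-then-renormalize arithmetic is one defensible reading
  of "corrected for differences in background spectrum and induced MF";
  cross-tissue conclusions sensitive to it should also be checked on the
  unclipped scale. Where a comparison tissue's background MF is
  unavailable, setting `mf = 0` for the control reduces the induced
  spectrum to the treated spectrum — an adequate approximation when
  induction is many-fold.
- `mf_test()` fits the binomial logistic regression of per-animal
  (mutant, non-mutant) counts on group and scales inference by the
  Pearson dispersion with t-based p-values on the residual df — the
  standard quasi-likelihood treatment of overdispersed proportions.
  `force_dispersion = 1` recovers ordinary binomial scaling.

## Numerical choices and degenerate inputs

- Coordinates are 1-based and fully closed on the transgene strand
  everywhere; deletions anchor at the first deleted base, insertions at
  the base to their left.
- Threshold comparisons use `>=` with a 1e-12 guard against floating
  division; LOD rounding is half-up via `floor(x + 0.5)`.
- Monte Carlo extremeness comparisons carry small tolerances (1e-9 on
  X2, 1e-7 on log-probabilities) so ties count as extreme.
- Degenerate inputs fail loudly: zero column margins, clonality targets
  of 1 (unreachable for a finite pool), more mutations than plaques,
  non-divisible ORF lengths, alt reads exceeding depth, and induced
  spectra with no positive signal are all rejected with messages; zero
  wildtype depth yields FMP 0 with a warning; empty groups yield
  undefined (NA) proportions, flagged, never silent zeros.

## Problem sizes used in the checked examples

The test suite and acceptance script simulate 600-3000 bp references
with 15-70 mutations per animal, 100-144 plaques, full 2700x per-copy
depth, and average properties over >= 20 seeds where a tolerance is
asserted; these sizes were chosen so parameter-recovery claims rest on
a few hundred mutations per condition while the whole suite stays quick
to run. Reported performance at those conditions: recall ~0.99, false
positives well under one per animal, clonality mean absolute error
under 0.04.

## Known limitations

- The FMP estimator is the pooled-count per-site rate; the originating
  pipeline's exact estimator is published elsewhere and may differ in
  smoothing. A floor/pooling option is available through the model
  object but not default.
- The published per-animal clonality values cannot be reconciled exactly
  with pooled identified/independent counts, so the per-animal
  definition implemented here (1 - independent/identified from adjusted
  clone counts) is one documented choice; analyses that consume the
  bundled table use its printed clonality directly.
- Large (> 2 bp) deletions are out of scope for calling and are excluded
  from spectra.
- Dose-response modelling is not implemented; the frequency module
  compares two groups.
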