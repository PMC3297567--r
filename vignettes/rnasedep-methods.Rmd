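---
title: "Methods: models, parameters, and numerical choices in rnasedep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and numerical choices in rnasedep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasedep)
```

`rnasedep` analyses strand-specific tiling-array experiments that measure
how depleting an essential ribonuclease (RNase Y, J1, or III in
*B. subtilis*) changes transcript abundance genome-wide. This vignette is
the package's account of the statistical machinery: what each stage
assumes, which knobs matter, and where we had to make a call that the
experimental design itself does not dictate.

## The signal model

A tiling array reports, per probe `p` and hybridization `h`, a raw log2
intensity that mixes biology with two large technical terms:

$$y_{ph} = \text{profile}_{ph} + a_p + s_h + r_{ph}$$

where `a_p` is a probe-specific affinity offset (sequence-dependent
hybridization efficiency), `s_h` a per-hybridization shift (labelling and
scanning differences), and `r` residual noise. `estimate_probe_profiles()`
removes the two nuisance terms robustly:

* **Shift.** Each value's deviation from its probe's per-condition median
  is, by construction, free of both the probe's affinity and the
  condition-level biology; a median polish of that deviation matrix
  yields the column (sample) effects, which are the within-condition
  shifts. Condition-level biology can never leak into this term. The
  polish runs to a 1e-9 tolerance with at most 20 sweeps; medians of even
  counts use the midpoint convention.
* **Affinity.** A per-probe offset cannot be separated from the probe's
  own expression without further structure. The structure tiling arrays
  genuinely have is *local constancy*: transcription is piecewise
  constant along the chromosome at the 22-nt probe pitch, so a probe's
  persistent deviation from a running median over its position-adjacent
  same-strand neighbours (window of 3 probes by default) is affinity, not
  biology. The per-probe median of that deviation across samples is the
  affinity estimate. Deep inside a transcription unit the estimator is
  exact; at unit boundaries the 3-probe window still sides with the
  majority, so only single-probe features (which the pipeline ignores
  anyway) are distorted. Both nuisance estimates are centred to median
  zero, and `profiles + affinity + shift` reconstructs the input exactly.

The profile term is deliberately left *per sample* rather than averaged
per condition: replicate-level variation must survive to feed the
downstream linear model.

**Aggregation.** Gene-level expression is the median of probe profiles
over probes that are unique on the genome and lie entirely within the
coding sequence, same strand only — antisense signal is never mixed in.
Units with fewer than `min_probes = 3` eligible probes are flagged rather
than dropped; fragments covering only one or two probes are not reliably
measurable at this pitch.

## Normalization without distributional assumptions

Depleting a major RNase moves a large, asymmetric fraction of the
transcriptome. Quantile normalization (and any method that equates
marginal distributions) would erase exactly the biology being measured.
Instead the pipeline anchors on genes that demonstrably do not move:

1. Genes are ranked by average expression and split into
   `n_strata = 10` **equal-count** intervals. Equal-count (rather than
   equal-width) strata guarantee every stratum is populated, so the
   anchor set covers the whole intensity range.
2. Within each stratum, the fraction `frac_per_stratum = 0.10` of genes
   with the lowest variance across the **four main-condition means**
   (wild type and the three depletions, replicates averaged first) is
   kept: `floor(frac × stratum size)` genes per stratum, variance ties
   broken lexicographically by gene id so the set is reproducible.
3. For each hybridization, a loess curve (span 0.5, locally linear with
   tricube weights) of `observed − reference` against the reference —
   the per-gene mean of the anchor set over all hybridizations, a
   symmetric, condition-agnostic baseline — becomes the correction.
   Corrections are evaluated at each unit's observed value, with
   constant extrapolation beyond the anchor range so extreme values are
   shifted, never extrapolated wildly.

Locally-linear fitting was chosen over the quadratic default because the
correction is a slowly varying calibration curve; degree 1 is stabler at
the range ends where anchors thin out.

## The depletion model and multiple testing

Per gene, expression in condition `i`, replicate `j` is modelled as
`x_ij = wt + ΔRNase_i + ε_ij`: an ordinary one-way layout over the four
main experiments, fitted by least squares with a pooled residual variance
on `N − 4` degrees of freedom, and a two-sided t-test of each
`ΔRNase_i = 0`. Pooling buys degrees of freedom that duplicate designs
badly need. Genes with zero residual variance get an *undefined* p-value
— flagged and excluded from the multiplicity correction (`m` is
decremented) — never a spurious 0.

P-values become Benjamini–Hochberg step-up q-values; calls at
`q ≤ 0.1` combined with a fold-change gate on the point estimate
(`|Δ| ≥ log2(2)` or `log2(1.5)`) give the U/D/− profile codes. The
`overlap_sets()` summary partitions affected genes into the seven Venn
regions of the three depletions, with genes showing both increases and
decreases (depending on the RNase) kept in a separate mixed class.
`assign_primary_rnase()` labels each up-regulated gene by the depletion
with the largest significant increase; exact ties break by the fixed
order Y > J1 > III, reflecting the enzymes' decreasing breadth of impact
in this experimental system.

## Segment discovery and classification

Outside annotated genes, maximal same-strand runs of at least 3 unique
probes above threshold (bridging at most one sub-threshold probe) are
candidate transcribed segments. Probes overlapping a same-strand gene are
masked before run-finding, so a 5'UTR run ends at its gene's boundary
instead of being swallowed by it. Two admission rules apply, both on
**raw, pre-normalization** values because the thresholds are defined
against the physical background level:

* catalogue ("S") segments need 5× the chromosome median (computed per
  hybridization over unique probes) in at least one hybridization;
* new ("T") segments need 10× background **and** a one-way ANOVA F-test
  across the four main experiments at `p ≤ 0.05`.

Classification uses position and boundary shape. A drop of at least
`downshift_factor = 2` log2 units between 3-probe windows flanking a
boundary counts as an abrupt downshift (a terminator signature); the
threshold is our reading of "abrupt" — the source material for this
analysis style never quantifies it, so it is a documented, configurable
default. Adjacency to a gene within `max_adjacency = 44` nt (two probe
pitches) makes a segment contiguous with that gene. The decision table:
contiguous downstream → `5prime`; contiguous upstream → `3prime` /
`3primePT` (downshift but elevated downstream signal, partial
termination) / `3primeMT` (no downshift, slow tail); contiguous both
sides → `intra`; isolated with a sharp 5' upshift → `indep` or
`indepMT`; otherwise `inter`. Antisense relations record every
opposite-strand feature overlapping at least
`min(50 nt, 25% of segment length)` — again a documented default, since
no principled floor exists for deciding when antisense overlap is
biologically meaningful.

## Enrichment

Per functional category (hierarchical paths like
`Lifestyles * coping with stress * cell envelope stress proteins`), a
two-sided Fisher exact test compares the category's flagged fraction
(U at the 2× / FDR ≤ 0.1 gate, or D for the down screen) with the rest of
the genome, Bonferroni-corrected across the number of categories
examined. Two-sided testing is deliberate: both over- and
under-representation are reported (`+Up`/`−Up`/`+Down`/`−Down`). The
reference population is all annotated genes in the run, not the expressed
subset — matching how whole-genome reference rows are usually tabulated —
and is switchable by passing a filtered result.

## Decay kinetics

Degradation pathways are small species graphs: endonucleolytic cleavage
(RNase Y or III) converts a parent into fragments; exonucleolytic decay
(RNase J1 5'→3', or generic 3'→5') removes species. All steps are first
order, so the chase after transcription arrest is the linear system
`dx/dt = Ax`, solved **exactly** with the matrix exponential — no
integrator tuning, no stiffness issues, and the two-compartment analytic
solution is reproduced to machine precision. Exonucleolytic removal is
modelled as whole-species loss rather than nucleotide-resolved
processivity: the observable is band presence and half-life, not
intermediate ladders. Depletion divides every rate of the depleted enzyme
by `fold_reduction = 30` (the experimentally achieved floor; an
incomplete knock-down, not a knock-out). Unless overridden, the chase
starts from the condition's pre-chase steady state, in which abundance ∝
synthesis × half-life — the identity that underpins effect
classification.

Half-lives come from log-linear least squares of `ln(intensity)` on time
(at least 3 positive timepoints; values at or below the censoring floor
are dropped with a warning). A non-positive fitted decay constant is
reported as a *stable* sentinel, never a negative half-life. Band-pattern
prediction fits each simulated trace from its peak onward, because a
downstream fragment first accumulates before it decays.
`classify_effect()` calls an abundance change post-transcriptional when
the half-life fold-change is within a factor `tolerance = 1.5` of
explaining it, transcriptional when the half-life barely moved
(fold-change ≤ 1.5) while abundance did, and mixed in between — the
thresholds are ours; the underlying steady-state reasoning is standard,
but no quantitative cut-off for "sufficiently altered" exists in the
literature this mirrors.

## What the generator emulates — and what it does not

`simulate_expression()` reproduces the statistical structure the analysis
assumes: piecewise-constant transcription over annotated features
(roughly half of genes active, matching rich-medium expectations),
low-abundance regulatory segments (~6× background by default, between the
5× and 10× admission thresholds, so both rules are exercised),
Gaussian probe affinities (sd 0.25), per-hybridization shifts (sd 0.2)
and residual noise (sd 0.15) on the log2 scale, background centred at 4
with per-probe sd 0.3, planted depletion effects confined to the matching
−IPTG samples, and fully complemented +IPTG arms (the differential
contrast only ever uses wild type vs −IPTG). A `truth` block stores every
latent draw, so tests can invert the generator exactly.

It does **not** emulate sequence-dependent affinity (affinities are
exchangeable Gaussians), cross-hybridization chemistry,
reverse-transcription artifacts on the antisense strand, or correlated
noise along the chromosome. Passing tests therefore demonstrate
correctness of the estimators under the stated model, not robustness to
every artifact of physical arrays; on real data the affinity term is
sequence-driven and the running-median identification is an
approximation whose quality depends on transcription-unit length.

## Problem sizes and numerical conventions in the checks

The test suite and `scripts/acceptance.R` use sizes chosen to make
Monte-Carlo error small relative to the tolerances while staying quick:
FDR control on 2000 null + 500 affected genes (effect 1 log2, sd 0.2,
duplicates) over 20 seeds; ANOVA calibration on 10,000 null segments
(sd 0.3); enrichment family-wise error over 200 simulated datasets × 110
null categories of 10–200 genes at the genome-wide flag rate 0.188 on
4234 genes; half-life recovery at 1.3 and 4.3 minutes over 50 noisy
chases (10% log-normal noise). Stochastic assertions use three binomial
(or between-seed) standard errors. All randomness flows from a single
integer seed; derived seeds stay below 2^31.

## Known limitations

* The affinity estimator is blind to affinity structure that is itself
  locally constant along the chromosome (indistinguishable from biology
  by design).
* Between-condition components of the hybridization shift are
  unidentifiable at the probe level and are deferred to the least-variant
  normalization; the two stages are complementary, not redundant.
* Segment classification is heuristic where the underlying biology is
  continuous (partial termination, slow 3' tails); classes are
  deterministic given the profiles but sensitive to `downshift_factor`
  near the boundary.
* The decay module's first-order, whole-species kinetics cannot represent
  processive intermediates or endonucleolytic site preferences within a
  species.
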