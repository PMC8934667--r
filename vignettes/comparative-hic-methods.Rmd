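---
title: "Comparative Hi-C analysis of bacterial chromosome reorganization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative Hi-C methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hicratio)
```

# The analysis problem

Inactivating topoisomerase IV in *E. coli* reorganizes the chromosome in
ways that genome-wide contact maps (Hi-C) can read out: contacts gain
intensity in the 50–300 kb range along the replication arms (attributed to
precatenane links between sister chromatids), the terminus region
(1315–1830 kb) loses mid-range contacts while gaining very short-range
ones with a sharp border at *dif*, and a pair of "butterfly wing" stripes
appears in mutant/wild-type ratio maps, connecting the ~200 kb zone
surrounding *dif* with regions megabases away on both arms. `hicratio`
implements the complete differential analysis used to detect and quantify
these signatures, together with a synthetic data generator so that every
stage can be exercised, and its statistical behavior calibrated, without
sequencing data.

# Pipeline and conventions

All coordinates are 0-based, half-open bp internally; read-pair text files
are 1-based at the boundary, matching the common `.pairs` arithmetic. Bin
`b` covers `[(b-1)*bin_size, b*bin_size)`; the genome is tiled by
`ceiling(L / bin_size)` bins and the last, possibly shorter, bin is kept.
Genomic separation on the circular chromosome is
`s(i, j) = min(|i - j|, n - |i - j|) * bin_size`.

**Ingest.** `digest()` scans the forward strand for a fixed restriction
site (HpaII `C^CGG` by default; the cut position is `match_start +
cut_offset`), wrap-aware on circular genomes; ambiguous bases never match.
`filter_pairs()` retains a pair only when both mates map to a known
replicon with MAPQ of at least 31, an inclusive encoding of "mapping
quality strictly above 30". `build_matrix()` bins pairs by position
(`floor(pos / bin_size)`) and can drop pairs whose two ends share a
restriction fragment, a minimal proxy for religation/self-circle products;
the drop count is reported so the choice is auditable. No other
uninformative-pair classification is attempted — deeper filters (dangling
ends, PCR duplicates) are deliberately out of scope.

**Normalization.** `mask_sparse_bins()` removes bins whose marginal falls
below 10% of the median nonzero marginal (the exact threshold is a
parameter and is recorded on the object), then `scn_normalize()` performs
sequential component normalization: alternately divide rows and columns by
their component norm until the maximum row-norm deviation from 1 drops
below `tol` (default `1e-6`, at most 200 sweeps), then symmetrize by
averaging with the transpose. The default component norm is L1, so every
unmasked row sums to 1 and reads as a contact-frequency distribution; an
L2 variant is available (`norm = "l2"`). Convergence is measured on row
sums rather than matrix change because it is the directly testable
invariant; after the final averaging, row sums are within `2 * tol` of 1.
A half-step of alternating balancing always leaves the matrix slightly
asymmetric, hence the explicit symmetrization.

**Comparison.** `ratio_map()` computes `log2((mutant + p) / (control +
p))` cellwise. The default pseudocount `p` is the smallest positive value
across the two maps — after L1 SCN this is approximately the weight of a
single read pair, the conventional choice when zeros occur at moderate
depth. `distance_ratio_plot()` builds the bin-by-separation scalogram: for
each bin and each separation on a 5 kb-stepped grid (5–1000 kb by
default), the average contact AC is the mean of the two map values exactly
that far upstream and downstream (orientations pooled, circular wrap), and
the displayed cell is the log2 AC ratio. `virtual_4c()` extracts an anchor
bin's row (or the row mean over a span). `zscore_window()` sums the
contacts of a query window (default 3500–3600 kb) with each bin of a
disjoint target region (default the 1250–2450 kb terminus-containing
region) and standardizes with the population SD over target bins; the
population convention is a deliberate, recorded choice since the
transformation is only described as a Z-transformation in the literature
this follows.

# Quantifying the butterfly wings

`butterfly_cells()` enumerates the quantified cells: the dif-surrounding
zone (200 kb total, both flanks, always excluding the bin containing *dif*
itself) against every bin outside the terminus span, at separations beyond
a 300 kb near-diagonal guard. The symmetric geometry follows the
observation that distant regions contact bins symmetrically placed around
*dif*; the *dif* "barrier" acts on terminus-internal contacts and is
modeled there, not as a side-pairing of wings with arms.

`wing_enrichment()` reports three readouts over those cells:

* the mean per-cell log2 ratio (and a per-arm-bin profile, which dips at
  the excluded *dif* bin when the wings spare it);
* a **pooled fold**: `sum(mutant) / sum(control)` taken from the ratio
  map's source maps.

The pooled fold is the recommended effect-size estimate. At a depth of
10^6 pairs on 5-kb bins the mean expected count per long-range cell is
below ~1–2, and any per-cell log ratio with a one-read pseudocount is
shrunk toward zero by tens of percent; the ratio of pooled sums is
unbiased and has sub-percent sampling error over the ~3 x 10^4 wing
cells.

`distance_law_test()` fits an OLS slope of log(contact) against
log(separation), averaging cells within each unique separation first so
that shot noise does not enter the log transform. For the wing hypothesis
the test is applied to the *differential* signal (mutant minus control):
an additive 3-D hub is exactly distance-independent there, whereas on the
raw mutant map the decaying background dominates the hub at short-to-mid
separations and would mask its flatness. Background cells give clearly
negative slopes (about -0.8 under the default decay).

# The synthetic generator

`expected_map()` builds a noise-free expected matrix

    lambda(i, j) = P(s) * boost(i, j) * insulation(i, j) + wing(i, j)

with `P(s) = (s0 + s)^(-gamma)` on the circular genome, scaled to unit
mean. Defaults (all are knobs, none are biological estimates):

| parameter | default | meaning |
|---|---|---|
| `gamma`, `s0` | 0.8, 10 kb | qualitative bacterial P(s) decay |
| `beta` | 0.1 | multiplicative gain at 50–300 kb outside the terminus, mutant only |
| `iota` | 0.5 | terminus mid-range (>= 50 kb) depletion factor |
| `dif_border` | 0.3 | extra factor for terminus cells straddling *dif* |
| `short_boost` | 0.3 | terminus < 50 kb gain |
| `alpha` | 1.5 | wing pooled fold enrichment (see below) |
| `wing_width`, `wing_guard` | 200 kb, 300 kb | wing zone and calibration guard |

Two defaults deserve explanation.

**Wing amplitude is calibrated post-normalization.** SCN is
row-stochastic: each row sums to 1, so any additive stripe mass placed on
the anchor rows is partially renormalized away (with the shallow default
decay, long-range separations hold most of a row's mass, so the loss is
tens of percent, not a rounding error). An "additive mass" parameter would
therefore not be the observable effect size. Instead `alpha` is *defined*
as the pooled wing fold between SCN-normalized maps, and `expected_map()`
finds the additive mass by a short deterministic fixed-point iteration
(build, normalize, measure, rescale; converges in a few rounds to 0.1%).
The planted excess itself is a constant per cell, hence exactly
distance-independent. The default `alpha = 1.5` mirrors the ~1.5-fold
long-range *dif*-zone enrichment that motivates the quantifier.

**The precatenane gain is modest by design.** Because normalized rows sum
to 1, a multiplicative in-band gain `beta` necessarily depletes all other
separations of the same rows by `log2(1 + beta * band_share)`; with the
default decay the 50–300 kb band carries roughly 28% of a row's mass, so
`beta = 0.1` keeps that compensation near 0.04 log2 units — visible as a
faint genome-wide offset, small enough that the planted band remains the
only feature its scalogram shows. Much larger boosts would make the
compensation itself a second, artifactual feature. This is a general
property of relative (normalized) contact data, not of the generator.

`sample_counts()` draws independent Poisson counts on the upper triangle
with means proportional to the expected intensities (total depth in
expectation); `sample_pairs()` draws a multinomial of bin pairs, places
ends uniformly within bins and writes a `.pairs` file whose re-ingestion
reproduces the sampled count matrix exactly; a chosen fraction of records
receives MAPQ 10 so the quality filter has something to remove.

`simulate_foci()` emulates the paired-tag imaging experiment: per cell, a
tag pair at a baseline distance `0.3 + 0.6 * Beta(2, 2)` µm, a per-cell
colocalization event (distance drawn below 0.22 µm) with probability 9%
(wt) or 18% (mutant), a mutant variance scale of 0.5 on the baseline
spread, and optionally a sister pair in the other cell half. The geometry
guarantees that cross-pair and sister distances stay above the 0.25 µm
colocalization threshold, so the planted colocalization probability and
variance ratio are exactly the quantities `coloc_fraction()` and
`variance_f_test()` estimate. What the generator does *not* emulate:
optical blur and detection noise, cell-cycle structure, replicate-level
variability, or any coupling between chromosome conformation and focus
position — passing recovery tests therefore validates the estimators and
pipeline plumbing, not microscope realism.

# Statistical conventions

* The F test puts the larger unbiased variance on top and doubles the
  upper tail (capped at 1); its type-I error at the 5% level is verified
  by simulation to be 0.05 ± 0.01.
* Colocalization fractions carry exact (Clopper-Pearson) binomial 95%
  intervals.
* Cells with more than two foci of one tag are excluded with a warning;
  cells missing a tag are skipped and counted.
* Distances are 2-D image-plane distances in µm; no z-component.

# Problem sizes and reproducibility checks

The package's self-checks run the whole pipeline at the study scale — the
4,641,652-bp circular genome at 5-kb bins (929 bins) with 10^6 read pairs
per condition — which keeps every simulation in seconds while leaving
per-cell counts realistic for a small bacterial Hi-C experiment. Three
choices there are worth recording:

* **Replicate nulls are checked at depth-matched binning.** A wt-vs-wt
  ratio map at 10^6 pairs and 5-kb bins has ~2 expected counts per cell;
  per-cell |log2| noise is then ~0.4 regardless of pipeline fidelity.
  The null check therefore asserts (i) no systematic bias of the signed
  mean at 5-kb bins and (ii) a mean |log2| below 0.05 at 200-kb bins,
  where each cell holds >10^3 counts and the per-cell noise floor sits
  well below the band.
* **Single-feature plants isolate each signature.** Recovery checks for
  the band, the terminus depletion and the wings each run with only that
  feature enabled; the all-features default is exercised by the
  end-to-end pairs-file path, where the band statistic is read on
  non-terminus rows (terminus rows carry their own planted depletion).
* **Distance-law slopes are evaluated on expected matrices.** Slope
  checks use the noise-free planted excess; fold-enrichment recovery uses
  sampled data. At 10^6 pairs the per-cell wing excess is a fraction of a
  count, so a per-cell log fit on sampled data would measure shot noise.

# Known limitations

* Single replicon only; no multi-chromosome genomes.
* Sister-chromatid (trans) contacts are rendered in cis, as conventional
  Hi-C sees them; the generator makes no attempt at polymer realism.
* No CID/TAD/loop callers — the comparison operations quantify
  pre-specified geometries.
* The same-fragment filter is a stand-in for the unstated
  uninformative-pair filters of real pipelines; retention statistics make
  it auditable.
* `iota`, `dif_border`, `short_boost` and `beta` have no measured
  counterparts; they are set to be detectable, never interpreted as
  biology.
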