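# hicratio

Comparative Hi-C analysis of bacterial chromosome reorganization on a
single circular replicon, written for the *E. coli* topoisomerase IV
system: when Topo IV (ParC/ParE) is inactivated, contact maps gain
short-to-mid-range contacts along the arms (precatenane-like signal), the
terminus macrodomain (1315–1830 kb) loses mid-range contacts with a sharp
border at *dif*, and "butterfly wing" stripes of distance-independent
long-range contacts connect the ~200 kb *dif*-surrounding zone with
regions megabases away. `hicratio` provides every stage needed to detect
and quantify these signatures, plus a synthetic generator so the whole
pipeline is testable without sequencing data.

## What it computes

* **Ingest** — FASTA genomes (`read_genome_fasta()`), in-silico HpaII
  digestion and fragment attribution (`digest()`, `assign_fragment()`),
  `.pairs`-style read-pair text (`read_pairs()`), the MAPQ > 30 filter
  (`filter_pairs()`), and binned contact matrices (`build_matrix()`) with
  an optional same-fragment (religation proxy) filter.
* **Normalization** — sparse-bin masking (`mask_sparse_bins()`) and
  sequential component normalization, SCN (`scn_normalize()`): alternate
  row/column balancing to unit L1 norm, then symmetrization, so each row
  reads as a contact-frequency distribution.
* **Comparison** — log2 ratio matrices
  `log2((mutant + p) / (control + p))` (`ratio_map()`),
  distance-stratified ratio scalograms where each cell is the log2 ratio
  of the average contact AC(bin, separation) between conditions
  (`distance_ratio_plot()`), virtual 4C profiles (`virtual_4c()`), and
  windowed Z-transformation `z_j = (c_j - mean(c)) / sd(c)` of the
  contacts a query window makes with a target region (`zscore_window()`).
* **Butterfly-wing quantification** — `wing_enrichment()` pools the
  (dif zone) x (non-terminus genome) cells beyond a 300-kb guard,
  excluding the *dif* bin, and reports mean log2, a per-bin profile and a
  depth-robust pooled fold; `distance_law_test()` fits the log-log slope
  of contact vs separation to distinguish a distance-independent 3-D hub
  (slope ~ 0 on the differential signal) from decaying background
  (slope < -0.3).
* **Synthetic data** — `expected_map()` / `sample_counts()` /
  `sample_pairs()` generate expected intensities
  `P(s) * boost * insulation + wing` with `P(s) = (s0 + s)^(-gamma)`,
  Poisson/multinomial sampling and `.pairs` output; `simulate_foci()`
  generates paired-tag microscopy coordinate tables.
* **Foci statistics** — per-cell closest/furthest interfocal distances
  (`interfocal_distances()`), colocalization fractions below 250 nm with
  exact binomial CIs (`coloc_fraction()`), two-sided variance F tests
  (`variance_f_test()`) and relative cell-axis position histograms
  (`relative_positions()`).

## Worked example

Simulate the two conditions at study scale (4.64-Mb circular genome,
5-kb bins, 10^6 read pairs each), normalize, and quantify the planted
signatures:

```r
library(hicratio)
p   <- sim_params()                  # defaults: alpha = 1.5, beta = 0.1, ...
wt  <- expected_map(p, "wt")
mut <- expected_map(p, "mutant")
wt_n  <- scn_normalize(mask_sparse_bins(sample_counts(wt,  1e6, seed = 1)))
mut_n <- scn_normalize(mask_sparse_bins(sample_counts(mut, 1e6, seed = 2)))
r  <- ratio_map(mut_n, wt_n)
we <- wing_enrichment(r)
sprintf("dif-zone long-range enrichment: %.2f-fold over %d cells",
        we$fold, we$n_cells)

z <- zscore_window(mut_n, query_window = c(3500e3, 3600e3),
                   target_region = c(1250e3, 2450e3))
# dif bin z score vs its 100-kb neighborhood ...

fp <- foci_sim_params()
dw <- interfocal_distances(simulate_foci(fp, "wt", seed = 3), "ter", "left")
dm <- interfocal_distances(simulate_foci(fp, "mutant", seed = 4), "ter", "left")
coloc_fraction(dw$closest); coloc_fraction(dm$closest)
variance_f_test(dw$closest, dm$closest)
```

Output:

```
dif-zone long-range enrichment: 1.51-fold over 32179 cells
z score at dif: -0.20; mean z over dif +/- 50 kb (dif excluded): 1.60
colocalized (<250 nm): wt 8.3%, mutant 18.5%
F test on interfocal distances: F = 1.25, p = 0.0059
```

Reading the numbers: the distant chromosome contacts the *dif*-flanking
zone ~1.5-fold more in the mutant (the planted wing amplitude), while the
*dif* bin itself sits ~1.8 z-units below its immediate neighbors — the
wings spare *dif*. In the imaging arm, mutant cells colocalize the *ter*
and *left* tags about twice as often as wild type (planted 9% vs 18%),
and the F test detects the compressed mutant distance distribution.
`plot(r)`, `plot(distance_ratio_plot(mut_n, wt_n))` and
`plot(virtual_4c(mut_n, 1588800))` render the ratio map, scalogram and
4C-like track with the conventional blue-white-red scale.

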