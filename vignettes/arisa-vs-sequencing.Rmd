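---
title: "Comparing ARISA fingerprints with amplicon sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ARISA fingerprints with amplicon sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arisacomp)
```

## The problem

Automated ribosomal intergenic spacer analysis (ARISA) profiles a bacterial
community by PCR-amplifying the 16S–23S intergenic spacer and sizing the
products on a capillary instrument. Fragment-length bins play the role of
OTUs: each electropherogram peak is a fluorescence intensity (RFU) at a
called size (bp). The method is cheap and fast but structurally limited —
only fragments of roughly 200–1150 bp are observable, distinct taxa can share
a spacer length, one taxon can carry several spacer lengths across its rRNA
operons, and weak signals drown in instrument noise. Amplicon sequencing
(here modeled after 16S pyrosequencing at ~10,800 reads per sample) resolves
thousands of sequence-defined OTUs and is limited mainly by depth.

`arisacomp` implements the complete desk side of a two-method comparison on
the same samples: the ARISA peak-processing pipeline, the shared community
statistics (α-diversity, Bray-Curtis β-diversity, ANOSIM, PCoA, Procrustes,
similarity-vector correlation), and a seeded simulator of group-structured
communities — modeled on rumen communities sampled across host age groups,
whose richness rises from hundreds of taxa in newborn calves to thousands in
adult cows — so that every stage is testable without access to instrument
data.

## ARISA processing model

The pipeline applies, in this fixed order:

1. **Intensity floor.** Peaks with intensity ≤ `min_rfu` (default 10 RFU)
   are excluded. The exclusion is strict at the boundary: a 10.0 RFU peak is
   removed.
2. **Window clip.** Peaks outside the detectable window are removed. The
   default window is [200, 1150] bp with both endpoints included, since both
   endpoint lengths are observable in principle. The lower bound is
   configurable: typical custom ladders start at 250 bp, so a 250 bp lower
   bound is a reasonable alternative for matching a specific instrument
   set-up.
3. **Binning.** A fixed grid anchored at the window start, with half-open
   bins `[lo, lo + w)`: 3-bp bins up to 700 bp, 5-bp bins from 700 to
   1000 bp, 10-bp bins above 1000 bp (242 bins in total for the default
   window). The last bin of each regime is truncated at the regime boundary
   (`[698, 700)`), a boundary size belongs to the higher regime's first bin,
   and the final bin is closed (`[1140, 1150]`). A fixed grid — rather than
   bins floated around observed peaks — was chosen because it is
   deterministic, independent of peak order and of other samples, and makes
   bin labels comparable across runs; the cost is that a peak pair straddling
   a grid edge can split into two bins where a peak-centered rule would merge
   them.
4. **Summation.** Intensities are summed per bin within each
   sample × replicate profile. Total intensity is conserved exactly.
5. **Relative-intensity filter.** Each bin's share of the profile's
   *pre-filter* total is computed, bins below `min_relative_intensity`
   (default 0.001, i.e. 0.1%) are dropped in a single pass, and the
   surviving bins are re-normalized to sum to one. A fixed-point iteration
   (re-applying the threshold after renormalization) would remove additional
   bins; the single pass matches the natural reading of "compute relative
   intensities, drop those under 0.1%". Renormalization is assumed so that
   downstream Bray-Curtis operates on compositions.
6. **Replicate QC.** The two technical replicates of each sample are
   compared as individual profiles by Bray-Curtis similarity over the union
   of their bins. Pairs at or above `replicate_threshold` (default 0.8 — a
   conventional reproducibility bar for fingerprint profiles; no published
   value is prescribed) are merged as the arithmetic mean of relative
   intensities, re-normalized; pairs below fail QC and are reported rather
   than merged.

The per-sample profiles are then assembled into a relative-intensity OTU
table (bins = OTUs, absent bins = 0).

## Comparison statistics

* **α-diversity.** Observed OTUs (support size) per sample and per group
  (an OTU counts toward a group if present in *any* of its samples — group
  totals are unions of supports, not pooled-read recounts), and
  Shannon–Wiener H' in natural-log units. Group means are compared with
  Welch's unequal-variance two-sided t-test; with several group pairs the
  p-values are Bonferroni-corrected (`min(1, m·p)`).
* **β-diversity.** Bray-Curtis dissimilarity
  `1 − 2·Σmin(x, y)/(Σx + Σy)`. Sequencing counts are converted to
  per-sample proportions first (no rarefaction is applied); ARISA tables are
  already compositional. On proportion vectors the index equals half the L1
  distance, which the tests exploit as an identity check.
* **ANOSIM.** R = (mean between-group rank − mean within-group rank)/(M/2)
  on the mid-ranked pairwise dissimilarities, M = n(n−1)/2. Significance is
  one-sided (large R) by label permutation with the +1 convention,
  so p is never 0. When the number of distinct labelings is at most `n_perm`
  (default 9999) the null is enumerated exhaustively and p is exact — this
  covers all pairwise tests at the default design (two groups of 5–6 samples
  have at most 462 distinct labelings). Pairwise p-values are
  Bonferroni-corrected by the number of pairs.
* **PCoA.** Gower double-centering of −½D², symmetric eigendecomposition,
  coordinates scaled by √eigenvalue. Bray-Curtis is semimetric, so negative
  eigenvalues can occur; they are counted and their axes dropped, with no
  Lingoes/Cailliez correction (the comparison uses only the leading three
  axes, where the distortion is immaterial and a correction would change
  both ordinations equally). Axis signs follow a deterministic convention
  (largest-magnitude loading positive) so outputs are bit-stable.
* **Procrustes.** Both 3-axis configurations are centered and scaled to unit
  root sum of squares — the *symmetric* scaling convention, chosen so that
  M² does not depend on which method is called the reference — and the
  optimal orthogonal transform comes from the SVD of the cross-covariance.
  Reflections are allowed because PCoA axis orientation is arbitrary.
  M² = 1 − (Σ singular values)², the minimized residual, in [0, 1].
  Significance is Monte-Carlo: rows of one configuration are randomly
  relabeled `n_perm` times (default 1000) and
  p = (1 + #\{M²_perm ≤ M²_obs\})/(1 + n_perm), floor 1/1001.
  Ordinations with fewer than three positive axes are zero-padded with a
  warning.
* **Similarity correlation.** Pearson r between the two methods'
  n(n−1)/2 pairwise similarities. Because pairs sharing a sample are not
  independent, a Mantel-style permutation p (joint row/column relabelings of
  one matrix, one-sided) is reported alongside the parametric p; for n ≤ 6
  the permutation null is enumerated exhaustively.

## The synthetic-data generator

The generator emulates the *statistical structure* the comparison assumes,
not any particular rumen dataset:

* **Groups.** Four age groups with 6/5/5/5 samples and true richness
  200/600/2000/2400 — the observed study design, with per-sample OTU counts
  of the right order of magnitude for 1–3-day, 2-month, 6-month and 2-year
  animals. Richness must be non-decreasing across the group order.
* **Abundances.** Log-normal ranked abundances (σ = 1.5) per group template;
  log-normal is the conventional null model for rank-abundance curves in
  community ecology and produces the long rare tail that exercises the 0.1%
  filter. Each sample is the mixture θ·template + (1−θ)·individual draw over
  the same taxa (θ = 0.85), so θ maps monotonically to expected within-group
  Bray-Curtis similarity; θ = 1 gives identical samples. θ = 0.85 yields
  within-group similarities around 0.8–0.9 and cleanly separated groups,
  matching a design in which every group pair separates under ANOSIM.
  Adjacent groups share 50% of the smaller group's taxa (a core community
  carried across ages).
* **Sequencing.** Depth per sample from a truncated normal
  (10,800 ± 2,860, floor 1,000 reads — the floor only prevents degenerate
  samples), reads multinomial on the true proportions.
* **ARISA signal.** Each taxon gets a fragment length uniform on the
  window; with probability 0.2 it gets a second length (operon-level spacer
  variation). Distinct taxa on the same length merge additively — together
  these reproduce the two mechanisms that make fingerprints mis-state
  richness. Fluorescence is `gain × abundance` (gain 10⁵ RFU, putting the
  10-RFU floor at 10⁻⁴ relative abundance), sizes get Gaussian calling noise
  (SD 0.3 bp, typical capillary precision), intensities get log-normal
  run-to-run noise (SD(log) 0.1), and ~25 spurious baseline peaks per run
  (exponential intensities, scale 5 RFU) mostly die at the RFU floor.

What the simulation does *not* model: PCR primer and amplification bias,
chimeras and sequencing error (the count table is a clean multinomial),
taxonomically structured spacer-length distributions, intensity saturation
of the detector, and size-ladder calibration error. Passing tests therefore
demonstrate that the *pipeline and statistics* behave correctly on data with
the assumed structure — not that ARISA and sequencing agree on any real
sample set.

## Determinism and numerics

Every stochastic operation takes an explicit seed and runs under
`withr::with_seed`, leaving the session RNG untouched; the pipeline derives
per-stage sub-seeds from one master seed, so a full run is byte-identical
when repeated. Ties in ANOSIM ranks use mid-ranks. Eigenvalue positivity in
PCoA uses a relative tolerance of 1e-9. The Bray-Curtis of two all-zero
vectors, Shannon of an all-zero sample, and a profile with zero total
intensity are errors, not silent zeros. A Welch test on two zero-variance
equal-mean groups returns p = 1 by convention rather than failing.

## Problem sizes

The test suite validates the pipeline against brute-force re-implementations
on 100 random peak tables of 1,000 peaks, enumerates ANOSIM and Mantel nulls
exhaustively up to n = 6, checks Procrustes against direct numerical
minimization over rotations and against vegan's symmetric Procrustes, and
sweeps the full simulated design over 20 seeds. These sizes give exact or
near-exact reference values while keeping a full check run in the order of a
minute on one CPU.

## Limitations

* The singleton/doubleton removal rule for sequencing tables is applied to
  OTU totals across the study, not per sample; a per-sample reading would
  remove more. The per-study reading treats "clusters of one or two reads"
  as a property of the clustering run, which is how denoising filters are
  conventionally applied.
* Bin labels encode integer base-pair boundaries; schemes anchored at
  non-integer positions would need a finer label format.
* The replicate-QC threshold, the fixed-grid binning and the symmetric
  Procrustes scaling are documented package choices; instruments, binning
  scripts and ordination toolkits vary on all three, so absolute numbers are
  comparable across studies only when these conventions match.
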