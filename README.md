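# arisacomp

Processing and cross-validation of ARISA community fingerprints against
amplicon-sequencing OTU tables.

## What this is for

Automated ribosomal intergenic spacer analysis (ARISA) sizes the 16S–23S
intergenic spacer on a capillary instrument and treats fragment-length bins
as OTUs. It is a fast, cheap fingerprint of a bacterial community — but the
detectable window (~200–1150 bp), spacer-length collisions between taxa,
multi-operon taxa and the instrument noise floor all distort richness,
especially in complex communities such as the rumen. Sequencing-based
profiling resolves far more taxa but costs more. A standard question for
microbial ecologists is therefore: *do the two methods tell the same story
about β-diversity and group structure, even where fingerprint richness
saturates?*

`arisacomp` implements both sides of that comparison:

* **ARISA processing** — from a size-called peak table (sample, replicate,
  size in bp, intensity in RFU) to a relative-intensity OTU table:
  exclusion of peaks ≤ 10 RFU, clipping to the 200–1150 bp window, binning
  on a fixed grid (3 bp up to 700 bp, 5 bp to 1000 bp, 10 bp above),
  per-bin intensity summation, removal of bins under 0.1% of the sample
  total, and technical-replicate QC (Bray-Curtis ≥ 0.8) with merging.
* **Community statistics** — observed OTUs and Shannon–Wiener H' with Welch
  t-tests; Bray-Curtis dissimilarity `1 − 2·Σmin(x,y)/(Σx+Σy)`; ANOSIM
  `R = (r̄_between − r̄_within)/(M/2)` with exhaustive or sampled permutation
  p-values and Bonferroni correction; PCoA by Gower double-centering;
  Procrustes superimposition with `M² = 1 − (Σσ)²` under symmetric scaling
  and Monte-Carlo significance; Mantel-style correlation of the two methods'
  pairwise-similarity vectors.
* **A synthetic study generator** — seeded, group-structured communities
  (4 age groups, n = 6/5/5/5, true richness 200→2400), multinomial
  pyrosequencing reads at ~10,800 per sample, and ARISA peak tables with
  collisions, operon multiplicity, calling noise and baseline peaks, so the
  whole pipeline runs and is tested without instrument data.

## Worked example

```r
library(arisacomp)

sim <- simulate_dataset(seed = 42)        # truth + pyro counts + ARISA peaks
res <- process_arisa(sim$peaks)           # RFU filter -> clip -> bin -> 0.1% -> QC
dim(res$otu_table)
#> [1]  21 241
head(res$qc, 3)
#>   sample_id similarity passed
#> 1       S01  0.8126803   TRUE
#> 2       S02  0.8294020   TRUE
#> 3       S03  0.8880463   TRUE

observed_otus(res$otu_table, sim$metadata)$per_group
#> 1-3 days 2 months  2 years 6 months
#>      163      212      236      231

D_arisa <- distance_matrix(res$otu_table)
D_pyro  <- distance_matrix(remove_rare_otus(sim$pyro))

anosim(D_arisa, sim$metadata, seed = 1)
#> ANOSIM: R = 1.0000, p = 0.0001 (sampled, 9999 labelings)

proc <- procrustes_monte_carlo(pcoa(D_pyro), pcoa(D_arisa), n_perm = 1000, seed = 1)
proc
#> Procrustes: M^2 = 0.0477 over 3 axes, p = 0.000999 (1000 permutations)

corr <- correlate_similarity_vectors(D_arisa, D_pyro, seed = 1)
sprintf("Pearson r = %.3f, Mantel p = %.3g", corr$pearson_r, corr$p_mantel)
#> "Pearson r = 0.888, Mantel p = 0.001"
```

Reading the output: the fingerprint's 21 samples occupy 241 of the scheme's
242 bins overall while per-group richness saturates near the bin capacity
(163–236), far below the thousands of sequencing OTUs — the expected
fingerprint compression. Despite that, ANOSIM separates the age groups
perfectly (R = 1 at the permutation floor), the two ordinations superimpose
almost exactly (M² = 0.048, p at the 1/1001 Monte-Carlo floor), and the two
methods' pairwise similarities correlate strongly (r = 0.89): the fingerprint
preserves the β-diversity story even where it understates richness.

The full pipeline in one call:

```r
report <- run_comparison(run_config(seed = 17))
render_report(report, "results/")   # report.json, TSV tables, PCoA/Procrustes plots
```

or from a shell:

```sh
Rscript inst/scripts/compare.R --simulate --seed 17 --out-dir results/
```

Re-running with the same seed reproduces every JSON/TSV output byte for
byte.

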