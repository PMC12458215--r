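# drscan

Analysis toolkit for pooled **deep receptor scanning** of G protein-coupled
receptor (GPCR) libraries — Sort-Seq experiments in which each cell of a
recombinant pool expresses a single barcoded receptor, cells are sorted into
fluorescence bins, and bin-resolved barcode sequencing quantifies every
receptor's plasma membrane expression (PME) in parallel.

The package is aimed at groups running (or reanalyzing) pooled
expression/stability scans of membrane-protein libraries and covers the full
computational stack:

* **Library design** — Hamming-constrained 10-nt UMI whitelists, HA-tag
  insertion, synonymous silencing of Golden-Gate sites, terminal-glycine
  cassette processing, cassette assembly with element maps.
* **Sort-Seq quantification** — expected-error read filtering, exact-match
  UMI counting, hypergeometric rarefaction, low-GFP enrichment with Fisher
  exact tests, bin-weighted intensity estimation, replicate normalization,
  splice-variant summaries.
* **Codon analytics** — sliding-window %MinMax profiles, common/rare codon
  fractions, GC content, random-reverse-translation null distributions.
* **Ribo-Seq metagenes** — monosome/disome length gating, 100-bin metagene
  profiles, coverage Z-scores, mock normalization and abundance adjustment.
* **Receptor features** — translocon insertion-energy (ΔG) scanning of
  transmembrane segments, topological/physicochemical/transcript feature
  vectors, Shrake–Rupley solvent-accessible surface areas with
  charged/polar/apolar partitioning, secondary-structure fractions.
* **Expression classification** — 67th-percentile high/low PME labeling,
  stratified splits, random forests over biologically motivated feature
  subsets, rank-statistic AUROC, path-dependent TreeSHAP attributions
  (C++), UMAP embeddings.
* **Synthetic data** — seeded generators for every assay stage, so the
  entire pipeline is testable offline.

## The core quantities

For receptor *r* with rarefied read counts *c<sub>r,b</sub>* across the five
high-GFP sorting bins with representative intensities *I<sub>b</sub>*:

* surface expression: *Î<sub>r</sub>* = Σ<sub>b</sub> c<sub>r,b</sub> I<sub>b</sub> / Σ<sub>b</sub> c<sub>r,b</sub>,
  normalized across replicates by each day's population mean and averaged;
* transcript stability: enrichment = c<sub>r,low</sub> / Σ<sub>b</sub> c<sub>r,b</sub>,
  tested with a two-sided Fisher exact test on the receptor-vs-rest 2×2 table;
* codon usage: %MinMax = 100·(Actual−Avg)/(Max−Avg) (or /(Avg−Min) below the
  mean) over 17-codon windows;
* membrane insertion: ΔG<sub>app</sub> of the minimal-energy 17–25-residue
  window inside each coarse TMD region, on the biological hydrophobicity
  scale.

## Worked example

```r
library(drscan)

# simulate a 200-receptor library and a Sort-Seq experiment
rs  <- simulate_receptor_set(200, seed = 1)
sim <- simulate_sortseq_experiment(rs$truth, reads_per_receptor = 2000,
                                   cell_cv = 0.5, seed = 2)

# estimate per-receptor surface expression from the bin counts
est <- estimate_intensity(sim$counts, sim$bin_intensities, min_freq = 0)
cor(est, rs$truth$latent_intensity, method = "spearman", use = "complete.obs")
#> [1] 0.9993833

# label high/low expressers at the 67th percentile
lab <- binarize_expression(est, 67)
lab$cutoff
#> [1] 1905.379
table(lab$labels)
#>
#>  low high
#>  134   66
```

The Spearman correlation near 1 says the bin-weighted estimator recovers the
simulated ground-truth intensities almost perfectly at this depth and noise
level; the cutoff is the 67th-percentile intensity (arbitrary fluorescence
units) above which a receptor is labeled high-PME, leaving about a third of
receptors in the high class.

```r
# a 100-barcode UMI whitelist under the assay's design constraints
umis <- generate_umi_set(100, umi_constraints(), seed = 3)
min_pairwise_hamming(umis)
#> [1] 4
```

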