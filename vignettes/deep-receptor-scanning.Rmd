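---
title: "Deep receptor scanning: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep receptor scanning: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscan)
```

# The assay this package models

Pooled "deep receptor scanning" couples single-copy genomic recombination
with fluorescence-activated cell sorting and barcode sequencing. Each cell
in a recombinant library expresses one G protein-coupled receptor (GPCR)
from a defined locus; an N-terminal HA epitope reports plasma membrane
expression (PME) by surface immunostaining, and a bicistronic IRES-GFP
cassette reports transcript accumulation. Cells are first split into low-
and high-GFP subpopulations (unstable transcripts enrich in the former);
the high-GFP population is then sorted into five quintile bins by
immunostaining intensity. Sequencing a 10-nt barcode (UMI) unique to each
receptor in every fraction yields, per receptor, a low-GFP enrichment score
and a bin-weighted surface-expression estimate. Downstream, codon-usage
profiles, ribosome-footprint metagenes and structure-derived feature
vectors explain where expression differences come from.

`drscan` implements every computational stage of that workflow, plus
seeded simulators that emulate each stage's data so the whole pipeline is
testable without any external download.

# Library design

`generate_umi_set()` builds the barcode whitelist. The defaults are the
design constraints of the assay: 10-nt barcodes, minimum pairwise Hamming
distance 4 (so two sequencing errors cannot convert one barcode into
another), homopolymer runs capped at 2, GC between 35% and 65%, and no ATG
or common cloning-enzyme recognition sequence (BsmBI, BsaI, EcoRI, XhoI,
NotI) on either strand. The motif list is a package choice: the assay
excludes "common restriction sites" without enumerating them, so we fixed
the Golden-Gate enzymes plus three ubiquitous cloners. The default search
enumerates all 4^10 candidates, filters, and then selects greedily in a
seeded random order with pairwise-distance rejection; `method = "greedy"`
samples candidates instead, which scales to longer barcodes at the cost of
not knowing the full pool size.

Construct processing mirrors the cloning rules: `insert_ha_tag()` places
the HA nonapeptide (YPYDVPDYA) after the second codon (receptors with
signal peptides need a caller-supplied insertion point downstream of the
predicted cleavage site — predicting that site is out of scope);
`silence_sites()` removes internal BsmBI sites by synonymous substitution,
preferring the most frequent codon that works and trying two-codon edits
only when no single edit suffices; `terminal_glycine_swap()` strips native
C-terminal glycines (preventing non-native diglycine motifs at the
junction) and appends one glycine codon (GGC, the most frequent human Gly
codon) before the native stop. `assemble_cassette()` concatenates enzyme
site, UMI, attB, ORF and a reverse-oriented 3' enzyme site, and verifies
that exactly two recognition occurrences exist on both strands combined.

# Sort-Seq quantification

Reads are filtered by expected errors: a read is kept when the sum of its
per-base error probabilities `sum(10^(-Q/10))` is at most 1.0 — the
standard reading of "likely to contain more than one error". Barcodes are
matched exactly; a single mismatch discards the read rather than rescuing
it, because the whitelist's Hamming-4 spacing makes silent
misassignment far less likely than honest loss.

Samples are rarefied (`rarefy_counts()`) to the smallest sample total by
multivariate-hypergeometric subsampling, each sample on an RNG stream
derived from `(seed, sample id)` so adding a sample never perturbs the
others. Enrichment in the low-GFP fraction is the receptor's low count
over its combined high-bin count, with a two-sided Fisher exact test on
the receptor-versus-rest 2x2 table; Benjamini-Hochberg q-values are
reported alongside the raw p-values. Receptors sampled below 0.0005% of
the low total or of the combined high total are flagged and left unscored;
the threshold is applied after rarefaction.

The surface-expression estimate is the intensity-weighted average of a
receptor's reads over the five bins. Bin representative intensities are
user-supplied; when only gate boundaries are known,
`bin_intensities_from_gates()` uses geometric means, since flow
intensities are approximately log-distributed. Replicates are rescaled by
the ratio of the grand-mean population intensity to each replicate's
population mean (ratio rather than subtraction: day-to-day drift in
cytometer calibration is multiplicative on the fluorescence axis), then
averaged over the replicates where the estimate is defined.

# Codon usage

`minmax_profile()` computes the sliding-window %MinMax statistic: within
each window (default 17 codons; 7 and 27 give rank-consistent summaries),
the mean usage frequency of the codons actually present is compared with
the window's attainable maximum, minimum and mean. Values are bounded in
[-100, +100]; +100 means every window codon is its family's most frequent
choice. Raw genome-wide frequencies are the default (the convention of the
original algorithm); within-family relative frequencies are available via
`relative = TRUE`. Methionine, tryptophan and stop codons are excluded
from window means — their single-codon families make the normalizing
denominator zero.

`random_reverse_translations()` supplies the null: codon sequences sampled
per residue proportional to genome-wide usage, each scored for common/rare
fractions and GC. `compare_median_groups()` performs the two-group
Mann-Whitney comparison used to contrast high- against low-GFP transcripts,
with ties at the median assigned to the low group.

# Ribosome profiling

Footprints of 28-38 nt are monosomes, 50-70 nt disomes, everything else
discarded (inclusive bounds). `metagene_profile()` pools one class across
transcripts into 100 relative-position bins anchored at the fragment 5'
end; no P-site offset is applied by default because the assay defines none,
but a fixed offset is available. Densities are fragments per million
mapped fragments per nucleotide, with the per-million denominator shared
between classes so monosome and disome profiles are directly comparable;
the per-bin nucleotide span is the mean CDS length over pooled transcripts
divided by 100, which makes the profile conserve fragment counts exactly.
Coverage Z-scores use the population (1/n) standard deviation.
RNA-Seq counts are mock-normalized by subtracting the parental-line
replicate mean, and abundance adjustment divides by the receptor's
fractional DNA-pool representation — a ratio, the simplest reading of
"adjusting for relative abundance"; negative mock-normalized values are
kept and flagged, never floored in stored values.

# Receptor features

Seven refined transmembrane segments per receptor are found by
`dg_scan()`: within a coarse predictor-supplied TMD region extended by a
5-residue flank, every window of 17-25 residues is scored with the
biological hydrophobicity scale's apparent insertion free energy and the
minimum is returned (ties to the longer window, then the smaller start).
The full predictor (per-residue Gaussian depth profiles with interface
terms for Trp/Tyr, a helical hydrophobic-moment term, and a quadratic
length correction) is the default; a plain sum over the scale's central
values is available as `mode = "sum"`. The scan is checked against
brute-force enumeration, so its correctness does not depend on which mode
is chosen.

The 27-feature topological schema (per-TMD normalized lengths and
insertion energies, six loops, two tails, totals, mean/min energy, protein
length) is fixed; the assay's own supplementary itemization is not
re-derived. All length features are normalized by protein length and
partition to 1. `sequence_properties()` yields molecular weight,
isoelectric point (bisection on the Henderson-Hasselbalch net charge),
aromaticity, the published dipeptide-composition instability index and the
Kyte-Doolittle GRAVY score. `transcript_feature_vector()` emits a fixed,
documented transcript descriptor set (GC by codon position, %MinMax
summaries, composition, skews, CpG density, 5'-region descriptors,
homopolymer maxima).

`shrake_rupley_sasa()` implements the classic sphere-point quadrature with
a deterministic golden-spiral point set (default 960 points, probe 1.4 A).
Atoms are classed charged (side chains of D/E/K/R/H), polar (backbone N/O
and other side-chain N/O) or apolar (remaining C/S/H), so class totals
partition the total surface exactly. Exactly coincident duplicate atoms
are collapsed to a single contributing sphere. Quadrature error at 960
points is well under 0.5% on test structures; doubling the point count is
the recommended convergence check.

# Expression classification

Receptors are labeled high-PME when their intensity reaches the 67th
percentile of the finite intensities (linear-interpolation quantile;
`>=` at the boundary). Splits are stratified 80:20. The classifier is a
random forest (500 trees, sqrt(p) features per split by default — the
assay states no hyperparameters, so the field's defaults are used) over
one of four feature subsets selected by schema name: full, protein
(topology + structure + sequence), topological, structural. Evaluation
reports balanced accuracy, precision, recall, F1 (hard labels at 0.5) and
a rank-statistic AUROC.

Attributions are path-dependent TreeSHAP computed over the fitted
ensemble (implemented in C++ in this package; node covers are the inbag
training counts routed through each tree). Per receptor, the base value
plus attributions reconstruct the predicted probability exactly, and the
global ranking by mean absolute attribution is reported next to the
forest's Gini importances. UMAP embeddings standardize features first and
run single-threaded under the stated defaults (n_neighbors 15, min_dist
0.1, Euclidean) so a seed fully determines the result. Note that
min_dist imposes a floor (~0.1) on how tightly duplicate receptors can
co-locate in the embedding.

# What the simulators emulate — and what they do not

* `simulate_receptor_set()`: random in-frame ORFs with tunable
  synonymous-codon bias and GC tilt; latent surface intensities are
  log-normal with a ~4-decade range across +-2 sd, the dynamic range seen
  in receptor surface immunostaining; optional planted unstable
  transcripts.
* `simulate_sortseq_experiment()`: log-normal cell-to-cell noise
  (default CV 0.5), population-quintile gates, multinomial read sampling
  per bin. Defaults: 500 cells and 2000 reads per receptor.
* `simulate_transcript_stability()`: low-GFP sampling weights
  proportional to 1/stability; depths 1e6 by default.
* `simulate_riboseq()`: uniform anchors with an optional multiplicative
  pause-bin boost; monosome fraction 0.92 (disomes are a small minority
  of footprints).
* `simulate_feature_table()`: two planted threshold effects — expression
  drops when TMD6 insertion energy is above 0 kcal/mol and when total
  SASA is below 1900 A^2 — plus pure-noise features. The feature
  distributions put about a third of receptors above the TMD6 threshold
  and half below the SASA threshold, so the no-defect group matches the
  ~33% high prevalence of the 67th-percentile cutoff; the default
  3-log-unit effects (~20-fold intensity change per defect, on the order
  of the largest between-receptor differences seen in surface staining)
  make the planted structure recoverable well above the irreducible label
  noise. With boundary-misaligned groups, no classifier can exceed
  ~0.87 AUROC regardless of effect size — a useful reminder that the
  benchmark tests the harness, not biology.

The simulators deliberately omit: sequencing error inside barcodes (reads
either match exactly or are discarded), PCR amplification bias,
cytometer spillover and gating artifacts, isoform-aware footprint
ambiguity, and any mechanistic link between a receptor's actual sequence
features and its simulated intensity (except where explicitly planted).
Passing recovery tests therefore demonstrates that the estimators invert
the generative model they assume — not that the model captures every
property of real sorter data.

# Numerical conventions

Coordinates are 0-based, half-open everywhere. Quantiles use the
linear-interpolation convention. Fisher tests use the exact hypergeometric
two-sided rule. Rarefaction uses sequential conditional hypergeometric
draws. %MinMax windows holding only excluded codons are NA and drop out of
the common/rare fractions. Zero-variance inputs (all-equal intensities,
constant coverage) raise errors rather than returning NaN. All stochastic
stages take explicit seeds and are bit-reproducible; derived per-sample
seeds keep streams independent of sibling samples.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script simulation sizes are package
choices balancing statistical resolution against desk-scale runtimes:
500 receptors at 2000 reads for Sort-Seq recovery, 200 null libraries of
500 receptors for Fisher calibration, 200 random proteins for scan
verification, 100 metagene simulations, and 20 train/test seeds (300
receptors each) for the classification benchmark.

# Known limitations

* The exact transcript/topological/structural descriptor itemizations of
  the original assay's supplement are not reproduced; the package ships
  its own fixed, documented schemas.
* Signal-peptide-aware HA placement requires external cleavage-site
  predictions; only the insertion mechanics are provided.
* The dG predictor transcribes the published biological-scale
  coefficients; segments shorter than ~15 or longer than ~30 residues are
  outside the scale's calibrated range.
* Path-dependent TreeSHAP conditions on the tree's own cover
  distribution, which differs from interventional SHAP when features are
  strongly correlated.
* UMI assignment to receptors is random, matching the assay's stated
  procedure; no balancing across receptor classes is attempted.
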