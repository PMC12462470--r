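# sskit

Super-silencer calling and regulatory-element analysis in R.

Silencers are DNA elements that repress transcription and are marked by
H3K27me3; enhancers activate transcription and are marked by H3K27ac. Just
as clusters of enhancers with exceptionally high aggregate H3K27ac form
**super-enhancers (SEs)**, clusters of silencers with exceptionally high
aggregate H3K27me3 form **super-silencers (SSs)**. `sskit` implements the
computational side of an SS study end to end for people working in
regulatory genomics and cancer epigenomics:

* **SS/SE calling** — elements within a stitching gap (default 12,500 bp)
  are merged into candidate regions, each region's mark signal is summed
  over its constituents, regions are rank-ordered, and the rank curve
  scaled to the unit square is cut at the rank maximising
  `x_scaled − y_scaled` (the discrete analogue of the classical slope-1
  tangent). Regions above the cutoff total are super; their member
  elements are *components*, all others are *typical* silencers/enhancers
  (TS/TE).
* **Cooperativity** — component activity across cell types is coded
  ternary per cell type *k* (H3K27ac peak only → `a_ik = 1`, H3K27me3 only
  → `−1`, both or neither → `0`) and pairs are scored with cosine
  similarity `Σ_k a_ik a_jk / (√Σ a_ik² √Σ a_jk²)`; TF-binding similarity
  uses the Jaccard index over a binary element × TF matrix. Within-region
  pairs are compared to distance-matched and random backgrounds
  (one-sided Wilcoxon rank-sum, no adjustment).
* **Annotation** — CpG-island status (overlap strictly > 200 bp), TAD
  geometry (boundary ≤ 20 kb, shore 20–50 kb, center beyond; counterpart
  shores across a boundary), nearest genes by TSS distance, genes
  contacted through chromatin loops, tissue specificity
  `tau = Σ(1 − x_i/max x)/(N−1)`, and mean CpG methylation.
* **Variant enrichment** — SNV density per kb over merged element sets,
  fraction-based enrichment with exact two-sided binomial tests, GWAS SNP
  expansion through strong LD (r² > 0.8, single pass), replicated-SNP and
  recurrent-SNV fractions, translocation-breakpoint fractions and partner
  classification.
* **SS-to-SE conversion** — normal-cell components overlapping cancer
  per-sample SE regions, recurrence in strictly more than half of the
  samples, and chromatin-contact retention between conditions with a
  permutation expectation.
* **Synthetic data** — `simulate_ss_dataset()` builds a complete,
  seed-deterministic dataset (elements with a log-normal signal body and
  planted heavy-tail clusters, correlated ternary activity, TFBS, CGIs,
  methylation, TADs, genes with expression, contacts, variants with
  planted enrichment folds, per-sample cancer SE sets with planted
  conversion recurrence) plus a ground-truth manifest, so the whole
  pipeline is testable without downloads.

## Worked example

```r
library(sskit)

bundle <- simulate_ss_dataset(seed = 1)
sil <- bundle$elements[bundle$elements$element_class == "silencer", ]
fit <- call_super_regions(sil, mark = "H3K27me3", gap_bp = 12500)
fit
#> Super-region call (mark: H3K27me3 , gap: 12500 bp)
#>   regions:   539 (43 super)
#>   elements:  1000 (253 components, 747 typical)
#>   cutoff total signal: 15.2
```

539 stitched regions were ranked by total H3K27me3; the elbow cutoff
leaves 43 regions (those with total signal above 15.2) as super-silencers
whose 253 member silencers are the SS components. `plot(fit)` draws the
hockey-stick rank curve with the cutoff. Running every downstream stage:

```r
res <- run_ss_pipeline(bundle, seed = 1)
res
#> Super-silencer pipeline report (seed 1)
#>   SS: 539 regions (43 super), 253 components
#>   SE: 571 regions (33 super), 211 components
#>   cooperativity median within 0.333 vs matched 0.000 (p = 4.8e-83)
#>   B-cell SNV fold in SS components vs genome: 2.85
#>   SS-to-SE: 12.3% converted, 25.8% recurrent over half
#>   contact retention 0.110 (expected by chance 0.119)
```

SS components show synchronized activity (median pairwise cosine 0.33
against 0 in the distance-matched background), carry the planted ~3-fold
B-cell cancer SNV enrichment, and 12.3% of them convert into cancer-sample
SE regions, a quarter of those recurrently in more than half of the
samples — matching the generator's ground-truth manifest
(`plant_report(bundle$manifest, res)` tabulates planted vs recovered).
Real inputs are loaded with `read_bed()`, `read_bedpe()`,
`read_variants()` and friends and fed to the same functions.

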