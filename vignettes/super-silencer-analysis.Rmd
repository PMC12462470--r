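---
title: "Super-silencer calling and analysis: models, parameters and design"
author: "sskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-silencer calling and analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sskit)
```

## The problem

Silencers — DNA elements that repress transcription, marked by H3K27me3 —
cluster in the genome the way enhancers do. Ranking stitched clusters by
aggregate H3K27me3 signal separates a small set of *super-silencers* (SSs)
with exceptional signal from the bulk of *typical silencers* (TSs),
exactly as rank-ordering aggregate H3K27ac separates super-enhancers (SEs)
from typical enhancers (TEs). `sskit` implements that caller and the
analyses used to characterise the called regions: cooperative activity of
SS components, CpG-island and TAD-geometry context, linkage to genes and
their expression, enrichment of disease variants, and the conversion of
normal-cell SS components into cancer SE regions across patient samples.

This vignette explains the models and procedures, every tunable parameter
that matters, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The caller

`call_super_regions()` performs three steps.

**Stitching.** Elements on a chromosome whose end-to-start distance is at
most `gap_bp` are merged transitively; each element belongs to exactly one
stitched region. The default gap is 12,500 bp, the classical convention
for super-enhancer detection; it is an argument everywhere.

**Aggregation.** A region's total signal is the sum of its constituents'
per-element mark signal (column `H3K27me3` or `H3K27ac`). No background is
subtracted by default; if a per-element background column is named, it is
subtracted per element and floored at zero. Missing marks are an error
naming the offending element — silent zeros would bias totals downward.

**Elbow cutoff.** Totals are sorted ascending; ranks and totals are
linearly mapped to $[0,1]$. The cutoff is the rank maximising
$x_{\text{scaled}} - y_{\text{scaled}}$, i.e. the point of the curve
farthest below the diagonal. This is the discrete equivalent of sliding a
slope-1 tangent along a convex ascending curve. Regions with total
*strictly greater* than the total at the cutoff rank are super — the
cutoff region itself is typical. Two deliberate tie-breaks make the rule
deterministic and oracle-checkable: ties in the gap go to the *higher*
rank (fewer supers), and the strict inequality keeps the boundary region
out. A degenerate curve (all totals equal, or fewer than three regions)
yields no supers rather than an arbitrary cutoff.

The same function with `mark = "H3K27ac"` on enhancers yields SE calls;
nothing in the algorithm is silencer-specific. TSS-proximal exclusion (an
option in classical SE callers) is not applied; element calls are taken as
given.

## Cooperativity

Activity of an element in cell type $k$ is coded ternary from that cell
type's peak sets: overlap (≥ 1 bp) with H3K27ac only is $+1$, with
H3K27me3 only is $-1$, with both is $0$ (uncertain). Elements overlapping
*neither* mark are also coded $0$: absence of evidence should not
contribute sign to a similarity. Pairs are scored with the cosine

$$\mathrm{coop}_{ij} = \frac{\sum_k a_{ik} a_{jk}}
  {\sqrt{\sum_k a_{ik}^2}\,\sqrt{\sum_k a_{jk}^2}},$$

undefined for an all-zero vector; such pairs are excluded and counted in
the returned diagnostics. TF-binding similarity is the Jaccard index over
a binary element × TF occupancy matrix, with the both-empty case defined
as 0.

Within-region component pairs are compared against two backgrounds drawn
from the typical elements: *random* pairs, and *distance-matched* pairs
whose midpoint-distance histogram (bin width 10 kb by default) follows the
within-region pair distances. Matching enumerates every same-chromosome
candidate pair up to the largest occupied target bin by a sliding window
over the position-sorted pool — random pair sampling would almost never
produce the short distances that dominate within-region pairs. Demand per
bin is proportional to the target histogram; within a bin, sampled target
distances are matched to the nearest unused candidate, so the within-bin
shape also follows the target; demand falling in bins with no candidates
is redistributed with a warning. Sampling is without replacement and
deterministic given `seed`. Group separation is tested with one-sided
Wilcoxon rank-sum tests, unadjusted, matching the conventions of the
analyses this package implements.

## Annotation

* **CGI status**: an element is `CGI` when its largest single-CGI overlap
  strictly exceeds 200 bp.
* **TAD geometry**: boundaries are the TAD interval endpoints (a shared
  endpoint of adjacent TADs counts once). The element *midpoint* is
  compared to the nearest boundary: ≤ 20 kb is `boundary`, 20–50 kb is
  `shore`, beyond is `center`. The midpoint convention is configurable in
  spirit but fixed here for determinism; half-open band edges
  ((20 kb, 50 kb]) keep the three labels a partition. The *counterpart
  shore* of a boundary is the 20–50 kb band on the opposite side,
  truncated (with a warning) at the chromosome start.
* **Gene linkage**: nearest gene by |TSS − element midpoint|, ties broken
  to the lexicographically smaller gene id (and logged); contact-based
  linkage connects an element to genes whose promoter (±2 kb around the
  TSS — the window is an argument, since no standard width exists)
  overlaps one anchor of a contact whose other anchor overlaps the
  element.
* **Tissue specificity**: $\tau = \sum_i (1 - x_i/\max x)/(N-1)$, 0 for
  uniform and 1 for single-tissue expression; undefined on all-zero
  profiles. $\tau$ is scale-invariant, so expression units do not matter.
* **Methylation**: the arithmetic mean of CpG beta values inside the
  element; elements without sites get `NA` rather than an imputed value.

## Variant enrichment

Densities are counted over *merged* element sets (variants per kb of
union length), so overlapping elements never double-count bases; a
consequence tested as an invariant is that splitting an element into
adjacent pieces leaves the density unchanged. Fraction-based enrichment
(e.g. the share of B-cell-cancer SNVs among all cancer SNVs inside a set)
is compared to a reference share as a fold, with an exact two-sided
binomial test; no multiple-testing adjustment is applied anywhere, by
design. GWAS seed SNPs are expanded through strong LD ($r^2 > 0.8$,
strict) in a *single* pass — partners of seeds only, no transitive
closure, because chaining LD blocks inflates the set with SNPs only
weakly linked to any seed. Replicated SNPs are those reported by ≥ 2
distinct studies; recurrent SNVs those seen in ≥ 2 distinct samples.
Translocation breakpoints count by breakpoint position (a translocation
with both ends in a set counts twice); partner breakpoints are classified
against region groups with the fixed precedence super before typical,
silencer before enhancer, ties logged.

## Conversion and contact retention

An element *converts* when it overlaps a cancer sample's super-element
region by ≥ `min_bp` (default 1 bp; full containment is available by
flag) in at least one sample. Recurrence over samples uses a strict
majority: converted in *more than* half of the samples (3 of 6 does not
qualify). Contact retention re-bins both conditions' contact anchors to a
common bin size (default 10 kb, the resolution of the contact maps this
mirrors) and demands both anchor bins identical — resolution-limited data
make fuzzy matching arbitrary. The by-chance expectation shuffles the
element labels over a matched pool with a seeded permutation test.

## The synthetic generator

`simulate_ss_dataset()` builds every input the pipeline consumes on a
three-chromosome, 10 Mb-per-chromosome genome — large enough for TAD and
shore geometry, small enough that a full bundle generates in about two
seconds. All randomness flows through one seeded generator; the same
(config, seed) reproduces the bundle bit-identically, and the manifest
records every planted parameter.

What is planted, and why these defaults:

* **Elements**: 1,000 silencers and 1,000 enhancers, background lengths
  0.8–2.5 kb (matching the ~1.5 kb average of real element calls). Forty
  silencer clusters (and thirty enhancer clusters) of 5–8 elements are
  placed with internal gaps below the stitching gap and a 13 kb isolation
  margin so each planted cluster stitches into exactly one region and
  never absorbs background elements — the margin is what makes the
  manifest's component list exact ground truth.
* **Signal**: a log-normal body (meanlog 1, sdlog 0.5) with cluster
  elements drawn from a Pareto tail (shape 1.5, scale 15) *truncated at
  10× scale*. Truncation keeps the tail heavy but bounded, as real
  ChIP-seq intensities are: an unbounded draw occasionally produces one
  region so extreme that the unit-square scaling compresses every other
  cluster toward the diagonal and the elbow lands above them.
* **Activity**: each cluster has a latent ternary program over 20 cell
  types; components copy it with each entry sign-flipped independently
  with probability $(1-\rho)/2$ (default $\rho = 0.6$), typical elements
  draw independent vectors from the same marginal. At $\rho = 0$ the two
  groups are exchangeable, which is the null the calibration tests use.
* **Variants**: background B-cell-cancer SNVs are uniform at a genome
  rate of about 2,000 over 30 Mb; components receive extra SNVs at the
  rate that makes the *density in components over the whole-genome
  density* equal the planted fold (default 3.0) — the planting corrects
  for the components' own contribution to the genome-wide rate, so the
  manifest fold is what the pipeline should recover.
* **Conversions**: exactly `round(0.13 · n_components)` planted SS
  components appear in per-sample cancer SE sets (10 samples), and
  exactly a quarter of those in more than half of the samples; decoy SE
  regions are rejected against every element so accidental overlaps never
  blur the planted counts. The planted counts are rounded, not Bernoulli
  draws, so the manifest is the truth rather than one noisy realisation
  of it.
* **Everything else** — CGIs with class-dependent overlap probabilities,
  class-ordered methylation betas, TADs tiling each chromosome at
  0.4–1.2 Mb, genes with repressed/stem-like profiles near SS clusters
  (low expression in the reference cell type, high $\tau$),
  distance-decaying contacts with planted retention, GWAS SNPs with
  study multiplicity, an LD table, and translocation breakpoints with
  SE-biased partners.

What the generator does **not** emulate: real chromosome lengths and
karyotype, empirical Hi-C distance-decay beyond a single exponential,
sequence content (no FASTA anywhere), replication timing or mutational
signatures behind variant placement, and correlated peak boundaries
(peaks coincide with element intervals exactly, which is what makes the
ternary activity matrix exactly recoverable). Passing tests on this
bundle therefore demonstrate that the *pipeline recovers planted
structure through the full file round-trip*, not that the statistical
model of any real dataset is correct.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally (BED native);
  1-based input is converted at the reader behind an explicit flag, and
  chromosome names are normalised to the `chr` prefix.
* Cosine scores are clamped to $[-1, 1]$ against floating-point drift.
* Degenerate rank curves (< 3 regions or all-equal totals) yield no
  supers; all-zero activity vectors, empty variant sets after filtering,
  elements without CpG sites, and chromosomes without TADs or genes all
  return flagged `NA`s or errors rather than silently fabricated values.
* Element identity is by id when present, else by exact coordinates;
  strand is ignored for elements and variants throughout.

## Problem sizes

The shipped tests run the caller-oracle comparison on 1,000 random
instances of up to 1,000 regions, the similarity algebra on 10,000 random
vector pairs, background-matching fidelity and planted-parameter recovery
on 20 seeds of the default bundle, and null calibration (unit folds,
$\rho = 0$) on 20 more; these sizes give the binomial pass counts the
calibration properties call for while keeping a full suite run in a few
minutes on one core.

## Known limitations

* The elbow rule always cuts *somewhere* on a non-degenerate curve: on a
  signal distribution with no genuine heavy tail it will still call the
  upper continuum super. Interpreting SS calls therefore requires the
  rank plot (`plot(fit)`); a clean hockey-stick is evidence, a smooth arc
  is not.
* Distance matching needs a pool dense enough to offer candidate pairs in
  every occupied distance bin; with sparse pools the sampler warns and
  redistributes, and the matched background degrades toward the random
  one.
* Contact retention's exact-bin identity is conservative: contacts that
  shift by one bin between conditions count as lost.
* LD expansion takes the pair table as given; it does not compute LD from
  genotypes, and SNPs absent from the table are never added.
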