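---
title: "Methods: molecular networking and information-theoretic lipidome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular networking and information-theoretic lipidome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lipidnet` analyzes untargeted LC-MS/MS lipidomes of host–symbiont archaeal
cultures. This vignette is the package's account of its methods: the models
and conventions each stage implements, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the design decisions taken where more than one
reasonable choice existed.

## Data model

A study consists of (i) a collection of MS² spectra, one per ion component
("feature"), held as a tibble with a `peaks` list-column; (ii) a
features-by-samples table of peak-area responses with per-sample metadata
(group, timepoint, replicate) and per-feature metadata (precursor *m/z*,
adduct form, retention time); and (iii) derived objects — a molecular
network, annotations, a composition profile, index tables. Peak areas are
*responses*, not concentrations: without authentic standards for every
uncharacterized lipid, only relative comparisons between samples are
meaningful, which is why every downstream statistic works on per-sample
proportions.

## Modified-cosine spectral similarity

Two fragment peaks may match directly (|Δ*m/z*| ≤ tolerance) or shifted by
the difference of the two precursor masses — the modification-tolerant rule
that lets structural analogs (e.g. homologs differing by one head group or
one saturation) align their shared backbone fragments. Matches are chosen
greedily in order of decreasing intensity product, each peak participating
at most once, and the score is the matched product sum normalized by the
product of the spectra's Euclidean intensity norms, so identical spectra
score exactly 1. Greedy selection follows the convention of the widely used
networking platforms; on small spectra the package's test suite verifies it
against an exhaustive maximum-weight one-to-one matching oracle, and in the
fixtures used the two agree to 1e-9.

Choices:

- **Fragment tolerance** `fragment_tol = 0.01` Th — appropriate for
  Orbitrap-resolution MS²; configurable.
- **Raw intensities** by default; `sqrt_intensity = TRUE` enables
  square-root weighting for users whose upstream platform applied it.
- **Ties** (equal products) break by ascending peak index; all matching is
  therefore deterministic.

## Network topology

Candidate edges are all spectrum pairs with |precursor Δ| ≤ `max_delta`
(default 500 Th), cosine ≥ `cosine_min` (default 0.5), and at least
`min_matched` = 5 matched fragment ions. An edge survives only if each
endpoint ranks the other within its `top_k` = 10 best candidates ("mutual
top-K"). Components larger than `max_component` = 100 nodes are then broken
by repeatedly removing the lowest-cosine edge inside each oversized
component until the cap holds. Whether the mutual-top-K filter runs before
or after thresholding does not change the final edge set, since both
filters are intersective; the package thresholds first. Ranking and removal
ties break by ascending feature id, making topology reproducible. Node
attributes carry each feature's mean relative abundance; exports are
GraphML and TSV edge lists.

## Lipid-class annotation

Annotation is an ordered rule list — data, not code (editable tibble,
JSON round-trip). A rule requires a set of fragment ions within tolerance
and optionally a precursor window; the first satisfied rule assigns the
class. The shipped defaults encode the diagnostic structure of
haloarchaeal ether lipids:

- the archaeol core ion (*m/z* 653.681, C43H89O3⁺) and lysoAR glycerol ion
  (*m/z* 373.368, C23H49O3⁺) anchor every AR-based glycerolipid;
- head-group marker ions distinguish PG, PGS, PA, PGP-Me, PGPG, CL, 1G,
  2G, and sulfur-containing classes, each tied to its class exemplar mass
  (e.g. PG-AR 807.684, PGP-Me-AR 901.666, CL-AR-AR 1522.313);
- menaquinones are recognized by their naphthoquinone-derived marker, and
  the MK(n:m) side-chain series (n isoprenoid units, m double bonds) is
  inferred from the precursor over the mass grid
  MK(n:m) = MK(8:8) + (n−8)·68.0626 + (n−m)·2.01565 Da;
- spectra showing only a core ion keep the affiliation (core = AR) with
  class `"unknown"` — mirroring how structurally unresolved lipids still
  enter the statistical analysis when subnetwork evidence ties them to a
  class.

Most-specific rules come first; permuting rules with non-overlapping
requirements cannot change assignments. The default rule set covers the
classes the generator plants; completing it for a real study's full
annotation table is user data, not code.

## Composition

The processing order mirrors standard practice: recovery correction →
adduct merging → closure.

- **Recovery correction** divides every sample by its internal-standard
  peak area and removes the standard's row; a zero or missing standard in
  any sample is an error naming that sample.
- **Adduct merging**: an [M+H]⁺ and an [M+NH₄]⁺ feature whose precursors
  differ by 17.02655 Th (monoisotopic NH₃) within `mz_tol` and which
  co-elute within `rt_tol` (default 30 s) are one ion component; their
  abundances are summed and the M+H id kept. Many-to-many candidates
  resolve greedily by smallest mass error, then smallest Δrt; a merge
  report is attached. Features labelled `unknown` never merge. Merging
  conserves per-sample totals exactly.
- **Relative abundance** closes each sample column to proportions;
  all-zero samples stay zero with a warning.
- **Presence** of a lipid in a condition group is called on the
  replicate-mean relative abundance at threshold 1e-4 (0.01% of total
  lipids); a value exactly at threshold counts as present, since absence
  is defined as *less than* the threshold. The aggregation over
  replicates is configurable (`replicate_mean`, the default, or
  `any_replicate`) because per-condition presence bars can be built from
  replicates either way; both modes are provided and tested.
- **UpSet counts** tally features by exact group-membership pattern;
  patterns partition the features present in at least one group.

## Information-theory indices

With $P_{ij}$ the relative frequency of lipid $i$ in sample $j$ (columns
sum to 1) and $P_i = \frac{1}{t}\sum_j P_{ij}$:

- diversity $H_j = -\sum_i P_{ij} \log_2 P_{ij}$ — 0 for a single-lipid
  sample, $\log_2 m$ for a uniform one;
- specificity $S_i = \frac{1}{t}\sum_j \frac{P_{ij}}{P_i}\log_2
  \frac{P_{ij}}{P_i}$ — 0 for a lipid with identical frequency everywhere,
  $\log_2 t$ for a lipid private to one sample; the per-sample summand
  $S_{ij}$ is exposed un-averaged;
- specialization $\delta_j = \sum_i P_{ij} S_i$, a convex combination of
  specificities, bounded by $[\min_i S_i, \max_i S_i]$ and globally by
  $[0, \log_2 t]$.

Conventions: base-2 logarithms throughout (results in bits);
$0\log 0 := 0$ by continuity; lipids absent in every sample are dropped
with a warning before $S_i$ (whose definition requires $P_i > 0$). The
lipid universe is configurable: `"annotated"` (features with an assigned
class, plus unknowns with a core-lipid affiliation) or `"all"` features;
no single choice is claimed to reproduce any particular published figure,
which is why both are exposed. Group summaries report mean ± sd across
replicates (sd is `NA`, not 0, for single-replicate groups), with an
optional seeded bootstrap over replicates.

## Multivariate and univariate statistics

- **Hellinger transform**: each sample row divided by its total, then
  square-rooted, so Euclidean distance between transformed rows equals
  Hellinger distance — the standard pre-treatment for zero-inflated
  composition data ahead of PCA.
- **PCA**: column-mean-centered, no variance scaling (Hellinger already
  equalizes scale), via `stats::prcomp`. Sign convention: each
  component's largest-magnitude loading is forced positive, so score
  plots are reproducible. A zero-variance input is flagged explicitly
  rather than producing NaN ratios.
- **Z-score clustering** of class-by-sample shares: per-class
  standardization with the sample (n−1) standard deviation (the heatmap
  convention of common tools); zero-variance classes get Z = 0 with a
  warning; rows and columns are ordered by agglomerative clustering
  (Euclidean distance, average linkage — the paperless defaults, both
  configurable). Clipping to ±3 SD happens only in the display method,
  never before clustering.
- **Tukey HSD + CLD**: one-way layout via the studentized range
  (`stats::aov` + `stats::TukeyHSD`), letters by insert-and-absorb so
  groups sharing no letter differ at `alpha` = 0.05 and groups sharing a
  letter do not. A directional ("one-sided") variant is exposed as a flag
  that halves the two-sided studentized-range p-value when the observed
  difference has the tested sign; since a one-sided HSD is non-standard
  and direction conventions vary, the two-sided test is the default.

## The synthetic-data generator

`simulation_design()` defines the study the tests and the acceptance
script run:

- **Shape**: host and co-culture sampled at 0/6/12/24/48 h with 3
  replicates each, symbiont with 2 replicates — 32 samples; 246 lipid
  species over 14 classes (8 AR, 13 PGS, 25 PG, 3 PA, 22 PGP-Me, 11 PGPG,
  41 CL, 3 S, 2 1G, 2 2G, 39 MK, 15 bacterioruberin, 1 squalene, 61
  unknowns).
- **Presence plan**: 86 species common to all groups, 20 private to
  host + co-culture, 55 host-only, 48 co-culture-only, 16
  symbiont + co-culture, 4 host + symbiont, 4 symbiont-only (richness
  110 symbiont / 165 host / 170 co-culture), plus 13 rare species planted
  at 2e-5 relative abundance — below the 0.01% presence threshold
  everywhere — to exercise the boundary. One species per class anchors
  the all-groups pattern so every class share is realizable in every
  group; remaining species consume the pattern budget in depth order,
  which places group-private species at lower planted abundance and
  thereby plants a specialization gradient (host > co-culture in δ, the
  symbiont set apart by its few but heavily weighted private lipids).
- **Class shares**: planted per group, anchored at the study-typical
  values — the symbiont's dominant phospholipid PGP-Me at 44% of total
  lipids versus 17% (host) and 25% (co-culture); bacterioruberins nearly
  absent from the symbiont (0.2%) but present in host (2%) and co-culture
  (3.5%); the residual share goes to the unknowns. Within a class-group,
  species shares decay as 1/√depth with a floor of 2e-4 so planted-present
  species always clear the presence threshold.
- **Noise**: log-normal replicate noise (sdlog 0.25 — a realistic
  peak-area CV of ~25%), log-normal per-sample recovery variation
  (sdlog 0.15) carried identically by the internal-standard row, fragment
  *m/z* jitter (sd 0.002 Th), and spurious peaks (0.1 per spectrum,
  resampled away from any diagnostic mass so noise never fakes an
  annotation). A lipid ionizes as both adduct forms with probability 0.6,
  the M+H ion carrying 65% of its signal. `zero_noise()` switches every
  noise source off.
- **Spectra**: each class template emits the class's diagnostic ions plus
  a class-specific neutral-loss series; one fragment's intensity varies
  with the species' depth in its class so that spectral similarity decays
  smoothly with structural distance — giving the within-class
  nearest-neighbor topology real networks show, while classes share too
  few fragments (at most the two AR core ions) to be linked at the
  5-matched-ion rule. Unknown-class lipids get private random fragment
  sets and become network singletons, emulating the uncharacterized
  fraction of a real lipidome.
- **Determinism**: a single integer seed drives isolated random streams
  (one for abundances, one for spectra); the same design is
  bit-reproducible and never perturbs the caller's RNG state.

All randomness-free ground truth (planted per-lipid shares, presence
patterns, class shares, and noise-free per-group H and δ computed by naive
loops independent of the vectorized implementation) is returned alongside
the data.

What the generator does **not** emulate: isotope envelopes, chromatographic
peak shape, intensity-dependent mass error, ionization suppression,
gap-filling artifacts, retention-time drift, and within-class fragmentation
diversity beyond the planted intensity gradient. Passing the recovery tests
therefore demonstrates correctness of the pipeline's algorithms under the
planted statistical structure, not robustness to every artifact of real
instrument data.

## Problem sizes and numerical conventions

The test suite runs the full design (246 lipids × 32 samples, ~390
features with adduct twins) for ground-truth recovery and a reduced
24-lipid design for per-stage unit tests; oracle comparisons use 100 random
20 × 6 frequency matrices (agreement to 1e-12), 50 spectrum pairs with ≤ 8
peaks against exhaustive matching (1e-9), and a 120-node
oversized-component fixture for topology rules. Relative-abundance columns
close to 1 within 1e-9; all m/z arithmetic is double precision with no
internal rounding; every tie-break (peak matching, edge ranking, capping,
adduct pairing, letter assignment) is deterministic.

## Known limitations

- Annotation is class-level and rule-based: positional isomers,
  double-bond positions, and novel head groups are out of reach by
  design; unknowns are first-class citizens instead.
- The greedy peak matching can in principle fall below the exact
  maximum-weight matching when one peak has several near-equal partners
  within tolerance; at 0.01 Th this did not occur in any tested fixture.
- Component capping is a greedy policy (weakest edge first); it matches
  the documented behavior of the reference networking platform but is not
  a globally minimal edge-removal set.
- The information-theoretic indices weight samples equally; unbalanced
  designs (here: 2 symbiont vs 15 host samples) therefore weight groups
  unevenly in $P_i$, which is faithful to the published formulation but
  worth remembering when comparing δ across groups of unequal size.
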