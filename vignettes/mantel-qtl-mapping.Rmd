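---
title: "Distance-based multi-locus QTL mapping with MantelQTL"
author: "MantelQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based multi-locus QTL mapping with MantelQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MantelQTL)
```

## The method

Complex behavioral and cognitive traits are controlled by many loci of
small-to-moderate effect, and which loci matter can shift with the
environment. MantelQTL implements a multivariate distance-based mapping
strategy suited to this regime. Instead of regressing one trait on one
marker, it represents both genotypes and phenotypes as pairwise sample
dissimilarities:

* **Genotype distance.** For a marker set $M$, the Manhattan dosage
  distance $d_G(i,j) = \sum_{m \in M} |g_i(m) - g_j(m)|$, where $g$ is the
  minor-allele dosage (0/1/2). Every marker gets equal weight; an
  identity-by-state mismatch count is available as an alternative metric.
  Manhattan distances are additive over markers, which the forward
  selection exploits.
* **Phenotype distance.** Related measures are grouped into composite
  categories (six by default, patterned on fear-conditioning studies:
  contextual/cued percent freezing, motion during training, shocks and the
  contextual test). Each category's measures form a vector per sample and
  the Manhattan distance is taken over it. Measures are standardised first
  by default: "equal weight per phenotype" is only meaningful on a common
  scale. A raw mode exists for same-unit categories.
* **Mantel correlation.** The association between a marker set and a
  category is the Pearson correlation over the $N(N-1)/2$ off-diagonal
  entries of the two distance matrices. Significance comes from joint
  row/column permutations of the phenotype matrix with the add-one
  estimator $p = (b+1)/(B+1)$, one-sided for positive correlation (genetic
  similarity predicting phenotypic similarity).

Marker sets are then built greedily: markers are ranked by single-marker
Mantel correlation, and the cumulative correlation $c_k$ of the first $k$
markers is tracked as $k$ grows. The typical curve rises, reaches a
plateau, and declines as uninformative markers dilute the set. Two guards
limit the obvious overfitting risk of this selection:

1. **Per-marker gate.** Only markers individually significant at
   $p < 0.01$ may enter the selection.
2. **Procedure-level empirical null.** The phenotype sample labels are
   shuffled $R$ times and the *entire* procedure (re-scan, re-gate,
   re-select) is repeated per shuffle. The observed $c_k$ is converted to
   $Z_k = (c_k - \mu_k)/\sigma_k$ against the per-$k$ null mean and
   standard deviation ($R-1$ divisor). Shuffled curves of differing
   lengths are right-padded by carrying their last value; a shuffle with
   no gate-passing markers contributes a flat zero curve. Re-running the
   whole procedure is essential: gating null shuffles on the fixed
   observed ranking would understate what selection alone can achieve.

The selected set is the earliest entry into the plateau: the smallest $k$
with $c_k \ge (1 - \texttt{plateauTol}) \max_k c_k$ (default tolerance
0.02; plateaus are otherwise a visual judgement).

Marker sets detected independently under two environmental strata
(cohorts, or sham versus irradiated arms) are compared by cross-tabulating
set membership over the shared post-MAF-filter marker universe: a Fisher
exact test provides the p-value, and the cross-product odds ratio with a
Haldane-Anscombe correction and Woolf confidence interval carries the
directional claim (concordant architectures give CI lower bounds above 1;
shifted architectures give odds ratios at or below 1). Genes within 1 Mb
of markers detected in both strata seed a hypergeometric
overrepresentation test against GMT gene-set collections, BH-adjusted per
collection.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `mafThreshold` | 0.05 | markers kept only if MAF strictly above this |
| `pGate` | 0.01 | per-marker permutation gate (strict `<`) |
| `B` | 999 | scan permutations; the gate is only attainable when `1/(B+1) < pGate`, so `B >= 199` at the default gate |
| `R` | 25 | label shuffles for the empirical null (the spread of selection-biased null curves is estimated from these) |
| `plateauTol` | 0.02 | plateau entry tolerance on the cumulative curve |
| `windowBp` | 1e6 | gene window half-width, matching heterogeneous-stock mapping resolution |
| `standardize` | TRUE | centre/scale measures before the phenotype distance |
| `metric` | manhattan | genotype distance; `ibs` counts mismatches instead |

## The permutation scheme

A scan draws **one pool of `B` sample-label permutations shared by every
marker**. This turns the scan into a single dense cross-product between
the marker pair-distance vectors and the (observed plus permuted)
phenotype pair vectors, which is what makes whole-procedure null
calibration affordable. Sharing the pool does not bias any single
marker's p-value: under the null the samples are exchangeable, so for
each marker the $B+1$ statistics (observed plus permuted) are
exchangeable and the add-one p-value is marginally exact; for independent
markers the gate-passing indicators are, conditional on the pool,
independent with exactly the nominal probability. Ties between permuted
and observed statistics count as exceedances. Scan results are
independent of marker execution order by construction.

## The synthetic cohort generator

No raw data accompany the study design this package addresses, so the
generator stands in for it with known ground truth:

* **Founder panel.** Eight founder strains (as in an HS mouse colony)
  with binary alleles per marker. A target MAF is drawn per marker in
  `[mafLow, mafHigh]` and realised by assigning the minor allele to
  `round(target * nFounders)` founders, so achievable population
  frequencies under equal founder mixing are quantised in steps of 1/8.
  Marker positions use ~100 kb mean spacing over 10 chromosomes by
  default.
* **Mosaic genomes.** Each sample carries two founder mosaics per
  chromosome; the founder of origin follows a Markov chain along ordered
  markers with switch probability `1/meanBlockMarkers` (default 1/20),
  giving approximately geometric block lengths. This is far simpler than
  simulating 70 generations of circular breeding but preserves the block
  structure that matters for mapping. Because founder alleles are drawn
  independently per marker, linkage between neighbouring markers arises
  only through chance founder-carrier overlap — real HS populations have
  stronger, structured LD, so tagging of unobserved causal variants is
  weaker here than in real data.
* **Phenotypes.** For each sample, a condition-specific genetic score
  (dosage-weighted sum over that condition's causal markers, standardised
  within condition) is mixed with a shared per-category latent factor and
  independent noise:
  $x = \sqrt{h^2} z + \sqrt{1-h^2}(\sqrt{\rho} F + \sqrt{1-\rho}\,\epsilon)$.
  The latent share $\rho$ is solved so the realised within-category
  correlation matches the `withinCor` target (default 0.7, inside the
  0.5-0.9 band typical of related fear-conditioning measures);
  between-category correlations are approximately the (geometric-mean)
  heritability, below 0.6 at the defaults. Cohort mean offsets and
  variance multipliers are applied last and do not change correlations
  once measures are standardised — which is exactly why rank orderings of
  genetic correlations survive cohort shifts.
* **Causal loci.** `simulateStudy` plants `nCausal` loci per condition at
  *distinct, common* markers (panel MAF at least 0.25, separated by more
  than one mean block): a request for ten causal loci yields ten
  detectable loci, not fewer through same-block collisions or rare
  alleles. The fraction of loci shared between the two conditions is the
  `architectureOverlap` knob (1 = identical architectures, 0 = fully
  shifted), which is what lets condition-shift experiments dial the truth
  continuously.
* **Radiation arm.** The generator applies no mean shift between sham and
  irradiated arms by default: the emulated phenomenon is a change in
  *which* loci matter, not in mean performance. Cohort effects, by
  contrast, default to a +0.5 SD offset and 1.5x variance in the second
  cohort.

What passing tests on this generator do **not** show: robustness to real
LD structure, missing data patterns, non-normal measure distributions, or
population structure beyond the founder mosaic — none of which the
generator emulates.

## Numerical choices

* Distances are stored dense (N at desk scale is at most a few thousand).
* The cumulative curve is updated incrementally via Manhattan additivity
  and uses the same cross-product arithmetic as the scan, so $c_1$ equals
  the top marker's scan statistic to machine precision.
* Permutation exceedance comparisons use a $10^{-12}$ tolerance so exact
  ties (a drawn identity permutation) count as exceedances.
* Zero-variance (monomorphic) markers are dropped from scans with a
  message; a zero-variance measure under standardisation is dropped with
  a warning; a constant distance vector is an error (the statistic is
  undefined).
* Odds ratios apply the +0.5 correction only when a cell is zero; the
  Fisher p-value always comes from the exact hypergeometric distribution.
* Scan ranking ties break by p-value, then marker map order, so results
  are reproducible across executions.
* Master seeds derive per-stage child seeds through a Lehmer sequence,
  keeping every stage below 2^31 and bit-reproducible.

## Problem sizes

The package's own simulation studies (tests and the acceptance script)
run at what a single desk machine handles comfortably: hundreds of
samples, a few hundred to two thousand markers, B of 199-999 permutations
and R of 15-25 shuffles. The planted-architecture study uses n = 200,
2,000 markers, ten causal loci at total heritability 0.5, B = 199 and
R = 20; the condition-shift study uses n = 240 (two strata of 120),
200 markers and five loci per condition at heritability 0.6; the
cohort-ranking study uses n = 600 (two cohorts of 300, mirroring the
smaller of the two cohorts a real study of this design would run), 300
markers and per-category heritabilities spread from 0.05 to 0.8 — a wide
but deliberate spread, since distinguishing the rank order of six
categories requires their genetic components to differ by more than the
sampling noise of a peak correlation at this sample size.

## Known limitations

* At desk scale the procedure-level Z-scores discriminate planted signal
  from null data only weakly: with 2,000 markers and ten loci summing to
  heritability 0.5 on 200 samples, selection bias lets null curves reach
  cumulative correlations comparable to the observed one, and the peak Z
  typically lands between 1 and 3 rather than clearly above 3. For the
  same reason the per-marker gate (effective p = 0.005 at B = 199)
  catches only a minority of loci that each carry a twentieth of the
  trait variance: peak sets typically tag three to five of the ten
  planted loci. Both sharpen with the much larger sample sizes and
  marker panels (and correspondingly longer selection curves) of a real
  heterogeneous-stock study; the fully null arm, by contrast, stays
  quiet (max Z below 3) essentially always, so the screen's specificity
  holds at desk scale even where its sensitivity does not. The package
  reports these quantities faithfully rather than tuning the generator
  to force a separation.
* Greedy order is fixed by the initial scan; markers are not re-scored
  after each inclusion (adaptive greedy is out of scope, as is backward
  elimination).
* No allele-frequency or functional weighting of markers in the distance.
* Gene-set enrichment uses supplied GMT collections; no live annotation
  database queries, and term-level p-values therefore depend entirely on
  the collections given.
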