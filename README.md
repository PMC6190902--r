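# MantelQTL

Distance-based multi-locus QTL mapping for genetically heterogeneous
populations, built for the situation behavioral genetics actually faces:
complex traits controlled by many loci of small effect, measured as
batteries of correlated behavioral measures, under environmental
conditions (cohort stressors, ionizing radiation) that can change *which*
loci matter.

## Who this is for

Researchers mapping multi-locus genotype–phenotype association in outbred
or heterogeneous-stock rodent populations (or any diploid SNP-dosage
panel), who want set-level inference rather than single-marker GWAS
peaks, and who need to compare the *identity* of detected marker sets
across environments.

## The method

Both data modalities become N×N pairwise sample dissimilarities:

* genotype: Manhattan dosage distance over a marker set,
  `d(i,j) = Σ_m |g_i(m) − g_j(m)|` (equal marker weight; an
  identity-by-state mismatch count is available);
* phenotype: Manhattan distance over a composite category of standardized
  behavioral measures.

Their association is the **Mantel correlation** — Pearson's r over the
N(N−1)/2 off-diagonal pairs — with one-sided permutation p-values
`p = (b+1)/(B+1)`. Marker sets grow by **forward selection** in
decreasing order of single-marker correlation, tracking the cumulative
correlation `c_k`; the selected set is the earliest entry into the
plateau of the curve. Two guards limit overfitting: only markers with
individual `p < 0.01` may enter, and the **entire procedure is re-run on
R label-shuffled datasets**, converting the observed curve into Z-scores
`Z_k = (c_k − μ_k)/σ_k` against the selection-biased empirical null.
Marker sets detected independently in two strata are compared with a
**Fisher exact overlap test** (odds ratio, Haldane–Anscombe correction,
Woolf CI) over the shared post-MAF marker universe, and genes within 1 Mb
of markers found in both strata feed a hypergeometric gene-set
enrichment. A founder-mosaic simulator generates heterogeneous-stock-like
genotypes (8 founder strains, geometric-length mosaic blocks) and
correlated, condition-dependent phenotypes with known causal loci.

## Worked example

```r
library(MantelQTL)

study <- simulateStudy(nSamples = 200, nMarkers = 1000, nCausal = 5,
                       heritability = 0.5, seed = 42)
geno <- filterMarkersByMAF(study$genotypes)
res <- calibratedAnalysis(geno, study$phenotypes, "context_avgmot",
                          B = 199, R = 20, seed = 7)

head(res$scan, 3)
#>   marker chrom      bp         r     p rank
#> 1 m00986 chr10 8213704 0.1442311 0.005    1
#> 2 m00323  chr4 2484622 0.1345609 0.005    2
#> 3 m00892  chr9 9523201 0.1223297 0.005    3

res$curve
#> SelectionCurve: 11 set sizes, gate p < 0.01
#> peak: k* = 10, c = 0.2959 (plateau tol 0.02)

round(max(res$z$z[res$z$defined], na.rm = TRUE), 2)
#> [1] 2.04

study$truth$causal$sham
#> [1] "m00562" "m00892" "m00986" "m00033" "m00446"
```

Reading the output: eleven markers pass the individual `p < 0.01` gate;
the cumulative Mantel correlation peaks at 0.296 with a ten-marker set
whose top members (m00986, m00892) are two of the five planted causal
loci. The peak Z of 2.04 says the curve sits about two null standard
deviations above what label-shuffled data achieve through selection bias
alone at this desk-scale problem size — set-level evidence grows much
sharper as samples and marker panels grow.

To contrast environments, give each condition its own architecture and
compare detected sets:

```r
shift <- simulateStudy(nSamples = 240, nMarkers = 200, nCausal = 5,
                       heritability = 0.6, architectureOverlap = 0,
                       seed = 1)
compareConditions(shift$genotypes, shift$phenotypes, shift$conditions,
                  split = "condition", categories = "context_avgmot",
                  B = 199, seed = 2)
```

`architectureOverlap = 0` plants disjoint causal loci in the two arms,
and the odds-ratio confidence interval correspondingly fails to clear 1;
with `architectureOverlap = 1` the same pipeline yields odds ratios far
above 1. `runFullAnalysis()` chains scan, selection, calibration, overlap,
gene windows and enrichment behind a single validated config.

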