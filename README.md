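# phosphoCircuits

From two-condition (phospho)proteomes to sign-consistent causal models.

`phosphoCircuits` is an R package for systems-biology groups who run
mass-spectrometry screens of the kind "two cell contexts, with and without
a drug, in replicates" and want to go beyond lists of regulated features:
which kinases, phosphatases and transcription factors changed *activity*,
and through which causal chains do those changes reach a phenotype such as
DNA damage? The motivating setting is FLT3-ITD leukemia cells
(juxtamembrane- vs. tyrosine-kinase-domain insertions) treated with a
DNA-damaging chemotherapeutic, but nothing in the package is specific to
it.

## What it computes

**Differential layer.** Per-feature two-sample t-tests on log2
intensities (Student pooled-variance by default),

&nbsp;&nbsp;&nbsp;&nbsp;*t* = (x̄_T − x̄_C) / (s_p √(1/n_T + 1/n_C)),

with Benjamini–Hochberg FDR (significant at FDR < 0.1 by default),
class-I filtering of phosphosites (localization probability ≥ 0.75),
replicate-correlation QC, cross-context overlap ("common core") counts and
hierarchical clustering (1 − Pearson, average linkage, k = 4) of
modulated features.

**Activity layer.** Footprint scores per regulator R with signed regulon
targets,

&nbsp;&nbsp;&nbsp;&nbsp;score(R) = (1/n) Σᵢ sᵢ·tᵢ,

tested against a seeded permutation null (random target sets of the same
size drawn from the measured features), plus a regulatory-phosphosite
score per protein (mean of log2FC × annotated effect), merged with a
conservative drop-on-conflict policy.

**Network layer.** Over a signed prior-knowledge network (SIF-like input,
SIGNOR-style sign vocabulary accepted), simple directed paths of ≤ 4
edges from each activity-scored protein to a phenotype node are kept iff
the running edge-sign product matches the inferred sign at every scored
node on the path and equals the requested phenotype direction at its end.
The union of kept paths plus consistent subgraph edges is the
context-specific mechanistic model; restricting path sources to a gene
set gives functional circuits. Models export to TSV, SIF and GraphML.

**Characterization.** Hypergeometric over-representation analysis
(universe = measured features; enrichment score = −log10 adjusted p),
kinase-substrate set enrichment, relative-apoptosis normalization
100·(dead_T − dead_C)/viable_C and Bliss-independence excess
f_AB − (f_A + f_B − f_A·f_B).

**Synthetic benchmark.** A seeded generator (`simulateStudy()`) builds a
prior network, signed regulons, ground-truth regulator activities and
two-genotype (phospho)proteome matrices in which expected shifts follow
the additive signed model exactly — so every downstream stage is testable
with known truth and no downloads.

## Worked example

```r
library(phosphoCircuits)

ex  <- simulateStudy(nNodes = 60, nRegulators = 12, nActive = 4,
                     genotypes = "ITD-JMD", seed = 1)
dp  <- differentialStats(ex@proteome, genotype = "ITD-JMD")
dph <- differentialStats(ex@phospho,  genotype = "ITD-JMD")
act <- inferActivities(dp, dph, ex@regulons, ex@regSites,
                       nPerm = 1000, seed = 2)
fp  <- attr(act, "footprint")
fp[fp$fdr < 0.1 & !is.na(fp$fdr), ]
```

```
 protein       class     score sign     p_value         fdr n_evidence
   G0011      kinase -5.559870   -1 0.000999001 0.003996004          4
   G0019 phosphatase -7.322426   -1 0.000999001 0.003996004          5
   G0016          TF  7.895730    1 0.001998002 0.005994006          5
   G0024          TF 16.175210    1 0.000999001 0.003996004          5
```

All four calls at FDR < 0.1 are exactly the four planted regulators with
their true signs (`truthTable(ex@truth)`: G0011 −, G0016 +, G0019 −,
G0024 +). The score is in t-units: G0019's regulon moved about 7 pooled
standard errors in the direction its signs predict; p = 1/1001 is the
permutation-test floor at 1000 draws. Connecting the scored proteins to
the phenotype:

```r
m <- connectToPhenotype(buildNaiveNetwork(act, ex@network), ex@network)
m
```

```
MechanisticModel: 11 nodes, 11 edges, 5 causal paths
  phenotype: DNA_damage (direction +1), max path length 4
```

i.e. a compact sign-consistent subnetwork in which every retained node
reaches `DNA_damage` within four causal steps with the correct net sign.

See `vignettes/phosphoCircuits-methods.Rmd` for the model, its
assumptions, all tunables and the generator's scope.

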