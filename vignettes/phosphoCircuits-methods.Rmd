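---
title: "Methods: footprint activities and sign-consistent causal models"
author: "phosphoCircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprint activities and sign-consistent causal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoCircuits)
```

# Overview

`phosphoCircuits` implements the analysis chain that leads from a
two-condition (phospho)proteomic screen to mechanistic hypotheses about a
phenotype. The motivating setting is a pair of leukemia cell-line contexts
(FLT3-ITD insertions in the juxtamembrane vs. tyrosine-kinase domain)
treated with a DNA-damaging chemotherapeutic, but every stage is generic:

1. **Differential statistics** — per-feature two-sample tests on log2
   intensities with Benjamini–Hochberg FDR control.
2. **Activity inference** — footprint scores for kinases, phosphatases and
   transcription factors from the behaviour of their known targets, plus a
   regulatory-phosphosite score for individual proteins.
3. **Network contextualization** — sign-consistent causal paths from the
   activity-modulated proteins to a phenotype node (by default
   `DNA_damage`) over a signed prior-knowledge network, yielding a compact
   mechanistic model and, restricted to a gene set of interest, functional
   circuits.
4. **Characterization** — over-representation analysis, kinase-substrate
   set enrichment, and simple drug-combination arithmetic.

Because the real deposited dataset is not required at desk scale, the
package ships a first-class synthetic-data generator with known ground
truth; all statistical guarantees quoted below are the ones the test suite
actually computes on that generator.

# The data model

An `OmicsMatrix` is a `SummarizedExperiment` of log2 intensities with a
`kind` (`"proteome"` or `"phospho"`) and a sample design
(genotype × treatment × replicate). Phosphosites use the string dialect
`PROTEIN_T170` — host protein, residue letter (S/T/Y), 1-based position —
which round-trips losslessly through `parsePhosphosite()` /
`phosphositeString()`. Missing intensities are `NA`, never zero: a zero is
a (wildly implausible) log2 value and would silently corrupt means,
variances and correlations.

Phosphosites may carry a localization probability. Sites below the
class-I convention of 0.75 are removed before testing
(`classIThreshold`, configurable); sites with no annotated probability
are retained, treating absence of annotation as absence of evidence
against the site.

# Differential statistics

For each feature, treated-minus-control means of log2 intensities give the
log2 fold change, and a two-sample t-test gives the statistic:

$$ t = \frac{\bar{x}_T - \bar{x}_C}{s_p\sqrt{1/n_T + 1/n_C}},
   \qquad s_p^2 = \frac{(n_T-1)s_T^2 + (n_C-1)s_C^2}{n_T+n_C-2}. $$

The default flavour is the Student equal-variance test; Welch is a
configuration switch (`flavor = "welch"`). With triplicates per condition
there is little information to estimate unequal variances, and the pooled
test is the simplest defensible default; no variance moderation (limma/SAM
s0 style) is applied, and none is claimed.

Missing values are handled complete-case per feature per group with a
minimum of two complete values per group; excluded features are reported,
never silently dropped. Degenerate inputs are given explicit conventions:
a zero pooled variance with zero mean difference yields $t = 0$, $p = 1$;
a zero pooled variance with a non-zero difference yields a signed infinite
$t$ with $p = 0$. The infinite case cannot occur in data with noise; it
arises only in the generator's noise-free limit (below).

FDR control is Benjamini–Hochberg, with the significance flag at
FDR < 0.1 by default — the conventional cut for this kind of screen —
and FDR < 0.05 for enrichment results. Replicate QC reports pairwise
Pearson correlations (pairwise-complete; undefined below two shared
observations) and flags within-condition pairs under a floor of 0.75, the
low end of what a well-behaved label-free experiment shows.

Hierarchical clustering of modulated features z-scores each feature
profile, uses 1 − Pearson correlation as the distance and average linkage
(the common proteomics default; both configurable), cuts the tree into
`k = 4` clusters by default, and breaks all ordering ties lexicographically
by feature ID so the assignment is deterministic.

# Footprint activity inference

A regulator's regulon is its set of signed targets: phosphosites for
kinases and phosphatases, proteins for transcription factors. The stored
sign is the expected direction of the *target's change* when the regulator
is active. This convention deliberately carries any dephosphorylation
semantics inside the sign, so phosphatases need no hidden extra flip.

The footprint score is the mean sign-weighted t-statistic over the
regulator's measured targets,

$$ \mathrm{score}(R) = \frac{1}{n}\sum_{i \in \mathrm{targets}(R)} s_i\, t_i, $$

a linear statistic chosen over rank/GSEA-style alternatives because it is
analyzable (its null is oracle-checkable by exhaustive enumeration) and
directly interpretable in t-units. Significance comes from a permutation
null: the same statistic on `nPerm` random draws of $n$ measured features
(sampled without replacement), with

$$ p = \frac{1 + \#\{|\mathrm{null}| \ge |\mathrm{score}|\}}{nPerm + 1} $$

two-sided, and BH-FDR across regulators. `nPerm` defaults to 1000 and is
rejected below 100, where the null is too coarse to be useful. Regulators
with fewer than `minTargets = 3` measured targets are skipped and listed;
lowering the floor to 2 lets very small regulons (phosphatases are the
usual casualty) survive at the cost of noisier scores. Kinase and
phosphatase regulons are evaluated against the phospho-layer table, TF
regulons against the proteome layer.

The regulatory-site score complements the footprint: for a protein with
annotated regulatory phosphosites, the mean over measured (by default,
significant) sites of log2FC × effect (+1 activating, −1 inhibiting).
It carries direction and magnitude but no calibrated test, so its p-value
is reported as `NA`. The two streams merge conservatively: single-source
proteins pass through; sign agreement keeps the footprint score under
method `"combined"`; contradictory non-zero signs drop the protein into a
conflict report rather than letting either method win by fiat.

# Sign-consistent models

The prior network is a signed directed graph with phenotype nodes as
sinks. Model construction has two stages:

* `buildNaiveNetwork()` induces the subgraph on proteins with non-zero
  inferred sign and keeps an edge $(u, v, s)$ only when
  $\mathrm{sign}(u)\cdot s = \mathrm{sign}(v)$.
* `connectToPhenotype()` enumerates simple directed paths of at most
  `maxLen = 4` edges from every scored node to the phenotype through the
  full prior. A path is kept when the sign implied by the running
  edge-sign product matches the inferred sign at **every scored node it
  traverses** and equals the requested phenotype direction at its end;
  unscored intermediates are unconstrained.

The per-node consistency rule is deliberately stronger than checking the
end-to-end product alone: an end-to-end check would admit paths that pass
through a scored node with the wrong implied sign, and the resulting model
would contain edges contradicting the inferred activities it is meant to
explain. With the rule as implemented, every model satisfies a global
validator (`validateModel()`): all edges between scored nodes are
consistent, every non-phenotype node lies on at least one kept path, and
every kept path is simple, bounded, sign-consistent and direction-correct.
Self-loops are ignored in path search (they only manufacture trivial
sign-flipping cycles), and where the literature provides both an
activating and an inhibiting edge for the same pair, the two are kept as
parallel candidates and each path commits to one.

`maxLen = 4` reflects that interpretable causal chains in such models are
shallow and keeps enumeration bounded at desk scale; the kept-node set
grows monotonically with `maxLen`. Circuits (`extractCircuit()`) restrict
a model to the paths whose source lies in a chosen gene set, plus the
model edges among retained nodes — so a circuit over all sources equals
the model, and every circuit inherits validity.

# Enrichment and phenotype arithmetic

Over-representation uses the one-sided hypergeometric upper tail with the
**measured** features as universe — the only defensible background when
the instrument, not the genome, decides what could have been seen. The
enrichment score is defined as $-\log_{10}(\text{adjusted } p)$, so a
score above 3 corresponds to an adjusted p below $10^{-3}$; results also
carry the adjusted-p < 0.05 flag. Kinase-substrate enrichment applies the
same test with query = significant sites moving in the requested
direction and one set per regulator.

Two closed-form assay metrics are included: relative treatment-induced
apoptosis, $100\,(d_T - d_C)/v_C$, and the Bliss-independence excess
$f_{AB} - (f_A + f_B - f_A f_B)$, positive under synergy and ≈ 0 under
additivity. Both are exact arithmetic and tested as such.

# The synthetic-data generator

The generator emulates the motivating study design: two genotype contexts,
control vs. treated, three replicates each.

* **Network**: `nNodes − 1` signaling nodes plus one phenotype sink; each
  ordered pair is an edge with probability `meanOutDegree/(nNodes−1)`
  (Binomial out-degrees), inhibitory with probability 0.3. Node classes
  default to kinase 0.35 / phosphatase 0.05 / TF 0.15 / other 0.45,
  echoing the strong class imbalance of curated signaling resources.
* **Regulons**: 5 phosphosite targets per kinase/phosphatase, 5 protein
  targets per TF, target signs negative with probability 0.2; every node
  gets 0–2 regulatory self-sites (activating with probability 0.7).
* **Truth**: `nActive = 8` active regulators per genotype at
  |activity| = 1.5, half of them shared across genotypes with identical
  activities (the context-independent treatment response) and half
  genotype-specific (context rewiring).
* **Signal**: the expected treated-minus-control shift of a feature is the
  **additive** sum over its regulators of activity × regulon sign — the
  simplest generative model the footprint statistic identifies. Kinase and
  phosphatase effects land on phosphosites, TF effects and the active
  regulators' own abundance on the proteome, and an active protein's
  regulatory self-sites shift by activity × effect.
* **Noise**: i.i.d. Gaussian with `noiseSd = 0.25` on log2 values — a
  calibration choice, not a claim about any real dataset. At
  `noiseSd = 0` the shifts equal the linear model exactly.
* **Localization**: each site falls below the class-I threshold with
  probability `locProbLowFraction = 0.2`. Because the generator promises
  experiments whose ground truth is recoverable, it additionally
  guarantees every regulon at least `minClassITargets = 3` class-I target
  sites, applied uniformly to all regulators so the guarantee carries no
  information about which are active.

What the generator does **not** emulate: missing-not-at-random intensity
dropout, batch effects, peptide-level quantification, correlated noise
between co-regulated sites, and realistic regulon overlap structure.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not performance on real
mass-spectrometry data.

# Degenerate inputs and numerical conventions

* Zero-variance features: $t = 0, p = 1$ (no difference) or signed
  infinite $t$, $p = 0$ (separated groups). In the noise-free generator
  limit footprint scores become ±Inf; permutation p-values then tie at
  infinity and are uninformative, but the score sign is exact — the
  pipeline's recovered-regulator report therefore admits infinite scores
  without the FDR gate, and the noise-free guarantee is stated (and
  tested) as perfect *sign* recovery.
* Exact cancellation in the phospho-score yields score 0, sign 0; such
  proteins never veto nor support a footprint call.
* Correlations over fewer than two shared observations, and activity
  comparisons over fewer than three shared proteins, are reported as
  undefined (`NA`) rather than guessed.
* All writers order rows lexicographically in the C locale and all
  randomness flows from one root seed through fixed per-stage offsets, so
  identical configuration yields byte-identical outputs.

# Problem sizes used by the test suite

The packaged checks run at desk scale, chosen as the smallest sizes at
which the properties are sharp: parameter recovery on a 200-node prior
with 20 regulators (8 active) and ~1,300 measured features; null
calibration with 2,000 regulators over 10,000 sites; path-search
equivalence against exhaustive enumeration on one hundred 15-node priors;
an exhaustive hypergeometric sweep over all universes up to size 25; and
byte-level reproducibility of the full two-genotype pipeline on a 50-node
study.

# Known limitations

* Activities for "other"-class proteins rest solely on regulatory-site
  evidence; no network propagation is attempted for proteins without
  regulons or annotated sites.
* The mean-of-signed-t footprint assumes roughly exchangeable target
  statistics; heavy regulon overlap induces correlated scores that the
  per-regulator permutation null does not model.
* Path enumeration is exhaustive and exponential in `maxLen`; the default
  bound keeps it tractable, but very dense priors with large `maxLen`
  will be slow by design (no ILP/heuristic pruning is provided).
* The enrichment-score convention ($-\log_{10}$ adjusted p) is this
  package's documented choice; other tools print other "enrichment
  scores", and thresholds should be compared only after matching
  definitions.

# A worked example

```{r example, eval = FALSE}
ex <- simulateStudy(nNodes = 60, nRegulators = 12, nActive = 4, seed = 1)
cfg <- analysisConfig(seed = 1, outDir = "results")
report <- runPipeline(cfg, experiment = ex)
report$contexts[["ITD-JMD"]]$recovered_regulators
```

The run writes per-genotype differential tables, activity tables, model
exports (TSV/SIF/GraphML), enrichment tables and `report.json` under
`results/`.
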