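---
title: "Methods: first-neighbour analysis of tissue-specific interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-neighbour analysis of tissue-specific interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neighbournet)
```

## The model

Cancer rewires cellular signalling both directly, through mutated
proteins, and indirectly, through genes whose expression switches on or
off between normal and tumour tissue.  `neighbournet` analyses this
rewiring at the level of a tissue-specific protein interaction network.
Its node classification is deliberately simple and fully deterministic:

* **cancer-related (CR)** — the protein's gene is mutated in the given
  cancer type and/or *binary-differentially expressed* (present in
  exactly one of the two tissue states);
* **first neighbour (FN)** — directly interacting with at least one CR
  protein while not CR itself.  A DE protein adjacent to a mutated one
  remains CR only — the classes are a partition;
* **unaffected (UA)** — everything else;
* **influencer** — a UA protein with a *directed* interaction into an
  FN; by default the FN must additionally be adjacent to a DE
  cancer-related protein, so influencers sit exactly two directed steps
  from an expression change.

Adjacency always ignores edge direction; direction is consulted only
for influencer detection.  The scientific interest is that, in
heavy-tailed networks, first neighbours of even randomly chosen seed
sets are systematically central (the friendship paradox), so the FN
class inherits — and often exceeds — the centrality of the CR class.

## Expression discretization

Expression enters the pipeline as a gene × sample matrix per tissue
state.  Each gene is summarized per state (arithmetic mean across that
state's samples by default; median available), all per-state summaries
of the network genes are pooled, and a gene is called *not expressed*
in a state when its summary falls strictly below

$$\tau = \mu - \sigma,$$

the pooled mean minus the pooled (sample, $n-1$) standard deviation.
A gene is DE when its call differs between states; graded
over-expression of an always-on gene is deliberately invisible to this
rule.  Two poolings are provided: `combined` (default; both states'
summaries enter one pool, two values per gene) and `per_state`.  The
rule is shift-invariant but *not* balanced: if a large fraction of
genes sits in the silent mode, $\mu-\sigma$ can fall below that mode
and nothing is called off.  With the default synthetic conditions
(30% silent, modes 4 and 8 at scale 0.5 on a log2-like scale) the
threshold lands between the modes and label recovery is essentially
perfect; the test suite asserts ≥ 95% recovery at ≥ 4σ mode
separation.

The tissue network then retains an interaction when both interactors
are present in at least one state (*union rule*).  The wording
"present in either tissue" is genuinely ambiguous between this and a
per-state conjunction; the union rule is the default because the
analysis targets one combined network in which the effect of switching
genes is visible, and `rule = "per_state"` is provided for sensitivity
analysis.  Network genes missing from the expression table are treated
as absent (strict) by default, with a permissive `"expressed"` mode.

## Topology and statistics

Degree, betweenness and local clustering are computed with igraph on
the undirected, unweighted, loop-free graph.  Betweenness uses the
unnormalized unordered-pair-count convention (on the path A–B–C, node
B has betweenness 1); a normalized variant is available but ranks —
and hence every rank-based test — are unaffected.  Clustering of
nodes with degree < 2 is recorded as 0, matching common library
behaviour; this affects class medians and is therefore fixed and
documented rather than configurable.

Class comparisons use two-sided Wilcoxon rank-sum tests (with the
whole network as the default control group, so a class is compared
against a superset containing it — intentional) plus Kolmogorov–
Smirnov as a concordance check.  When both groups have at most 10
observations the Wilcoxon p-value is computed by *full enumeration*
over all group assignments of the tied ranks, which stays exact in the
presence of ties; larger groups use the tie-corrected normal
approximation with continuity correction.

**Giant-component test.**  The connectivity of a class is measured as
the fraction of its members inside the largest connected component of
the class-induced subgraph.  The null distribution perturbs the class
annotation: `n_perm` (default 1000, minimum 100) uniformly random node
sets of the same size.  Both a Z-score and an upper-tail empirical
p-value $(1 + \#\{r_\text{null} \ge r_\text{obs}\})/(n_\text{perm}+1)$
are reported; when the null ratios are constant the Z is undefined and
the empirical p stands alone.  A degree-stratified null would be a
natural alternative; the uniform relabelling is the default because it
matches the plain reading of "perturbing the annotation", and its
calibration (type-I error ≈ 0.035 at α = 0.05 in the test suite) and
power (planted connected 5% modules give Z > 3 essentially always)
are verified empirically on 400-node networks with class size 40 and
250 perturbations — sizes chosen to make the null ratio distribution
reasonably continuous.

**Randomization analysis.**  Robustness of the FN list is assessed by
drawing `n_draws` (default 100) uniform seed sets of the real CR size,
listing their first neighbours with the same rule as `classify()`, and
comparing per-node occurrence counts of the real FN class against UA
and CR with Wilcoxon tests.  On a star $K_{1,n}$ with single-node
seeds the centre's expected occurrence is $R\,n/(n+1)$, which the test
suite checks against the closed form.

## Functional reach and druggability

The GO analysis asks what the FN class *adds*: CR proteins are
annotated first, first neighbours then contribute only biological-
process terms not already annotated to a CR protein.  The added count
$k$ is tested one-sided against $n = |\mathrm{BP}_{CR} \cup
\mathrm{BP}_{added}|$ trials with expected success probability
$|FN|/|\text{network}|$.  The trials universe is a design choice (the
natural one for "added" terms) and is the only free quantity in the
test; terms are used as annotated, without ancestor propagation.

Bioactivity records are filtered into *compounds* (IC50/Ki/Kd ≤ 500 nM)
and *drugs* (compounds whose compound reached clinical phase 4).  A
compound counts once per class but may count in several classes when
it hits targets in each.  Class compositions are compared with a 2×2
χ² without continuity correction (Fisher's exact test when any
expected cell < 5) and against a stated expected share with one-sided
binomial tests.  Venn partition counts over per-cancer sets are exact
subset enumerations.

## The synthetic-data generator

The generator emulates the *statistical premises* of the analysis, not
any particular dataset:

* **Interactome** — undirected preferential attachment (`n_nodes`
  = 2000, `attachment_edges` = 3 by default), guaranteeing the
  heavy-tailed degree distribution on which the friendship-paradox
  behaviour rests; a static power-law fitness model is available.  A
  configurable fraction (default 0.3) of edges carries a random
  direction flag, mimicking mixed signalling/PPI resources.
* **Expression** — two Gaussian modes on a log-intensity scale
  (silent N(4, 0.5), expressed N(8, 0.5); 10 samples per state),
  mimicking RMA-normalized intensities without modelling probes; 30%
  of genes are silent at baseline and a fraction `frac_de_genes`
  (default 0.1) switches mode between states.  Ground-truth labels are
  always emitted.
* **Mutations** — `n_seed_proteins` (default 100) nodes sampled with
  weight $\mathrm{degree}^{b}$; $b=0$ is uniform, the default study
  uses $b=2$ so mutated genes are hubs while DE genes are uniform —
  the synthetic analogue of the observed two-strategy dichotomy
  (mutated proteins at least as central as their first neighbours; DE
  proteins less central than theirs).
* **GO / bioactivity** — term assignments from a 200-term pool (1–5
  per protein; disjoint pools via `term_offset` give exact expected
  added-BP counts), and compounds with log-uniform potencies over
  1–10000 nM and P(phase 4) = 0.2.

What the generator does **not** emulate: probe-level noise and batch
effects, cancer-subtype structure, biologically coherent GO structure
(terms are exchangeable, so the added-BP test on default synthetic
data is usually non-significant — the machinery, not the biology, is
what the tests validate), and correlated mutation/expression of the
same pathway.  Passing tests therefore demonstrate correctness and
calibration of the pipeline, not biological conclusions about real
tissue.

A consequence worth knowing: with hub-biased mutated seeds the CR
class itself is well connected (its giant-component test is
significant), and with 100 seeds plus ~200 DE genes the FN class can
cover half the network, making its giant-component ratio *lower* than
uniform same-size sets.  Real cancer interactomes, where CR proteins
are sparsely interconnected, sit in a different corner of parameter
space; the package reports whatever the data imply.

## Numerical and degenerate-input choices

* σ uses the sample (n−1) convention; population available.
* All calls are strict: a summary exactly at τ counts as expressed, so
  a constant matrix (σ = 0) leaves every gene expressed.
* A single-value pool makes σ undefined and raises an error rather
  than guessing.
* Empty seed sets, empty tissue networks, missing directed edges and
  `n_draws = 0` each produce a defined result (error, warning + empty
  network, warning + empty influencer set, zero counts) rather than
  silent misbehaviour.
* Every stochastic stage takes an explicit seed; generators are pure
  functions of `(config, rng_seed)`, and `run_pipeline()` derives all
  stage seeds from one recorded master seed, so identical configs give
  byte-identical output files.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the study at
desk scale: 2000-node networks for classification/recovery properties
(100 replicates for the friendship-paradox and dichotomy rates),
400-node networks × 250 perturbations × 200 replicates for permutation
calibration, and 1000 perturbations / 100 randomization draws in the
single full pipeline run.  These sizes are the package's reference
conditions; all of them are plain function arguments and scale up
unchanged.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_nodes = 500, n_seed_proteins = 30,
                        seed_centrality_bias = 2, rng_seed = 7)
pc <- pipeline_config(synthetic = cfg, n_resources = 3,
                      consensus_k = 2, n_perm = 200, n_random = 50,
                      rng_seed = 7)
report <- run_pipeline(pc)
report$summary
report$consensus_influencers
```

## Known limitations

* The classification is one-step (plus the two-step influencer rule);
  no propagation, community detection or diseasome-module analysis.
* Binary DE only; fold changes and moderated statistics are out of
  scope by design.
* The GAF reader handles aspect-P association rows only; no ontology
  DAG, so no term propagation.
* No continuous direction semantics: an edge is directed or not;
  stimulation/inhibition signs are not modelled.
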