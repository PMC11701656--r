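---
title: "Bin-free Bayesian inference of functional coupling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-free Bayesian inference of functional coupling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupnet)
```

## The model

Two genes are *functionally coupled* when they act in a common biological
process — as members of one complex, pathway or operon, as physically
interacting proteins, or as a regulator and its target. No single omics
data type measures coupling directly; `coupnet` infers it by naive
Bayesian integration of heterogeneous evidence against curated *gold
standards* that act as proxies for true couplings.

For each evidence type, dataset and gold standard, the raw score
distribution of known couplings and of unknown pairs is modelled with
Gaussian kernel density estimates, and each raw score $x$ is converted to
a log-likelihood ratio

$$\mathrm{LLR}(x) \;=\; \ln \frac{P(x \mid FC)}{P(x \mid \neg FC)},$$

where $FC$ denotes gold-standard (known coupling) pairs and $\neg FC$ all
other scored pairs. The pointwise curve is summarised by a polynomial of
degree 2–4 ("bin-free": no score discretization anywhere). Datasets of
the same evidence type are combined with sequential redundancy weights,
and the *final Bayesian score* of a pair is the sum of its per-type
contributions,

$$\mathrm{FBS}(A,B) = \sum_t \mathrm{LLR}_t(A,B),$$

which the conditional-independence assumption of naive Bayes justifies.
FBS is finally calibrated to a positive predictive value (PPV) by fitting
a logistic curve to the empirical precision of gold-standard links over
an FBS threshold sweep, and the network keeps links with PPV ≥ 0.85.

## Evidence scores

Ten evidence types are supported. The scoring functions reproduce the
field's conventions: domain-interaction support weighted by domain
degrees (`dom_score`), publication-weighted physical interactions with
hub down-weighting (`pin_score`), Spearman profile correlations with
evidence-specific validity minima — 5 valid positions for genetic
interaction and protein co-expression profiles, 3 for mRNA co-expression
(`profile_correlation_score`) — Jaccard indices of shared microRNA or
transcription-factor regulators (`jaccard_regulator_score`) and of top-25
% expressed tissues (`pex_top_tissue_score`), a branch-length-weighted
phylogenetic profile log-ratio (`php_score`), ChIP-seq peak-to-gene
assignment with per-dataset min–max normalization (`grg_score`), and the
Wang graph-based semantic similarity of annotation terms
(`wang_semantic_similarity`).

mRNA co-expression is post-processed before training
(`mex_postprocess`): homolog pairs are removed, correlations with
$|r| \le 0.5$ are discarded, and retained $|r|$ values are min–max
scaled per dataset. Gene-regulation scores are directed (TF → target) and
a positive gene-regulation LLR is what makes a final link directed.

All logarithms in the package are natural; the sources the scores mimic
do not state a base, and $\ln$ matches the LLR convention. Spearman ties
get average ranks. The top-tissue count is $\lceil 0.25\,T \rceil$. The
peak-to-gene window defaults to 10 kb upstream of the annotated start
plus the gene body and is configurable; unstranded genes are treated as
plus-strand. Wang edge weights default to 0.8 (is-a) and 0.6 (part-of)
and term sets aggregate by best-match average.

## Gold standards

Six link sets are constructed from raw records: complexes (clique
expansion, complexes with more than 100 members are *excluded* — a
deterministic reading of the size limit; truncation would require an
arbitrary member choice), metabolic and signaling pathways (cliques),
shared operons (cliques), physical interactions (kept when supported by
at least two experiments of ≤ 100 interactions each, or rescued by
presence in any other gold standard), and a directed regulatory set
(union of TF → target sources). Gold standards never contain self-links.

## Training and its acceptance gates

`estimate_llr_curve` evaluates the LLR on 512 evenly spaced grid points
over the common score range of positives and negatives, truncated at the
98th percentile of the pooled scores to exclude outliers. The lowest
polynomial degree in {2, 3, 4} reaching $R^2 \ge 0.9$ is accepted
(parsimony; the admissible band is fixed, the selection rule is the
package's choice). Training is rejected — with the reason recorded —
when the positive sample is outside $[10^3, 10^6]$ observations (the
bound is applied to the positive class, the scarcer one) or when no
degree fits. Kernel bandwidths follow Silverman's rule,
$h = 0.9\min(\hat\sigma, \mathrm{IQR}/1.34)\,n^{-1/5}$. Evaluation
outside the trained score range clamps to the range endpoints.

Redundancy weighting ranks a pair's dataset LLRs decreasingly and
down-weights sequentially, $w_1 = 1$ and
$w_k = \alpha\,[1 - \max(0, r_{k,k-1})]\,w_{k-1}$ with $\alpha = 0.7$;
$r$ is the Spearman correlation between the two datasets' LLRs on shared
pairs (fewer than 10 shared pairs gives $r = 0$: no redundancy
evidence). The reference dataset is the immediate predecessor in the
ranking; a most-correlated-predecessor variant is available via
`predecessor = "max"` since the sequential schema can be read either
way.

The negative ("unknown") population is all scored pairs not in the gold
standard. This matches the prior-free LLR construction: the unknown set
approximates the background because true couplings are rare in real
interactomes.

## Confidence calibration

`ppv_curve` sweeps 1000 evenly spaced FBS thresholds with equal numbers
of gold-standard positives and resampled negatives (30 resamples,
uniformly drawn non-gold-standard scored pairs), so a threshold below
all examples has TP = FP and PPV 0.5. `fit_ppv_logistic` fits
$\widehat{PPV}(x) = a/(1 + e^{-b(x - c)})$ and requires $R^2 \ge 0.9$.
The variant with denominator $1 - e^{-b(x-c)}$ appears in some written
accounts of this curve; it is singular at $x = c$ and not a logistic
function, so it is kept only behind `form = "printed"` for auditing.

Assembly takes, per pair, the maximum calibrated PPV over gold standards
(the union of gold-standard networks), applies the gsPPV floor — 0.85 /
0.90 / 0.95 / 1.0 for 1 / 2 / 3 / >3 supporting gold standards — unless
the evidence PPV already exceeds it, keeps links with final PPV ≥ 0.85,
and flags a link directed when its gene-regulation LLR is positive. The
website notion of a graded "direction confidence" is reduced here to
the binary flag plus the underlying GRG LLR.

## Orthology

Evidence of types GIN, GRG, MEX, MIR, PEX, PIN and TFB can be
transferred between species through ortholog maps; DOM, PHP and SCL are
refused because they already contain cross-species information.
Many-to-one co-orthology is resolved by averaging all source-pair scores
mapping onto one target pair (per target pair, matching the worked
convention of InParanoid-style transfers). Whole networks transfer by
expanding each link to the cross-product of its endpoints' orthologs,
keeping the original confidence; duplicate target pairs keep the
maximum PPV (conservative for a confidence score). Species distances are
one minus the average ortholog fraction in both directions; trees are
built with UPGMA (orthophylogram) or neighbour joining rooted at the
species of interest (negative NJ branch lengths are clamped to zero).
Closest-species selection prefers the taxonomic lineage distance and
falls back on the orthophylogram distance for ties or missing taxonomy.

## Search, enrichment and benchmark

Group search ranks candidates by summed link PPV to the query (common
neighbors first when requested); independent search expands each query
gene separately; MaxLink ranks by links into the query with a
hypergeometric tail p-value on a population of $N-1$ nodes, primary key
the link count. All rankings break ties lexicographically so results are
deterministic. EASE enrichment is the one-sided hypergeometric test with
the observed overlap reduced by one. Expansion depth > 1 re-runs the
chosen search on the grown node set.

The benchmark runs a random walk with restart (restart 0.75) from half
of a gene set and scores recovery of the held-out half as an AUROC
against all other network genes; the walk uses the unweighted undirected
adjacency by default (a PPV-weighted variant is behind a flag, as the
standard protocol does not state edge weighting). Performance gain
compares the median AUROC over 30 splits with the median over 30 splits
× 30 degree-preserving rewirings (swap count equal to the number of
links, no self-loops).

## The synthetic-data module

`generate_world` plants a known set of coupled pairs among synthetic
proteins ("P0001", …; no accession semantics). `generate_evidence`
draws Gaussian raw scores — positives and negatives from configurable
distributions — with seeded Bernoulli thinning for assay coverage;
Gaussians are the default because the true LLR is then the linear
closed form $(\mu_1 - \mu_0)x/\sigma^2 + \text{const}$, giving exact
oracles for the training stage. `generate_gold_standard` applies a
recall/false-positive model to the planted truth, and
`generate_ortholog_map` produces ortholog tables with a controllable
many-to-one rate.

What the generator emulates: class-conditional score distributions,
incomplete coverage, imperfect gold standards, co-orthology. What it
does not: realistic marginal distributions of any omics platform, batch
effects, correlated evidence errors, protein-family structure, or
species-specific proteome sizes. Green tests therefore demonstrate the
*mechanics and calibration* of the inference engine, not performance on
real data.

## Fixture sizes and frozen experimental designs

The test and acceptance workloads use problem sizes chosen once as
realistic desk-scale conditions:

* **LLR recovery** — positives $N(1,1)$ versus negatives $N(0,1)$,
  $5 \times 10^4$ per class; the fitted polynomial is compared with the
  analytic $x - 0.5$ on $[-1, 2]$.
* **Calibration** — a world of 142 proteins (10 011 pairs), coupling
  fraction 0.5, gold standard equal to the planted truth, one Gaussian
  dataset with positives $N(1.25, 1)$ versus negatives $N(0, 1)$. The
  effect size is chosen so the PPV-versus-FBS relation is sigmoidal
  enough for the logistic calibration to clear its own $R^2 \ge 0.9$
  gate with margin across seeds, while the cumulative-versus-local
  precision gap (the fitted PPV estimates precision *above* a score,
  the bins measure it *within* a score band) stays far inside the
  tolerance. The fitted PPV estimates precision under the *balanced*
  positive/negative sampling of the calibration protocol, so a check
  against planted truth is only well-posed when the class prior is
  balanced and the gold standard matches the truth; gold-standard noise
  paths are exercised separately. Empirical precision per fitted-PPV bin
  of width 0.05 is compared with the bin midpoint.
* **Benchmark** — a preferential-attachment background of 150 nodes
  with a 40-gene module planted on mid-degree nodes
  (interconnection probability 0.5). With a uniform background, degree
  alone identifies the module and degree-preserving nulls are as good as
  the real network; the heterogeneous background makes the rewired null
  a fair baseline. Null instances are mixed with $20\times$ the number
  of links in swaps, since a single pass leaves residual module signal;
  the benchmark's internal nulls keep the standard swap count. The
  reduced scale is 10 splits × 10 randomizations.

## Degenerate inputs and numerical conventions

Constant-score samples have zero bandwidth and are rejected by the KDE.
Densities are floored at the smallest positive double before taking
logs. A dataset with constant ChIP-seq signal normalizes to 1. MEX
min–max scaling of a single retained value gives 1. The phylogenetic
score regularizes an empty positive or negative species set with
$\varepsilon = 10^{-6}$ of the total tree length, which caps the score.
Networks store undirected pairs with the lexicographically smaller
protein first; direction is a per-row flag.

## Limitations

The engine is exercised on synthetic fixtures only; no downloading,
identifier mapping or full-scale data ingestion is included. TOPAS and
ANUBIX, which appear alongside these tools in production settings, are
external algorithms and are not reimplemented. The RWR benchmark holds
entire networks in dense matrices and is intended for the
hundreds-of-nodes scale of the fixtures, not for genome-scale networks.
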