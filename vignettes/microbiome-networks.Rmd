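---
title: "Inferring microbial association networks and selecting disease-associated taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial association networks and selecting disease-associated taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

## The problem

Amplicon surveys of a microbial community deliver a samples-by-taxa table of
read counts. Two questions recur: which taxa co-occur in a way that suggests
ecological association, and which taxa are associated with a binary outcome
such as disease status of the host or crop. micronet answers both with one
toolkit: a conditional-mutual-information (CMI) skeleton learner for the
network question, a consensus layer for combining it with other inference
methods, a bootstrap harness to quantify how reproducible any inferred
network is, and a multi-method taxon-selection framework that crosses
machine-learning rankers with network-centrality evidence.

Everything operates on a plain tibble (`sample_id`, optional `label`, one
numeric column per taxon), so the pieces compose with the usual tidyverse
verbs and with each other.

## Gaussian mutual information and conditional mutual information

For taxa $X$ and $Y$ (abundance profiles after normalization), mutual
information measures how much knowing one reduces uncertainty about the
other. Under a working Gaussian assumption it has the closed form

$$MI(X,Y) = \tfrac12 \log \frac{\sigma_X^2\,\sigma_Y^2}{|C(X,Y)|}
          = -\tfrac12 \log\bigl(1-\rho^2\bigr),$$

with $C(X,Y)$ the $2\times2$ sample covariance matrix (denominator $n-1$)
and $\rho$ the sample correlation. Conditional MI extends this to ask
whether the association survives after accounting for a set of other taxa
$\mathbf Z$:

$$CMI(X,Y\mid \mathbf Z) = \tfrac12 \log
  \frac{|C(X,\mathbf Z)|\;|C(Y,\mathbf Z)|}
       {|C(\mathbf Z)|\;|C(X,Y,\mathbf Z)|},$$

which for a single conditioning taxon equals
$-\tfrac12\log(1-\rho^2_{XY\cdot Z})$ in terms of the partial correlation.
A CMI near zero says the edge is explained away by the mediator — the key
device for separating direct from indirect association.

Numerical choices, all deliberate:

* natural logarithm throughout, so values are in nats;
* sample covariances use the $n-1$ denominator;
* a ridge of $10^{-10}\cdot\mathrm{trace}/\mathrm{dim}$ is added to the
  joint covariance before taking determinants, guarding near-singular
  conditioning sets;
* perfectly collinear pairs, where MI diverges, are capped at a
  configurable 10 nats with a warning;
* estimates in $(-10^{-9}, 0)$ — floating-point noise around the true 0 —
  are clamped to exactly 0, while anything more negative raises an error,
  since the Gaussian forms are mathematically nonnegative and a clearly
  negative value signals a covariance bug, not data.

## The skeleton algorithm

`infer_cmi_network()` recovers an undirected skeleton in two
quantile-thresholded stages:

0. start from the complete graph on the taxa;
1. compute MI for every pair on the normalized data;
2. remove edges with MI strictly below the empirical `q1` quantile
   (default 0.70) of all pairwise MI values — the surviving graph is `S0`;
3. for each `S0` edge, freeze its candidate separators as the common
   neighbors of its endpoints in `S0`, compute the CMI given each single
   separator, and retain the maximum — the strongest dependence left after
   allowing any one mediator to explain the edge;
4. remove edges whose maximum CMI falls strictly below the `q2` quantile
   (default 0.95) of the max-CMI values, leaving the final skeleton `S1`.

Three design points deserve emphasis.

**Dynamic thresholds.** A fixed CMI cutoff is poorly calibrated across
datasets; quantile thresholds adapt to the scale of the MI/CMI distribution
at hand, and `q1`/`q2` become direct sparsity dials: lower quantiles give
denser graphs, higher give sparser ones — `glance()` on a fit reports both
stage sizes, and the monotonicity is covered by tests. "Below the
threshold" means *strictly* below the interpolated empirical quantile
(type-7), so ties at the threshold are kept: removal requires being clearly
under it. A consequence worth knowing: because the interpolated quantile at
any $q>0$ sits slightly above the minimum, the smallest value is removed
even as $q \to 0$; the complete graph is only recovered in the exact $q=0$
limit, which lies outside the admissible $(0,1)$ range.

**Order independence.** Separator sets are fixed from `S0` *before* any
stage-4 removal, so the result cannot depend on the order in which edges
are examined; `permutation_invariance_check()` verifies the edge set is
invariant under random relabelings of the taxa. The procedure contains no
randomness at all.

**Separator-less edges.** An `S0` edge whose endpoints share no common
neighbor offers no conditioning evidence that could explain it away, so it
bypasses the CMI filter and is retained; the `q2` quantile is computed over
the max-CMI values of edges that do have separators. Conditioning is
order 1 only — one mediator at a time, maximized over mediators — which
keeps the test well-posed at microbiome sample sizes.

Taxon columns that are constant after normalization carry no information
and are dropped with a warning rather than failing the run. For
density-matched comparisons (e.g. against a ground-truth network of known
size), `tune_q2_to_edges()` reuses one fit's max-CMI values and selects the
`q2` on a 0.001-step grid whose edge count is closest to the target;
separator-less edges put a floor on the reachable count.

## Normalization

Raw counts make MI/CMI estimates unstable; four sample-wise transforms are
provided (`normalize_abundance()`): `log` ($\log(c+1)$ by default), `clr`
(centered log-ratio, rows sum to 0), `tss` (relative abundances, rows sum
to 1), and `gmpr` (division by geometric-mean-of-pairwise-ratios size
factors, robust to zero inflation). The inference default is the log
transform (`quantitative = TRUE`); pass `quantitative = FALSE` to supply
data normalized elsewhere, e.g. CLR for a compositionality-aware analysis.
The pseudocount defaults to 1 — the conventional choice for count data —
and is exposed because results at low counts are sensitive to it. None of
the transforms removes compositional dependence entirely; with strong
compositional bias, spurious associations remain possible whichever is
chosen, which is one reason to compare transforms
(`pairwise_normalization_similarity()` scores the structural agreement of
networks inferred under each pair of normalizations on shared bootstrap
resamples).

GMPR factors are undefined for a sample that shares no nonzero taxon with
any other sample; that is an error naming the sample rather than a silent
factor of 1, because such a sample cannot be placed on a common scale.

## Consensus networks

Different inference algorithms disagree on microbiome data, often
substantially. `build_consensus()` takes binarized networks from any
ensemble of methods (import external adjacency exports with
`read_adjacency()`) and weights each edge by the number of supporting
methods, 0 to M. Thresholding the weight trades density against
confidence: weight $\ge 1$ is the union, weight $=M$ the
every-method intersection. All edges are treated as unsigned dependencies —
MI-based methods cannot sign them, so signed inputs are harmonized to
strength-only before voting. Node sets must match exactly; silently
unioning or intersecting them would mask upstream filtering bugs.
`edge_overlap_partition()` reports the full method-subset decomposition
(the cells a Venn diagram would show).

## Bootstrap reproducibility

`bootstrap_stability()` infers a reference network from the full table,
then re-infers on bootstrap resamples (rows drawn with replacement,
original size kept; 50 replicates by default) and scores each replicate
against the reference: precision, recall, F1, and Jaccard on edge sets,
with the summary being the median, standard deviation, and the 2.5%/97.5%
percentile interval of the F1 distribution. Conventions: the full-data
network is the reference (precision/recall directions follow from that; F1
and Jaccard are direction-free); two empty networks count as perfect
agreement (1), one empty network as 0. Replicate $r$ draws from seed
$\mathrm{seed}+r$, so different pipelines can share identical resamples —
`pairwise_normalization_similarity()` relies on exactly that. This measures
*reproducibility under resampling*, not biological accuracy: a method that
stably infers the wrong network scores high.

`compare_method_f1()` wraps paired two-sided Wilcoxon signed-rank tests on
per-replicate F1 scores across methods. The multiple-pair adjustment is
Holm — conservative and assumption-free — and exposed as an argument; the
degenerate all-zero-differences case (identical distributions) is reported
as $p = 1$ rather than an error.

## Selecting disease-associated taxa

### Machine-learning route

Seven rankers each keep the top $\lceil 0.2\,p\rceil$ taxa for the binary
label: the one-way F statistic; a binned mutual-information score
(equal-frequency bins, $\min(10, \lfloor\sqrt{n/2}\rfloor)$ of them);
recursive feature elimination under ridge logistic regression
($L_2$, fixed penalty $\lambda = 1/n$), a decision tree, gradient-boosted
trees (100 rounds, depth 3), and a random forest (100 trees); and an
abundance filter keeping taxa whose per-taxon maximum reaches the
$1-0.2$ quantile of the maxima — a deliberately model-free member that
catches dominant taxa the model-driven rankers can miss. Hyperparameters
are pinned to these defaults for reproducibility, and the stochastic
learners are seeded. The abundance filter is interpreted as ranking taxa by
their maximum abundance (other readings of "top of the dataset" are
possible; this one is deterministic and scale-respecting).

`total_score()` runs all methods under each requested normalization (CLR,
raw, log, TSS by default). Within a normalization, a taxon's TOTAL is the
number of selecting methods (0–7), and the majority rule `TOTAL > 3`
defines the selected set; the report also carries the intersection across
normalizations. The headline set uses the log normalization by default
(configurable), since that is also the inference default.

### Network route

`network_centralities()` computes five per-node metrics: degree;
eigenvector centrality (per connected component, scaled to max 1 within
each, 0 for isolated nodes — a single global eigenvector is undefined on
disconnected graphs); PageRank at damping 0.85; harmonic closeness
normalized by $n-1$ (finite on disconnected graphs, unlike classical
closeness); and betweenness normalized by $(n-1)(n-2)/2$.

**Strategy 1 (differential centrality)** compares condition-specific
networks method by method: per metric, taxa are ranked by the absolute
centrality difference between the healthy and diseased networks, the top
20% per metric flag the taxon for that method (union over metrics, with the
responsible metrics recorded), and the final set is the intersection across
methods. **Strategy 2 (composite score)** scores each taxon within one
network as $0.1\,DE + 0.1\,EV + 0.1\,PR + 0.2\,CL + 0.5\,BE$ after min-max
scaling each metric to $[0,1]$ within the network. The scaling is a design
decision: the five metrics live on incompatible scales, and raw betweenness
would dominate the sum regardless of the weights. The weight profile favors
the path-based metrics (betweenness, closeness) that signal bridging,
keystone-like roles. `strategy2_consensus()` keeps, per condition, the taxa
in the top 20% for every method of the ensemble.

Ties at any top-fraction boundary are resolved by including all tied taxa —
deterministic and label-independent — with a warning recording the
expansion. When the two condition networks are identical every difference
is zero, everything ties, and the selection degenerates to all taxa; this
is warned about rather than hidden. A metric whose range across nodes is
below $10^{-9}$ is treated as constant (contribution 0) because min-max
scaling would otherwise amplify solver noise to order 1. The 20% fraction
is a user parameter; values between 10% and 30% are reasonable, with
stricter cutoffs shrinking cross-method overlap and looser ones admitting
weak signals.

`finalize_selection()` crosses the three routes and assigns evidence tiers:
selected by all three (`"a"`), ML + Strategy 1 (`"b"`), ML + Strategy 2
(`"c"`), both network strategies (`"d"`).

## The synthetic test bed

Because no gold-standard microbial interaction network exists, the package
ships a generator whose ground truth is known exactly. `band_graph()`
builds the true conditional-independence graph (edges between taxa within
`band_width` index positions); `make_precision()` places $\pm$`strength`
(default 0.3, random signs) on its edges and sets the diagonal to the
maximum absolute row sum plus 0.1, guaranteeing positive definiteness by
diagonal dominance. `sample_counts()` draws latent multivariate normal data
from the inverted precision and pushes each column through its normal CDF
into the quantile function of a count marginal — the "normal to anything"
(Gaussian copula) construction. The default marginal is zero-inflated
negative binomial with mean 20, dispersion (NB size) 0.5, and 30% extra
zero mass: overdispersed and zero-rich in the way 16S count tables are. A
plain NB and a Poisson marginal are available; the NB approaches the
Poisson as the size parameter grows, and the copula preserves the sign
pattern of the latent correlations in the count ranks.

`two_class_dataset()` emulates a healthy/diseased design: the two
condition graphs share a chosen fraction of the band edges and rewire the
remainder disjointly, so class-specific structure exists by construction
and selection methods can be checked for enrichment of the truly differing
taxa.

What the generator does *not* emulate: sequencing-depth variation and the
resulting compositional coupling between taxa, taxon-specific marginals
fitted to a real survey, and phylogenetic correlation among taxa. Passing
the synthetic checks therefore demonstrates correct recovery of
copula-Gaussian dependence structure under realistic sparsity and
overdispersion — not performance on any particular real dataset.

`random_baseline_f1()` supplies the comparison point for recovery: a
density-matched random guess with $E_t$ edges against a truth of $E_r$
edges over $N$ pairs attains expected F1 $\approx 2E_rE_t/(N(E_r+E_t))$,
and an informative method should clear a multiple of that.

## Problem sizes and runtime

The shipped checks run at desk scale, chosen so the whole suite completes
in a few minutes on one core: estimator and algebra properties at
$p \le 15$; the exhaustive naive-reference comparison at $p \le 7$ over 50
fixtures; the recovery benchmark at $p = 50$, $n = 300$, band width 2
(97 true edges), where the tuned skeleton reaches F1 around 0.85 against a
random baseline of 0.079; and bootstrap analyses at 50 replicates. The
inference itself is quadratic in taxa with an order-1 CMI stage and handles
hundreds of taxa comfortably.

## Known limitations

* The Gaussian closed forms capture monotone, roughly elliptical
  dependence after transformation; strongly nonlinear or non-monotone
  associations can be missed.
* Compositionality is mitigated, not removed, by the available transforms.
* Edges are unsigned; cooperative and competitive interactions are not
  distinguished.
* Conditioning is on single mediators; higher-order indirect paths are not
  tested.
* Bootstrap stability is reproducibility, not accuracy; a consensus of
  correlated methods can be confidently wrong.
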