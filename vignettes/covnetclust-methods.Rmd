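---
title: "Covariate-adjusted network mixtures: model, algorithm and design choices"
author: "covnetclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted network mixtures: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covnetclust)
```

## The problem

Cohorts in myeloid malignancies (AML, MDS, CMML, MPN) and other cancers
carry two very different kinds of baseline information: binary genomic
features (gene-level mutation indicators, cytogenetic alterations) and
clinical covariates (demographics, blood and bone-marrow values).
Clustering patients on such data faces two traps. Treating covariates as
ordinary features lets demographics drive the clustering — an "old
versus young" split restates a known covariate instead of revealing
mutational structure. Dropping covariates altogether is no better: when a
covariate shifts mutation probabilities (age shifting the rate of
splicing-factor mutations, say), the induced variation masquerades as
cluster structure and confounds the result.

`covnetclust` implements a model-based answer: each cluster is a Bayesian
network over all variables, and *cluster-independent covariates* — those
that can causally influence mutations but not the reverse, such as age
and sex — are restricted to outgoing edges and conditioned on in the
cluster assignment. The covariates inform the network parameters, but the
membership of a sample depends only on how well its *cluster-dependent*
variables (mutations, cytogenetics, and clinical values such as blast
counts that reflect disease state) fit each cluster's network given the
covariates.

## Model

With cluster-dependent variables $X_V$ and cluster-independent covariates
$X_C$, the data distribution is a K-component mixture

$$p(X_V) = \sum_{k=1}^{K} \pi_k \, P(X_V \mid X_C, \mathcal{G}_k, \theta_k),$$

where each component is a categorical Bayesian network
$(\mathcal{G}_k, \theta_k)$ that factorizes as

$$P(X_V \mid X_C, \mathcal{G}_k, \theta_k)
  = \prod_{i \in V} P(X_i \mid X_C, X_{pa(i)_k}, \theta_k).$$

Because covariates have only outgoing edges, this conditional probability
is exact — no marginalization over latent configurations is needed — and
summing it over all configurations of $X_V$ gives 1 for any fixed $X_C$
(`bn_loglik()` is tested against brute-force enumeration).

Cluster responsibilities use the adjusted membership function

$$\tilde\phi(X_V \mid k) =
  \frac{\chi + \gamma_k P(X_V \mid X_C, \hat{\mathcal{G}}_k, \hat\theta_k)}
       {\chi K + \sum_{k'} \gamma_{k'} P(X_V \mid X_C,
        \hat{\mathcal{G}}_{k'}, \hat\theta_{k'})},$$

with $\gamma_k$ the mean membership of cluster $k$ and $\chi \ge 0$ a
regularizer pulling memberships toward uniform.

**Choice of $\chi$.** The default is $\chi = 0$, the unregularized
posterior weights. The reason is one of scale: $\chi$ competes with
$\gamma_k P(X_V \mid X_C)$, and that likelihood shrinks geometrically
with the number of modelled variables (about $e^{-6.4}$ per sample for
20 binary features in the default synthetic scenario). Any fixed positive
default is therefore either negligible for small models or
membership-flattening for realistic ones; a useful $\chi$ must be chosen
relative to the typical likelihood magnitude of the data at hand, and the
argument is exposed for that purpose.

## Structure learning

Cluster DAGs are learned by greedy hill climbing over single-edge
addition, deletion and reversal moves on a decomposable Bayesian score:
weighted BDeu (equivalent sample size 1 by default) plus a log edge-prior
term. Three kinds of background knowledge shape the search space:

* **Role constraints.** Cluster-independent covariates accept no incoming
  edges.
* **Modality constraints.** Edges from blood or bone-marrow variables
  into genomic features are excluded, reflecting the plausible causal
  direction; genomic-to-clinical edges remain allowed.
* **Prior interactions.** Known gene-gene interactions (e.g. a STRING
  export supplied as a two-column TSV) enter as a prior-odds factor:
  listed pairs carry multiplier 1 in either direction, all other
  gene-gene edges $1/2$ under the default penalty factor 2 (so each such
  edge pays $\log 2$ in score), and edges involving clinical or covariate
  nodes are unpenalized. The penalty is interpreted as a prior-odds
  factor on edge inclusion — log-additive in the score — rather than a
  multiplicative rescaling of the data term.

Moves are enumerated in lexicographic (parent, child) order and only
strictly improving moves are taken, so the search is deterministic,
cannot cycle (no tabu list is needed), and terminates at a local
optimum. Random restarts (default 5 in standalone use) start from random
constraint-satisfying DAGs. `max_parents` defaults to 4, bounding CPT
size. Soft (fractional) sample weights are first-class throughout, so
the same scoring machinery serves both hard-weighted and EM-weighted
structure updates.

## The staged EM algorithm

Fitting alternates an E-step (adjusted memberships) with M-steps
($\gamma_k$ as mean membership; Dirichlet-smoothed CPT refits every
iteration with the soft weights; structure re-learning every
`structure_every = 5` iterations). Two dynamical facts about the
uniform-membership starting point shaped the algorithm:

1. Equal weights are an unstable equilibrium, and the run starts from a
   0.1% per-sample perturbation of uniform. That perturbation first
   *contracts* (its uninformative components decay within an iteration
   or two) before its informative projection grows back exponentially.
   Declaring convergence on a small membership change would therefore
   stop at the saddle; convergence is never declared while memberships
   remain near-uniform.
2. Learning cluster-specific structures while memberships differ by only
   0.1% commits the clustering to arbitrary structural noise: each
   cluster's search sees essentially the same weights, returns slightly
   different DAGs, and the next E-step hard-assigns samples along those
   meaningless differences. On the default synthetic scenario this
   yields ARI ≈ 0 against the generating labels.

The fit is therefore staged. Stage 1 runs EM under edge-free networks
(an independence mixture), which reliably grows the perturbation into a
stable partition. Stage 2 starts per-cluster structure learning (gated
on memberships having separated from uniform) and alternates it with
parametric EM until the membership change falls below `tol = 1e-4` or
`max_iter` is reached. Structure searches inside EM warm-start from the
previous cluster DAG with a single greedy run, keeping fits fast and
deterministic given the seed. Optionally `n_starts` stage-1 runs from
independently perturbed starts are raced and the best by log-likelihood
continues into stage 2; the benchmark harness uses 3, the plain fit 1.

With $\chi = 0$ and fixed structures the alternation is exact EM for the
mixture, so the observed-data log-likelihood is non-decreasing; the test
suite asserts this with the CPT pseudocount set near zero, since the
posterior-mean (pseudocount-smoothed) M-step optimizes the penalized
rather than the raw likelihood. A starvation guard re-seeds any cluster
whose total membership collapses below $10^{-6}$ from the samples the
current model fits worst, with a warning.

## Synthetic cohorts

`simulation_scenario()` declares the generator's study conditions; its
defaults — K = 3 clusters, 20 binary genomic features, 2 binary
cluster-independent covariates, n = 600, uniform proportions — are the
package's standing small-cohort benchmark. Each cluster gets its own
random feature DAG (edge density 0.15, at most 4 parents). CPT rows are
drawn and then *sharpened*: a random baseline log-odds is drawn from
$\mathrm{logit}(U[0.2, 0.8])$, each feature parent adds a crossing
log-odds effect of magnitude 3 (signed away from the baseline, so every
generated edge flips its child between a low and a high regime and is
identifiable from data), and the resulting probability is interpolated
toward its nearest one-hot row with weight `cpt_strength` (0.85 by
default; 1 gives deterministic networks). Covariate effects — which
covariate points into which feature, and a ±1.5 log-odds shift — are
shared across clusters, so covariates shift feature probabilities
identically in every cluster and carry no cluster information unless
confounding is switched on, in which case the covariate marginal becomes
a logistic function of the cluster index.

The confounded benchmark condition used by the acceptance checks
(`cpt_strength = 0.6`, `covariate_effect = 2.5`, `cov_edge_prob = 0.8`,
`confounding_strength = 1`) represents the regime the adjustment is for:
pervasive, strong covariate effects on moderately informative features,
with a moderate label-covariate association. Under it the adjusted fit
outperforms the same mixture with covariates treated as cluster-dependent
features, which in turn outperforms a Bernoulli mixture on the
feature-plus-covariate matrix.

What the generator does *not* emulate: missing data, measurement error,
variable-cardinality categorical features, within-gene mutation
heterogeneity, and the long-tailed prevalence spectrum of real mutation
panels. Passing tests on these cohorts demonstrates correctness of the
machinery and the expected qualitative orderings, not clinical
performance on any real cohort.

## Post-fit analyses

* **Stability.** `robustness_assessment()` re-runs the whole fit from
  independently perturbed uniform starts (the 0.1% rule) and reports the
  ARI of each restart against a reference fit.
* **Projection.** `mds_projection()` embeds samples by classical MDS of
  the Euclidean distances between their K-vectors of per-cluster
  conditional log-likelihoods. Axis signs are canonicalized by making
  the largest-magnitude loading positive, so coordinates are
  reproducible.
* **Entropy node scores.** For a categorical variable,
  $H(X) = -\sum_x p(x)\log p(x)$ (natural log) over the pooled cohort,
  $H_k$ within cluster $k$ (hard labels by argmax, ties to the lowest
  index), $H^\Delta_k = H_k - H$, and
  $S_k = 1 - (H^\Delta_k - \min_k H^\Delta_k) /
  (\lvert\max_k H^\Delta_k\rvert + \lvert\min_k H^\Delta_k\rvert)$, with
  min and max taken over clusters for the fixed variable so that node
  sizes are comparable across clusters. The cluster where the variable
  is most concentrated relative to the cohort scores 1, the least 0.
  Since the pooled entropy is at least the weighted mean of the cluster
  entropies, $\min_k H^\Delta_k \le 0$ always holds, and the denominator
  equals $\max - \min$ whenever some cluster is more entropic than the
  pool; if every cluster matches the pooled distribution (or the
  variable is constant) the score is defined as 0.5 for all clusters.
* **Edge annotation.** Edge signs are the sign of the
  membership-weighted correlation of the endpoint category codes within
  the cluster ("undefined" on zero variance). Orientation is reported
  as "undirected" when the edge is reversible within the DAG's Markov
  equivalence class — computed from the skeleton and v-structures with
  Meek-rule propagation — and with the learned direction otherwise.
* **Sub-stratification.** `sub_stratify()` splits one cluster's members
  at their median membership weight toward another cluster, a pure
  function of the membership matrix intended as the entry point for
  downstream survival contrasts (survival analysis itself is out of
  scope; only labels are exported).

## Preprocessing rules

Binary genomic features below 1% prevalence (computed over non-missing
entries) are dropped; covariates are never dropped. Continuous clinical
variables are median-split with ties at the median going to "low"
(deterministic; the cutoff is stored so unseen cohorts are discretized
with the *training* median, never their own). Bone-marrow blasts are
binned into 0–10 / 11–20 / 21–100 and peripheral-blood blasts into zero
vs 1–100, with non-integer percentages rounded half-to-even before
binning. Missing modelled values are rejected at fit time by default; a
configuration flag drops such samples with a warning instead, since how
the original cohort handled missingness is not documented.

## Numerical choices and limitations

All likelihood arithmetic is in log space; responsibilities use the
log-sum-exp pattern when $\chi = 0$ and absorb underflow into $\chi$
otherwise. CPT estimation is posterior-mean with pseudocount 1 (rows
never contain exact zeros unless fitted with a vanishing pseudocount).
Ties in hard labels go to the lowest cluster index. Model JSON
serialization writes full-precision numbers; write–read–write round
trips are byte-identical.

Known limitations: hill climbing finds local score optima only — the
structure-recovery tests measure skeleton F1 around 0.9, not exact
recovery; the number of clusters is user-specified (no automatic K
selection is attempted, since how K would best be chosen for the
motivating application is an open question); EM convergence is assessed
on memberships, not on the structure score, so alternating structure
updates may keep toggling an edge pair at equal score (the cadence and
warm start make this rare); and computation grows quickly with
`max_parents` and the number of variables — the test-suite problem sizes
(hundreds of samples, tens of variables) are the intended desk scale.

## Reproducing the package's numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates, from
scratch: the median recovery ARI on the default scenario, the three
mean ARIs of the confounded benchmark (adjusted, covariate-as-feature,
Bernoulli mixture), the median skeleton F1 at n = 5000, and the median
perturbed-restart robustness ARI. Problem sizes are chosen to keep the
full script in the minutes range: 10 recovery cohorts, 8 benchmark
replicates, 5 structure-recovery seeds, 10 robustness restarts.
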