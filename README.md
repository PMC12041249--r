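# covnetclust

Covariate-adjusted network-based clustering of binary genomic profiles
with clinical covariates.

## What it is for

Cancer cohorts — the motivating case is myeloid malignancies (AML, MDS,
CMML, MPN) — mix binary mutation/cytogenetic indicators with clinical
covariates. Clustering such patients runs into a dilemma: covariates like
age and sex either dominate the clustering (old-vs-young "clusters") or,
if dropped, confound it through their causal effects on the mutations.
`covnetclust` models each cluster as a categorical Bayesian network over
all variables while restricting *cluster-independent covariates* to
outgoing edges and conditioning on them in the cluster assignment, so
clusters reflect mutational patterns and their probabilistic
relationships rather than demographics.

The model is a K-component mixture

```
p(X_V) = Σ_k π_k · P(X_V | X_C, G_k, θ_k),
P(X_V | X_C, G_k, θ_k) = Π_{i∈V} P(X_i | X_C, X_pa(i)_k, θ_k)
```

with cluster responsibilities given by the adjusted membership function

```
φ̃(X_V | k) = (χ + γ_k · P(X_V | X_C, Ĝ_k, θ̂_k)) /
             (χK + Σ_k' γ_k' · P(X_V | X_C, Ĝ_k', θ̂_k'))
```

where `γ_k` is the mean membership of cluster k and `χ ≥ 0` an optional
regularizer. Cluster DAGs are learned by greedy hill climbing on a
weighted BDeu score under hard direction constraints (covariates
source-only; no blood/bone-marrow → genomic edges) and a prior-knowledge
edge penalty (unlisted gene-gene edges pay a factor 2 in prior odds).
Fitting is a staged EM: an independence-mixture stage grows a 0.1%
perturbation of uniform memberships into a stable partition, then
structure learning alternates with parametric EM.

Around the core fit the package provides: preprocessing rules for
clinical cohorts (1% prevalence filter, median splits with stored
cutoffs, clinical blast bins), classification of unseen cohorts under a
frozen model, cluster-stability assessment by adjusted Rand index over
perturbed restarts, a 2D MDS projection of per-sample network fit,
entropy-based node scores, edge sign/orientation annotation (undirected
when reversible within the Markov equivalence class), a synthetic-cohort
generator, and baseline comparators (Bernoulli mixture, k-means).

## Worked example

```r
library(covnetclust)

# a labelled synthetic cohort: 3 clusters, 20 binary features,
# 2 cluster-independent covariates, n = 600
sc <- simulation_scenario(K = 3, p_features = 20, n_covariates = 2,
                          n = 600, seed = 7)
cohort <- generate_cohort(sc)

fit <- network_mixture(cohort$data, K = 3, seed = 1)
fit
#> Covariate-adjusted network mixture
#>   K = 3 clusters, n = 600 samples, 22 variables
#>   chi = 0, 66 EM iterations (converged)
#>   cluster weights: 0.352 0.325 0.323

adjusted_rand_index(fit$labels, cohort$labels)
#> [1] 1
```

The fit recovers the generating partition exactly (ARI 1; 0 would be
chance level). The cluster weights estimate the mixture proportions
(truth: uniform 1/3). Downstream:

```r
summary(fit)                       # sizes, weights, edges, top features
head(predict(fit, newdata = cohort$data))   # memberships of (new) samples
summarize_cluster(fit, cluster = 1)         # node/edge tables for display
mds_projection(fit, fit$data)               # 2D fit-space coordinates
robustness_assessment(cohort$data, fit, n_restarts = 5)
#> [1] 0.5469383 1.0000000 0.5469383 1.0000000 1.0000000
```

The robustness distribution shows three of five perturbed restarts
reproducing the reference clustering exactly and two landing in a
different local optimum — exactly the kind of stability information the
restart protocol is meant to surface. File-based pipelines (preprocess → fit →
classify → report, with provenance-preserving discretization for unseen
cohorts) are available through `run_config()` / `run_preprocess()` /
`run_fit()` / `run_classify()` / `run_report()` and the thin CLI at
`inst/cli/covnetclust.R`.

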