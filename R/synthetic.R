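#' Define a simulation scenario
#'
#' Parameterizes the synthetic-cohort generator used for tests and
#' benchmarks: K cluster-specific random DAGs over binary genomic
#' features, binary covariates with outgoing causal edges into the
#' features, mixture proportions, CPT sharpness, and optional confounding
#' of the covariates with cluster identity.
#'
#' @param K Number of clusters.
#' @param p_features Number of binary genomic features.
#' @param n Cohort size.
#' @param n_covariates Number of binary cluster-independent covariates.
#' @param proportions Cluster proportions (default uniform); must sum to 1.
#' @param edge_density Probability of each feasible feature-feature edge in
#'   a cluster DAG.
#' @param cpt_strength In `[0, 1]`: how far CPT rows are pushed from their
#'   random draw toward a deterministic one-hot row (1 = deterministic).
#' @param covariate_effect Absolute log-odds shift a covariate exerts on
#'   the features it points into; identical across clusters.
#' @param cov_edge_prob Probability that a given covariate points into a
#'   given feature.
#' @param confounding If `TRUE`, the covariate distribution depends on the
#'   cluster label.
#' @param confounding_strength Log-odds scale of the label-covariate
#'   association.
#' @param parent_effect Absolute log-odds effect of each feature parent on
#'   its child (before sharpening); every parent has a consistent signed
#'   effect so that generated dependencies are identifiable.
#' @param max_parents Per-node parent cap in the generated DAGs.
#' @param seed Integer seed; all generation is reproducible under it.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(K = 3L, p_features = 20L, n = 600L,
                                n_covariates = 2L, proportions = NULL,
                                edge_density = 0.15, cpt_strength = 0.85,
                                covariate_effect = 1.5, cov_edge_prob = 0.3,
                                confounding = FALSE,
                                confounding_strength = 1.5,
                                parent_effect = 3, max_parents = 4L,
                                seed = 1L) {
  if (is.null(proportions)) proportions <- rep(1 / K, K)
  stopifnot(K >= 1, p_features >= 1, n >= 1, n_covariates >= 0,
            length(proportions) == K, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-8,
            edge_density >= 0, edge_density <= 1,
            cpt_strength >= 0, cpt_strength <= 1)
  if (edge_density * (p_features - 1) / 2 > max_parents)
    stop("infeasible density: expected parent count exceeds max_parents")
  structure(list(K = as.integer(K), p_features = as.integer(p_features),
                 n = as.integer(n), n_covariates = as.integer(n_covariates),
                 proportions = proportions, edge_density = edge_density,
                 cpt_strength = cpt_strength,
                 covariate_effect = covariate_effect,
                 cov_edge_prob = cov_edge_prob, confounding = confounding,
                 confounding_strength = confounding_strength,
                 parent_effect = parent_effect,
                 max_parents = as.integer(max_parents),
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

scenario_spec <- function(scenario) {
  specs <- list()
  for (c_ in seq_len(scenario$n_covariates))
    specs[[length(specs) + 1L]] <- variable_spec(
      sprintf("C%d", c_), "cluster_independent_covariate", "binary",
      modality = "demographic")
  for (i in seq_len(scenario$p_features))
    specs[[length(specs) + 1L]] <- variable_spec(
      sprintf("G%d", i), "genomic_feature", "binary", modality = "mutation")
  do.call(spec_table, specs)
}

decode_config <- function(j, cards) {
  # inverse of config_index: first parent slowest
  m <- length(cards)
  out <- integer(m)
  j <- j - 1L
  for (i in rev(seq_len(m))) {
    out[i] <- j %% cards[i] + 1L
    j <- j %/% cards[i]
  }
  out
}

sharpen <- function(p, strength) (1 - strength) * p + strength * round(p)

#' Generate the cluster-specific networks of a scenario
#'
#' Draws K Bayesian networks sharing node set and roles: covariates are
#' source-only; each cluster has its own random feature DAG at the
#' requested density; CPT rows are drawn uniformly then sharpened toward
#' one-hot by `cpt_strength`; covariate effects on features (edge set and
#' log-odds shifts) are shared across clusters, so covariates shift feature
#' probabilities identically in every cluster.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list of K `bayes_net` objects (reproducible under the
#'   scenario seed).
#' @export
generate_cluster_networks <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  spec <- scenario_spec(scenario)
  covs <- spec$name[spec$role == "cluster_independent_covariate"]
  feats <- spec$name[spec$role == "genomic_feature"]

  # shared covariate -> feature causal structure and effects
  cov_parents <- stats::setNames(
    lapply(feats, function(f)
      covs[stats::runif(length(covs)) < scenario$cov_edge_prob]), feats)
  beta <- matrix(sample(c(-1, 1), length(covs) * length(feats),
                        replace = TRUE) * scenario$covariate_effect,
                 nrow = length(covs), ncol = length(feats),
                 dimnames = list(covs, feats))

  # cluster-dependent covariate marginals (only differ under confounding)
  cov_marginal <- function(k, c_idx) {
    if (!scenario$confounding) return(0.5)
    sgn <- if (c_idx %% 2L == 0L) -1 else 1
    stats::plogis(sgn * scenario$confounding_strength *
                    (k - (scenario$K + 1) / 2))
  }

  nets <- vector("list", scenario$K)
  for (k in seq_len(scenario$K)) {
    dag <- new_dag(spec$name)
    ord <- sample(feats)
    for (j in seq_along(ord)) {
      child <- ord[j]
      for (pc in cov_parents[[child]])
        dag <- dag_add_edge(dag, pc, child, check = FALSE)
      if (j == 1L) next
      cand <- ord[seq_len(j - 1L)]
      pick <- cand[stats::runif(length(cand)) < scenario$edge_density]
      room <- scenario$max_parents - length(dag$parents[[child]])
      if (length(pick) > room) pick <- pick[seq_len(max(0L, room))]
      for (pa in pick) dag <- dag_add_edge(dag, pa, child, check = FALSE)
    }
    cards <- stats::setNames(n_categories(spec), spec$name)
    cpts <- vector("list", length(spec$name))
    names(cpts) <- spec$name
    for (v in spec$name) {
      pa <- dag$parents[[v]]
      r <- cards[[v]]
      q <- if (length(pa)) prod(cards[pa]) else 1L
      tab <- matrix(0, q, r)
      if (v %in% covs) {
        p1 <- cov_marginal(k, match(v, covs))
        tab[1L, ] <- c(1 - p1, p1)
      } else {
        fp <- setdiff(pa, covs)
        # each feature parent exerts a consistent signed log-odds effect
        # on a random baseline; the resulting row probabilities are then
        # sharpened toward one-hot by cpt_strength, and covariate parents
        # add their (cluster-shared) log-odds shifts afterwards so that
        # covariate effects survive the sharpening
        base0 <- stats::qlogis(stats::runif(1L, 0.2, 0.8))
        # parent effects push across the baseline so every generated edge
        # flips its child between a low and a high regime (identifiable
        # dependence even for low-prevalence children)
        b_fp <- stats::setNames(
          rep(-sign(base0) * scenario$parent_effect, length(fp)), fp)
        for (j in seq_len(q)) {
          codes <- decode_config(j, unname(cards[pa]))
          names(codes) <- pa
          raw <- stats::plogis(base0 + sum(b_fp * (codes[fp] - 1L)))
          p_base <- sharpen(raw, scenario$cpt_strength)
          shift <- sum(beta[pa[pa %in% covs], v] *
                         (codes[pa %in% covs] - 1L))
          p1 <- stats::plogis(stats::qlogis(p_base) + shift)
          if (is.nan(p1)) p1 <- p_base  # 0/1 base stays deterministic
          tab[j, ] <- c(1 - p1, p1)
        }
      }
      cpts[[v]] <- list(child = v, parents = pa, card = r,
                        parent_cards = unname(cards[pa]), table = tab)
    }
    nets[[k]] <- structure(list(dag = dag, cpts = cpts, spec = spec),
                           class = "bayes_net")
  }
  nets
}

#' Generate a labelled synthetic cohort
#'
#' Draws cluster labels from the scenario proportions and forward-samples
#' each sample from its cluster's network (covariates included; their
#' distribution depends on the label only when confounding is on).
#'
#' @param scenario A [simulation_scenario()].
#' @return A list with elements `data` (a `cohort_data`), `labels`
#'   (integer ground truth), and `networks` (the generating networks).
#' @export
generate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  nets <- generate_cluster_networks(scenario)  # seeds the RNG stream
  n <- scenario$n
  labels <- sample.int(scenario$K, n, replace = TRUE,
                       prob = scenario$proportions)
  rows <- vector("list", scenario$K)
  for (k in seq_len(scenario$K)) {
    nk <- sum(labels == k)
    if (nk) rows[[k]] <- bn_sample(nets[[k]], nk)$values
  }
  stacked <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  idx <- order(labels)
  vals <- stacked
  vals[idx, ] <- stacked
  rownames(vals) <- NULL
  list(data = cohort_data(vals, nets[[1L]]$spec, codes = TRUE),
       labels = labels,
       networks = nets)
}

#' Bernoulli mixture model clustering (EM baseline)
#'
#' Classical mixture of independent Bernoulli distributions fitted by EM;
#' the non-graph-based comparator in the simulation benchmarks.
#'
#' @param x Binary 0/1 matrix (samples by features).
#' @param K Number of clusters.
#' @param seed Integer seed for the responsibility initialisation.
#' @param max_iter,tol EM controls.
#' @return A list with `labels`, `responsibilities`, `prob` (K-by-p
#'   Bernoulli parameters) and `pi` (mixing weights).
#' @export
bernoulli_mixture <- function(x, K, seed = 1L, max_iter = 200L, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "numeric"
  n <- nrow(x)
  resp <- initialize_memberships(n, K, perturbation = 0.05, seed = seed)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    nk <- colSums(resp)
    pi_ <- nk / n
    prob <- (t(resp) %*% x + 1) / (nk + 2)  # Laplace-smoothed
    lp <- x %*% t(log(prob)) + (1 - x) %*% t(log(1 - prob))
    lp <- sweep(lp, 2L, log(pi_), "+")
    m <- apply(lp, 1L, max)
    ll <- sum(m + log(rowSums(exp(lp - m))))
    resp <- exp(lp - m)
    resp <- resp / rowSums(resp)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(labels = max.col(resp, ties.method = "first"),
       responsibilities = resp, prob = prob, pi = pi_)
}

set_roles <- function(spec, names, role) {
  spec$role[spec$name %in% names] <- role
  validate_spec(spec)
  spec
}

#' Benchmark clustering methods on synthetic cohorts
#'
#' Runs the simulation-study harness: for each replicate, generates a
#' cohort from the scenario and clusters it with each requested method,
#' scoring the hard labels against the ground truth by adjusted Rand
#' index. Methods: `"adjusted"` (the covariate-adjusted network mixture),
#' `"unadjusted"` (the same mixture with covariates re-declared as
#' cluster-dependent features), `"bernoulli"` (Bernoulli mixture on the
#' feature-plus-covariate matrix), `"kmeans"` (k-means on the same
#' matrix).
#'
#' @param scenario A [simulation_scenario()]; replicate r uses
#'   `scenario$seed + r - 1`.
#' @param replicates Number of replicate cohorts.
#' @param methods Character vector of methods to run.
#' @param n_starts Stage-1 starts per network-mixture fit (both arms).
#' @param ... Passed to [network_mixture()] (e.g. `structure_every`,
#'   `max_iter`).
#' @return A replicates-by-methods matrix of ARI values.
#' @export
benchmark_clustering <- function(scenario, replicates = 10L,
                                 methods = c("adjusted", "unadjusted",
                                             "bernoulli", "kmeans"),
                                 n_starts = 3L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- matrix(NA_real_, replicates, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(replicates)) {
    sc <- scenario
    sc$seed <- scenario$seed + r - 1L
    cohort <- generate_cohort(sc)
    truth <- cohort$labels
    raw <- as.matrix(cohort$data$values) - 1L  # back to 0/1
    for (m in methods) {
      labs <- switch(
        m,
        adjusted = network_mixture(cohort$data, K = sc$K, seed = sc$seed,
                                   n_starts = n_starts, ...)$labels,
        unadjusted = {
          d2 <- cohort$data
          d2$spec <- set_roles(d2$spec,
                               d2$spec$name[d2$spec$role ==
                                              "cluster_independent_covariate"],
                               "cluster_dependent_covariate")
          network_mixture(d2, K = sc$K, seed = sc$seed,
                          n_starts = n_starts, ...)$labels
        },
        bernoulli = bernoulli_mixture(raw, K = sc$K, seed = sc$seed)$labels,
        kmeans = {
          set.seed(sc$seed)
          stats::kmeans(raw, centers = sc$K, nstart = 10L)$cluster
        })
      out[r, m] <- adjusted_rand_index(labs, truth)
    }
  }
  out
}
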