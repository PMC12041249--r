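# Shared fixtures and independent oracles, built in code.

# small spec: one demographic covariate, mutations, one blood value
toy_spec <- function() {
  spec_table(
    variable_spec("age_high", "cluster_independent_covariate", "binary",
                  modality = "demographic"),
    variable_spec("TP53", "genomic_feature", "binary",
                  modality = "mutation"),
    variable_spec("ASXL1", "genomic_feature", "binary",
                  modality = "mutation"),
    variable_spec("HGB_high", "cluster_dependent_covariate", "binary",
                  modality = "blood"))
}

# random binary-only spec of p cluster-dependent features and optional
# covariates
binary_spec <- function(p, n_cov = 0L) {
  specs <- list()
  for (c_ in seq_len(n_cov))
    specs[[length(specs) + 1L]] <- variable_spec(
      sprintf("C%d", c_), "cluster_independent_covariate", "binary",
      modality = "demographic")
  for (i in seq_len(p))
    specs[[length(specs) + 1L]] <- variable_spec(
      sprintf("V%d", i), "genomic_feature", "binary", modality = "mutation")
  do.call(spec_table, specs)
}

# random Bayesian network over a binary spec: random DAG (covariates
# source-only) and Dirichlet-ish CPT rows
random_network <- function(p, n_cov = 0L, edge_prob = 0.3, seed = 1L) {
  set.seed(seed)
  spec <- binary_spec(p, n_cov)
  vars <- spec$name
  dag <- new_dag(vars)
  ci <- spec$name[spec$role == "cluster_independent_covariate"]
  for (j in seq_along(vars)) {
    for (i in seq_len(j - 1L)) {
      if (vars[j] %in% ci) next
      if (stats::runif(1) < edge_prob)
        dag <- dag_add_edge(dag, vars[i], vars[j], check = FALSE)
    }
  }
  cpts <- list()
  for (v in vars) {
    pa <- dag$parents[[v]]
    q <- if (length(pa)) 2L ^ length(pa) else 1L
    p1 <- stats::runif(q, 0.05, 0.95)
    cpts[[v]] <- list(child = v, parents = pa, card = 2L,
                      parent_cards = rep(2L, length(pa)),
                      table = cbind(1 - p1, p1))
  }
  structure(list(dag = dag, cpts = cpts, spec = spec), class = "bayes_net")
}

# independent enumeration oracle for the conditional likelihood: joint
# probability from first principles (product over ALL node CPT entries on
# expand.grid configurations), then P(x_V | x_C) = P(x) / sum over all
# cluster-dependent configurations with x_C fixed
oracle_conditional <- function(net, assignment) {
  vars <- net$dag$nodes
  spec <- net$spec
  ci <- spec$name[spec$role == "cluster_independent_covariate"]
  dep <- setdiff(vars, ci)
  joint_p <- function(x) {
    p <- 1
    for (v in vars) {
      cpt <- net$cpts[[v]]
      row <- 1L
      if (length(cpt$parents)) {
        cards <- cpt$parent_cards
        idx <- 0L
        for (j in seq_along(cpt$parents))
          idx <- idx * cards[j] + (x[[cpt$parents[j]]] - 1L)
        row <- idx + 1L
      }
      p <- p * cpt$table[row, x[[v]]]
    }
    p
  }
  num <- joint_p(assignment)
  grid <- do.call(expand.grid, stats::setNames(
    lapply(dep, function(v) seq_len(net$cpts[[v]]$card)), dep))
  den <- 0
  for (r in seq_len(nrow(grid))) {
    x <- assignment
    for (v in dep) x[[v]] <- grid[r, v]
    den <- den + joint_p(x)
  }
  unname(num / den)
}

# one-row cohort from a named list of codes
assignment_data <- function(assignment, spec) {
  cohort_data(as.data.frame(assignment), spec, codes = TRUE)
}

expect_valid_dag <- function(dag, constraints) {
  ed <- covnetclust:::dag_edges(dag)
  expect_true(covnetclust:::dag_is_acyclic(dag))
  if (nrow(ed)) expect_false(any(constraints$forbidden[ed]))
  expect_true(all(lengths(dag$parents) <= constraints$max_parents))
}

# closed-form weighted BDeu family score, written independently of the
# implementation (direct Gamma-function formula on a counts matrix)
bdeu_family_oracle <- function(counts, ess = 1) {
  q <- nrow(counts); r <- ncol(counts)
  aj <- ess / q; ajk <- ess / (q * r)
  s <- 0
  for (j in seq_len(q)) {
    s <- s + lgamma(aj) - lgamma(aj + sum(counts[j, ]))
    for (k in seq_len(r))
      s <- s + lgamma(ajk + counts[j, k]) - lgamma(ajk)
  }
  s
}
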