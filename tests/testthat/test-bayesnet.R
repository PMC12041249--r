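test_that("conditional log-likelihood matches the enumeration oracle", {
  # independence, uniform: 3 cluster-dependent binary nodes -> log(1/8)
  spec <- binary_spec(3)
  dag <- new_dag(spec$name)
  d_all <- cohort_data(data.frame(V1 = 1L, V2 = 2L, V3 = 1L), spec,
                       codes = TRUE)
  unif <- fit_cpts(dag, cohort_data(data.frame(V1 = 0:1, V2 = 0:1, V3 = 0:1),
                                    spec), weights = c(1, 1))
  expect_equal(bn_loglik(unif, d_all), log(1 / 8), tolerance = 1e-12)

  # random 5-node networks (with and without covariates) vs brute force
  for (seed in 1:20) {
    n_cov <- seed %% 3L  # 0, 1 or 2 covariates
    net <- random_network(5 - n_cov, n_cov = n_cov, seed = seed)
    set.seed(seed + 100)
    x <- as.list(stats::setNames(sample(1:2, 5, replace = TRUE),
                                 net$dag$nodes))
    d <- assignment_data(x, net$spec)
    expect_equal(exp(bn_loglik(net, d)), oracle_conditional(net, x),
                 tolerance = 1e-10)
  }
})

test_that("exp(log-likelihood) sums to one over cluster-dependent configurations", {
  net <- random_network(4, n_cov = 2, seed = 7)
  dep <- setdiff(net$dag$nodes,
                 net$spec$name[net$spec$role == "cluster_independent_covariate"])
  grid <- do.call(expand.grid, stats::setNames(
    rep(list(1:2), length(dep)), dep))
  for (cov_val in list(c(1L, 1L), c(2L, 1L), c(2L, 2L))) {
    full <- cbind(C1 = cov_val[1], C2 = cov_val[2], grid)
    d <- cohort_data(full, net$spec, codes = TRUE)
    expect_equal(sum(exp(bn_loglik(net, d))), 1, tolerance = 1e-9)
  }
})

test_that("covariate parents enter through the CPT row only", {
  # a covariate is the sole parent of a feature: likelihood is the CPT entry
  spec <- binary_spec(1, n_cov = 1)
  dag <- dag_add_edge(new_dag(spec$name), "C1", "V1")
  tab <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  net <- structure(list(
    dag = dag,
    cpts = list(C1 = list(child = "C1", parents = character(0), card = 2L,
                          parent_cards = integer(0),
                          table = matrix(c(0.5, 0.5), 1)),
                V1 = list(child = "V1", parents = "C1", card = 2L,
                          parent_cards = 2L, table = tab)),
    spec = spec), class = "bayes_net")
  d1 <- assignment_data(list(C1 = 1L, V1 = 2L), spec)
  d2 <- assignment_data(list(C1 = 2L, V1 = 2L), spec)
  expect_equal(exp(bn_loglik(net, d1)), 0.1, tolerance = 1e-12)
  expect_equal(exp(bn_loglik(net, d2)), 0.7, tolerance = 1e-12)

  dm <- assignment_data(list(C1 = 1L), spec[1, ])
  expect_error(bn_loglik(net, dm), "incomplete sample")
  expect_error(cohort_data(data.frame(C1 = 1L, V1 = 5L), spec),
               "invalid category")
})

test_that("CPT fitting is Laplace-smoothed weighted counting", {
  spec <- binary_spec(1)
  dag <- new_dag("V1")
  d <- cohort_data(data.frame(V1 = c(1L, 1L, 1L, 0L)), spec)
  # unit weights: counts (1, 3) -> pseudocount 1 -> (2/6, 4/6)
  net <- fit_cpts(dag, d, weights = rep(1, 4), pseudocount = 1)
  expect_equal(net$cpts$V1$table[1, ], c(2 / 6, 4 / 6), tolerance = 1e-12)

  # fractional weights: weighted counts (0.25, 2.25)
  net2 <- fit_cpts(dag, d, weights = c(1, 1, 0.25, 0.25), pseudocount = 0.5)
  expect_equal(net2$cpts$V1$table[1, ],
               c(0.75 / 3.5, 2.75 / 3.5), tolerance = 1e-12)

  # pseudocount -> 0 limit concentrates on the observed category
  net3 <- fit_cpts(dag, d, weights = c(0, 0, 0, 1), pseudocount = 1e-12)
  expect_equal(net3$cpts$V1$table[1, 1], 1, tolerance = 1e-9)

  # rows with zero weighted count become uniform
  spec2 <- binary_spec(2)
  dag2 <- dag_add_edge(new_dag(spec2$name), "V1", "V2")
  d2 <- cohort_data(data.frame(V1 = c(1L, 1L), V2 = c(0L, 1L)), spec2)
  net4 <- fit_cpts(dag2, d2, pseudocount = 1)
  expect_equal(net4$cpts$V2$table[1, ], c(0.5, 0.5))  # V1 = 0 never seen

  expect_error(fit_cpts(dag, d, weights = c(-1, 1, 1, 1)), "invalid weight")
})

test_that("forward sampling respects CPTs, clamping and the seed", {
  # deterministic network: all samples equal the forced configuration
  spec <- binary_spec(2, n_cov = 1)
  dag <- dag_add_edge(new_dag(spec$name), "V1", "V2")
  onehot <- function(child, parents, pc, rows) {
    list(child = child, parents = parents, card = 2L, parent_cards = pc,
         table = rows)
  }
  net <- structure(list(
    dag = dag,
    cpts = list(C1 = onehot("C1", character(0), integer(0),
                            matrix(c(0, 1), 1)),
                V1 = onehot("V1", character(0), integer(0),
                            matrix(c(0, 1), 1)),
                V2 = onehot("V2", "V1", 2L, rbind(c(1, 0), c(0, 1)))),
    spec = spec), class = "bayes_net")
  s <- bn_sample(net, 10, seed = 1)
  expect_true(all(s$values$C1 == 2L & s$values$V1 == 2L & s$values$V2 == 2L))

  # clamping forces covariate values
  s2 <- bn_sample(net, 5, covariate_values = list(C1 = 1L), seed = 1)
  expect_true(all(s2$values$C1 == 1L))
  expect_error(bn_sample(net, 2, covariate_values = list(C1 = 9L)),
               "invalid category")

  # same seed, same draw; empirical frequency near the CPT marginal
  net_r <- random_network(3, seed = 5)
  a <- bn_sample(net_r, 100, seed = 42)
  b <- bn_sample(net_r, 100, seed = 42)
  expect_identical(a$values, b$values)

  root <- net_r$dag$nodes[lengths(net_r$dag$parents) == 0][1]
  p1 <- net_r$cpts[[root]]$table[1, 2]
  big <- bn_sample(net_r, 20000, seed = 9)
  se <- sqrt(p1 * (1 - p1) / 20000)
  expect_lt(abs(mean(big$values[[root]] == 2L) - p1), 3 * se + 1e-3)
})

test_that("network score is weighted BDeu plus the log edge prior", {
  spec <- binary_spec(2)
  d <- cohort_data(data.frame(V1 = c(0, 0, 0, 0, 1, 1, 1, 1),
                              V2 = c(0, 0, 1, 1, 0, 1, 1, 1)), spec)
  e01 <- new_dag(spec$name)
  e1 <- dag_add_edge(e01, "V1", "V2")

  # hand-computed BDeu from the closed-form Gamma expression
  w <- rep(1, 8)
  s_v1 <- bdeu_family_oracle(matrix(c(4, 4), 1))
  s_v2_empty <- bdeu_family_oracle(matrix(c(3, 5), 1))
  s_v2_edge <- bdeu_family_oracle(rbind(c(2, 2), c(1, 3)))
  expect_equal(score_network(e01, d, w), s_v1 + s_v2_empty,
               tolerance = 1e-12)
  expect_equal(score_network(e1, d, w), s_v1 + s_v2_edge, tolerance = 1e-12)

  # all weights zero: only the prior term remains
  pr <- edge_prior(spec, NULL, penalty_factor = 2)
  expect_equal(score_network(e1, d, rep(0, 8), prior = pr), -log(2),
               tolerance = 1e-12)
  expect_equal(score_network(e01, d, rep(0, 8), prior = pr), 0)

  # adding a non-prior edge changes the score by the family delta minus
  # exactly log 2 at penalty factor 2
  delta_family <- s_v2_edge - s_v2_empty
  expect_equal(score_network(e1, d, w, prior = pr) -
                 score_network(e01, d, w, prior = pr),
               delta_family - log(2), tolerance = 1e-12)

  expect_error(score_network(e1, d, rep(-1, 8)), "invalid weight")
})

test_that("the score is decomposable across families", {
  net <- random_network(5, seed = 11)
  d <- bn_sample(net, 60, seed = 2)
  spec <- net$spec
  pr <- edge_prior(spec, rbind(c("V1", "V2")), penalty_factor = 2)
  dag_a <- new_dag(spec$name, rbind(c("V1", "V3"), c("V2", "V4")))
  dag_b <- dag_add_edge(dag_a, "V1", "V4")  # only V4's family changes
  w <- runif(60)
  full_delta <- score_network(dag_b, d, w, pr) - score_network(dag_a, d, w, pr)
  cards <- c(2L, 2L)
  fam <- function(pa) covnetclust:::family_score_bdeu(
    d$values$V4, lapply(pa, function(p) d$values[[p]]), 2L,
    rep(2L, length(pa)), w, 1)
  family_delta <- fam(c("V1", "V2")) - fam("V2")
  expect_equal(full_delta,
               family_delta + covnetclust:::prior_log_multiplier(pr, "V1", "V4"),
               tolerance = 1e-10)
})

test_that("DAG utilities enforce acyclicity and detect cycles", {
  dag <- new_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_error(dag_add_edge(dag, "c", "a"), "cycle")
  expect_error(new_dag(c("a", "a")), "duplicate")
  expect_error(dag_add_edge(dag, "a", "a"), "self-loop")
  expect_equal(covnetclust:::dag_topo_sort(dag), c("a", "b", "c"))
})
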