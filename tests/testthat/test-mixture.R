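test_that("adjusted memberships follow the regularized weighting formula", {
  # scalar case with hand-set likelihoods P = (0.2, 0.1), gamma uniform
  L <- matrix(log(c(0.2, 0.1)), nrow = 1)
  m0 <- covnetclust:::memberships_from_loglik(L, c(0.5, 0.5), chi = 0)
  expect_equal(as.numeric(m0), c(2 / 3, 1 / 3), tolerance = 1e-12)

  # chi = 0.05: (0.05 + 0.5*0.2) / (0.05*2 + 0.5*0.2 + 0.5*0.1) = 0.15/0.25
  m1 <- covnetclust:::memberships_from_loglik(L, c(0.5, 0.5), chi = 0.05)
  expect_equal(as.numeric(m1), c(0.15 / 0.25, 0.10 / 0.25),
               tolerance = 1e-12)

  # rows always sum to 1 across randomized models and chi values
  set.seed(3)
  for (chi in c(0, 1e-6, 0.05, 1, 1e12)) {
    L <- matrix(log(runif(60 * 4)), 60, 4)
    m <- covnetclust:::memberships_from_loglik(L, rep(0.25, 4), chi)
    expect_equal(rowSums(m), rep(1, 60), tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
})

test_that("membership limits: K = 1, identical networks, huge chi", {
  net <- random_network(4, seed = 2)
  d <- bn_sample(net, 30, seed = 3)

  one <- list(networks = list(net), gamma = 1, chi = 0)
  expect_equal(as.numeric(adjusted_memberships(one, d)), rep(1, 30))

  # identical networks with uniform gamma: uniform rows for any chi
  for (chi in c(0, 0.3)) {
    same <- list(networks = list(net, net, net), gamma = rep(1 / 3, 3),
                 chi = chi)
    m <- adjusted_memberships(same, d)
    expect_equal(m, matrix(1 / 3, 30, 3), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  # chi -> infinity flattens distinct networks to uniform
  other <- random_network(4, seed = 9)
  big <- list(networks = list(net, other), gamma = c(0.7, 0.3), chi = 1e12)
  m2 <- adjusted_memberships(big, d)
  expect_true(all(abs(m2 - 0.5) < 1e-6))
})

test_that("initial memberships implement the perturbed-uniform rule", {
  # perturbation 0: exactly uniform
  expect_equal(initialize_memberships(5, 3, 0, seed = 1),
               matrix(1 / 3, 5, 3))

  # K = 2, 0.1%: rows are (1.001, 1) / 2.001 in one order or the other
  m <- initialize_memberships(200, 2, 0.001, seed = 7)
  hi <- 1.001 / 2.001
  lo <- 1 / 2.001
  expect_true(all(abs(apply(m, 1, max) - hi) < 1e-12))
  expect_true(all(abs(apply(m, 1, min) - lo) < 1e-12))
  # both columns get perturbed somewhere (uniformly sampled cluster)
  expect_true(all(colSums(m > 0.5) > 0))

  expect_identical(initialize_memberships(50, 3, 0.001, seed = 5),
                   initialize_memberships(50, 3, 0.001, seed = 5))
})

test_that("EM recovers well-separated clusters and degenerate K = 1 works", {
  sc <- simulation_scenario(K = 2, p_features = 10, n = 400,
                            cpt_strength = 0.9, seed = 5)
  co <- generate_cohort(sc)
  fit <- network_mixture(co$data, K = 2, seed = 1)
  expect_gte(adjusted_rand_index(fit$labels, co$labels), 0.95)
  expect_equal(rowSums(fit$memberships), rep(1, 400), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(fit$gamma), 1, tolerance = 1e-12)

  fit1 <- network_mixture(co$data, K = 1, seed = 1)
  expect_equal(as.numeric(fit1$memberships), rep(1, 400))
  expect_equal(fit1$gamma, 1, ignore_attr = TRUE)
  # K = 1 reduces to single-network structure learning on unit weights
  expect_gt(sum(lengths(fit1$networks[[1]]$dag$parents)), 0)
})

test_that("EM with chi = 0 and fixed structures never decreases the log-likelihood", {
  for (seed in 1:3) {
    sc <- simulation_scenario(K = 2, p_features = 6, n = 150,
                              cpt_strength = 0.7, seed = seed)
    co <- generate_cohort(sc)
    dags <- lapply(co$networks, function(nw) nw$dag)
    fit <- network_mixture(co$data, K = 2, chi = 0, seed = seed,
                           structures = dags, pseudocount = 1e-9,
                           max_iter = 40)
    expect_true(all(diff(fit$loglik) >= -1e-8))
  }
})

test_that("duplicating every sample leaves the fit unchanged per unique sample", {
  sc <- simulation_scenario(K = 2, p_features = 6, n = 80,
                            cpt_strength = 0.9, seed = 12)
  co <- generate_cohort(sc)
  dags <- lapply(co$networks, function(nw) nw$dag)
  init <- initialize_memberships(80, 2, 0.05, seed = 3)

  dup_vals <- rbind(co$data$values, co$data$values)
  rownames(dup_vals) <- NULL
  dup <- cohort_data(dup_vals, co$data$spec, codes = TRUE)

  f1 <- network_mixture(co$data, K = 2, structures = dags, chi = 0,
                        pseudocount = 1e-9, init = init, seed = 1)
  f2 <- network_mixture(dup, K = 2, structures = dags, chi = 0,
                        pseudocount = 1e-9, init = rbind(init, init),
                        seed = 1)
  expect_equal(f2$memberships[1:80, ], f1$memberships, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f2$networks[[1]]$cpts$G1$table, f1$networks[[1]]$cpts$G1$table,
               tolerance = 1e-8)
})

test_that("classification freezes the model and checks cohort compatibility", {
  sc <- simulation_scenario(K = 2, p_features = 8, n = 200,
                            cpt_strength = 0.9, seed = 8)
  co <- generate_cohort(sc)
  fit <- network_mixture(co$data, K = 2, seed = 1)

  # classifying the training data reproduces the stored memberships
  phi <- predict(fit, newdata = co$data)
  expect_equal(phi, fit$memberships, tolerance = 1e-12, ignore_attr = TRUE)

  # a new sample identical to a training sample gets the same row
  d1 <- cohort_data(co$data$values[3, , drop = FALSE], co$data$spec,
                    codes = TRUE)
  expect_equal(as.numeric(predict(fit, newdata = d1)),
               as.numeric(fit$memberships[3, ]), tolerance = 1e-12)

  # extra variables are ignored with a notice
  extra_vals <- cbind(co$data$values,
                      EXTRA = rep(1L, 200))
  extra_spec <- rbind(co$data$spec,
                      variable_spec("EXTRA", "genomic_feature", "binary",
                                    modality = "mutation"))
  extra <- cohort_data(extra_vals, extra_spec, codes = TRUE)
  expect_message(phi2 <- predict(fit, newdata = extra), "extra")
  expect_equal(phi2, phi, tolerance = 1e-12, ignore_attr = TRUE)

  # missing model variable is an error
  miss <- cohort_data(co$data$values[, -3],
                      co$data$spec[-3, ], codes = TRUE)
  expect_error(predict(fit, newdata = miss), "incompatible cohort")
})

test_that("a sample matching a cluster's deterministic signature is classified to it", {
  # two clusters with opposite deterministic feature patterns
  spec <- binary_spec(4)
  dag <- new_dag(spec$name)
  all1 <- cohort_data(data.frame(V1 = 1L, V2 = 1L, V3 = 1L, V4 = 1L), spec)
  all0 <- cohort_data(data.frame(V1 = 0L, V2 = 0L, V3 = 0L, V4 = 0L), spec)
  net1 <- fit_cpts(dag, all1, pseudocount = 1e-6)
  net0 <- fit_cpts(dag, all0, pseudocount = 1e-6)
  model <- structure(list(K = 2, networks = list(net1, net0),
                          gamma = c(0.5, 0.5), chi = 0, spec = spec),
                     class = "network_mixture")
  expect_equal(predict(model, newdata = all1, type = "label"), 1L)
  expect_equal(predict(model, newdata = all0, type = "label"), 2L)
})

test_that("cluster labels are invariant to relabelling", {
  sc <- simulation_scenario(K = 3, p_features = 8, n = 150,
                            cpt_strength = 0.9, seed = 15)
  co <- generate_cohort(sc)
  fit <- network_mixture(co$data, K = 3, seed = 2)
  perm <- c(2, 3, 1)
  permuted <- list(networks = fit$networks[perm], gamma = fit$gamma[perm],
                   chi = fit$chi)
  m <- adjusted_memberships(fit, co$data)
  mp <- adjusted_memberships(permuted, co$data)
  expect_equal(mp, m[, perm], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(adjusted_rand_index(max.col(mp), max.col(m)), 1)
})
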