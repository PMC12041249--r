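test_that("adjusted Rand index matches pair-counting arithmetic", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # relabelling leaves it at 1
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # hand-computed from the contingency table: all pair counts cancel to
  # (0 - 2/3) / (2 - 2/3) = -1/2
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  # symmetry
  a <- c(1, 2, 1, 3, 2, 1)
  b <- c(2, 2, 1, 3, 3, 1)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("robustness assessment reproduces the reference under zero perturbation", {
  sc <- simulation_scenario(K = 2, p_features = 8, n = 150,
                            cpt_strength = 0.9, seed = 2)
  co <- generate_cohort(sc)
  # exact uniform weights are a fixed point of the EM, so the
  # deterministic reference uses the same zero-perturbation protocol
  ref <- network_mixture(co$data, K = 2, seed = 1, perturbation = 0)
  aris <- robustness_assessment(co$data, ref, n_restarts = 2,
                                perturbation = 0)
  expect_equal(aris, c(1, 1))
  one <- robustness_assessment(co$data, ref, n_restarts = 1)
  expect_length(one, 1)
})

test_that("MDS embedding preserves exactly embeddable distances", {
  # fit vectors forming a 3-4-5 right triangle embed exactly
  L <- rbind(c(0, 0), c(-3, 0), c(-3, -4))
  xy <- covnetclust:::mds_embed(L)
  d <- as.matrix(dist(xy))
  expect_equal(sort(d[upper.tri(d)]), c(3, 4, 5), tolerance = 1e-6)

  # identical fit vectors map to identical coordinates; model-level call
  sc <- simulation_scenario(K = 2, p_features = 6, n = 40,
                            cpt_strength = 0.9, seed = 3)
  co <- generate_cohort(sc)
  fit <- network_mixture(co$data, K = 2, seed = 1)
  dup_vals <- rbind(co$data$values, co$data$values[1:5, ])
  rownames(dup_vals) <- NULL
  dup <- cohort_data(dup_vals, co$data$spec, codes = TRUE)
  xy2 <- mds_projection(fit, dup)
  expect_equal(unname(xy2[41:45, ]), unname(xy2[1:5, ]), tolerance = 1e-8)
  # deterministic under the sign canonicalization
  expect_equal(mds_projection(fit, dup), xy2)

  few <- cohort_data(co$data$values[1:2, ], co$data$spec, codes = TRUE)
  expect_error(mds_projection(fit, few), "too few samples")
})

test_that("entropy node scores follow the normalized cluster-entropy formulas", {
  # uniform binary variable: H = ln 2
  spec <- binary_spec(1)
  d <- cohort_data(data.frame(V1 = rep(c(0, 1), 10)), spec)
  phi <- cbind(rep(c(1, 0), each = 10), rep(c(0, 1), each = 10))
  s <- entropy_node_score(d, phi, "V1")
  expect_equal(attr(s, "H"), log(2), tolerance = 1e-12)

  # cluster frequencies equal to overall: degenerate convention 0.5
  d2 <- cohort_data(data.frame(V1 = rep(c(0, 1), 10)), spec)
  # consecutive pairs alternate clusters, so each cluster sees (0.5, 0.5)
  phi2 <- cbind(rep(c(1, 1, 0, 0), 5), rep(c(0, 0, 1, 1), 5))
  s2 <- entropy_node_score(d2, phi2, "V1")
  expect_equal(as.numeric(s2), c(0.5, 0.5))
  expect_equal(attr(s2, "H_delta"), c(0, 0), tolerance = 1e-12)

  # hand-worked two-cluster example: p1 = (0.9, 0.1), p2 = (0.5, 0.5),
  # overall (0.7, 0.3)
  x <- c(rep(0, 9), 1, rep(0, 5), rep(1, 5))
  d3 <- cohort_data(data.frame(V1 = x), spec)
  phi3 <- cbind(rep(c(1, 0), c(10, 10)), rep(c(0, 1), c(10, 10)))
  s3 <- entropy_node_score(d3, phi3, "V1")
  H <- -(0.7 * log(0.7) + 0.3 * log(0.3))
  H1 <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  H2 <- log(2)
  expect_equal(attr(s3, "H"), H, tolerance = 1e-12)
  expect_equal(attr(s3, "H_k"), c(H1, H2), tolerance = 1e-12)
  # the low-entropy (most concentrated) cluster scores 1, the other 0
  expect_equal(as.numeric(s3), c(1, 0), tolerance = 1e-12)

  # constant variable: degenerate 0.5 everywhere
  d4 <- cohort_data(data.frame(V1 = rep(1, 20)), spec)
  s4 <- entropy_node_score(d4, phi3, "V1")
  expect_equal(as.numeric(s4), c(0.5, 0.5))

  # randomized inputs stay within [0, 1]
  set.seed(8)
  for (r in 1:10) {
    dr <- cohort_data(data.frame(V1 = rbinom(60, 1, runif(1, 0.2, 0.8))),
                      spec)
    phir <- initialize_memberships(60, 3, 0.5, seed = r)
    sr <- entropy_node_score(dr, phir, "V1")
    expect_true(all(sr >= 0 & sr <= 1))
  }
})

test_that("edge signs reflect weighted correlation and orientation the equivalence class", {
  spec <- binary_spec(3)
  # chain V1 -> V2 -> V3: no v-structure, so edges are reversible
  chain <- new_dag(spec$name, rbind(c("V1", "V2"), c("V2", "V3")))
  set.seed(4)
  x <- rbinom(200, 1, 0.5)
  vals <- data.frame(V1 = x, V2 = x, V3 = 1 - x)  # V2 = V1, V3 = NOT V2
  d <- cohort_data(vals, spec)
  net <- fit_cpts(chain, d)
  model <- structure(list(K = 1, networks = list(net), gamma = 1, chi = 0,
                          spec = spec, memberships = matrix(1, 200, 1)),
                     class = "network_mixture")
  ann <- edge_signs(model, d, cluster = 1)
  expect_equal(ann$orientation, c("undirected", "undirected"))
  expect_equal(ann$sign[ann$parent == "V1"], "+")
  expect_equal(ann$sign[ann$parent == "V2"], "-")

  # v-structure V1 -> V3 <- V2: both edges compelled
  vee <- new_dag(spec$name, rbind(c("V1", "V3"), c("V2", "V3")))
  net2 <- fit_cpts(vee, d)
  model2 <- structure(list(K = 1, networks = list(net2), gamma = 1, chi = 0,
                           spec = spec, memberships = matrix(1, 200, 1)),
                      class = "network_mixture")
  ann2 <- edge_signs(model2, d, cluster = 1)
  expect_equal(ann2$orientation, c("directed", "directed"))

  # zero-variance endpoint: undefined sign
  vals3 <- data.frame(V1 = rep(1, 50), V2 = rbinom(50, 1, 0.5),
                      V3 = rbinom(50, 1, 0.5))
  d3 <- cohort_data(vals3, spec)
  net3 <- fit_cpts(new_dag(spec$name, rbind(c("V1", "V2"))), d3)
  model3 <- structure(list(K = 1, networks = list(net3), gamma = 1, chi = 0,
                           spec = spec, memberships = matrix(1, 50, 1)),
                      class = "network_mixture")
  expect_message(ann3 <- edge_signs(model3, d3, cluster = 1),
                 "zero within-cluster variance")
  expect_equal(ann3$sign, "undefined")
})

test_that("cluster summaries rank variables by degree then frequency", {
  sc <- simulation_scenario(K = 2, p_features = 6, n = 120,
                            cpt_strength = 0.9, seed = 6)
  co <- generate_cohort(sc)
  fit <- network_mixture(co$data, K = 2, seed = 1)
  s <- summarize_cluster(fit, cluster = 1, top_m = 3)
  expect_s3_class(s, "cluster_summary")
  expect_equal(nrow(s$nodes), nrow(co$data$spec))
  expect_equal(sum(s$nodes$displayed), 3)
  # ranking respects (degree, frequency) ordering
  o <- order(-s$nodes$degree, -s$nodes$frequency, s$nodes$name)
  expect_equal(o, seq_len(nrow(s$nodes)))
  # top_m beyond p returns everything
  s_all <- summarize_cluster(fit, cluster = 1, top_m = 100)
  expect_true(all(s_all$nodes$displayed))
  # a feature present in every weighted sample has frequency 1
  hard <- fit
  hard$memberships <- cbind(as.numeric(co$data$values$G1 == 2L),
                            as.numeric(co$data$values$G1 != 2L))
  s2 <- summarize_cluster(hard, memberships = hard$memberships, cluster = 1)
  expect_equal(s2$nodes$frequency[s2$nodes$name == "G1"], 1)
})

test_that("sub-stratification is a pure function of the membership matrix", {
  phi <- rbind(c(0.6, 0.4), c(0.7, 0.3), c(0.9, 0.1), c(0.2, 0.8))
  out <- sub_stratify(phi, cluster = 1, toward = 2)
  expect_true(is.na(out[4]))
  # member weights toward cluster 2: 0.4, 0.3, 0.1; median 0.3
  expect_equal(out[1:3], c(2L, 1L, 1L))
})
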