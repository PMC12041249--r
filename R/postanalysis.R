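#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions up
#' to relabelling, expectation about 0 for independent random partitions.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Cluster stability under perturbed restarts
#'
#' Re-runs the whole clustering from independently perturbed uniform
#' starting memberships (the 0.1% rule of [initialize_memberships()]) and
#' scores each restart's hard labels against a reference fit by adjusted
#' Rand index.
#'
#' @param data The `cohort_data` used for the reference fit.
#' @param reference A fitted `network_mixture` (or a reference label
#'   vector).
#' @param n_restarts Number of perturbed restarts.
#' @param perturbation Relative weight perturbation; default 0.001 (0.1%).
#' @param seeds Integer seeds, one per restart; defaults to
#'   `reference$seed + 1:n_restarts` (or `1:n_restarts`).
#' @param ... Passed to [network_mixture()]; `K` defaults to the
#'   reference's.
#' @param K Number of clusters.
#' @return Numeric vector of ARI values, one per restart.
#' @export
robustness_assessment <- function(data, reference, n_restarts = 20L,
                                  perturbation = 0.001, seeds = NULL,
                                  K = NULL, ...) {
  if (inherits(reference, "network_mixture")) {
    ref_labels <- reference$labels
    if (is.null(K)) K <- reference$K
    base_seed <- reference$seed
  } else {
    ref_labels <- reference
    if (is.null(K)) K <- length(unique(ref_labels))
    base_seed <- 0L
  }
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_restarts)
  stopifnot(length(seeds) == n_restarts)
  vapply(seq_len(n_restarts), function(r) {
    init <- initialize_memberships(nrow(data$values), K, perturbation,
                                   seed = seeds[r])
    fit <- network_mixture(data, K = K, seed = seeds[r], init = init, ...)
    adjusted_rand_index(fit$labels, ref_labels)
  }, numeric(1))
}

#' Project samples by their fit to the cluster networks
#'
#' Each sample is described by its K-vector of per-cluster conditional
#' log-likelihoods; classical (Torgerson) multidimensional scaling of the
#' Euclidean distances between these fit vectors gives 2D coordinates.
#' Axis signs are canonicalized (the largest-magnitude loading on each
#' axis is made positive) so the embedding is deterministic up to the
#' inherent rotation of MDS.
#'
#' @param model A fitted `network_mixture`.
#' @param data A `cohort_data` (>= 3 samples).
#' @return An n-by-2 coordinate matrix.
#' @export
mds_projection <- function(model, data) {
  if (nrow(data$values) < 3L) stop("too few samples to embed")
  L <- vapply(model$networks, bn_loglik, numeric(nrow(data$values)),
              data = data)
  L <- matrix(L, nrow = nrow(data$values))
  xy <- mds_embed(L)
  rownames(xy) <- data$samples
  xy
}

# classical MDS of fit-vector rows with sign canonicalization
mds_embed <- function(L) {
  xy <- stats::cmdscale(stats::dist(L), k = 2L)
  if (ncol(xy) < 2L)
    xy <- cbind(xy, matrix(0, nrow(xy), 2L - ncol(xy)))
  for (j in 1:2) {
    i <- which.max(abs(xy[, j]))
    if (length(i) && xy[i, j] < 0) xy[, j] <- -xy[, j]
  }
  colnames(xy) <- c("MDS1", "MDS2")
  xy
}

#' Normalized cluster-specific entropy score of a variable
#'
#' Quantifies how informative a categorical variable is for each cluster.
#' With `p(x)` the overall relative frequency and `p_k(x)` the frequency
#' within cluster k (hard labels = argmax memberships, ties to the lowest
#' index), the overall Shannon entropy is `H(X) = -sum p(x) log p(x)`
#' (natural log), the cluster-specific entropy `H_k(X)` uses `p_k`, and
#' the difference is `Hd_k = H_k - H`. The normalized score is
#' `S_k = 1 - (Hd_k - min_k Hd_k) / (|max_k Hd_k| + |min_k Hd_k|)`, with
#' the min/max taken over clusters for the given variable, so `S_k = 1`
#' for the cluster where the variable is most concentrated relative to the
#' cohort and `S_k = 0` where it is least. If all clusters equal the
#' overall distribution (or the variable is constant) the score is the
#' declared degenerate convention 0.5 for every cluster.
#'
#' @param data A `cohort_data`.
#' @param memberships n-by-K membership matrix.
#' @param variable Name of a discrete variable.
#' @return Numeric K-vector of scores in `[0, 1]`, with attributes `H`
#'   (overall entropy), `H_k` and `H_delta`.
#' @export
entropy_node_score <- function(data, memberships, variable) {
  j <- spec_row(data$spec, variable)
  if (data$spec$dtype[j] == "continuous")
    stop("entropy score requires a discrete variable")
  K <- ncol(memberships)
  labels <- max.col(memberships, ties.method = "first")
  x <- data$values[[variable]]
  r <- length(data$spec$categories[[j]])
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  p_all <- tabulate(x, nbins = r) / length(x)
  H <- ent(p_all)
  Hk <- vapply(seq_len(K), function(k) {
    xk <- x[labels == k]
    if (!length(xk)) return(H)  # empty cluster: no deviation
    ent(tabulate(xk, nbins = r) / length(xk))
  }, numeric(1))
  Hd <- Hk - H
  denom <- abs(max(Hd)) + abs(min(Hd))
  S <- if (denom < 1e-12) rep(0.5, K) else 1 - (Hd - min(Hd)) / denom
  attr(S, "H") <- H
  attr(S, "H_k") <- Hk
  attr(S, "H_delta") <- Hd
  S
}

# CPDAG of a DAG: edges compelled by v-structures plus Meek-rule closure
# are directed; the rest are reversible within the Markov equivalence
# class and reported undirected.
compelled_edges <- function(dag) {
  vars <- dag$nodes
  p <- length(vars)
  adj <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  ed <- dag_edges(dag)
  if (nrow(ed)) adj[ed] <- TRUE
  skel <- adj | t(adj)
  dir <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  # v-structures: a -> v <- b with a, b non-adjacent
  for (v in vars) {
    pa <- dag$parents[[v]]
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in seq(i + 1L, length(pa))) {
      a <- pa[i]; b <- pa[j]
      if (!skel[a, b]) { dir[a, v] <- TRUE; dir[b, v] <- TRUE }
    }
  }
  und <- skel & !(dir | t(dir))
  repeat {
    changed <- FALSE
    orient <- function(a, b) {
      # orient a - b as a -> b, but never against the DAG's own direction
      # for an edge the rules force; Meek closure on a consistent DAG
      # always orients along some member of the class, so record a -> b
      dir[a, b] <<- TRUE
      und[a, b] <<- FALSE; und[b, a] <<- FALSE
      changed <<- TRUE
    }
    for (a in vars) for (b in vars) {
      if (!und[a, b]) next
      # R1: c -> a, a - b, c and b non-adjacent  =>  a -> b
      for (c_ in vars[dir[, a]])
        if (!skel[c_, b] && c_ != b) { orient(a, b); break }
      if (!und[a, b]) next
      # R2: a -> c -> b and a - b  =>  a -> b
      if (any(dir[a, ] & dir[, b])) { orient(a, b); next }
      # R3: a - c -> b, a - d -> b, c and d non-adjacent, a - b  =>  a -> b
      cs <- vars[und[a, ] & dir[, b]]
      if (length(cs) >= 2L) {
        pairs <- utils::combn(cs, 2L)
        if (any(!skel[t(pairs)])) { orient(a, b); next }
      }
    }
    if (!changed) break
  }
  dir
}

#' Annotate a cluster network's edges with sign and orientation
#'
#' For each edge of the chosen cluster's DAG, reports the sign of the
#' membership-weighted correlation between the two variables' category
#' codes within the cluster (`"+"`, `"-"`, or `"undefined"` when an
#' endpoint has zero within-cluster variance), and whether the learned
#' direction is compelled by the DAG's Markov equivalence class
#' (`"directed"`) or reversible within it (`"undirected"`).
#'
#' @param model A fitted `network_mixture`.
#' @param data A `cohort_data`.
#' @param memberships n-by-K membership matrix (default the model's).
#' @param cluster Cluster index.
#' @return A `data.frame` with columns parent, child, orientation, sign,
#'   correlation.
#' @export
edge_signs <- function(model, data, memberships = model$memberships,
                       cluster = 1L) {
  dag <- model$networks[[cluster]]$dag
  ed <- dag_edges(dag)
  w <- memberships[, cluster]
  dirm <- compelled_edges(dag)
  out <- data.frame(parent = character(0), child = character(0),
                    orientation = character(0), sign = character(0),
                    correlation = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(ed)) return(out)
  wmean <- function(z) sum(w * z) / sum(w)
  for (i in seq_len(nrow(ed))) {
    a <- ed[i, 1L]; b <- ed[i, 2L]
    x <- as.numeric(data$values[[a]])
    y <- as.numeric(data$values[[b]])
    vx <- wmean(x^2) - wmean(x)^2
    vy <- wmean(y^2) - wmean(y)^2
    if (vx <= 1e-12 || vy <= 1e-12) {
      message("zero within-cluster variance on edge ", a, " -> ", b)
      sgn <- "undefined"; cor_w <- NA_real_
    } else {
      cor_w <- (wmean(x * y) - wmean(x) * wmean(y)) / sqrt(vx * vy)
      sgn <- if (cor_w >= 0) "+" else "-"
    }
    out[nrow(out) + 1L, ] <-
      list(a, b, if (dirm[a, b]) "directed" else "undirected", sgn, cor_w)
  }
  out
}

#' Summarize one cluster of a fitted mixture
#'
#' Collects, for a chosen cluster: membership-weighted frequencies of the
#' discrete variables (for binary variables, the prevalence of the
#' altered/high category), optional means of raw continuous companions,
#' the normalized entropy scores of [entropy_node_score()], and the
#' sign/orientation-annotated edge list. Variables are ranked by
#' (degree within the cluster network, frequency), and the `top_m` ranked
#' variables are flagged for display.
#'
#' @param model A fitted `network_mixture`.
#' @param data A `cohort_data` (default the training data).
#' @param memberships Membership matrix (default the model's).
#' @param cluster Cluster index.
#' @param top_m How many variables to flag for display (values above the
#'   variable count return all).
#' @param raw Optional data.frame of pre-discretization continuous values
#'   (same sample order) whose weighted means are reported.
#' @return An object of class `cluster_summary` with `nodes` and `edges`
#'   data.frames.
#' @export
summarize_cluster <- function(model, data = model$data,
                              memberships = model$memberships,
                              cluster = 1L, top_m = 10L, raw = NULL) {
  w <- memberships[, cluster]
  spec <- data$spec
  dag <- model$networks[[cluster]]$dag
  deg <- stats::setNames(rep(0L, nrow(spec)), spec$name)
  ed <- dag_edges(dag)
  if (nrow(ed)) {
    tab <- table(c(ed[, 1L], ed[, 2L]))
    deg[names(tab)] <- as.integer(tab)
  }
  freq <- vapply(seq_len(nrow(spec)), function(j) {
    v <- spec$name[j]
    card <- length(spec$categories[[j]])
    sum(w * (data$values[[v]] - 1L) / (card - 1L)) / sum(w)
  }, numeric(1))
  raw_mean <- rep(NA_real_, nrow(spec))
  if (!is.null(raw)) {
    for (v in intersect(names(raw), spec$name))
      raw_mean[match(v, spec$name)] <- sum(w * raw[[v]]) / sum(w)
  }
  S <- vapply(spec$name, function(v)
    entropy_node_score(data, memberships, v)[cluster], numeric(1))
  nodes <- data.frame(name = spec$name, role = spec$role,
                      modality = spec$modality, frequency = freq,
                      raw_mean = raw_mean, entropy_score = S,
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  ord <- order(-nodes$degree, -nodes$frequency, nodes$name)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$displayed <- seq_len(nrow(nodes)) <= min(top_m, nrow(nodes))
  edges <- edge_signs(model, data, memberships, cluster)
  structure(list(cluster = cluster, nodes = nodes, edges = edges),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("cluster", x$cluster, "summary:", nrow(x$nodes), "variables,",
      nrow(x$edges), "edges\n")
  print(utils::head(x$nodes[, c("name", "frequency", "entropy_score",
                                "degree")], 10L))
  invisible(x)
}

#' Sub-stratify a cluster by similarity to another
#'
#' Splits the members of one cluster into high/low groups by their
#' membership weight toward another cluster (threshold: the median weight
#' among the members). A pure function of the membership matrix.
#'
#' @param memberships n-by-K membership matrix.
#' @param cluster Cluster whose members are split (hard labels by argmax).
#' @param toward Cluster whose membership weight drives the split.
#' @return Integer vector over all samples: NA outside `cluster`, 1 = low,
#'   2 = high similarity to `toward`.
#' @export
sub_stratify <- function(memberships, cluster, toward) {
  labels <- max.col(memberships, ties.method = "first")
  out <- rep(NA_integer_, nrow(memberships))
  members <- labels == cluster
  wt <- memberships[members, toward]
  out[members] <- ifelse(wt > stats::median(wt), 2L, 1L)
  out
}
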