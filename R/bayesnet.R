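#' Construct a directed acyclic graph over model variables
#'
#' @param nodes Ordered character vector of variable names.
#' @param edges Optional two-column matrix or data.frame of (parent, child)
#'   pairs.
#' @return An object of class `bn_dag`: the node order plus a named list of
#'   parent sets.
#' @export
new_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  parents <- stats::setNames(replicate(length(nodes), character(0),
                                       simplify = FALSE), nodes)
  dag <- structure(list(nodes = nodes, parents = parents), class = "bn_dag")
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    for (i in seq_len(nrow(edges)))
      dag <- dag_add_edge(dag, edges[i, 1L], edges[i, 2L])
  }
  dag
}

#' @export
print.bn_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat("bn_dag:", length(x$nodes), "nodes,", ne, "edges\n")
  invisible(x)
}

dag_edges <- function(dag) {
  ps <- dag$parents
  kid <- rep(names(ps), lengths(ps))
  par <- unlist(ps, use.names = FALSE)
  if (is.null(par)) par <- character(0)
  cbind(parent = par, child = kid)
}

dag_has_edge <- function(dag, parent, child) {
  parent %in% dag$parents[[child]]
}

dag_add_edge <- function(dag, parent, child, check = TRUE) {
  if (!(parent %in% dag$nodes) || !(child %in% dag$nodes))
    stop("edge references unknown node")
  if (parent == child) stop("self-loop not allowed")
  if (dag_has_edge(dag, parent, child)) return(dag)
  dag$parents[[child]] <- sort(c(dag$parents[[child]], parent))
  if (check && !dag_is_acyclic(dag))
    stop("edge ", parent, " -> ", child, " creates a cycle")
  dag
}

dag_remove_edge <- function(dag, parent, child) {
  dag$parents[[child]] <- setdiff(dag$parents[[child]], parent)
  dag
}

# Kahn's algorithm; returns NULL on a cycle
dag_topo_sort <- function(dag) {
  nodes <- dag$nodes
  indeg <- lengths(dag$parents)[nodes]
  children <- stats::setNames(replicate(length(nodes), character(0),
                                        simplify = FALSE), nodes)
  for (ch in nodes)
    for (pa in dag$parents[[ch]])
      children[[pa]] <- c(children[[pa]], ch)
  queue <- nodes[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(nodes)) return(NULL)
  order
}

dag_is_acyclic <- function(dag) !is.null(dag_topo_sort(dag))

# TRUE if a directed path child ~> parent exists (so parent -> child would
# close a cycle)
dag_path_exists <- function(dag, from, to, children = NULL) {
  if (is.null(children)) {
    children <- stats::setNames(replicate(length(dag$nodes), character(0),
                                          simplify = FALSE), dag$nodes)
    for (ch in dag$nodes)
      for (pa in dag$parents[[ch]])
        children[[pa]] <- c(children[[pa]], ch)
  }
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    if (to %in% nxt) return(TRUE)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# row index into a CPT for each sample: first parent slowest (row-major
# parent-configuration order)
config_index <- function(codes, cards, n = NULL) {
  if (length(cards) == 0L)
    return(rep(1L, if (!is.null(n)) n else 1L))
  n <- length(codes[[1L]])
  idx <- rep(0L, n)
  for (j in seq_along(cards)) idx <- idx * cards[j] + (codes[[j]] - 1L)
  idx + 1L
}

#' Fit conditional probability tables for a fixed structure
#'
#' Posterior-mean (Dirichlet-smoothed) CPT estimation from weighted counts:
#' each row is the weighted category counts plus `pseudocount`, normalized.
#' Rows with zero weighted count reduce to the uniform distribution.
#' Fractional sample weights (soft cluster memberships) are first-class.
#'
#' @param dag A `bn_dag` whose nodes match the data variables.
#' @param data A `cohort_data` with all modelled variables discrete and
#'   complete.
#' @param weights Nonnegative per-sample weights; default all 1.
#' @param pseudocount Dirichlet pseudocount added per CPT cell (> 0).
#' @return An object of class `bayes_net`: the DAG, one CPT per node, and
#'   the variable spec.
#' @export
fit_cpts <- function(dag, data, weights = NULL, pseudocount = 1) {
  stopifnot(inherits(dag, "bn_dag"), inherits(data, "cohort_data"),
            pseudocount > 0)
  if (!identical(sort(dag$nodes), sort(data$spec$name)))
    stop("DAG nodes and data variables differ")
  n <- nrow(data$values)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("invalid weight: length mismatch")
  if (any(weights < 0)) stop("invalid weight: negative")
  cards <- stats::setNames(n_categories(data$spec), data$spec$name)
  cpts <- vector("list", length(dag$nodes))
  names(cpts) <- dag$nodes
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    r <- cards[[v]]
    q <- if (length(pa)) prod(cards[pa]) else 1L
    child <- data$values[[v]]
    idx <- config_index(lapply(pa, function(p) data$values[[p]]), cards[pa])
    counts <- matrix(0, q, r)
    if (n > 0L) {
      cell <- idx + q * (child - 1L)
      acc <- rowsum(weights, cell)
      counts[as.integer(rownames(acc))] <- acc
    }
    tab <- counts + pseudocount
    tab <- tab / rowSums(tab)
    cpts[[v]] <- list(child = v, parents = pa, card = r,
                      parent_cards = unname(cards[pa]), table = tab)
  }
  structure(list(dag = dag, cpts = cpts, spec = data$spec),
            class = "bayes_net")
}

#' @export
print.bayes_net <- function(x, ...) {
  cat("bayes_net:", length(x$dag$nodes), "nodes,",
      sum(lengths(x$dag$parents)), "edges\n")
  invisible(x)
}

ci_covariates <- function(spec)
  spec$name[spec$role == "cluster_independent_covariate"]

#' Conditional log-likelihood of samples under a network
#'
#' Computes `log P(X_V | X_C)` for each sample: the sum over
#' cluster-dependent nodes of the log CPT entry for the observed category
#' given the observed parent configuration. Cluster-independent covariate
#' nodes are conditioned on and contribute no factor. Because covariates
#' have only outgoing edges, this factorized form is the exact conditional
#' probability, and summing `exp()` over all cluster-dependent
#' configurations (covariates fixed) yields 1.
#'
#' @param net A `bayes_net`.
#' @param data A `cohort_data` with matching variables (any order).
#' @return Numeric vector of per-sample conditional log-likelihoods; `-Inf`
#'   where a required CPT entry is zero.
#' @export
bn_loglik <- function(net, data) {
  stopifnot(inherits(net, "bayes_net"), inherits(data, "cohort_data"))
  miss <- setdiff(net$dag$nodes, data$spec$name)
  if (length(miss))
    stop("incomplete sample: missing variable ", paste(miss, collapse = ", "))
  n <- nrow(data$values)
  ll <- rep(0, n)
  ci <- ci_covariates(net$spec)
  for (v in net$dag$nodes) {
    cpt <- net$cpts[[v]]
    code <- data$values[[v]]
    if (anyNA(code)) stop("incomplete sample: NA in variable ", v)
    if (any(code < 1L | code > cpt$card))
      stop("invalid category in variable ", v)
    if (v %in% ci) next
    idx <- config_index(lapply(cpt$parents, function(p) data$values[[p]]),
                        cpt$parent_cards, n = n)
    p <- cpt$table[cbind(idx, code)]
    ll <- ll + ifelse(p > 0, log(p), -Inf)
  }
  ll
}

#' Forward-sample a Bayesian network
#'
#' Ancestral sampling in topological order; covariate nodes can be clamped
#' to fixed values.
#'
#' @param net A `bayes_net`.
#' @param n Number of samples (>= 1).
#' @param covariate_values Optional named list/vector of category codes (or
#'   labels) at which to clamp nodes; clamped nodes are not sampled.
#' @param seed Optional integer seed for reproducibility.
#' @return A `cohort_data` with `n` sampled rows.
#' @export
bn_sample <- function(net, n, covariate_values = NULL, seed = NULL) {
  stopifnot(inherits(net, "bayes_net"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  order <- dag_topo_sort(net$dag)
  vals <- as.data.frame(matrix(NA_integer_, n, length(net$dag$nodes)))
  names(vals) <- net$dag$nodes
  clamp <- list()
  if (!is.null(covariate_values)) {
    for (v in names(covariate_values)) {
      cpt <- net$cpts[[v]]
      if (is.null(cpt)) stop("unknown clamped node: ", v)
      val <- covariate_values[[v]]
      if (is.character(val)) {
        cats <- net$spec$categories[[spec_row(net$spec, v)]]
        val <- match(val, cats)
      }
      val <- as.integer(val)
      if (is.na(val) || val < 1L || val > cpt$card)
        stop("invalid category for clamped node ", v)
      clamp[[v]] <- val
    }
  }
  for (v in order) {
    cpt <- net$cpts[[v]]
    if (!is.null(clamp[[v]])) {
      vals[[v]] <- rep(clamp[[v]], n)
      next
    }
    if (cpt$card == 1L) {
      vals[[v]] <- rep(1L, n)
      next
    }
    idx <- config_index(lapply(cpt$parents, function(p) vals[[p]]),
                        cpt$parent_cards, n = n)
    u <- stats::runif(n)
    cum <- t(apply(cpt$table, 1L, cumsum))
    # draw category: first column of the row cumsum exceeding u
    vals[[v]] <- as.integer(rowSums(u > cum[idx, , drop = FALSE]) + 1L)
  }
  cohort_data(vals, net$spec, codes = TRUE)
}

# Weighted BDeu family score: for child with r categories and q parent
# configurations, with weighted counts N_jk and ESS alpha,
#   sum_j [ lgamma(a_j) - lgamma(a_j + N_j.) ]
#   + sum_jk [ lgamma(a_jk + N_jk) - lgamma(a_jk) ],
# a_j = alpha/q, a_jk = alpha/(q r). Zero weighted counts give score 0.
family_score_bdeu <- function(child_codes, parent_codes, r, parent_cards,
                              weights, ess = 1) {
  q <- if (length(parent_cards)) prod(parent_cards) else 1
  idx <- config_index(parent_codes, parent_cards)
  counts <- matrix(0, q, r)
  cell <- idx + q * (child_codes - 1L)
  acc <- rowsum(weights, cell)
  counts[as.integer(rownames(acc))] <- acc
  aj <- ess / q
  ajk <- ess / (q * r)
  nj <- rowSums(counts)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + counts) - lgamma(ajk))
}

#' Score a DAG against weighted data
#'
#' Decomposable Bayesian (BDeu) structure score over weighted counts plus a
#' log edge-prior term: the sum over nodes of the family marginal-likelihood
#' score, plus the sum over present edges of the log prior multiplier (see
#' [load_prior_edges()]). Changing one node's parent set changes only that
#' node's family term plus the affected edge-prior terms.
#'
#' @param dag A `bn_dag`.
#' @param data A discrete, complete `cohort_data`.
#' @param weights Nonnegative per-sample weights; default all 1.
#' @param prior Optional `edge_prior`; omitted means all multipliers 1.
#' @param ess Equivalent sample size of the BDeu score.
#' @return The scalar log score.
#' @export
score_network <- function(dag, data, weights = NULL, prior = NULL, ess = 1) {
  stopifnot(inherits(dag, "bn_dag"), inherits(data, "cohort_data"))
  n <- nrow(data$values)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stop("invalid weight")
  cards <- stats::setNames(n_categories(data$spec), data$spec$name)
  total <- 0
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    total <- total + family_score_bdeu(
      data$values[[v]], lapply(pa, function(p) data$values[[p]]),
      cards[[v]], unname(cards[pa]), weights, ess)
  }
  if (!is.null(prior)) {
    ed <- dag_edges(dag)
    if (nrow(ed))
      total <- total + sum(prior_log_multiplier(prior, ed[, 1L], ed[, 2L]))
  }
  total
}
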