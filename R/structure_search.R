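#' Learn a cluster network structure from weighted data
#'
#' Score-based DAG search by greedy hill climbing over single-edge
#' addition, deletion and reversal moves, maximizing the BDeu structure
#' score plus the log edge-prior term, under the hard direction constraints
#' of [build_constraints()]. Random restarts explore distinct starting
#' DAGs; ties between equal-score moves are broken lexicographically by
#' (parent, child) so the search is deterministic given `seed`.
#'
#' @param data A discrete, complete `cohort_data`.
#' @param weights Nonnegative per-sample weights (fractional cluster
#'   memberships are the intended use); default all 1.
#' @param constraints An `edge_constraints`; defaults to those implied by
#'   the data's variable spec.
#' @param prior Optional `edge_prior`.
#' @param seed Integer seed controlling restart initialisation.
#' @param restarts Number of hill-climbing runs (>= 1); the first starts
#'   from `start` (or the empty graph), the rest from random DAGs.
#' @param ess BDeu equivalent sample size.
#' @param start Optional `bn_dag` warm start for the first run.
#' @return The best-scoring `bn_dag` found, with the score in
#'   `attr(, "score")`.
#' @export
learn_structure <- function(data, weights = NULL, constraints = NULL,
                            prior = NULL, seed = 1L, restarts = 5L,
                            ess = 1, start = NULL) {
  stopifnot(inherits(data, "cohort_data"), restarts >= 1L)
  if (is.null(constraints)) constraints <- build_constraints(data$spec)
  if (constraints$max_parents < 1L) stop("max_parents must be >= 1")
  n <- nrow(data$values)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stop("invalid weight")
  if (all(weights == 0)) stop("need at least one sample with positive weight")
  vars <- data$spec$name
  svars <- sort(vars)  # lexicographic move enumeration for tie-breaking
  cards <- stats::setNames(n_categories(data$spec), vars)
  cache <- new.env(parent = emptyenv())
  fam <- function(v, pa) {
    key <- paste0(v, "|", paste(pa, collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- family_score_bdeu(
      data$values[[v]], lapply(pa, function(p) data$values[[p]]),
      cards[[v]], unname(cards[pa]), weights, ess)
    cache[[key]] <- val
    val
  }
  lm <- if (is.null(prior)) matrix(0, length(vars), length(vars),
                                   dimnames = list(vars, vars))
        else prior$logmult

  dag_score <- function(dag) {
    s <- sum(vapply(vars, function(v) fam(v, dag$parents[[v]]), numeric(1)))
    ed <- dag_edges(dag)
    if (nrow(ed)) s <- s + sum(lm[ed])
    s
  }

  hill_climb <- function(dag) {
    score <- dag_score(dag)
    repeat {
      reach <- dag_reachability(dag)
      best_delta <- 1e-10
      best_move <- NULL
      for (x in svars) for (y in svars) {
        if (x == y) next
        if (dag_has_edge(dag, x, y)) {
          pay <- dag$parents[[y]]
          base_y <- fam(y, pay)
          # deletion
          d_del <- fam(y, setdiff(pay, x)) - base_y - lm[x, y]
          if (d_del > best_delta) {
            best_delta <- d_del; best_move <- list("del", x, y)
          }
          # reversal
          if (!constraints$forbidden[y, x] &&
              length(dag$parents[[x]]) < constraints$max_parents) {
            tmp <- dag_remove_edge(dag, x, y)
            if (!dag_path_exists(tmp, x, y)) {
              pax <- dag$parents[[x]]
              d_rev <- (fam(y, setdiff(pay, x)) - base_y) +
                (fam(x, sort(c(pax, y))) - fam(x, pax)) -
                lm[x, y] + lm[y, x]
              if (d_rev > best_delta) {
                best_delta <- d_rev; best_move <- list("rev", x, y)
              }
            }
          }
        } else if (!dag_has_edge(dag, y, x)) {
          # addition
          if (constraints$forbidden[x, y]) next
          pay <- dag$parents[[y]]
          if (length(pay) >= constraints$max_parents) next
          if (reach[y, x]) next  # y ~> x exists; x -> y would close a cycle
          d_add <- fam(y, sort(c(pay, x))) - fam(y, pay) + lm[x, y]
          if (d_add > best_delta) {
            best_delta <- d_add; best_move <- list("add", x, y)
          }
        }
      }
      if (is.null(best_move)) break
      x <- best_move[[2L]]; y <- best_move[[3L]]
      dag <- switch(best_move[[1L]],
                    add = dag_add_edge(dag, x, y, check = FALSE),
                    del = dag_remove_edge(dag, x, y),
                    rev = dag_add_edge(dag_remove_edge(dag, x, y), y, x,
                                       check = FALSE))
      score <- score + best_delta
    }
    list(dag = dag, score = dag_score(dag))
  }

  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) {
      if (is.null(start)) new_dag(vars) else start
    } else {
      random_dag(data$spec, constraints, edge_prob = 0.25)
    }
    res <- hill_climb(init)
    if (is.null(best) || res$score > best$score + 1e-10) best <- res
  }
  structure(best$dag, score = best$score)
}

# reach[i, j]: directed path i ~> j (including i == j)
dag_reachability <- function(dag) {
  vars <- dag$nodes
  p <- length(vars)
  adj <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  ed <- dag_edges(dag)
  if (nrow(ed)) adj[ed] <- TRUE
  reach <- adj | diag(TRUE, p)
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# random constraint-satisfying DAG: random topological order, feasible
# earlier -> later edges kept with probability edge_prob
random_dag <- function(spec, constraints, edge_prob = 0.25) {
  vars <- spec$name
  ord <- sample(vars)
  dag <- new_dag(vars)
  for (j in seq_along(ord)) {
    if (j == 1L) next
    child <- ord[j]
    cand <- ord[seq_len(j - 1L)]
    cand <- cand[!constraints$forbidden[cand, child]]
    if (!length(cand)) next
    pick <- cand[stats::runif(length(cand)) < edge_prob]
    if (length(pick) > constraints$max_parents)
      pick <- pick[seq_len(constraints$max_parents)]
    for (pa in pick) dag <- dag_add_edge(dag, pa, child, check = FALSE)
  }
  dag
}

#' Skeleton F1 between two DAGs
#'
#' Compares the undirected skeletons (edge presence ignoring orientation)
#' of two DAGs over the same nodes and returns the F1 score of the learned
#' skeleton against the reference skeleton.
#'
#' @param true_dag,learned_dag `bn_dag` objects over the same node set.
#' @return F1 in `[0, 1]`; 1 when both skeletons are empty.
#' @export
skeleton_f1 <- function(true_dag, learned_dag) {
  skel <- function(dag) {
    ed <- dag_edges(dag)
    if (!nrow(ed)) return(character(0))
    unique(apply(ed, 1L, function(e) paste(sort(e), collapse = "~")))
  }
  st <- skel(true_dag)
  sl <- skel(learned_dag)
  if (!length(st) && !length(sl)) return(1)
  tp <- length(intersect(st, sl))
  prec <- if (length(sl)) tp / length(sl) else 0
  rec <- if (length(st)) tp / length(st) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
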