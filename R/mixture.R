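#' Adjusted membership probabilities
#'
#' Computes the covariate-adjusted responsibility of each cluster for each
#' sample,
#' \deqn{\tilde\phi(x \mid k) = \frac{\chi + \gamma_k P(X_V \mid X_C,
#'   \mathcal{G}_k, \theta_k)}{\chi K + \sum_{k'} \gamma_{k'} P(X_V \mid
#'   X_C, \mathcal{G}_{k'}, \theta_{k'})},}
#' where each \eqn{P} is the conditional likelihood of the sample's
#' cluster-dependent variables given its cluster-independent covariates.
#' Conditioning on the covariates removes their influence on the cluster
#' assignment; the regularizer \eqn{\chi \ge 0} shrinks memberships toward
#' uniform (and \eqn{\chi = 0} recovers the unregularized posterior
#' weights). Rows sum to 1.
#'
#' @param model A fitted `network_mixture` (or a list with elements
#'   `networks`, `gamma`, `chi`).
#' @param data A `cohort_data` sharing the model's variables.
#' @return An n-by-K membership matrix.
#' @export
adjusted_memberships <- function(model, data) {
  L <- vapply(model$networks, bn_loglik, numeric(nrow(data$values)),
              data = data)
  L <- matrix(L, nrow = nrow(data$values))
  memberships_from_loglik(L, model$gamma, model$chi)
}

memberships_from_loglik <- function(L, gamma, chi) {
  K <- length(gamma)
  n <- nrow(L)
  lg <- log(gamma)
  A <- sweep(L, 2L, lg, "+")  # log(gamma_k P_nk)
  if (chi == 0) {
    m <- apply(A, 1L, max)
    bad <- !is.finite(m)
    m[bad] <- 0
    w <- exp(A - m)
    phi <- w / rowSums(w)
    if (any(bad)) phi[bad, ] <- 1 / K
  } else {
    t_ <- exp(A)  # underflow to 0 is absorbed by chi
    phi <- (chi + t_) / (chi * K + rowSums(t_))
  }
  colnames(phi) <- names(gamma)
  phi
}

#' Initial membership perturbation
#'
#' Builds the starting responsibilities for the EM run: every row is
#' uniform `1/K`, then one uniformly chosen cluster per sample has its
#' weight multiplied by `1 + perturbation` and the row is renormalized.
#' Equal weights are an unstable equilibrium, so this small independent
#' per-sample perturbation (default 0.1%) lets repeated runs explore
#' diverse parts of the clustering space.
#'
#' @param n Number of samples.
#' @param K Number of clusters.
#' @param perturbation Relative weight increase (>= 0); default 0.001.
#' @param seed Optional integer seed.
#' @return An n-by-K membership matrix with rows summing to 1.
#' @export
initialize_memberships <- function(n, K, perturbation = 0.001, seed = NULL) {
  stopifnot(n >= 1, K >= 1, perturbation >= 0)
  if (!is.null(seed)) set.seed(seed)
  phi <- matrix(1 / K, n, K)
  pick <- sample.int(K, n, replace = TRUE)
  phi[cbind(seq_len(n), pick)] <- (1 + perturbation) / K
  phi / rowSums(phi)
}

#' Covariate-adjusted network mixture clustering
#'
#' Fits a mixture of K cluster-specific Bayesian networks to a discrete
#' cohort by a staged EM algorithm with covariate-adjusted memberships.
#' The E-step evaluates [adjusted_memberships()]; the M-step updates the
#' cluster weights \eqn{\gamma_k} as mean memberships, refits all CPTs
#' with the soft membership weights every iteration, and re-learns the
#' cluster DAGs (via [learn_structure()], under the direction constraints
#' and edge prior) every `structure_every` iterations. Cluster-independent
#' covariates are conditioned on throughout, so clusters reflect the
#' dependence structure of the cluster-dependent variables rather than
#' covariate strata.
#'
#' The run is staged: EM first runs under edge-free networks (an
#' independence mixture), letting the small initial perturbation of the
#' uniform memberships grow into a stable partition, and only then
#' alternates structure learning with parametric EM. Learning
#' cluster-specific structures while memberships are still near-uniform
#' would commit the clustering to arbitrary structural noise, so
#' structure updates are also gated on the memberships having separated
#' from uniform; for the same reason convergence is never declared while
#' the memberships still sit at the uniform saddle point.
#'
#' @param data A discrete, complete `cohort_data` (see [handle_missing()]).
#' @param K Number of clusters (>= 1, <= number of samples).
#' @param constraints Optional `edge_constraints`; defaults to
#'   [build_constraints()] on the data's spec.
#' @param prior Optional `edge_prior`; default none.
#' @param chi Membership regularizer \eqn{\chi \ge 0}; default 0
#'   (unregularized posterior weights). Useful nonzero values are of the
#'   order of typical \eqn{\gamma_k P(X_V \mid X_C)} values and therefore
#'   shrink with the number of modelled variables.
#' @param seed Integer seed governing initialisation and structure search.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the maximum absolute membership
#'   change.
#' @param structure_every Re-learn cluster DAGs every this many
#'   iterations; CPTs are refit every iteration.
#' @param structures Optional list of K fixed `bn_dag`s; if supplied,
#'   structures are never re-learned (pure parametric EM).
#' @param pseudocount CPT Dirichlet pseudocount.
#' @param ess BDeu equivalent sample size for structure search.
#' @param perturbation Initial membership perturbation fraction.
#' @param n_starts Number of independently perturbed stage-1 runs; the
#'   one with the highest log-likelihood is continued into stage 2.
#'   Ignored (single run) when `init` is supplied.
#' @param init Optional n-by-K starting membership matrix (overrides
#'   `perturbation`/`seed` initialisation and `n_starts`).
#' @param verbose Print per-iteration log-likelihood.
#' @return An object of class `network_mixture` with elements `networks`
#'   (list of K `bayes_net`), `gamma`, `chi`, `memberships`, `labels`
#'   (argmax memberships, ties to the lowest cluster index), `loglik`
#'   (per-iteration observed-data log-likelihood trace), `iterations`,
#'   `converged`, `seed`, `data`, and the call.
#' @seealso [predict.network_mixture()] for classifying unseen cohorts,
#'   [robustness_assessment()], [mds_projection()], [summarize_cluster()].
#' @examples
#' sc <- simulation_scenario(K = 2, p_features = 8, n = 120, seed = 1)
#' cohort <- generate_cohort(sc)
#' fit <- network_mixture(cohort$data, K = 2, seed = 1, structure_every = 10)
#' table(fit$labels, cohort$labels)
#' @export
network_mixture <- function(data, K, constraints = NULL, prior = NULL,
                            chi = 0, seed = 1L, max_iter = 100L,
                            tol = 1e-4, structure_every = 5L,
                            structures = NULL, pseudocount = 1, ess = 1,
                            perturbation = 0.001, n_starts = 1L,
                            init = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "cohort_data"), K >= 1)
  n <- nrow(data$values)
  if (K > n) stop("K exceeds the number of samples")
  if (any(data$spec$dtype == "continuous"))
    stop("continuous variables must be discretized before fitting")
  if (anyNA(as.matrix(data$values)))
    stop("missing values present; apply handle_missing() first")
  if (is.null(constraints)) constraints <- build_constraints(data$spec)
  fixed <- !is.null(structures)
  if (fixed && length(structures) != K)
    stop("need one fixed structure per cluster")

  phi <- if (!is.null(init)) init
         else initialize_memberships(n, K, perturbation, seed)
  stopifnot(nrow(phi) == n, ncol(phi) == K)
  nets <- vector("list", K)
  trace <- numeric(0)
  iterations <- 0L
  # never declare convergence while the memberships still sit at the
  # uniform saddle; never learn cluster-specific structures there either
  sep_conv <- 1 / K + 0.05
  sep_learn <- 1 / K + 0.5 * (1 - 1 / K)

  run_em <- function(phi, dags, n_iter, relearn_on) {
    converged <- FALSE
    delta <- Inf
    gamma <- rep(1 / K, K)
    for (it in seq_len(n_iter)) {
      iterations <<- iterations + 1L
      gamma <- colMeans(phi)
      # cluster starvation guard: re-seed a dying cluster from the
      # samples the current model fits worst
      starved <- which(colSums(phi) < 1e-6)
      if (length(starved) && it > 1L) {
        warning("reinitializing starved cluster(s): ",
                paste(starved, collapse = ", "))
        fitness <- apply(phi, 1L, max)
        worst <- order(fitness)[seq_len(max(2L, floor(n / (2 * K))))]
        for (k in starved) {
          phi[worst, ] <- 0.1 / max(1, K - 1)
          phi[worst, k] <- 0.9
        }
        phi <- phi / rowSums(phi)
        gamma <- colMeans(phi)
      }
      sep <- mean(apply(phi, 1L, max))
      relearn <- relearn_on && (it == 1L ||
                                  (it - 1L) %% structure_every == 0L) &&
        (K == 1L || sep > sep_learn)
      for (k in seq_len(K)) {
        if (relearn)
          dags[[k]] <- learn_structure(
            data, weights = phi[, k], constraints = constraints,
            prior = prior,
            seed = (as.integer(seed) %% 65536L) * 977L + it * 31L + k,
            restarts = 1L, ess = ess, start = dags[[k]])
        nets[[k]] <<- fit_cpts(dags[[k]], data, weights = phi[, k],
                               pseudocount = pseudocount)
      }
      L <- vapply(nets, bn_loglik, numeric(n), data = data)
      L <- matrix(L, nrow = n)
      A <- sweep(L, 2L, log(gamma), "+")
      m <- apply(A, 1L, max)
      trace <<- c(trace, sum(m + log(rowSums(exp(A - m)))))
      if (verbose)
        message(sprintf("iter %d: loglik %.4f", iterations,
                        trace[length(trace)]))
      phi_new <- memberships_from_loglik(L, gamma, chi)
      delta <- max(abs(phi_new - phi))
      phi <- phi_new
      sep <- mean(apply(phi, 1L, max))
      if (delta < tol && (K == 1L || fixed || sep > sep_conv)) {
        converged <- TRUE
        break
      }
    }
    list(phi = phi, dags = dags, converged = converged, gamma = gamma)
  }

  if (fixed) {
    s2 <- run_em(phi, structures, max_iter, relearn_on = FALSE)
  } else {
    # stage 1: independence mixture (edge-free networks) grows the
    # initial perturbation into a stable partition; optionally the best
    # of several perturbed starts by log-likelihood
    empty <- replicate(K, new_dag(data$spec$name), simplify = FALSE)
    if (is.null(init) && n_starts > 1L) {
      s1 <- NULL
      best_ll <- -Inf
      for (s in seq_len(n_starts)) {
        phi_s <- initialize_memberships(n, K, perturbation,
                                        seed = as.integer(seed) +
                                          7919L * (s - 1L))
        trace_at <- length(trace)
        cand <- run_em(phi_s, empty, 2L * max_iter, relearn_on = FALSE)
        ll_s <- trace[length(trace)]
        trace <- trace[seq_len(trace_at)]
        if (ll_s > best_ll) { best_ll <- ll_s; s1 <- cand }
      }
      trace <- c(trace, best_ll)
    } else {
      s1 <- run_em(phi, empty, 2L * max_iter, relearn_on = FALSE)
    }
    # stage 2: alternate structure learning with parametric EM
    s2 <- run_em(s1$phi, s1$dags, max_iter, relearn_on = TRUE)
  }
  phi <- s2$phi
  converged <- s2$converged
  # gamma of the final E-step, so that classifying the training data
  # reproduces the stored memberships exactly
  gamma <- s2$gamma
  labels <- max.col(phi, ties.method = "first")
  rownames(phi) <- data$samples
  structure(list(K = K, networks = nets, gamma = gamma, chi = chi,
                 spec = data$spec, constraints = constraints, prior = prior,
                 memberships = phi, labels = labels, loglik = trace,
                 iterations = iterations, converged = converged,
                 seed = as.integer(seed), pseudocount = pseudocount,
                 ess = ess, structure_every = structure_every,
                 tol = tol, data = data, provenance = NULL,
                 call = match.call()),
            class = "network_mixture")
}

align_cohort <- function(model, newdata) {
  miss <- setdiff(model$spec$name, newdata$spec$name)
  if (length(miss))
    stop("incompatible cohort: missing variable ", paste(miss, collapse = ", "))
  extra <- setdiff(newdata$spec$name, model$spec$name)
  if (length(extra)) {
    message("ignoring ", length(extra), " extra variable(s): ",
            paste(extra, collapse = ", "))
    keep <- newdata$spec$name %in% model$spec$name
    newdata$spec <- newdata$spec[keep, , drop = FALSE]
    newdata$values <- newdata$values[, newdata$spec$name, drop = FALSE]
  }
  ord <- match(model$spec$name, newdata$spec$name)
  newdata$spec <- newdata$spec[ord, , drop = FALSE]
  rownames(newdata$spec) <- NULL
  newdata$values <- newdata$values[, model$spec$name, drop = FALSE]
  newdata
}

#' Classify new samples with a frozen model
#'
#' Computes adjusted memberships of unseen samples under a fitted model
#' without any model update. The new cohort must contain every model
#' variable, preprocessed identically to the training cohort (use the
#' stored provenance from [run_preprocess()] / [run_fit()]); extra
#' variables are ignored with a notice.
#'
#' @param object A fitted `network_mixture`.
#' @param newdata A `cohort_data`; defaults to the training data.
#' @param type `"membership"` for the n-by-K matrix, `"label"` for hard
#'   cluster labels (argmax, ties to the lowest index).
#' @param ... Unused.
#' @return A membership matrix or an integer label vector.
#' @export
predict.network_mixture <- function(object, newdata = NULL,
                                    type = c("membership", "label"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    phi <- object$memberships
  } else {
    newdata <- align_cohort(object, newdata)
    phi <- adjusted_memberships(object, newdata)
    rownames(phi) <- newdata$samples
  }
  if (type == "label") max.col(phi, ties.method = "first") else phi
}

#' @rdname predict.network_mixture
#' @param model A fitted `network_mixture`.
#' @param new_data A `cohort_data` to classify.
#' @export
classify <- function(model, new_data) {
  predict(model, newdata = new_data, type = "membership")
}

#' @export
print.network_mixture <- function(x, ...) {
  cat("Covariate-adjusted network mixture\n")
  cat(sprintf("  K = %d clusters, n = %d samples, %d variables\n",
              x$K, nrow(x$memberships), nrow(x$spec)))
  cat(sprintf("  chi = %g, %d EM iterations (%s)\n", x$chi, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat("  cluster weights:", paste(sprintf("%.3f", x$gamma), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.network_mixture <- function(object, top = 5L, ...) {
  sizes <- tabulate(object$labels, nbins = object$K)
  feats <- object$spec$name[object$spec$role == "genomic_feature"]
  topfeat <- lapply(seq_len(object$K), function(k) {
    w <- object$memberships[, k]
    if (sum(w) == 0 || !length(feats)) return(character(0))
    freq <- vapply(feats, function(v)
      sum(w * (object$data$values[[v]] == 2L)) / sum(w), numeric(1))
    names(sort(freq, decreasing = TRUE))[seq_len(min(top, length(feats)))]
  })
  out <- list(K = object$K, sizes = sizes, gamma = object$gamma,
              chi = object$chi, loglik = object$loglik,
              edges = vapply(object$networks,
                             function(nw) sum(lengths(nw$dag$parents)),
                             integer(1)),
              top_features = topfeat, converged = object$converged,
              iterations = object$iterations)
  class(out) <- "summary.network_mixture"
  out
}

#' @export
print.summary.network_mixture <- function(x, ...) {
  cat("Covariate-adjusted network mixture:", x$K, "clusters\n")
  cat(sprintf("  final log-likelihood %.3f after %d iterations (%s)\n",
              x$loglik[length(x$loglik)], x$iterations,
              if (x$converged) "converged" else "not converged"))
  for (k in seq_len(x$K)) {
    cat(sprintf("  cluster %d: n=%d, gamma=%.3f, edges=%d", k, x$sizes[k],
                x$gamma[k], x$edges[k]))
    if (length(x$top_features[[k]]))
      cat(", top features:", paste(x$top_features[[k]], collapse = ", "))
    cat("\n")
  }
  invisible(x)
}

#' @export
logLik.network_mixture <- function(object, ...) {
  df <- (object$K - 1) + sum(vapply(object$networks, function(nw) {
    sum(vapply(nw$cpts, function(cpt) nrow(cpt$table) * (cpt$card - 1),
               numeric(1)))
  }, numeric(1)))
  structure(object$loglik[length(object$loglik)], df = df,
            nobs = nrow(object$memberships), class = "logLik")
}

#' @export
coef.network_mixture <- function(object, ...) object$gamma

#' Simulate cohorts from a fitted mixture
#'
#' Draws cluster labels from the fitted weights and forward-samples each
#' sample's variables (covariates included) from its cluster's network.
#'
#' @param object A fitted `network_mixture`.
#' @param nsim Number of cohorts to simulate.
#' @param seed Optional integer seed.
#' @param n Samples per cohort; defaults to the training size.
#' @param ... Unused.
#' @return A list of `nsim` elements, each `list(data, labels)`.
#' @export
simulate.network_mixture <- function(object, nsim = 1, seed = NULL,
                                     n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- nrow(object$memberships)
  lapply(seq_len(nsim), function(s) {
    labels <- sample.int(object$K, n, replace = TRUE, prob = object$gamma)
    rows <- vector("list", object$K)
    for (k in seq_len(object$K)) {
      nk <- sum(labels == k)
      if (nk)
        rows[[k]] <- bn_sample(object$networks[[k]], nk)$values
    }
    stacked <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    idx <- order(labels)  # row j of stacked is sample idx[j]
    vals <- stacked
    vals[idx, ] <- stacked
    rownames(vals) <- NULL
    list(data = cohort_data(vals, object$spec, codes = TRUE),
         labels = labels)
  })
}

#' Plot a fitted mixture as an MDS projection
#'
#' Scatter plot of the classical multidimensional-scaling projection of
#' per-sample network fit (see [mds_projection()]), coloured by hard
#' cluster label.
#'
#' @param x A fitted `network_mixture`.
#' @param ... Passed to [graphics::plot()].
#' @return The coordinates, invisibly.
#' @export
plot.network_mixture <- function(x, ...) {
  xy <- mds_projection(x, x$data)
  graphics::plot(xy, col = x$labels, pch = 19,
                 xlab = "MDS 1", ylab = "MDS 2", ...)
  invisible(xy)
}
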