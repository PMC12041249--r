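#' Build edge constraints from variable roles and modalities
#'
#' Encodes the causal direction knowledge used during structure search:
#' cluster-independent covariates may only have outgoing edges (no incoming
#' edges from any node), and edges from blood or bone-marrow variables into
#' genomic features are excluded, reflecting the likely causal direction.
#' Genomic-to-clinical edges remain allowed.
#'
#' @param spec A spec table (see [spec_table()]).
#' @param max_parents Maximum number of parents per node during search.
#' @return An object of class `edge_constraints`: a logical
#'   parent-by-child `forbidden` matrix plus `max_parents`.
#' @export
build_constraints <- function(spec, max_parents = 4L) {
  validate_spec(spec)
  p <- nrow(spec)
  vars <- spec$name
  forbidden <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  ci <- spec$role == "cluster_independent_covariate"
  # covariate nodes are source-only: nothing may point into them
  forbidden[, ci] <- TRUE
  clinical <- spec$modality %in% c("blood", "bone_marrow")
  genomic <- spec$role == "genomic_feature"
  forbidden[clinical, genomic] <- TRUE
  diag(forbidden) <- TRUE
  structure(list(forbidden = forbidden, max_parents = as.integer(max_parents)),
            class = "edge_constraints")
}

#' @export
print.edge_constraints <- function(x, ...) {
  off <- sum(x$forbidden) - nrow(x$forbidden)
  cat("edge_constraints:", off, "forbidden edges, max_parents =",
      x$max_parents, "\n")
  invisible(x)
}

edge_allowed <- function(constraints, parent, child) {
  !constraints$forbidden[parent, child]
}

dag_satisfies <- function(dag, constraints) {
  ed <- dag_edges(dag)
  if (nrow(ed) == 0L) return(TRUE)
  if (any(constraints$forbidden[ed])) return(FALSE)
  all(lengths(dag$parents) <= constraints$max_parents)
}

#' Build an edge prior from a known-interaction list
#'
#' Prior knowledge about expected edges enters the structure score as a
#' per-edge prior-odds multiplier: edges between two genes listed as
#' interacting (in either direction) carry multiplier 1, all other
#' gene-gene edges are penalized by `1/penalty_factor`, and edges involving
#' clinical or covariate nodes are unpenalized (multiplier 1). Each present
#' edge contributes the log of its multiplier to the score.
#'
#' @param spec A spec table; genomic features are the penalized node class.
#' @param pairs Optional two-column matrix/data.frame of undirected gene
#'   pairs, or `NULL` for no prior interactions.
#' @param penalty_factor Penalty for unlisted gene-gene edges (>= 1);
#'   the default 2 halves their prior odds. 1 disables the prior.
#' @return An object of class `edge_prior` holding the log-multiplier
#'   matrix.
#' @export
edge_prior <- function(spec, pairs = NULL, penalty_factor = 2) {
  validate_spec(spec)
  stopifnot(penalty_factor >= 1)
  vars <- spec$name
  p <- length(vars)
  logmult <- matrix(0, p, p, dimnames = list(vars, vars))
  genomic <- spec$name[spec$role == "genomic_feature"]
  logmult[genomic, genomic] <- -log(penalty_factor)
  diag(logmult) <- 0
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    pairs <- as.matrix(pairs)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1L]; b <- pairs[i, 2L]
      if (!(a %in% vars) || !(b %in% vars)) {
        warning("prior edge names unknown variable, ignored: ", a, " - ", b)
        next
      }
      logmult[a, b] <- 0
      logmult[b, a] <- 0
    }
  }
  structure(list(logmult = logmult, penalty_factor = penalty_factor),
            class = "edge_prior")
}

#' Read a prior edge list file
#'
#' Reads a two-column TSV of undirected variable pairs (`#` comments and
#' blank lines allowed) and builds the corresponding [edge_prior()].
#'
#' @param path Path to the TSV file.
#' @param spec A spec table.
#' @param penalty_factor Penalty for unlisted gene-gene edges (>= 1).
#' @return An `edge_prior`.
#' @export
load_prior_edges <- function(path, spec, penalty_factor = 2) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pairs <- NULL
  if (length(lines)) {
    parts <- strsplit(lines, "[\t ]+")
    if (any(lengths(parts) < 2L)) stop("malformed prior edge line")
    pairs <- do.call(rbind, lapply(parts, function(x) x[1:2]))
  }
  edge_prior(spec, pairs, penalty_factor)
}

prior_log_multiplier <- function(prior, parent, child) {
  prior$logmult[cbind(parent, child)]
}
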