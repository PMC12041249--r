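#' Read and write cohort tables
#'
#' A cohort is stored as a CSV (header row of variable names, one sample
#' per row, first column `sample_id`) plus a companion TSV spec file with
#' columns name, role, dtype, modality and `|`-separated category labels.
#'
#' @param path CSV path.
#' @param spec_path Spec TSV path.
#' @return A `cohort_data`.
#' @export
read_cohort <- function(path, spec_path) {
  spec_df <- utils::read.delim(spec_path, stringsAsFactors = FALSE)
  need <- c("name", "role", "dtype", "modality")
  if (!all(need %in% names(spec_df))) stop("invalid variable spec")
  ok_roles <- c("cluster_independent_covariate",
                "cluster_dependent_covariate", "genomic_feature")
  if (!all(spec_df$role %in% ok_roles))
    stop("invalid variable spec: unknown role")
  specs <- lapply(seq_len(nrow(spec_df)), function(i) {
    cats <- NULL
    if (!is.null(spec_df$categories) && nzchar(spec_df$categories[i]))
      cats <- strsplit(spec_df$categories[i], "|", fixed = TRUE)[[1L]]
    variable_spec(spec_df$name[i], spec_df$role[i], spec_df$dtype[i],
                  spec_df$modality[i], cats)
  })
  spec <- do.call(spec_table, specs)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  samples <- NULL
  if ("sample_id" %in% names(tab)) {
    samples <- as.character(tab$sample_id)
    tab$sample_id <- NULL
  }
  cohort_data(tab, spec, samples = samples)
}

#' @rdname read_cohort
#' @param data A `cohort_data` to write.
#' @export
write_cohort <- function(data, path, spec_path) {
  out <- as.data.frame(data)
  out <- cbind(sample_id = data$samples, out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  spec_df <- data$spec[, c("name", "role", "dtype", "modality")]
  spec_df$categories <- vapply(data$spec$categories, paste,
                               character(1), collapse = "|")
  utils::write.table(spec_df, spec_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(data)
}

bn_to_list <- function(net) {
  ed <- dag_edges(net$dag)
  list(nodes = as.list(net$dag$nodes),
       edges = if (nrow(ed)) lapply(seq_len(nrow(ed)),
                                    function(i) as.list(unname(ed[i, ])))
               else list(),
       cpts = lapply(net$dag$nodes, function(v) {
         cpt <- net$cpts[[v]]
         list(child = v, parents = as.list(cpt$parents),
              card = cpt$card,
              parent_cards = as.list(cpt$parent_cards),
              # rows (parent configurations, first parent slowest) flattened
              # row-major
              table = as.vector(t(cpt$table)))
       }))
}

bn_from_list <- function(x, spec) {
  nodes <- unlist(x$nodes)
  edges <- if (length(x$edges))
    do.call(rbind, lapply(x$edges, unlist)) else NULL
  dag <- new_dag(nodes, edges)
  cpts <- stats::setNames(lapply(x$cpts, function(cp) {
    pc <- as.integer(unlist(cp$parent_cards))
    q <- if (length(pc)) prod(pc) else 1L
    list(child = cp$child, parents = as.character(unlist(cp$parents)),
         card = as.integer(cp$card), parent_cards = pc,
         table = matrix(unlist(cp$table), nrow = q, ncol = cp$card,
                        byrow = TRUE))
  }), vapply(x$cpts, function(cp) cp$child, character(1)))
  cpts <- cpts[nodes]
  structure(list(dag = dag, cpts = cpts, spec = spec), class = "bayes_net")
}

spec_to_list <- function(spec) {
  lapply(seq_len(nrow(spec)), function(i)
    list(name = spec$name[i], role = spec$role[i], dtype = spec$dtype[i],
         modality = spec$modality[i],
         categories = as.list(spec$categories[[i]])))
}

spec_from_list <- function(x) {
  do.call(spec_table, lapply(x, function(s)
    variable_spec(s$name, s$role, s$dtype, s$modality,
                  if (length(s$categories)) unlist(s$categories) else NULL)))
}

#' Persist a fitted mixture model as JSON
#'
#' Serializes the full model (node order, edge lists, flattened CPTs,
#' category labels, cluster weights, chi, seed and any preprocessing
#' provenance) with full numeric precision, so that writing and re-reading
#' reproduces the model bit-exactly.
#'
#' @param model A fitted `network_mixture`.
#' @param path Output JSON path.
#' @export
write_model <- function(model, path) {
  obj <- list(K = model$K, gamma = as.list(unname(model$gamma)),
              chi = model$chi, seed = model$seed,
              pseudocount = model$pseudocount, ess = model$ess,
              spec = spec_to_list(model$spec),
              networks = lapply(model$networks, bn_to_list),
              provenance = model$provenance)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(model)
}

#' @rdname write_model
#' @return `read_model()` returns the `network_mixture` (without training
#'   data or memberships; use [predict.network_mixture()] with a cohort).
#' @export
read_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  spec <- spec_from_list(x$spec)
  structure(list(K = as.integer(x$K), gamma = as.numeric(unlist(x$gamma)),
                 chi = as.numeric(x$chi), seed = as.integer(x$seed),
                 pseudocount = as.numeric(x$pseudocount),
                 ess = as.numeric(x$ess), spec = spec,
                 networks = lapply(x$networks, bn_from_list, spec = spec),
                 provenance = x$provenance),
            class = "network_mixture")
}

#' Run configuration
#'
#' Assembles the settings consumed by the pipeline commands
#' ([run_preprocess()], [run_fit()], [run_classify()], [run_report()]).
#' A JSON config file round-trips bit-exactly.
#'
#' @param data,spec,prior_edges,out_dir Input/output paths.
#' @param K,chi,penalty_factor,prevalence_threshold Model settings.
#' @param tol,max_iter,structure_every EM settings.
#' @param seed Master seed.
#' @param n_restarts,perturbation Robustness settings.
#' @param bm_variable,pb_variable Blast variable names (or `NULL`).
#' @param missing_action `"reject"` or `"drop"`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(data = NULL, spec = NULL, prior_edges = NULL,
                       out_dir = ".", K = 3L, chi = 0,
                       penalty_factor = 2, prevalence_threshold = 0.01,
                       tol = 1e-4, max_iter = 100L, structure_every = 5L,
                       seed = 1L, n_restarts = 20L, perturbation = 0.001,
                       bm_variable = NULL, pb_variable = NULL,
                       missing_action = "reject") {
  stopifnot(K >= 1, chi >= 0, penalty_factor >= 1,
            prevalence_threshold >= 0, prevalence_threshold <= 1,
            perturbation >= 0)
  structure(list(data = data, spec = spec, prior_edges = prior_edges,
                 out_dir = out_dir, K = as.integer(K),
                 chi = as.numeric(chi),
                 penalty_factor = as.numeric(penalty_factor),
                 prevalence_threshold = as.numeric(prevalence_threshold),
                 tol = as.numeric(tol),
                 max_iter = as.integer(max_iter),
                 structure_every = as.integer(structure_every),
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 perturbation = as.numeric(perturbation),
                 bm_variable = bm_variable,
                 pb_variable = pb_variable, missing_action = missing_action),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = I(17), null = "null",
                              pretty = TRUE),
             path)
  invisible(config)
}

preprocess_cohort <- function(data, config, provenance = NULL) {
  # with stored provenance (classification), replay the training decisions;
  # otherwise derive them from this cohort
  if (is.null(provenance)) {
    log <- list(prevalence_threshold = config$prevalence_threshold,
                medians = list(), blast_bins = list())
    data <- filter_by_prevalence(data, config$prevalence_threshold)
    log$dropped_features <- as.list(attr(data, "dropped_features"))
    blast_vars <- c(config$bm_variable, config$pb_variable)
    if (!is.null(config$bm_variable) || !is.null(config$pb_variable)) {
      data <- discretize_blasts(data, bm_variable = config$bm_variable,
                                pb_variable = config$pb_variable)
      log$blast_bins <- list(bm = config$bm_variable,
                             bm_breaks = c(11, 21),
                             pb = config$pb_variable, pb_breaks = 1)
    }
    for (v in data$spec$name[data$spec$dtype == "continuous"]) {
      data <- discretize_median(data, v)
      log$medians[[v]] <- attr(data, "medians")[[v]]
    }
    data <- handle_missing(data, config$missing_action)
    attr(data, "provenance") <- log
  } else {
    drop <- unlist(provenance$dropped_features)
    keep <- !(data$spec$name %in% drop)
    data$spec <- data$spec[keep, , drop = FALSE]
    rownames(data$spec) <- NULL
    data$values <- data$values[, data$spec$name, drop = FALSE]
    if (length(provenance$blast_bins))
      data <- discretize_blasts(data,
                                bm_variable = provenance$blast_bins$bm,
                                pb_variable = provenance$blast_bins$pb)
    for (v in names(provenance$medians))
      data <- apply_median_cutoff(data, v, provenance$medians[[v]])
    data <- handle_missing(data, config$missing_action)
    attr(data, "provenance") <- provenance
  }
  data
}

#' Pipeline command: preprocess a cohort
#'
#' Applies the prevalence filter, blast binning and median discretization
#' to a raw cohort and writes the preprocessed CSV, updated spec, and a
#' provenance log (dropped features, medians used, bin edges) to
#' `config$out_dir`.
#'
#' @param config A `run_config` (or path to its JSON).
#' @return The preprocessed `cohort_data`, invisibly.
#' @export
run_preprocess <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$data) || !file.exists(config$data))
    stop("data file not found: ", config$data)
  if (is.null(config$spec) || !file.exists(config$spec))
    stop("spec file not found: ", config$spec)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- read_cohort(config$data, config$spec)
  data <- preprocess_cohort(data, config)
  write_cohort(data, file.path(config$out_dir, "preprocessed.csv"),
               file.path(config$out_dir, "preprocessed_spec.tsv"))
  writeLines(jsonlite::toJSON(attr(data, "provenance"), auto_unbox = TRUE,
                              digits = I(17), pretty = TRUE),
             file.path(config$out_dir, "preprocess_log.json"))
  invisible(data)
}

write_memberships <- function(phi, labels, samples, dir) {
  phi_df <- data.frame(sample_id = samples, phi, check.names = FALSE)
  names(phi_df)[-1L] <- sprintf("cluster_%d", seq_len(ncol(phi)))
  utils::write.csv(phi_df, file.path(dir, "memberships.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample_id = samples, cluster = labels),
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
}

#' Pipeline command: fit the mixture
#'
#' Preprocesses the configured cohort, fits the covariate-adjusted network
#' mixture, and writes the model JSON (with preprocessing provenance),
#' memberships CSV and hard-label CSV to `config$out_dir`.
#'
#' @param config A `run_config` (or path to its JSON).
#' @return The fitted `network_mixture`, invisibly.
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- read_config(config)
  data <- run_preprocess(config)
  if (config$K > nrow(data$values))
    stop("K exceeds the number of samples")
  prior <- if (!is.null(config$prior_edges))
    load_prior_edges(config$prior_edges, data$spec, config$penalty_factor)
  else edge_prior(data$spec, NULL, config$penalty_factor)
  fit <- network_mixture(data, K = config$K, prior = prior,
                         chi = config$chi, seed = config$seed,
                         max_iter = config$max_iter, tol = config$tol,
                         structure_every = config$structure_every,
                         perturbation = config$perturbation)
  fit$provenance <- attr(data, "provenance")
  write_model(fit, file.path(config$out_dir, "model.json"))
  write_memberships(fit$memberships, fit$labels, data$samples,
                    config$out_dir)
  invisible(fit)
}

#' Pipeline command: classify an unseen cohort
#'
#' Loads a persisted model, re-applies its stored preprocessing provenance
#' (stored medians and bins, not recomputed ones) to the new cohort, and
#' writes memberships and hard labels.
#'
#' @param config A `run_config` (or path); `out_dir` receives the outputs.
#' @param model_path Path to a model JSON from [run_fit()].
#' @param cohort_path,spec_path Raw cohort CSV and spec TSV.
#' @return The membership matrix, invisibly.
#' @export
run_classify <- function(config, model_path, cohort_path, spec_path) {
  if (is.character(config)) config <- read_config(config)
  model <- read_model(model_path)
  data <- read_cohort(cohort_path, spec_path)
  data <- preprocess_cohort(data, config, provenance = model$provenance)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  phi <- predict(model, newdata = data)
  labels <- max.col(phi, ties.method = "first")
  write_memberships(phi, labels, data$samples, config$out_dir)
  invisible(phi)
}

#' Pipeline command: post-fit report
#'
#' Writes, for a fitted model on its training data: per-cluster node and
#' edge tables (TSV), the 2D MDS coordinates (CSV), and the robustness ARI
#' distribution over perturbed restarts (CSV).
#'
#' @param config A `run_config` (or path).
#' @param fit A fitted `network_mixture` with training data attached.
#' @param robustness Whether to run the perturbed-restart assessment.
#' @return Invisible list of the written tables.
#' @export
run_report <- function(config, fit, robustness = TRUE) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- list(); edges <- list()
  for (k in seq_len(fit$K)) {
    s <- summarize_cluster(fit, cluster = k, top_m = nrow(fit$spec))
    s$nodes$cluster <- k
    if (nrow(s$edges)) s$edges$cluster <- k
    nodes[[k]] <- s$nodes
    edges[[k]] <- s$edges
  }
  node_tab <- do.call(rbind, nodes)
  edge_tab <- do.call(rbind, edges[vapply(edges, nrow, integer(1)) > 0])
  utils::write.table(node_tab, file.path(config$out_dir, "node_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(edge_tab))
    utils::write.table(edge_tab, file.path(config$out_dir, "edge_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  xy <- mds_projection(fit, fit$data)
  utils::write.csv(data.frame(sample_id = rownames(xy), xy),
                   file.path(config$out_dir, "mds_coordinates.csv"),
                   row.names = FALSE, quote = FALSE)
  aris <- NULL
  if (robustness) {
    aris <- robustness_assessment(fit$data, fit,
                                  n_restarts = config$n_restarts,
                                  perturbation = config$perturbation,
                                  chi = fit$chi, max_iter = config$max_iter,
                                  tol = config$tol,
                                  structure_every = config$structure_every)
    utils::write.csv(data.frame(restart = seq_along(aris), ari = aris),
                     file.path(config$out_dir, "robustness_ari.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(nodes = node_tab, edges = edge_tab, mds = xy,
                 robustness = aris))
}
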