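#' Declare a modelled variable
#'
#' Builds a one-row variable specification describing how a column of a cohort
#' table enters the model: its causal role, its type, and (for discrete
#' variables) its ordered category labels.
#'
#' @param name Variable name, matching a column of the cohort table.
#' @param role One of `"cluster_independent_covariate"` (only outgoing edges,
#'   conditioned on in the membership probabilities; e.g. age, sex),
#'   `"cluster_dependent_covariate"` (clinical variable modelled alongside the
#'   mutations; e.g. blast counts), or `"genomic_feature"` (binary mutation or
#'   cytogenetic indicator).
#' @param dtype `"binary"`, `"categorical"` or `"continuous"`. Continuous
#'   variables must be discretized (see [discretize_median()],
#'   [discretize_blasts()]) before fitting.
#' @param modality Data modality used to build direction constraints:
#'   `"mutation"`, `"cytogenetic"`, `"blood"`, `"bone_marrow"`,
#'   `"demographic"` or `"other"`.
#' @param categories Ordered character vector of category labels; required for
#'   discrete variables. Binary variables default to `c("0", "1")`.
#' @return A one-row `data.frame` with a `categories` list column.
#' @export
variable_spec <- function(name, role, dtype,
                          modality = "other", categories = NULL) {
  role <- match.arg(role, c("cluster_independent_covariate",
                            "cluster_dependent_covariate",
                            "genomic_feature"))
  dtype <- match.arg(dtype, c("binary", "categorical", "continuous"))
  modality <- match.arg(modality, c("mutation", "cytogenetic", "blood",
                                    "bone_marrow", "demographic", "other"))
  if (dtype == "binary" && is.null(categories)) categories <- c("0", "1")
  if (dtype != "continuous") {
    if (is.null(categories) || length(categories) < 1L)
      stop("discrete variable '", name, "' needs non-empty categories")
    categories <- as.character(categories)
  } else {
    categories <- character(0)
  }
  out <- data.frame(name = as.character(name), role = role, dtype = dtype,
                    modality = modality, stringsAsFactors = FALSE)
  out$categories <- list(categories)
  out
}

#' Bind variable specifications into a spec table
#'
#' @param ... One-row specs from [variable_spec()] (or spec tables to append).
#' @return A validated spec `data.frame`.
#' @export
spec_table <- function(...) {
  spec <- do.call(rbind, list(...))
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("name", "role", "dtype", "modality", "categories") %in%
                  names(spec)))
  if (anyDuplicated(spec$name))
    stop("duplicate variable names in spec")
  disc <- spec$dtype != "continuous"
  if (any(disc & lengths(spec$categories) == 0L))
    stop("discrete variable without categories")
  invisible(spec)
}

n_categories <- function(spec) {
  ifelse(spec$dtype == "continuous", NA_integer_, lengths(spec$categories))
}

#' Assemble a cohort data matrix
#'
#' Combines a samples-by-variables table with a variable specification into
#' the container consumed by every modelling stage. Discrete variables are
#' stored as 1-based category codes; continuous variables stay numeric until
#' discretized. Character or factor columns are matched against the declared
#' category labels.
#'
#' @param values A `data.frame` (or matrix) with one row per sample and one
#'   column per declared variable. Row names, if present, become sample
#'   identifiers.
#' @param spec A spec table from [spec_table()] covering every column.
#' @param samples Optional character vector of unique sample identifiers.
#' @param codes If `TRUE`, numeric discrete columns are taken to be 1-based
#'   category codes as stored internally. If `FALSE` (default), numeric
#'   values of binary 0/1 variables are read as raw indicator values.
#' @return An object of class `cohort_data` with elements `values`
#'   (integer codes / numeric), `spec` and `samples`.
#' @export
cohort_data <- function(values, spec, samples = NULL, codes = FALSE) {
  validate_spec(spec)
  values <- as.data.frame(values)
  missing_vars <- setdiff(spec$name, names(values))
  if (length(missing_vars))
    stop("variables missing from data: ", paste(missing_vars, collapse = ", "))
  values <- values[, spec$name, drop = FALSE]
  if (is.null(samples)) {
    samples <- rownames(values)
    if (is.null(samples) || identical(samples, as.character(seq_len(nrow(values)))))
      samples <- sprintf("S%d", seq_len(nrow(values)))
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  if (length(samples) != nrow(values)) stop("sample id length mismatch")

  for (j in seq_len(nrow(spec))) {
    v <- spec$name[j]
    col <- values[[v]]
    if (spec$dtype[j] == "continuous") {
      values[[v]] <- as.numeric(col)
    } else {
      cats <- spec$categories[[j]]
      if (is.factor(col)) col <- as.character(col)
      if (is.character(col)) {
        code <- match(col, cats)
        if (any(is.na(code) & !is.na(col)))
          stop("invalid category in variable '", v, "'")
      } else {
        code <- as.integer(col)
        # numeric input: raw 0/1 indicators unless declared as codes
        if (!codes && identical(cats, c("0", "1"))) {
          if (!all(code %in% c(0L, 1L, NA)))
            stop("invalid category in variable '", v,
                 "' (expected raw 0/1; use codes = TRUE for category codes)")
          code <- code + 1L
        }
        if (any(!is.na(code) & (code < 1L | code > length(cats))))
          stop("invalid category in variable '", v, "'")
      }
      values[[v]] <- as.integer(code)
    }
  }
  rownames(values) <- samples
  structure(list(values = values, spec = spec, samples = samples),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", nrow(x$values), "samples x", ncol(x$values),
      "variables\n")
  tab <- table(x$spec$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort_data <- function(x) dim(x$values)

#' Convert a cohort back to labelled form
#'
#' @param x A `cohort_data` object.
#' @param ... Unused.
#' @return A `data.frame` with category labels for discrete variables.
#' @export
as.data.frame.cohort_data <- function(x, ...) {
  out <- x$values
  for (j in seq_len(nrow(x$spec))) {
    if (x$spec$dtype[j] != "continuous") {
      cats <- x$spec$categories[[j]]
      out[[x$spec$name[j]]] <- cats[out[[x$spec$name[j]]]]
    }
  }
  out
}

spec_row <- function(spec, name) {
  i <- match(name, spec$name)
  if (is.na(i)) stop("unknown variable: ", name)
  i
}

#' Drop rare genomic features
#'
#' Removes binary genomic features whose prevalence (fraction of non-missing
#' samples carrying the alteration) falls below `threshold`. Covariates are
#' never removed, whatever their frequency; variable order is otherwise
#' preserved.
#'
#' @param data A `cohort_data` object.
#' @param threshold Prevalence threshold in `[0, 1]`; features with
#'   prevalence strictly below it are dropped. Default 0.01 (1%).
#' @return A filtered `cohort_data`.
#' @export
filter_by_prevalence <- function(data, threshold = 0.01) {
  stopifnot(inherits(data, "cohort_data"),
            is.numeric(threshold), threshold >= 0, threshold <= 1)
  spec <- data$spec
  keep <- rep(TRUE, nrow(spec))
  for (j in seq_len(nrow(spec))) {
    if (spec$role[j] != "genomic_feature" || spec$dtype[j] != "binary") next
    col <- data$values[[spec$name[j]]]
    prev <- mean(col == 2L, na.rm = TRUE)
    if (is.nan(prev)) prev <- 0
    keep[j] <- prev >= threshold
  }
  if (!any(keep & spec$role == "genomic_feature") &&
      any(spec$role == "genomic_feature"))
    stop("empty feature set: all genomic features removed by prevalence filter")
  out <- data
  out$spec <- spec[keep, , drop = FALSE]
  rownames(out$spec) <- NULL
  out$values <- data$values[, spec$name[keep], drop = FALSE]
  attr(out, "dropped_features") <- spec$name[!keep]
  out
}

#' Median-split a continuous variable
#'
#' Replaces a continuous variable by a binary low/high indicator using the
#' median of the non-missing values as cutoff; values strictly above the
#' median map to `"high"`, values at or below it (including ties at the
#' median) map to `"low"`.
#'
#' @param data A `cohort_data` object.
#' @param variable Name of a continuous variable with at least two distinct
#'   non-missing values.
#' @return The updated `cohort_data`; the cutoff is recorded in
#'   `attr(, "medians")`.
#' @export
discretize_median <- function(data, variable) {
  stopifnot(inherits(data, "cohort_data"))
  j <- spec_row(data$spec, variable)
  if (data$spec$dtype[j] != "continuous")
    stop("variable '", variable, "' is not continuous")
  x <- data$values[[variable]]
  med <- stats::median(x, na.rm = TRUE)
  if (length(unique(x[!is.na(x)])) < 2L)
    stop("constant variable, cannot discretize: ", variable)
  data$values[[variable]] <- ifelse(is.na(x), NA_integer_,
                                    ifelse(x > med, 2L, 1L))
  data$spec$dtype[j] <- "binary"
  data$spec$categories[[j]] <- c("low", "high")
  meds <- attr(data, "medians")
  meds[[variable]] <- med
  attr(data, "medians") <- meds
  data
}

#' Apply a stored median cutoff
#'
#' Used when classifying unseen cohorts: the cutoff learned on the training
#' cohort is applied verbatim instead of recomputing a median.
#'
#' @param data A `cohort_data` object.
#' @param variable Continuous variable name.
#' @param cutoff Stored median value.
#' @return The updated `cohort_data`.
#' @export
apply_median_cutoff <- function(data, variable, cutoff) {
  stopifnot(inherits(data, "cohort_data"))
  j <- spec_row(data$spec, variable)
  if (data$spec$dtype[j] != "continuous")
    stop("variable '", variable, "' is not continuous")
  x <- data$values[[variable]]
  data$values[[variable]] <- ifelse(is.na(x), NA_integer_,
                                    ifelse(x > cutoff, 2L, 1L))
  data$spec$dtype[j] <- "binary"
  data$spec$categories[[j]] <- c("low", "high")
  data
}

BM_BLAST_CATEGORIES <- c("0-10", "11-20", "21-100")
PB_BLAST_CATEGORIES <- c("zero", "1-100")

#' Bin blast percentages into clinical ranges
#'
#' Bone marrow (BM) blast percentages are binned into three established
#' hematopathological ranges, 0-10, 11-20 and 21-100; peripheral blood (PB)
#' blasts into two, exactly zero versus 1-100. Non-integer percentages are
#' rounded half-to-even to an integer before binning.
#'
#' @param data A `cohort_data` object.
#' @param bm_variable,pb_variable Names of the continuous BM / PB blast
#'   variables; either may be `NULL` to skip.
#' @return The updated `cohort_data`.
#' @export
discretize_blasts <- function(data, bm_variable = "BM_blast",
                              pb_variable = "PB_blast") {
  stopifnot(inherits(data, "cohort_data"))
  bin_one <- function(data, variable, breaks, cats) {
    j <- spec_row(data$spec, variable)
    if (data$spec$dtype[j] != "continuous")
      stop("variable '", variable, "' is not continuous")
    x <- data$values[[variable]]
    if (any(!is.na(x) & (x < 0 | x > 100)))
      stop("blast percentage out of range in '", variable, "'")
    xi <- round(x)  # round() is round-half-to-even in R
    code <- findInterval(xi, breaks) + 1L
    data$values[[variable]] <- ifelse(is.na(x), NA_integer_, as.integer(code))
    data$spec$dtype[j] <- "categorical"
    data$spec$categories[[j]] <- cats
    data
  }
  if (!is.null(bm_variable))
    data <- bin_one(data, bm_variable, breaks = c(11, 21),
                    cats = BM_BLAST_CATEGORIES)
  if (!is.null(pb_variable))
    data <- bin_one(data, pb_variable, breaks = c(1),
                    cats = PB_BLAST_CATEGORIES)
  data
}

#' Drop samples with missing modelled values
#'
#' The mixture model requires complete data on all modelled variables. By
#' default samples with any missing modelled value are rejected with an
#' error; with `action = "drop"` they are removed with a warning.
#'
#' @param data A `cohort_data` object.
#' @param action `"reject"` (default) or `"drop"`.
#' @return A complete-case `cohort_data`.
#' @export
handle_missing <- function(data, action = c("reject", "drop")) {
  action <- match.arg(action)
  bad <- rowSums(is.na(as.matrix(data$values))) > 0L
  if (!any(bad)) return(data)
  if (action == "reject")
    stop(sum(bad), " sample(s) have missing modelled values; ",
         "use action = 'drop' to remove them")
  warning("dropping ", sum(bad), " sample(s) with missing modelled values")
  data$values <- data$values[!bad, , drop = FALSE]
  data$samples <- data$samples[!bad]
  data
}
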