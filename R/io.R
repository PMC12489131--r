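# Readers/writers for subject tables, model serialization and run
# configuration.

MODEL_FORMAT_VERSION <- "1.0"

#' Declare the column roles of a cohort table
#'
#' A schema maps columns of a delimited subject table onto the roles the
#' pipeline understands: the subject key, cohort and timepoint labels, the
#' six analysis features, and optional covariate, diagnosis and environment
#' blocks.
#'
#' @param id Subject key column name.
#' @param cohort,timepoint Grouping column names (`NULL` if absent).
#' @param features Character vector of analysis feature columns. The default
#'   is the canonical six-feature set: three cognitive factors (`VA`,
#'   `EFPS`, `MEM`) and three behavioral scores (`internalizing`,
#'   `externalizing`, `stress`).
#' @param covariates,diagnoses,environment Optional character vectors.
#' @return A list with class `cohort_schema`.
#' @export
#' @examples
#' cohort_schema(diagnoses = c("AD", "ADHD"))
cohort_schema <- function(id = "subject_id",
                          cohort = "cohort",
                          timepoint = "timepoint",
                          features = c("VA", "EFPS", "MEM",
                                       "internalizing", "externalizing",
                                       "stress"),
                          covariates = NULL,
                          diagnoses = NULL,
                          environment = NULL) {
  structure(list(id = id, cohort = cohort, timepoint = timepoint,
                 features = features, covariates = covariates,
                 diagnoses = diagnoses, environment = environment),
            class = "cohort_schema")
}

schema_required <- function(schema) {
  c(schema$id, schema$cohort, schema$timepoint, schema$features,
    schema$covariates, schema$diagnoses, schema$environment)
}

#' Read a delimited cohort table
#'
#' Reads a comma- or tab-delimited subject table (one row per subject per
#' timepoint), checks that every column the schema declares is present, and
#' enforces uniqueness of the subject-by-timepoint key. Missing values may be
#' encoded as empty fields or `NA`; row order is preserved.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @param schema A [cohort_schema()].
#' @return A tibble with one row per subject per timepoint.
#' @export
read_cohort_table <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  # base strtod parsing round-trips %.17g decimal text bit-exactly
  data <- as_tibble(utils::read.table(path, header = TRUE, sep = delim,
                                      na.strings = c("", "NA"),
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE,
                                      quote = "\"", comment.char = ""))
  check_columns(data, schema_required(schema), "declared column")
  key <- data[[schema$id]]
  if (!is.null(schema$timepoint) && schema$timepoint %in% names(data)) {
    key <- paste(key, data[[schema$timepoint]], sep = "\r")
  }
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("Duplicate subject_id x timepoint key: ",
                 gsub("\r", " / ", dup)),
          class = "fp_integrity_error")
  }
  for (dx in schema$diagnoses) {
    bad <- !is.na(data[[dx]]) & !data[[dx]] %in% c(0, 1)
    if (any(bad)) {
      abort(paste0("Diagnosis column '", dx, "' must be 0/1/missing."),
            class = "fp_integrity_error")
    }
  }
  fp_log("read_cohort_table", path = path, n = nrow(data))
  data
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort_table()]: UTF-8 delimited text with a header,
#' missing values written as `NA`, full-precision numerics (values round-trip
#' exactly).
#'
#' @param data A data frame.
#' @param path Output path; a `.tsv`/`.txt` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(data, path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  out <- as.data.frame(data)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    } else if (is.character(out[[j]]) &&
               any(grepl(delim, out[[j]], fixed = TRUE), na.rm = TRUE)) {
      abort("Character fields must not contain the delimiter.")
    }
  }
  utils::write.table(out, path, sep = delim, na = "NA", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a fitted profile model
#'
#' Writes a versioned, human-readable JSON document holding the centroids,
#' per-profile covariance matrices, fuzzifier, feature names, labels and fit
#' metadata at full double precision, so membership predictions after a
#' round trip are bit-identical. This is the exchange format that lets a new
#' study reuse centroids fitted on a reference cohort.
#'
#' @param model A `profile_model` from [fit_fcm()].
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @seealso [read_profile_model()]
#' @export
write_profile_model <- function(model, path) {
  stopifnot(inherits(model, "profile_model"))
  doc <- list(
    format = "fuzzyprofiles/profile_model",
    version = MODEL_FORMAT_VERSION,
    k = model$k,
    m = model$m,
    features = model$features,
    labels = model$labels,
    centroids = apply(model$centroids, 1, as.numeric, simplify = FALSE),
    covariances = lapply(model$covariances, function(s) {
      apply(s, 1, as.numeric, simplify = FALSE)
    }),
    objective = model$objective,
    n_iter = model$n_iter,
    tol = model$tol,
    seed = model$seed
  )
  # digits = I(17): decimal shortest-exact for IEEE doubles, so centroids
  # and covariances round-trip bit-identically.
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized profile model
#'
#' Validates the document version and the model invariants (finite
#' centroids, symmetric positive-definite covariances) before returning.
#'
#' @param path Path to a JSON document written by [write_profile_model()].
#' @return A `profile_model`.
#' @export
read_profile_model <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "fuzzyprofiles/profile_model")) {
    abort("Not a profile model document.", class = "fp_format_error")
  }
  if (!identical(doc$version, MODEL_FORMAT_VERSION)) {
    abort(paste0("Model format version mismatch: file has '", doc$version,
                 "', reader supports '", MODEL_FORMAT_VERSION, "'."),
          class = "fp_format_error")
  }
  as_mat <- function(x) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
  cent <- as_mat(doc$centroids)
  dimnames(cent) <- list(doc$labels, doc$features)
  covs <- lapply(doc$covariances, function(rows) {
    s <- as_mat(rows)
    dimnames(s) <- list(doc$features, doc$features)
    s
  })
  names(covs) <- doc$labels
  model <- new_profile_model(
    centroids = cent, covariances = covs, m = as.numeric(doc$m),
    k = as.integer(doc$k), labels = doc$labels, features = doc$features,
    objective = as.numeric(doc$objective), n_iter = as.integer(doc$n_iter),
    tol = as.numeric(doc$tol), seed = doc$seed
  )
  validate_profile_model(model)
  model
}

#' Run configuration with the pipeline's analysis defaults
#'
#' Bundles the tunable parameters shared across stages: the fuzzifier, the
#' candidate profile counts, permutation iteration counts (5000 for the
#' graph test, 10000 for the regression test), cross-validation folds,
#' imputation neighborhood size, the FDR threshold and the edge distance
#' transform, plus the single global seed from which every stage derives
#' its own substream via [substream_seed()].
#'
#' @param seed Integer global seed.
#' @param m Fuzzifier, > 1.
#' @param k_range Integer vector of candidate profile counts.
#' @param n_perm_graph,n_perm_plsr Permutation counts for the graph and
#'   regression tests.
#' @param cv_folds Cross-validation folds for component selection.
#' @param knn_k Neighborhood size for imputation.
#' @param fdr_alpha Significance threshold on FDR-adjusted p-values.
#' @param distance_transform `"one_minus_u"` or `"neg_log_u"`.
#' @return A list with class `run_config`.
#' @export
run_config <- function(seed = 1L, m = 2, k_range = 2:10,
                       n_perm_graph = 5000L, n_perm_plsr = 10000L,
                       cv_folds = 10L, knn_k = 5L, fdr_alpha = 0.05,
                       distance_transform = c("one_minus_u", "neg_log_u")) {
  distance_transform <- match.arg(distance_transform)
  cfg <- list(seed = as.integer(seed), m = m, k_range = as.integer(k_range),
              n_perm_graph = as.integer(n_perm_graph),
              n_perm_plsr = as.integer(n_perm_plsr),
              cv_folds = as.integer(cv_folds), knn_k = as.integer(knn_k),
              fdr_alpha = fdr_alpha, distance_transform = distance_transform)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$m <= 1) abort("Fuzzifier m must be > 1.")
  counts <- c(cfg$k_range, cfg$n_perm_graph, cfg$n_perm_plsr, cfg$cv_folds,
              cfg$knn_k)
  if (any(counts < 1)) abort("All counts must be >= 1.")
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) {
    abort("fdr_alpha must lie in (0, 1).")
  }
  invisible(TRUE)
}

#' Read or write a run configuration as YAML
#'
#' @param path Path to a YAML document.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration keys: ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
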