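# Cross-cohort harmonization, covariate residualization and KNN imputation.

#' Harmonize features across cohorts and follow-ups
#'
#' Removes cohort-specific location and scale differences by z-scoring each
#' feature within each group (cohort, or cohort-by-timepoint), so every
#' group's feature distribution has mean 0 and standard deviation 1 before
#' joint analysis. The per-group transformation parameters are attached as
#' the `"harmonization"` attribute. The operation is idempotent: a second
#' pass is the identity up to round-off.
#'
#' @param data Data frame with feature and grouping columns.
#' @param features Feature column names.
#' @param by Grouping column names; defaults to whichever of `cohort` and
#'   `timepoint` are present.
#' @param reference Optional reference group label (recorded in the report;
#'   with location/scale standardization every group is anchored to
#'   mean 0 / sd 1, so the reference is a labeling convention).
#' @return `data` with the feature columns rescaled; missing values are
#'   left missing and ignored when estimating the parameters.
#' @export
harmonize <- function(data, features, by = NULL, reference = NULL) {
  if (is.null(by)) by <- intersect(c("cohort", "timepoint"), names(data))
  check_columns(data, c(features, by))
  groups <- if (length(by) == 0) rep("all", nrow(data)) else {
    interaction(as.data.frame(data)[, by, drop = FALSE], drop = TRUE,
                sep = " / ")
  }
  out <- data
  report <- list()
  for (g in levels(factor(groups))) {
    rows <- which(groups == g)
    for (f in features) {
      v <- out[[f]][rows]
      ok <- !is.na(v)
      if (sum(ok) == 0) next # declared-missing cell; left for imputation
      if (sum(ok) < 2) {
        abort(paste0("Fewer than 2 non-missing values for ", f, " in ", g,
                     "."), class = "fp_degenerate_scale_error")
      }
      mu <- mean(v[ok])
      sigma <- sd(v[ok])
      if (!is.finite(sigma) || sigma < 1e-12) {
        abort(paste0("Constant feature '", f, "' in group '", g,
                     "': scale is degenerate."),
              class = "fp_degenerate_scale_error")
      }
      out[[f]][rows] <- (v - mu) / sigma
      report[[length(report) + 1]] <-
        tibble(group = g, feature = f, mean = mu, sd = sigma)
    }
  }
  rep_tbl <- dplyr::bind_rows(report)
  rep_tbl$reference <- if (is.null(reference)) FALSE else {
    grepl(reference, rep_tbl$group, fixed = TRUE)
  }
  attr(out, "harmonization") <- rep_tbl
  fp_log("harmonize", groups = nlevels(factor(groups)),
         features = length(features))
  out
}

#' Residualize features on covariates
#'
#' Replaces each feature by its least-squares residual on an intercept plus
#' the covariates, then re-standardizes, so downstream profiles reflect
#' cognition and behavior net of demographic structure (age, sex, ethnicity,
#' handedness). Categorical covariates are expanded to treatment-coded
#' indicators with the most frequent level as reference. A rank-deficient
#' design after expansion is handled by dropping the redundant columns with
#' a warning. Residuals are exactly orthogonal to every retained covariate
#' column.
#'
#' @param data Data frame with feature and covariate columns.
#' @param features Feature column names (missing feature values are carried
#'   through as missing; an all-missing feature is an error).
#' @param covariates Covariate column names.
#' @return `data` with the feature columns replaced by standardized
#'   residuals.
#' @export
residualize <- function(data, features, covariates) {
  check_columns(data, c(features, covariates))
  df <- as.data.frame(data)[, covariates, drop = FALSE]
  for (v in names(df)) {
    if (is.character(df[[v]]) || is.factor(df[[v]]) || is.logical(df[[v]])) {
      tab <- sort(table(df[[v]]), decreasing = TRUE)
      df[[v]] <- factor(df[[v]], levels = names(tab))
    }
  }
  mf <- stats::model.frame(~ ., data = df, na.action = stats::na.pass)
  mm <- model.matrix(~ ., data = mf)
  out <- data
  for (f in features) {
    y <- out[[f]]
    ok <- !is.na(y) & stats::complete.cases(df)
    if (!any(ok)) abort(paste0("Feature '", f, "' has no usable values."))
    fit <- lm.fit(mm[ok, , drop = FALSE], y[ok])
    if (fit$rank < ncol(mm)) {
      dropped <- colnames(mm)[is.na(fit$coefficients)]
      warn(paste0("Collinear covariate design; dropped: ",
                  paste(dropped, collapse = ", ")))
    }
    res <- rep(NA_real_, length(y))
    res[ok] <- fit$residuals
    s <- sd(res, na.rm = TRUE)
    if (!is.finite(s) || s < 1e-12) {
      # A perfectly explained feature leaves a zero residual vector.
      res[ok] <- 0
    } else {
      res <- (res - mean(res, na.rm = TRUE)) / s
    }
    out[[f]] <- res
  }
  out
}

#' K-nearest-neighbor imputation of one feature
#'
#' Fills missing values of `target` with the unweighted mean of the `k`
#' nearest donors (rows where `target` is observed) in Euclidean distance
#' over the standardized remaining features. Observed target values are
#' never touched. The per-row donor report (donor ids and distances) is
#' attached as the `"imputation"` attribute.
#'
#' @param data Data frame.
#' @param target Name of the feature to impute.
#' @param predictors Feature columns used for the distance; defaults to
#'   every feature except the target. They must be complete for all rows
#'   being imputed.
#' @param k Number of donors (default 5).
#' @return `data` with `target` completed.
#' @export
impute_knn <- function(data, target, predictors, k = 5) {
  check_columns(data, c(target, predictors))
  miss <- which(is.na(data[[target]]))
  if (length(miss) == 0) return(data)
  donors <- which(!is.na(data[[target]]))
  if (length(donors) < k) {
    abort(paste0("Only ", length(donors), " donor rows for '", target,
                 "' but k = ", k, "."))
  }
  px <- feature_matrix(data, predictors)
  px <- scale(px)
  bad <- miss[!stats::complete.cases(px[miss, , drop = FALSE])]
  if (length(bad) > 0) {
    abort(paste0("All predictors missing for row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  out <- data
  ids <- subject_ids(data, nrow(data))
  report <- vector("list", length(miss))
  for (j in seq_along(miss)) {
    r <- miss[j]
    d <- sqrt(rowSums(sweep(px[donors, , drop = FALSE], 2, px[r, ], "-")^2))
    nn <- donors[order(d)[seq_len(k)]]
    out[[target]][r] <- mean(data[[target]][nn])
    report[[j]] <- tibble(row = r, subject_id = ids[r],
                          donor_id = ids[nn], distance = sort(d)[seq_len(k)])
  }
  attr(out, "imputation") <- dplyr::bind_rows(report)
  fp_log("impute_knn", target = target, k = k, imputed = length(miss))
  out
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying the pipeline's stage order: harmonize within
#' cohort/timepoint, impute any declared missing feature, residualize on
#' covariates, and re-standardize — producing the complete n x 6 analysis
#' matrix.
#'
#' @param data Data frame of stacked cohort rows.
#' @param features Feature column names.
#' @param covariates Covariate column names (skipped if `NULL`).
#' @param impute_target Feature to KNN-impute after harmonization (skipped
#'   if `NULL` or complete).
#' @param knn_k Donors for imputation.
#' @param by Harmonization grouping columns (see [harmonize()]).
#' @return A tibble with preprocessed features; no missing entries among
#'   `features`.
#' @export
preprocess_features <- function(data, features, covariates = NULL,
                                impute_target = NULL, knn_k = 5, by = NULL) {
  out <- harmonize(data, features, by = by)
  if (!is.null(impute_target) && anyNA(out[[impute_target]])) {
    out <- impute_knn(out, impute_target,
                      predictors = setdiff(features, impute_target),
                      k = knn_k)
  }
  if (!is.null(covariates)) {
    out <- residualize(out, features, covariates)
  }
  for (f in features) {
    v <- out[[f]]
    out[[f]] <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  }
  as_tibble(out)
}
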