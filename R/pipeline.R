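# End-to-end analysis driver: simulate (or accept) a multi-cohort study,
# preprocess, fit and label profiles on the reference cohort, predict the
# validation cohorts, test diagnosis aggregation on the membership graph,
# summarize longitudinal transitions, and relate environmental predictors
# to memberships.

#' Run the full profiling pipeline on a multi-cohort study
#'
#' Orchestrates every stage with substreams of the single configuration
#' seed: preprocessing (per-cohort/timepoint harmonization, KNN imputation
#' of declared-missing features, covariate residualization), silhouette
#' selection of the profile count on the reference cohort's first
#' timepoint, fuzzy C-means fitting, Mahalanobis membership computation
#' and centroid-based prediction for the remaining cohorts, ASWP
#' permutation tests per diagnosis (plus the any-diagnosis index) with
#' BH-FDR across diagnoses within each cohort, independent per-timepoint
#' refits aligned by centroid matching for transition summaries, and a
#' permutation-validated PLSR of environmental predictors on memberships.
#'
#' @param data A stacked cohort tibble (as from [generate_cohorts()]).
#' @param config A [run_config()].
#' @param reference Reference cohort label fitted from scratch; all other
#'   cohorts are predicted from its centroids.
#' @param features,covariates,diagnoses Column names; defaults match the
#'   canonical schema.
#' @param env Environmental predictor columns (`NULL` disables the
#'   regression stage).
#' @param impute_target Feature to KNN-impute when missing.
#' @param k Fixed profile count (skips silhouette selection when given).
#' @param label_threshold Centroid threshold for [label_profiles()].
#' @return A `profile_study` list: `model`, `k_selection`, `memberships`
#'   (per cohort), `aswp` (tidy tibble), `transitions`, `trajectories`,
#'   `plsr`, and the preprocessed `data`.
#' @export
run_study <- function(data, config = run_config(),
                      reference = "ABCD",
                      features = c("VA", "EFPS", "MEM", "internalizing",
                                   "externalizing", "stress"),
                      covariates = c("age_months", "sex", "ethnicity",
                                     "handedness"),
                      diagnoses = c("AD", "ADHD", "CD", "DD", "OCD",
                                    "ODD"),
                      env = grep("^env_", names(data), value = TRUE),
                      impute_target = "stress",
                      k = NULL, label_threshold = 0.5) {
  stopifnot(inherits(config, "run_config"))
  diagnoses <- intersect(diagnoses, names(data))
  if (length(env) == 0) env <- NULL
  pp <- preprocess_features(data, features,
                            covariates = intersect(covariates,
                                                   names(data)),
                            impute_target = impute_target,
                            knn_k = config$knn_k)
  ref1 <- pp[pp$cohort == reference & pp$timepoint == "T1", ]
  if (nrow(ref1) == 0) abort("Reference cohort has no T1 rows.")

  sel <- NULL
  if (is.null(k)) {
    sel <- select_k(ref1, features, k_range = config$k_range,
                    m = config$m, seed = substream_seed(config$seed,
                                                        "select_k"))
    k <- sel$k_best
  }
  model <- fit_fcm(ref1, features, k = k, m = config$m,
                   seed = substream_seed(config$seed, "fcm"))
  model <- label_profiles(model, threshold = label_threshold)

  cohorts <- unique(pp$cohort)
  memberships <- list()
  for (co in cohorts) {
    sub <- pp[pp$cohort == co & pp$timepoint == "T1", ]
    memberships[[co]] <- predict(model, sub)
  }

  # Diagnosis aggregation on the reference cohort's membership graph.
  aswp_tbl <- NULL
  if (length(diagnoses) > 0) {
    graph <- build_membership_graph(memberships[[reference]],
                                    transform = config$distance_transform)
    dmat <- subject_distance_matrix(graph)
    ref_rows <- data[data$cohort == reference & data$timepoint == "T1", ]
    flag_sets <- c(
      lapply(setNames(diagnoses, diagnoses),
             function(dx) ref_rows[[dx]]),
      list(PSYPATHO = psypatho_index(ref_rows, diagnoses))
    )
    results <- list()
    for (nm in names(flag_sets)) {
      flags <- flag_sets[[nm]]
      flags[is.na(flags)] <- 0
      if (sum(flags) < 2) next
      res <- aswp_permutation_test(
        graph, flags, B = config$n_perm_graph,
        seed = substream_seed(config$seed, paste0("aswp_", nm)),
        label_name = nm, dist_matrix = dmat
      )
      results[[nm]] <- tidy(res)
    }
    aswp_tbl <- dplyr::bind_rows(results)
    if (!is.null(aswp_tbl) && nrow(aswp_tbl) > 0) {
      adj <- fdr_bh(aswp_tbl$p_left, alpha = config$fdr_alpha)
      aswp_tbl$p_left_fdr <- adj$p_fdr
      aswp_tbl$significant <- adj$reject
    }
  }

  # Longitudinal transitions: independent per-timepoint fits on the
  # reference cohort, aligned to the T1 model by centroid matching.
  transitions <- NULL
  trajectories <- NULL
  tps <- sort(unique(pp$timepoint[pp$cohort == reference]))
  if (length(tps) >= 2) {
    assignments <- list(main_profile(memberships[[reference]]))
    for (tp in tps[-1]) {
      sub <- pp[pp$cohort == reference & pp$timepoint == tp, ]
      fit_tp <- fit_fcm(sub, features, k = k, m = config$m,
                        seed = substream_seed(config$seed,
                                              paste0("fcm_", tp)))
      fit_tp <- relabel_profiles(fit_tp, match_profiles(fit_tp, model))
      fit_tp$labels <- model$labels
      rownames(fit_tp$centroids) <- model$labels
      u_tp <- predict(fit_tp, sub)
      names(u_tp)[-1] <- model$labels
      assignments[[length(assignments) + 1]] <- main_profile(u_tp)
    }
    transitions <- lapply(seq_len(length(assignments) - 1), function(i) {
      transition_summary(assignments[[i]], assignments[[i + 1]])
    })
    names(transitions) <- paste0(tps[-length(tps)], "_to_", tps[-1])
    if (length(assignments) >= 3) {
      trajectories <- trajectory_paths(assignments)
    }
  }

  # Environmental associations on the reference cohort.
  plsr <- NULL
  if (!is.null(env)) {
    ref_rows <- data[data$cohort == reference & data$timepoint == "T1", ]
    x <- ref_rows[, env]
    y <- memberships[[reference]]
    selc <- plsr_select_components(
      x, y, folds = config$cv_folds,
      seed = substream_seed(config$seed, "plsr_cv")
    )
    plsr <- plsr_permutation(
      x, y, ncomp = selc$a_best, B = config$n_perm_plsr,
      seed = substream_seed(config$seed, "plsr_perm"),
      fdr_alpha = config$fdr_alpha
    )
    plsr$component_selection <- selc
  }

  structure(list(model = model, k_selection = sel,
                 memberships = memberships, aswp = aswp_tbl,
                 transitions = transitions, trajectories = trajectories,
                 plsr = plsr, data = pp, config = config),
            class = "profile_study")
}

#' @export
print.profile_study <- function(x, ...) {
  cat("Fuzzy profile study (k =", x$model$k, ")\n")
  cat("Profiles:", paste(x$model$labels, collapse = ", "), "\n")
  cat("Cohorts:", paste(names(x$memberships), collapse = ", "), "\n")
  if (!is.null(x$aswp)) {
    cat("\nDiagnosis aggregation (ASWP):\n")
    print(as.data.frame(x$aswp[, c("label", "aswp", "p_left",
                                   "p_left_fdr")]))
  }
  if (!is.null(x$transitions)) {
    for (nm in names(x$transitions)) {
      cat("\n", nm, ": ",
          sprintf("%.2f%%", x$transitions[[nm]]$stability_percent),
          " stable\n", sep = "")
    }
  }
  if (!is.null(x$plsr)) {
    cat("\nEnvironment PLSR: R^2 =",
        format(x$plsr$fit$r_squared, digits = 3),
        ", model p =", format(x$plsr$model_p, digits = 3), "\n")
  }
  invisible(x)
}
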