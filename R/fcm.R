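# Fuzzy C-means profiles: fitting, Mahalanobis memberships, model selection,
# out-of-sample prediction and profile labeling.

new_profile_model <- function(centroids, covariances, m, k, labels, features,
                              objective, n_iter, tol, seed,
                              objective_trace = NULL) {
  structure(list(centroids = centroids, covariances = covariances, m = m,
                 k = k, labels = labels, features = features,
                 objective = objective, n_iter = n_iter, tol = tol,
                 seed = seed, objective_trace = objective_trace),
            class = "profile_model")
}

validate_profile_model <- function(model) {
  if (any(!is.finite(model$centroids))) abort("Centroids must be finite.")
  if (anyDuplicated(model$labels)) abort("Profile labels must be unique.")
  if (model$m <= 1) abort("Fuzzifier m must be > 1.")
  for (i in seq_along(model$covariances)) {
    s <- model$covariances[[i]]
    if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s)))) {
      abort(paste0("Covariance ", i, " is not symmetric."),
            class = "fp_model_invariant_error")
    }
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      abort(paste0("Covariance ", i, " is not positive definite."),
            class = "fp_model_invariant_error")
    }
  }
  invisible(model)
}

# One FCM alternating-optimization run from a given centroid init.
# Returns centroids, Euclidean memberships, objective and its trace.
fcm_run <- function(x, k, m, tol, max_iter, centers) {
  n <- nrow(x)
  u <- euclidean_memberships(x, centers, m)
  trace <- numeric(0)
  j_prev <- Inf
  for (iter in seq_len(max_iter)) {
    um <- u^m
    w <- colSums(um)
    if (any(w < 1e-300)) w <- pmax(w, 1e-300)
    centers <- crossprod(um, x) / w
    d2 <- cross_dist2(x, centers)
    j <- sum(um * d2)
    # The alternating updates cannot increase J beyond round-off.
    if (j > j_prev * (1 + 1e-10) + 1e-12) {
      abort("FCM objective increased between iterations.")
    }
    trace <- c(trace, j)
    j_prev <- j
    u_new <- memberships_from_dist2(d2, m)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  list(centers = centers, u = u, objective = j_prev, n_iter = iter,
       trace = trace)
}

# Membership formula from squared distances: u_ik = d_ik^{-1/(m-1)} /
# sum_j d_jk^{-1/(m-1)} (on squared distances, i.e. the 2/(m-1) exponent on
# d). Rows with a zero distance become indicators split over the zeros.
memberships_from_dist2 <- function(d2, m) {
  expo <- -1 / (m - 1)
  zero <- d2 <= 0
  any_zero <- rowSums(zero) > 0
  g <- d2
  g[!any_zero, ] <- d2[!any_zero, , drop = FALSE]^expo
  u <- g / rowSums(g)
  if (any(any_zero)) {
    zr <- which(any_zero)
    u[zr, ] <- 0
    u[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
  }
  u
}

euclidean_memberships <- function(x, centers, m) {
  memberships_from_dist2(cross_dist2(x, centers), m)
}

#' Fit fuzzy C-means profiles
#'
#' Alternating optimization of the fuzzy C-means objective
#' \deqn{J(U, C) = \sum_{i=1}^{k} \sum_{s=1}^{n} u_{is}^m \|x_s - c_i\|^2}
#' with the standard membership and centroid updates, run until the maximum
#' membership change falls below `tol` or `max_iter` is reached. `n_init`
#' seeded restarts are run and the solution with the lowest objective kept.
#' After fitting, per-profile fuzzy covariance matrices are estimated
#' (see [fuzzy_covariance()]) so the model supports Mahalanobis membership
#' computation and out-of-sample prediction.
#'
#' @param data A data frame containing the feature columns.
#' @param features Character vector of feature column names.
#' @param k Number of profiles (>= 1; must be < number of rows).
#' @param m Fuzzifier (> 1); `m = 2` is the conventional default, and
#'   `m -> 1` approaches hard k-means assignment.
#' @param tol Convergence tolerance on the membership matrix.
#' @param max_iter Iteration cap per restart.
#' @param n_init Number of random restarts.
#' @param seed Integer seed for the restarts (`NULL` to use the session RNG).
#' @return A `profile_model` with elements `centroids` (k x p), `covariances`
#'   (list of k p x p matrices), `m`, `k`, `labels`, `objective` and fit
#'   metadata, plus `u`: the fitted (Euclidean) membership tibble.
#' @seealso [compute_memberships()] for the Mahalanobis memberships used in
#'   all downstream analyses, [select_k()] for choosing `k`.
#' @export
#' @examples
#' x <- data.frame(subject_id = as.character(1:60),
#'                 f1 = c(rnorm(30, -2), rnorm(30, 2)),
#'                 f2 = rnorm(60))
#' fit <- fit_fcm(x, c("f1", "f2"), k = 2, seed = 1)
#' fit$centroids
fit_fcm <- function(data, features, k, m = 2, tol = 1e-6, max_iter = 1000,
                    n_init = 10, seed = NULL) {
  x <- feature_matrix(data, features)
  n <- nrow(x)
  if (k >= n) abort("k must be smaller than the number of subjects.")
  if (m <= 1) abort("Fuzzifier m must be > 1.")
  if (max(cross_dist2(x, x[1, , drop = FALSE])) < 1e-24) {
    abort("All points are identical; profiles are undefined.",
          class = "fp_degenerate_error")
  }
  fp_log("fit_fcm", n = n, k = k, m = m, n_init = n_init)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      centers <- x[sample.int(n, k), , drop = FALSE] +
        matrix(rnorm(k * ncol(x), sd = 1e-4), k)
      run <- fcm_run(x, k, m, tol, max_iter, centers)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  })
  centroids <- best$centers
  labels <- paste0("P", seq_len(k))
  dimnames(centroids) <- list(labels, features)
  covs <- fuzzy_covariance(x, best$u, centroids, m)
  names(covs) <- labels
  model <- new_profile_model(
    centroids = centroids, covariances = covs, m = m, k = as.integer(k),
    labels = labels, features = features, objective = best$objective,
    n_iter = best$n_iter, tol = tol, seed = seed,
    objective_trace = best$trace
  )
  colnames(best$u) <- labels
  model$u <- membership_tibble(best$u, subject_ids(data, n))
  validate_profile_model(model)
}

subject_ids <- function(data, n) {
  if ("subject_id" %in% names(data)) as.character(data$subject_id)
  else as.character(seq_len(n))
}

#' Membership-weighted per-profile covariance matrices
#'
#' For each profile the covariance is the `u^m`-weighted outer-product sum
#' around the centroid,
#' \deqn{\Sigma_i = \sum_s u_{is}^m (x_s - c_i)(x_s - c_i)^\top /
#'   \sum_s u_{is}^m,}
#' regularized by adding `1e-6 * trace(Sigma)/p` to the diagonal so the
#' result is always symmetric positive definite (required by the Mahalanobis
#' membership function).
#'
#' @param x Numeric matrix (n x p) of features.
#' @param u Membership matrix (n x k) or membership tibble.
#' @param centroids k x p centroid matrix.
#' @param m Fuzzifier.
#' @return List of k symmetric positive-definite p x p matrices.
#' @export
fuzzy_covariance <- function(x, u, centroids, m) {
  if (is.data.frame(u)) u <- membership_matrix(u)
  check_memberships(u)
  p <- ncol(x)
  lapply(seq_len(ncol(u)), function(i) {
    w <- u[, i]^m
    sw <- sum(w)
    if (sw < 1e-12) {
      abort(paste0("Profile ", i, " has vanishing total membership weight."))
    }
    cx <- sweep(x, 2, centroids[i, ], "-")
    s <- crossprod(cx * sqrt(w)) / sw
    s <- (s + t(s)) / 2
    eps <- 1e-6 * sum(diag(s)) / p
    if (eps <= 0) eps <- 1e-12
    s + diag(eps, p)
  })
}

# Mahalanobis distances (n x k) from rows of x to each profile centroid.
mahalanobis_dist <- function(x, model) {
  k <- model$k
  d <- matrix(0, nrow(x), k)
  for (i in seq_len(k)) {
    d[, i] <- mahalanobis(x, model$centroids[i, ], model$covariances[[i]])
  }
  sqrt(pmax(d, 0))
}

#' Compute Mahalanobis membership values under a fitted model
#'
#' Memberships are computed from the Mahalanobis distance of each subject to
#' each profile centroid,
#' \deqn{d_{is} = \sqrt{(x_s - c_i)^\top \Sigma_i^{-1} (x_s - c_i)}, \quad
#'   u_{is} = 1 / \sum_j (d_{is}/d_{js})^{2/(m-1)},}
#' so each row lies in `[0, 1]` and sums to 1 across profiles. A subject at
#' distance zero from a centroid receives the indicator row of that profile
#' (exact ties among zero distances split equally). The same formula serves
#' fitting-cohort memberships and out-of-sample prediction; no refitting is
#' involved.
#'
#' @param model A `profile_model`.
#' @param data Data frame containing the model's feature columns.
#' @return A membership tibble: `subject_id` plus one column per profile
#'   label; rows sum to 1.
#' @export
compute_memberships <- function(model, data) {
  stopifnot(inherits(model, "profile_model"))
  check_columns(data, model$features, "feature column")
  x <- feature_matrix(data, model$features)
  bad <- which(!stats::complete.cases(x) | rowSums(!is.finite(x)) > 0)
  if (length(bad) > 0) {
    abort(paste0("Non-finite feature values in row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  d <- mahalanobis_dist(x, model)
  u <- memberships_from_dist2(d^2, model$m)
  colnames(u) <- model$labels
  membership_tibble(u, subject_ids(data, nrow(x)))
}

#' Predict profile memberships for new subjects
#'
#' Applies a stored model's centroids and covariances to a new cohort via
#' the identical Mahalanobis membership formula used on the fitting cohort;
#' works for a single subject and never refits. This is the mechanism that
#' carries a reference cohort's profiles to external studies.
#'
#' @param object A `profile_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return A membership tibble (rows sum to 1).
#' @export
predict.profile_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("New data lacks model feature(s): ",
                 paste(missing, collapse = ", ")),
          class = "fp_schema_error")
  }
  compute_memberships(object, newdata)
}

#' Select the number of profiles by silhouette
#'
#' For each candidate `k` a fuzzy C-means model is fitted, memberships are
#' hardened by row-argmax, and the mean silhouette width
#' `s = mean((b - a) / max(a, b))` over subjects is computed on Euclidean
#' distances. The `k` with the highest mean silhouette wins. A candidate
#' whose hardened partition leaves a profile empty is scored `-Inf` with a
#' warning.
#'
#' @param data Data frame with the feature columns.
#' @param features Feature column names.
#' @param k_range Integer vector of candidate profile counts (each in
#'   `[2, n - 1]`).
#' @param m Fuzzifier.
#' @param n_init Restarts per candidate fit.
#' @param seed Integer seed; each candidate draws a deterministic substream.
#' @return A `k_selection` object: list with `k_best`, `scores` (tibble of
#'   `k` and `silhouette`), and the fitted model for `k_best`.
#' @export
select_k <- function(data, features, k_range = 2:10, m = 2, n_init = 10,
                     seed = NULL) {
  x <- feature_matrix(data, features)
  n <- nrow(x)
  if (any(k_range < 2 | k_range > n - 1)) {
    abort("k_range must lie within [2, n - 1].")
  }
  dmat <- dist(x)
  scores <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    sub <- if (is.null(seed)) NULL else substream_seed(seed, paste0("select_k", k))
    fit <- fit_fcm(data, features, k = k, m = m, n_init = n_init, seed = sub)
    hard <- max.col(membership_matrix(fit$u), ties.method = "first")
    if (length(unique(hard)) < k) {
      warn(paste0("k = ", k, ": hardened partition has an empty profile; ",
                  "scored -Inf."))
      scores[j] <- -Inf
    } else {
      sil <- cluster::silhouette(hard, dmat)
      scores[j] <- mean(sil[, "sil_width"])
    }
    fits[[j]] <- fit
  }
  best <- which.max(scores)
  structure(list(k_best = k_range[best],
                 scores = tibble(k = as.integer(k_range),
                                 silhouette = scores),
                 model = fits[[best]]),
            class = "k_selection")
}

#' Label profiles from their centroid patterns
#'
#' Gives each centroid a deterministic, human-readable label composed of a
#' cognitive tier and a behavioral tag, both read off the standardized
#' centroid: the tier is `H`/`M`/`L` according to whether the mean of the
#' cognitive features exceeds `+threshold`, falls below `-threshold`, or
#' neither; the tag lists which behavioral dimensions exceed `+threshold`
#' (`S` stress, `I` internalizing, `E` externalizing), or `LB` when none
#' does. Typical labels are `HC/LB` (high cognition, low behavior), `LC/LB`,
#' `MC/HSI` (moderate cognition, high stress/internalizing) and `MC/HE`
#' (moderate cognition, high externalizing). Duplicate labels are
#' disambiguated with the centroid index.
#'
#' @param model A `profile_model` with centroids on the standardized scale.
#' @param threshold Positive cutoff in standard-deviation units.
#' @param cognitive,behavioral Feature names making up each block.
#' @return The model with `labels` (and membership column names) replaced.
#' @export
label_profiles <- function(model, threshold = 0.5,
                           cognitive = c("VA", "EFPS", "MEM"),
                           behavioral = c("internalizing", "externalizing",
                                          "stress")) {
  stopifnot(inherits(model, "profile_model"))
  check_columns(as.data.frame(model$centroids), c(cognitive, behavioral),
                "centroid feature")
  cent <- model$centroids
  labels <- character(model$k)
  tag_code <- c(stress = "S", internalizing = "I", externalizing = "E")
  tag_order <- intersect(c("stress", "internalizing", "externalizing"),
                         behavioral)
  for (i in seq_len(model$k)) {
    cog <- mean(cent[i, cognitive])
    tier <- if (cog > threshold) "H" else if (cog < -threshold) "L" else "M"
    high <- tag_order[cent[i, tag_order] > threshold]
    tag <- if (length(high) == 0) "LB" else paste0("H", paste(tag_code[high],
                                                              collapse = ""))
    labels[i] <- paste0(tier, "C/", tag)
  }
  dup <- labels %in% labels[duplicated(labels)]
  labels[dup] <- paste0(labels[dup], " #", which(dup))
  old <- model$labels
  model$labels <- labels
  rownames(model$centroids) <- labels
  names(model$covariances) <- labels
  if (!is.null(model$u)) {
    names(model$u)[match(old, names(model$u))] <- labels
  }
  model
}

#' Align the profiles of one model to another
#'
#' Finds the permutation of `model`'s profiles minimizing the total
#' Euclidean distance between matched centroids (optimal linear sum
#' assignment), so independently fitted models — e.g. per-timepoint fits —
#' can be compared profile by profile.
#'
#' @param model,reference `profile_model` objects with equal `k` and
#'   identical feature sets.
#' @return An integer permutation `perm` such that profile `perm[i]` of
#'   `model` corresponds to profile `i` of `reference`.
#' @export
match_profiles <- function(model, reference) {
  stopifnot(inherits(model, "profile_model"),
            inherits(reference, "profile_model"))
  if (model$k != reference$k ||
      !identical(model$features, reference$features)) {
    abort("Models must share k and feature set.")
  }
  cost <- sqrt(cross_dist2(reference$centroids, model$centroids))
  as.integer(clue::solve_LSAP(cost))
}

#' Reorder a model's profiles
#'
#' @param model A `profile_model`.
#' @param perm Integer permutation of `1:k` (as from [match_profiles()]).
#' @return The model with profiles (centroids, covariances, labels,
#'   memberships) reordered.
#' @export
relabel_profiles <- function(model, perm) {
  perm <- as.integer(perm)
  stopifnot(inherits(model, "profile_model"),
            all(sort(perm) == seq_len(model$k)))
  old_labels <- model$labels
  model$centroids <- model$centroids[perm, , drop = FALSE]
  model$covariances <- model$covariances[perm]
  model$labels <- model$labels[perm]
  if (!is.null(model$u)) {
    u <- model$u
    model$u <- u[, c("subject_id", old_labels[perm])]
  }
  model
}

#' @export
print.profile_model <- function(x, ...) {
  cat("Fuzzy profile model: k =", x$k, ", m =", x$m,
      ", J =", format(x$objective, digits = 6), "\n")
  cat("Profiles:", paste(x$labels, collapse = ", "), "\n")
  cat("Centroids (standardized features):\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Profile-count selection by mean silhouette\n")
  print(x$scores)
  cat("Selected k =", x$k_best, "\n")
  invisible(x)
}

#' Tidy a fitted profile model into a long centroid tibble
#'
#' @param x A `profile_model`.
#' @param ... Unused.
#' @return Tibble with columns `profile`, `feature`, `centroid`.
#' @export
tidy.profile_model <- function(x, ...) {
  as_tibble(x$centroids, rownames = "profile") |>
    tidyr::pivot_longer(-"profile", names_to = "feature",
                        values_to = "centroid")
}

#' One-row summary of a fitted profile model
#'
#' @param x A `profile_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `m`, `objective`, `n_iter`.
#' @export
glance.profile_model <- function(x, ...) {
  tibble(k = x$k, m = x$m, objective = x$objective, n_iter = x$n_iter)
}
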