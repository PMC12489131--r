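# Seeded multi-cohort, multi-timepoint synthetic data generator with
# planted profile structure — the test substrate for every other module.

default_centroids <- function() {
  # Four profiles in the standardized 6-feature space, mirroring the
  # geometry reported for pediatric populations: two large low-behavior
  # profiles differing in cognition, and two smaller moderate-cognition
  # profiles with elevated internalizing/stress or externalizing scores.
  m <- rbind(
    `MC/HSI` = c(VA = 0.0, EFPS = 0.0, MEM = 0.0,
                 internalizing = 1.2, externalizing = 0.2, stress = 1.1),
    `MC/HE` = c(VA = 0.0, EFPS = 0.0, MEM = 0.0,
                internalizing = 0.2, externalizing = 1.3, stress = 0.2),
    `HC/LB` = c(VA = 0.9, EFPS = 0.8, MEM = 0.9,
                internalizing = -0.5, externalizing = -0.5, stress = -0.5),
    `LC/LB` = c(VA = -0.9, EFPS = -0.8, MEM = -0.9,
                internalizing = -0.5, externalizing = -0.5, stress = -0.5)
  )
  m
}

default_within_cov <- function(overlap = 0.4) {
  # Within-profile covariance: cognitive features correlate 0.4 among
  # themselves, behavioral features 0.3, blocks independent; overall scale
  # set by the overlap parameter (sd units).
  r <- diag(6)
  r[1:3, 1:3] <- 0.4
  r[4:6, 4:6] <- 0.3
  diag(r) <- 1
  s <- overlap^2 * r
  dimnames(s) <- list(names(default_centroids()[1, ]),
                      names(default_centroids()[1, ]))
  s
}

#' Specify a synthetic multi-cohort study
#'
#' Declares the planted structure the generator emulates: profile centroids
#' and within-profile covariance in the standardized 6-feature space,
#' mixing weights, per-cohort location/scale shifts, covariate effects,
#' per-profile diagnosis enrichment, an environmental predictor block with
#' a known linear effect on memberships, a between-timepoint transition
#' matrix, and a missing-variable pattern. Defaults plant four profiles
#' with sizes and shapes echoing the reference geometry (two large
#' low-behavior profiles split by cognition, two smaller high-behavior
#' profiles), a 65%-stay transition matrix, diagnosis enrichment of
#' externalizing disorders in the high-externalizing profile and of
#' anxiety/OCD in the high-internalizing profile, and the stress scale
#' missing in the `GESTE` cohort.
#'
#' @param n_per_cohort Named integer vector of first-timepoint sizes.
#' @param centroids k x 6 matrix of profile centroids (rownames are the
#'   planted labels).
#' @param within_cov 6 x 6 within-profile covariance (shared), or a list of
#'   k matrices.
#' @param mixing Profile mixing weights (sum to 1).
#' @param fuzzifier Fuzzifier used to compute the true reference
#'   memberships from the planted geometry.
#' @param cohort_shift,cohort_scale Named lists of per-cohort location
#'   shifts / scale factors applied to all features (cohort batch effects).
#' @param covariate_effects List with per-unit effects of age (months,
#'   centered), sex and handedness on each feature.
#' @param diagnosis_enrichment Named list: per-diagnosis baseline log-odds
#'   (`alpha`) and per-profile log-odds weights (`beta`, length k) applied
#'   to the true membership vector.
#' @param env_p Number of environmental predictors.
#' @param env_beta env_p x k effect matrix of memberships on predictors.
#' @param env_noise_sd Environmental noise standard deviation.
#' @param transition k x k transition matrix between consecutive
#'   timepoints (rows sum to 1).
#' @param timepoints Number of timepoints for the first cohort.
#' @param missing_pattern List of `list(cohort =, feature =)` cells to
#'   blank.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_cohort = c(ABCD = 2000, BANDA = 200,
                                            GESTE = 270),
                           centroids = default_centroids(),
                           within_cov = default_within_cov(),
                           mixing = c(0.168, 0.146, 0.356, 0.330),
                           fuzzifier = 2,
                           cohort_shift = list(ABCD = 0, BANDA = 0.3,
                                               GESTE = -0.25),
                           cohort_scale = list(ABCD = 1, BANDA = 1.15,
                                               GESTE = 0.9),
                           covariate_effects = list(age = 0.004,
                                                    sex = 0.15,
                                                    handedness = 0.05),
                           diagnosis_enrichment = list(
                             AD = list(alpha = -3.4, beta = c(2.2, 0.4, -0.5, -0.2)),
                             ADHD = list(alpha = -3.2, beta = c(0.5, 2.4, -0.6, 0.2)),
                             CD = list(alpha = -4.6, beta = c(0.2, 2.8, -0.8, 0.0)),
                             DD = list(alpha = -4.2, beta = c(1.8, 1.6, -0.6, -0.2)),
                             OCD = list(alpha = -3.8, beta = c(2.0, 0.3, -0.4, -0.1)),
                             ODD = list(alpha = -4.0, beta = c(0.4, 2.6, -0.7, 0.1))
                           ),
                           env_p = 5,
                           env_beta = NULL,
                           env_noise_sd = 1,
                           transition = NULL,
                           timepoints = 3,
                           missing_pattern = list(list(cohort = "GESTE",
                                                       feature = "stress"))) {
  k <- nrow(centroids)
  if (is.null(env_beta)) {
    env_beta <- matrix(0, env_p, k)
    # Each of the first min(env_p, k) predictors loads on one profile.
    for (j in seq_len(min(env_p, k))) env_beta[j, j] <- 1.5
  }
  if (is.null(transition)) {
    transition <- matrix(0.35 / (k - 1), k, k)
    diag(transition) <- 0.65
  }
  mixing <- mixing / sum(mixing)
  if (!is.list(within_cov)) within_cov <- rep(list(within_cov), k)
  spec <- list(n_per_cohort = n_per_cohort, centroids = centroids,
               within_cov = within_cov, mixing = mixing,
               fuzzifier = fuzzifier, cohort_shift = cohort_shift,
               cohort_scale = cohort_scale,
               covariate_effects = covariate_effects,
               diagnosis_enrichment = diagnosis_enrichment,
               env_p = env_p, env_beta = env_beta,
               env_noise_sd = env_noise_sd, transition = transition,
               timepoints = timepoints, missing_pattern = missing_pattern)
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  k <- nrow(spec$centroids)
  if (abs(sum(spec$mixing) - 1) > 1e-8) abort("Mixing weights must sum to 1.")
  if (any(abs(rowSums(spec$transition) - 1) > 1e-8)) {
    abort("Transition matrix rows must sum to 1.")
  }
  for (s in spec$within_cov) {
    ev <- eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      abort("Within-profile covariance is not positive definite.")
    }
  }
  invisible(TRUE)
}

# True Mahalanobis memberships of feature rows under the planted geometry.
true_memberships <- function(x, spec) {
  model <- new_profile_model(
    centroids = spec$centroids, covariances = spec$within_cov,
    m = spec$fuzzifier, k = nrow(spec$centroids),
    labels = rownames(spec$centroids),
    features = colnames(spec$centroids),
    objective = NA_real_, n_iter = 0L, tol = NA_real_, seed = NULL
  )
  d <- mahalanobis_dist(x, model)
  u <- memberships_from_dist2(d^2, spec$fuzzifier)
  colnames(u) <- rownames(spec$centroids)
  u
}

#' Generate a synthetic multi-cohort study
#'
#' Draws subjects per cohort and timepoint under the planted spec: profile
#' labels from the mixing weights, features from the within-profile
#' Gaussian around the planted centroid, covariate effects and per-cohort
#' location/scale batch shifts added on top, diagnoses as Bernoulli draws
#' whose log-odds are linear in the true membership vector, environmental
#' predictors linear in the true memberships plus Gaussian noise, and
#' follow-up labels drawn from the transition matrix (the first cohort
#' carries all timepoints; validation cohorts are single-timepoint).
#' Declared missing cells are blanked last. Identical seeds reproduce
#' identical tables.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A `synthetic_cohort` list: `data` (one tibble of stacked
#'   subject-by-timepoint rows), `truth` (tibble of planted labels and true
#'   memberships per row), and `spec`.
#' @export
generate_cohorts <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- nrow(spec$centroids)
  feats <- colnames(spec$centroids)
  labels <- rownames(spec$centroids)
  cohorts <- names(spec$n_per_cohort)
  rows <- list()
  truth <- list()
  with_seed(substream_seed(seed, "generate"), {
    for (ci in seq_along(cohorts)) {
      co <- cohorts[ci]
      n <- spec$n_per_cohort[[co]]
      n_tp <- if (ci == 1) spec$timepoints else 1L
      ids <- sprintf("%s-%05d", co, seq_len(n))
      lab <- sample.int(k, n, replace = TRUE, prob = spec$mixing)
      age0 <- round(rnorm(n, mean = 120, sd = 8))
      sex <- sample(c("F", "M"), n, replace = TRUE)
      ethnicity <- sample(c("A", "B", "C", "D"), n, replace = TRUE,
                          prob = c(0.5, 0.2, 0.2, 0.1))
      handedness <- sample(c("right", "left"), n, replace = TRUE,
                           prob = c(0.9, 0.1))
      for (tp in seq_len(n_tp)) {
        if (tp > 1) {
          lab <- vapply(lab, function(l) {
            sample.int(k, 1, prob = spec$transition[l, ])
          }, integer(1))
        }
        x <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
        for (i in seq_len(k)) {
          sel <- lab == i
          if (!any(sel)) next
          x[sel, ] <- MASS::mvrnorm(sum(sel), mu = spec$centroids[i, ],
                                    Sigma = spec$within_cov[[i]])
        }
        u_true <- true_memberships(x, spec)
        age <- age0 + (tp - 1) * 24
        ce <- spec$covariate_effects
        x <- x + outer(ce$age * (age - mean(age)), rep(1, length(feats)))
        x <- x + outer(ce$sex * (sex == "M"),
                       c(0, 0, 0, -0.5, 1, 0) * 1) * 1
        x <- x + outer(ce$handedness * (handedness == "left"),
                       rep(1, length(feats)))
        x <- x * spec$cohort_scale[[co]] + spec$cohort_shift[[co]]
        dx <- matrix(NA_integer_, n, length(spec$diagnosis_enrichment),
                     dimnames = list(NULL,
                                     names(spec$diagnosis_enrichment)))
        for (d in names(spec$diagnosis_enrichment)) {
          en <- spec$diagnosis_enrichment[[d]]
          eta <- en$alpha + as.vector(u_true %*% en$beta)
          dx[, d] <- rbinom(n, 1, 1 / (1 + exp(-eta)))
        }
        env <- u_true %*% t(spec$env_beta) +
          matrix(rnorm(n * spec$env_p, sd = spec$env_noise_sd), n)
        colnames(env) <- paste0("env_", seq_len(spec$env_p))
        tab <- dplyr::bind_cols(
          tibble(subject_id = ids, cohort = co,
                 timepoint = paste0("T", tp), age_months = age,
                 sex = sex, ethnicity = ethnicity,
                 handedness = handedness),
          as_tibble(x), as_tibble(dx), as_tibble(env)
        )
        rows[[length(rows) + 1]] <- tab
        colnames(u_true) <- paste0("u_", seq_len(k))
        truth[[length(truth) + 1]] <- dplyr::bind_cols(
          tibble(subject_id = ids, cohort = co,
                 timepoint = paste0("T", tp),
                 true_profile = factor(labels[lab], levels = labels),
                 true_profile_index = lab),
          as_tibble(u_true)
        )
      }
    }
  })
  data <- dplyr::bind_rows(rows)
  for (cell in spec$missing_pattern) {
    data[[cell$feature]][data$cohort == cell$cohort] <- NA_real_
  }
  structure(list(data = data, truth = dplyr::bind_rows(truth), spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic study:", nrow(x$data), "subject-timepoint rows,",
      nrow(x$spec$centroids), "planted profiles,",
      length(x$spec$n_per_cohort), "cohorts\n")
  print(dplyr::count(x$data, .data$cohort, .data$timepoint))
  invisible(x)
}

#' Compare estimated profiles to the planted ground truth
#'
#' Matches estimated profiles to planted ones by optimal assignment on
#' centroid distance, then reports the per-coordinate RMSE of the matched
#' centroids (`centroid_rmse`, in sd units), the mean Euclidean centroid
#' distance (`centroid_dist`), the hardened-label agreement rate, and
#' (when supplied) the sign-recovery rate of effect estimates.
#'
#' @param model A fitted `profile_model`.
#' @param u Membership tibble for the rows of `truth`.
#' @param truth Ground-truth tibble from [generate_cohorts()] aligned with
#'   `u` (matched on `subject_id`).
#' @param spec The generating [synthetic_spec()].
#' @param env_coef Optional estimated predictor-by-profile coefficient
#'   matrix to score sign recovery against `spec$env_beta`.
#' @return One-row tibble of recovery metrics.
#' @export
truth_compare <- function(model, u, truth, spec, env_coef = NULL) {
  stopifnot(inherits(model, "profile_model"))
  if (model$k != nrow(spec$centroids)) {
    abort("Profile count differs from the planted k.")
  }
  ref <- new_profile_model(
    centroids = spec$centroids, covariances = spec$within_cov,
    m = spec$fuzzifier, k = nrow(spec$centroids),
    labels = rownames(spec$centroids),
    features = colnames(spec$centroids),
    objective = NA_real_, n_iter = 0L, tol = NA_real_, seed = NULL
  )
  perm <- match_profiles(model, ref)
  diff <- spec$centroids - model$centroids[perm, , drop = FALSE]
  cent_rmse <- sqrt(mean(diff^2))
  cent_dist <- mean(sqrt(rowSums(diff^2)))
  um <- membership_matrix(u)
  ids <- rownames(um)
  tr <- truth[match(ids, truth$subject_id), ]
  hard <- perm_inverse(perm)[max.col(um, ties.method = "first")]
  agreement <- mean(hard == tr$true_profile_index, na.rm = TRUE)
  out <- tibble(centroid_rmse = cent_rmse, centroid_dist = cent_dist,
                label_agreement = agreement)
  if (!is.null(env_coef)) {
    beta <- spec$env_beta
    est <- env_coef[seq_len(nrow(beta)), perm_order_cols(perm, ncol(beta)),
                    drop = FALSE]
    nz <- abs(beta) > 1e-12
    out$sign_recovery <- mean(sign(est[nz]) == sign(beta[nz]))
  }
  out
}

# Inverse permutation: if model profile perm[i] matches truth profile i,
# model profile j corresponds to truth profile inverse[j].
perm_inverse <- function(perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  inv
}

perm_order_cols <- function(perm, k) perm[seq_len(k)]
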