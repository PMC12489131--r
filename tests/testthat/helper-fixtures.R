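# Shared fixtures, built in code at test time.

FEATURES <- c("VA", "EFPS", "MEM", "internalizing", "externalizing",
              "stress")

# A small single-cohort table with separable planted structure.
tiny_cohort <- function(n = 120, seed = 7, overlap = 0.3) {
  spec <- synthetic_spec(
    n_per_cohort = c(ABCD = n),
    within_cov = overlap^2 * stats::cov2cor(default_within_cov_fixture()),
    timepoints = 1,
    missing_pattern = list()
  )
  generate_cohorts(spec, seed = seed)
}

default_within_cov_fixture <- function() {
  r <- diag(6)
  r[1:3, 1:3] <- 0.4
  r[4:6, 4:6] <- 0.3
  diag(r) <- 1
  dimnames(r) <- list(FEATURES, FEATURES)
  r
}

# Regular-simplex geometry: four spherical clusters, all pairwise
# centroid separations equal to `separation_sd` within-cluster sds.
simplex_spec <- function(n = 800, sigma = 0.4, separation_sd = 6) {
  c4 <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (separation_sd * sigma / (2 * sqrt(2)))
  cent <- cbind(c4, matrix(0, 4, 3))
  dimnames(cent) <- list(paste0("C", 1:4), FEATURES)
  synthetic_spec(
    n_per_cohort = c(ABCD = n), centroids = cent,
    within_cov = diag(sigma^2, 6), mixing = rep(0.25, 4),
    timepoints = 1,
    covariate_effects = list(age = 0, sex = 0, handedness = 0),
    missing_pattern = list()
  )
}

# Hand-built membership tibble.
u_tbl <- function(m, ids = NULL, labels = NULL) {
  m <- as.matrix(m)
  colnames(m) <- labels %||% paste0("P", seq_len(ncol(m)))
  tibble::tibble(subject_id = as.character(ids %||% seq_len(nrow(m)))) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference FCM oracle: plain alternating optimization from given start,
# independent of the package's implementation.
oracle_fcm <- function(x, k, m, centers, iters = 2000, tol = 1e-12) {
  for (it in seq_len(iters)) {
    d2 <- matrix(0, nrow(x), k)
    for (i in seq_len(k)) {
      d2[, i] <- colSums((t(x) - centers[i, ])^2)
    }
    u <- matrix(0, nrow(x), k)
    for (r in seq_len(nrow(x))) {
      if (any(d2[r, ] == 0)) {
        u[r, ] <- (d2[r, ] == 0) / sum(d2[r, ] == 0)
      } else {
        for (i in seq_len(k)) {
          u[r, i] <- 1 / sum((d2[r, i] / d2[r, ])^(1 / (m - 1)))
        }
      }
    }
    new_centers <- centers
    for (i in seq_len(k)) {
      w <- u[, i]^m
      new_centers[i, ] <- colSums(x * w) / sum(w)
    }
    if (max(abs(new_centers - centers)) < tol) break
    centers <- new_centers
  }
  list(centers = centers, u = u)
}

# Brute-force Mahalanobis membership oracle for one probe row.
oracle_membership <- function(x_row, centroids, covs, m) {
  k <- nrow(centroids)
  d <- numeric(k)
  for (i in seq_len(k)) {
    diff <- x_row - centroids[i, ]
    d[i] <- sqrt(drop(t(diff) %*% solve(covs[[i]]) %*% diff))
  }
  if (any(d == 0)) return((d == 0) / sum(d == 0))
  u <- numeric(k)
  for (i in seq_len(k)) u[i] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
  u
}

# Closed-form subject-subject distance on a bipartite 1-u graph.
oracle_pair_distance <- function(u_a, u_b) {
  min((1 - u_a) + (1 - u_b))
}
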