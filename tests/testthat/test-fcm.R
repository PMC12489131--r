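test_that("k = 1 yields the sample mean and mirrored data mirrored centroids", {
  set.seed(3)
  x <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, FEATURES))
  tab <- tibble::as_tibble(x)
  fit1 <- fit_fcm(tab, FEATURES, k = 1, seed = 1, n_init = 2)
  expect_equal(drop(fit1$centroids), colMeans(x), tolerance = 1e-8,
               ignore_attr = TRUE)
  mirrored <- tibble::as_tibble(rbind(x, -x))
  fit2 <- fit_fcm(mirrored, FEATURES, k = 2, seed = 1, tol = 1e-9)
  expect_lt(sqrt(sum((fit2$centroids[1, ] + fit2$centroids[2, ])^2)), 1e-8 * 10)
})

test_that("two tight clusters match the reference alternating-optimization oracle", {
  set.seed(9)
  n <- 100
  x <- rbind(matrix(rnorm(n * 6, sd = 0.05), n, 6),
             matrix(rnorm(n * 6, sd = 0.05), n, 6))
  x[1:n, 1] <- x[1:n, 1] + 5
  x[(n + 1):(2 * n), 1] <- x[(n + 1):(2 * n), 1] - 5
  colnames(x) <- FEATURES
  fit <- fit_fcm(tibble::as_tibble(x), FEATURES, k = 2, m = 2, seed = 2,
                 tol = 1e-12)
  oracle <- oracle_fcm(x, k = 2, m = 2,
                       centers = rbind(c(4, rep(0, 5)), c(-4, rep(0, 5))))
  perm <- if (fit$centroids[1, 1] > 0) 1:2 else 2:1
  expect_equal(unname(fit$centroids[perm, ]), unname(oracle$centers),
               tolerance = 1e-6)
  means <- rbind(colMeans(x[1:n, ]), colMeans(x[(n + 1):(2 * n), ]))
  expect_lt(max(abs(fit$centroids[perm, ] - means)), 0.05)
})

test_that("the FCM objective is non-increasing along the trace", {
  synth <- tiny_cohort(n = 150)
  fit <- fit_fcm(synth$data, FEATURES, k = 4, seed = 6)
  expect_true(all(diff(fit$objective_trace) <=
                    1e-10 * abs(fit$objective_trace[-1]) + 1e-12))
})

test_that("degenerate inputs are rejected", {
  tab <- tibble::as_tibble(matrix(1, 10, 6,
                                  dimnames = list(NULL, FEATURES)))
  expect_error(fit_fcm(tab, FEATURES, k = 2, seed = 1),
               class = "fp_degenerate_error")
  synth <- tiny_cohort(n = 5)
  expect_error(fit_fcm(synth$data, FEATURES, k = 5, seed = 1), "smaller")
})

test_that("fuzzy covariances reduce to the weighted MLE and stay SPD", {
  set.seed(13)
  x <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, FEATURES))
  u <- matrix(1, 80, 1)
  cen <- matrix(colMeans(x), 1)
  s <- fuzzy_covariance(x, u, cen, m = 2)[[1]]
  mle <- crossprod(sweep(x, 2, colMeans(x))) / 80
  eps <- 1e-6 * sum(diag(mle)) / 6
  expect_equal(s, mle + diag(eps, 6), tolerance = 1e-6)

  # two points at +-1 on the first axis: Sigma = diag(1,0,...) + eps I
  x2 <- rbind(c(1, rep(0, 5)), c(-1, rep(0, 5)))
  s2 <- fuzzy_covariance(x2, matrix(1, 2, 1), matrix(0, 1, 6), m = 2)[[1]]
  expect_equal(s2[1, 1], 1 + 1e-6 * 1 / 6, tolerance = 1e-9)
  expect_equal(s2[2:6, 2:6], diag(1e-6 * 1 / 6, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(min(eigen(s2, symmetric = TRUE)$values), 0)
})

test_that("Mahalanobis memberships obey the zero-distance and symmetry rules", {
  cent <- matrix(c(0, 4, 0, -4, 4, 0, -4, 0, rep(0, 4 * 4)), 4, 6)
  colnames(cent) <- FEATURES
  rownames(cent) <- paste0("P", 1:4)
  model <- structure(list(
    centroids = cent, covariances = rep(list(diag(6)), 4), m = 2, k = 4L,
    labels = rownames(cent), features = FEATURES,
    objective = 0, n_iter = 1L, tol = 1e-6, seed = NULL
  ), class = "profile_model")
  probe <- tibble::as_tibble(rbind(cent[2, ], rep(0, 6)))
  u <- compute_memberships(model, probe)
  um <- membership_matrix(u)
  expect_equal(unname(um[1, ]), c(0, 1, 0, 0)) # exactly at centroid 2
  expect_equal(unname(um[2, ]), rep(0.25, 4)) # equidistant from all four
})

test_that("membership at d = (1, 3) with identity covariance is (0.9, 0.1)", {
  cent <- rbind(c(0, 0, rep(0, 4)), c(4, 0, rep(0, 4)))
  colnames(cent) <- FEATURES
  model <- structure(list(
    centroids = cent, covariances = rep(list(diag(6)), 2), m = 2, k = 2L,
    labels = c("P1", "P2"), features = FEATURES,
    objective = 0, n_iter = 1L, tol = 1e-6, seed = NULL
  ), class = "profile_model")
  probe <- tibble::as_tibble(matrix(c(1, rep(0, 5)), 1,
                                    dimnames = list(NULL, FEATURES)))
  u <- membership_matrix(compute_memberships(model, probe))
  expect_equal(unname(u[1, ]), c(0.9, 0.1), tolerance = 1e-12)
})

test_that("memberships match the brute-force formula on random probes", {
  synth <- tiny_cohort(n = 200, seed = 21)
  fit <- fit_fcm(synth$data, FEATURES, k = 4, seed = 3)
  set.seed(77)
  probes <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, FEATURES))
  u <- membership_matrix(compute_memberships(fit, tibble::as_tibble(probes)))
  for (r in seq_len(50)) {
    expected <- oracle_membership(probes[r, ], fit$centroids,
                                  fit$covariances, fit$m)
    expect_equal(unname(u[r, ]), expected, tolerance = 1e-10)
  }
  expect_true(all(abs(rowSums(u) - 1) <= 1e-9))
})

test_that("prediction is idempotent on the training set and handles one row", {
  synth <- tiny_cohort(n = 150, seed = 5)
  fit <- fit_fcm(synth$data, FEATURES, k = 4, seed = 8)
  u_fit <- compute_memberships(fit, synth$data)
  u_pred <- predict(fit, synth$data)
  expect_identical(u_pred, u_fit)
  one <- predict(fit, synth$data[3, ])
  expect_equal(nrow(one), 1)
  expect_equal(sum(membership_matrix(one)), 1, tolerance = 1e-9)
  expect_error(predict(fit, dplyr::select(synth$data, -"stress")),
               "stress", class = "fp_schema_error")
})

test_that("held-out subjects from a planted profile map to the matched profile", {
  spec <- simplex_spec(n = 600)
  train <- generate_cohorts(spec, seed = 61)
  fit <- fit_fcm(train$data, FEATURES, k = 4, seed = 9)
  perm <- match_profiles(fit, structure(list(
    centroids = spec$centroids, covariances = spec$within_cov,
    m = 2, k = 4L, labels = rownames(spec$centroids), features = FEATURES,
    objective = 0, n_iter = 1L, tol = 1e-6, seed = NULL
  ), class = "profile_model"))
  test_set <- generate_cohorts(spec, seed = 62)
  u_new <- membership_matrix(predict(fit, test_set$data))
  for (i in 1:4) {
    rows <- test_set$truth$true_profile_index == i
    col_means <- colMeans(u_new[rows, , drop = FALSE])
    expect_equal(unname(which.max(col_means)), perm[i])
  }
})

test_that("fuzzifier near 1 approaches hard assignment on separated data", {
  spec <- simplex_spec(n = 400)
  synth <- generate_cohorts(spec, seed = 71)
  fit <- fit_fcm(synth$data, FEATURES, k = 4, m = 1.05, seed = 4)
  u <- membership_matrix(fit$u)
  expect_gte(mean(apply(u, 1, max)), 0.99)
})

test_that("silhouette selection returns the single candidate and its score", {
  synth <- tiny_cohort(n = 80)
  sel <- select_k(synth$data, FEATURES, k_range = 2, seed = 1, n_init = 3)
  expect_equal(sel$k_best, 2)
  expect_equal(nrow(sel$scores), 1)
  expect_true(is.finite(sel$scores$silhouette))
})

test_that("profile labels follow the tier and behavior-tag rules", {
  mk_model <- function(cent) {
    rownames(cent) <- paste0("P", seq_len(nrow(cent)))
    colnames(cent) <- FEATURES
    structure(list(centroids = cent,
                   covariances = rep(list(diag(6)), nrow(cent)),
                   m = 2, k = nrow(cent),
                   labels = rownames(cent), features = FEATURES,
                   objective = 0, n_iter = 1L, tol = 1e-6, seed = NULL),
              class = "profile_model")
  }
  cent <- rbind(
    c(0.8, 0.7, 0.9, -0.2, -0.4, -0.1), # high cognition, low behavior
    c(0, 0, 0, 0, 0, 0), # neutral fallback
    c(0, 0, 0, 1.2, 0, 1.0), # stress + internalizing
    c(-0.8, -0.9, -0.7, 0.1, 1.4, 0.2) # low cognition, externalizing
  )
  labeled <- label_profiles(mk_model(cent))
  expect_equal(labeled$labels,
               c("HC/LB", "MC/LB", "MC/HSI", "LC/HE"))
  # duplicates get a centroid-index suffix
  dup <- label_profiles(mk_model(cent[c(1, 1), ]))
  expect_false(anyDuplicated(dup$labels) > 0)
  expect_true(all(grepl("^HC/LB", dup$labels)))
})

test_that("profile matching undoes a planted permutation", {
  synth <- tiny_cohort(n = 150, seed = 19)
  fit <- fit_fcm(synth$data, FEATURES, k = 4, seed = 2)
  shuffled <- relabel_profiles(fit, c(3, 1, 4, 2))
  perm <- match_profiles(shuffled, fit)
  expect_equal(perm, c(2L, 4L, 1L, 3L))
  expect_equal(relabel_profiles(shuffled, perm)$centroids, fit$centroids)
})
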