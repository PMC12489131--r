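# Generator for a planted predictor-membership relation.
plsr_sim <- function(n = 500, p = 5, k = 4, beta_scale = 0, seed = 1,
                     ncomp_structure = 0, noise_sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  if (ncomp_structure > 0) {
    # y driven by `ncomp_structure` orthogonal latent directions of x
    w <- qr.Q(qr(matrix(rnorm(p * ncomp_structure), p)))
    scores <- x %*% w
    load <- matrix(rnorm(ncomp_structure * k), ncomp_structure, k)
    y <- scores %*% load + matrix(rnorm(n * k, sd = noise_sd), n, k)
  } else if (beta_scale > 0) {
    b <- matrix(0, p, k)
    b[1, 1] <- beta_scale
    b[2, 2] <- -beta_scale
    y <- x %*% b + matrix(rnorm(n * k, sd = noise_sd), n, k)
  } else {
    y <- matrix(rnorm(n * k, sd = noise_sd), n, k)
  }
  colnames(y) <- paste0("u", 1:k)
  list(x = x, y = y)
}

test_that("a perfect single-predictor relation gives R2 = 1, coefficient 1", {
  set.seed(2)
  x <- matrix(as.numeric(scale(rnorm(100))), dimnames = list(NULL, "x"))
  fit <- plsr_fit(x, x[, 1, drop = FALSE], ncomp = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$B[1, 1]), 1, tolerance = 1e-12)
})

test_that("the first weight vector matches the dominant singular direction", {
  sim <- plsr_sim(n = 400, ncomp_structure = 2, seed = 5, noise_sd = 0.3)
  xs <- scale(sim$x)
  ys <- scale(sim$y, scale = FALSE)
  fit <- plsr_fit(sim$x, sim$y, ncomp = 2)
  sv <- svd(crossprod(xs, ys))
  cosine <- abs(sum(fit$W[, 1] * sv$u[, 1]))
  expect_gte(cosine, 1 - 1e-10)
  # single response: w1 proportional to X'y
  y1 <- sim$y[, 1, drop = FALSE]
  fit1 <- plsr_fit(sim$x, y1, ncomp = 1)
  w_direct <- crossprod(xs, scale(y1, scale = FALSE))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  expect_gte(abs(sum(fit1$W[, 1] * w_direct)), 1 - 1e-10)
})

test_that("X-scores are mutually orthogonal and independent noise gives low R2", {
  sim <- plsr_sim(n = 500, seed = 7) # y independent of x
  fit <- plsr_fit(sim$x, sim$y, ncomp = 3)
  tt <- crossprod(fit$T)
  expect_lt(max(abs(tt[upper.tri(tt)])), 1e-8)
  fit1 <- plsr_fit(sim$x, sim$y, ncomp = 1)
  expect_lt(fit1$r_squared, 0.05)
})

test_that("membership responses give coefficient rows summing to zero", {
  synth <- tiny_cohort(n = 300, seed = 13)
  model <- fit_fcm(synth$data, FEATURES, k = 4, seed = 2)
  u <- compute_memberships(model, synth$data)
  x <- synth$data[, paste0("env_", 1:5)]
  fit <- plsr_fit(x, u, ncomp = 2)
  expect_lt(max(abs(rowSums(fit$B))), 1e-8)
})

test_that("zero-variance predictors and excessive ncomp are rejected", {
  sim <- plsr_sim(n = 50)
  xbad <- sim$x
  xbad[, 3] <- 2
  expect_error(plsr_fit(xbad, sim$y, 1), "x3")
  expect_error(plsr_fit(sim$x, sim$y, ncomp = 6), "rank")
})

test_that("cross-validation recovers the planted component count", {
  # noise-free rank-1 relation: A* = 1
  set.seed(3)
  x <- matrix(rnorm(200 * 4), 200, 4)
  y <- (x %*% c(1, -1, 0.5, 0)) %*% t(c(1, 2))
  sel <- plsr_select_components(x, y, folds = 10, a_max = 3, seed = 1)
  expect_equal(sel$a_best, 1)
  # planted 2-component structure: A* = 2 in >= 18/20 seeds
  hits <- 0
  for (s in 1:20) {
    sim <- plsr_sim(n = 1000, ncomp_structure = 2, seed = 100 + s,
                    noise_sd = 0.3)
    sel2 <- plsr_select_components(sim$x, sim$y, folds = 10, a_max = 4,
                                   seed = s)
    hits <- hits + (sel2$a_best == 2)
  }
  expect_gte(hits, 18)
  # same seed reproduces the same selection
  sim <- plsr_sim(n = 200, ncomp_structure = 2, seed = 9)
  s1 <- plsr_select_components(sim$x, sim$y, seed = 4)
  s2 <- plsr_select_components(sim$x, sim$y, seed = 4)
  expect_identical(s1, s2)
})

test_that("permutation smoothing gives p = 1/(B+1) for a dominant statistic", {
  sim <- plsr_sim(n = 300, beta_scale = 1, seed = 21, noise_sd = 0.3)
  res <- plsr_permutation(sim$x, sim$y, ncomp = 1, B = 999, seed = 2)
  expect_equal(res$model_p, 1 / 1000)
  expect_true(all(res$coefficients$p_fdr >= res$coefficients$p))
})

test_that("a planted strong effect is detected with p <= 0.01", {
  sim <- plsr_sim(n = 1000, beta_scale = 0.5, seed = 31)
  res <- plsr_permutation(sim$x, sim$y, ncomp = 2, B = 999, seed = 3)
  expect_lte(res$model_p, 0.01)
  # the planted coefficients are flagged after FDR
  tbl <- res$coefficients
  expect_true(tbl$significant[tbl$predictor == "x1" & tbl$response == "u1"])
  expect_gt(tbl$estimate[tbl$predictor == "x1" & tbl$response == "u1"], 0)
})

test_that("coefficient signs are recovered in >= 95% of replicates", {
  correct <- 0
  total <- 0
  for (s in 1:20) {
    sim <- plsr_sim(n = 1000, beta_scale = 0.3, seed = 200 + s)
    fit <- plsr_fit(sim$x, sim$y, ncomp = 2)
    correct <- correct + (fit$B[1, 1] > 0) + (fit$B[2, 2] < 0)
    total <- total + 2
  }
  expect_gte(correct / total, 0.95)
})

test_that("BH adjustment matches the closed-form step-up", {
  expect_equal(fdr_bh(0.03)$p_fdr, 0.03)
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$p_fdr, rep(0.04, 4))
  # closed-form oracle: sorted p * m / i with right-to-left running min
  set.seed(6)
  p <- runif(25)
  ord <- order(p)
  stepup <- pmin(1, rev(cummin(rev(p[ord] * 25 / seq_len(25)))))
  expected <- numeric(25)
  expected[ord] <- stepup
  expect_equal(fdr_bh(p)$p_fdr, expected)
  expect_equal(fdr_bh(rep(0.2, 5))$p_fdr, rep(0.2, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("ANOVA and Tukey agree with textbook identities", {
  # two groups: F equals the squared pooled t statistic
  set.seed(41)
  tab <- tibble::tibble(
    value = c(rnorm(20, 0), rnorm(25, 0.8)),
    grp = rep(c("a", "b"), c(20, 25))
  )
  res <- anova_tukey(tab, "value", "grp")
  tt <- t.test(value ~ grp, data = tab, var.equal = TRUE)
  expect_equal(res$anova$f_statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  # three groups: F matches the direct sum-of-squares computation
  tab3 <- tibble::tibble(value = c(1, 2, 3, 2, 4, 6, 5, 7, 9),
                         grp = rep(c("g1", "g2", "g3"), each = 3))
  res3 <- anova_tukey(tab3, "value", "grp")
  gm <- mean(tab3$value)
  ssb <- sum(tapply(tab3$value, tab3$grp,
                    function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(tab3$value, tab3$grp,
                    function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res3$anova$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(nrow(res3$tukey), 3)
  # identical groups: all pairwise differences zero
  tab_id <- tibble::tibble(value = rep(c(1, 2, 3), 3),
                           grp = rep(c("a", "b", "c"), each = 3))
  res_id <- anova_tukey(tab_id, "value", "grp")
  expect_true(all(abs(res_id$tukey$difference) < 1e-12))
  # a singleton group is excluded with a warning
  tab_s <- dplyr::bind_rows(tab3, tibble::tibble(value = 1, grp = "g4"))
  expect_warning(res_s <- anova_tukey(tab_s, "value", "grp"), "g4")
  expect_equal(res_s$anova$df_between, 2)
})

test_that("the NIPALS fit agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  sim <- plsr_sim(n = 150, ncomp_structure = 2, seed = 77, noise_sd = 0.5)
  ys <- scale(sim$y) # common scale for both routes
  fit <- plsr_fit(sim$x, ys, ncomp = 2)
  ref <- mixOmics::pls(sim$x, ys, ncomp = 2, scale = TRUE,
                       mode = "regression")
  for (a in 1:2) {
    cosine <- abs(cor(fit$T[, a], ref$variates$X[, a]))
    expect_gte(cosine, 1 - 1e-6)
  }
})
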