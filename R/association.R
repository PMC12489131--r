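# PLSR of environmental predictors on profile memberships, with
# cross-validated component selection, permutation inference and BH-FDR,
# plus ANOVA/Tukey contrasts between primary profiles.

# Core NIPALS PLS2 on already centered/scaled matrices. Returns weights W,
# X-loadings P, Y-loadings Q, X-scores T and coefficients B.
nipals_pls <- function(x, y, ncomp, tol = 1e-12, max_iter = 500) {
  n <- nrow(x)
  p <- ncol(x)
  q <- ncol(y)
  w_mat <- matrix(0, p, ncomp)
  p_mat <- matrix(0, p, ncomp)
  q_mat <- matrix(0, q, ncomp)
  t_mat <- matrix(0, n, ncomp)
  xd <- x
  yd <- y
  for (a in seq_len(ncomp)) {
    u <- yd[, which.max(colSums(yd^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(xd, u)
      w <- w / sqrt(sum(w^2))
      t_vec <- xd %*% w
      qv <- crossprod(yd, t_vec) / sum(t_vec^2)
      if (q > 1) {
        u <- yd %*% qv / sum(qv^2)
      }
      if (sqrt(sum((t_vec - t_old)^2)) < tol * sqrt(sum(t_vec^2))) break
      t_old <- t_vec
      if (q == 1) break
    }
    pv <- crossprod(xd, t_vec) / sum(t_vec^2)
    xd <- xd - tcrossprod(t_vec, pv)
    yd <- yd - tcrossprod(t_vec, qv)
    w_mat[, a] <- w
    p_mat[, a] <- pv
    q_mat[, a] <- qv
    t_mat[, a] <- t_vec
  }
  b <- w_mat %*% solve(crossprod(p_mat, w_mat), t(q_mat))
  list(W = w_mat, P = p_mat, Q = q_mat, T = t_mat, B = b)
}

#' Fit a partial least squares regression of memberships on predictors
#'
#' NIPALS PLS2: predictors and responses are projected onto `ncomp` pairs
#' of latent components chosen to maximize their covariance, with the
#' predictor matrix deflated after each component; the regression
#' coefficient matrix `B` (predictor x response, on the standardized scale)
#' summarizes the direction and relative importance of each predictor for
#' each profile's membership. Because responses that sum to one per row are
#' centered before fitting, each predictor's coefficients sum to zero
#' across profiles. PLSR tolerates the strong collinearity among
#' membership columns that would destabilize ordinary least squares.
#'
#' @param x Data frame or matrix of predictors (standardized internally;
#'   ordinal predictors are treated as numeric; missing entries are
#'   mean-imputed with a logged count).
#' @param y Membership tibble or numeric response matrix (centered
#'   internally).
#' @param ncomp Number of components `A` (must not exceed the predictor
#'   rank).
#' @return A `plsr_fit`: weights `W`, loadings `P` and `Q`, scores `T`,
#'   coefficients `B`, `r_squared`, and the column bookkeeping.
#' @export
plsr_fit <- function(x, y, ncomp) {
  xm <- prepare_predictors(x)
  ym <- prepare_responses(y)
  if (nrow(xm) != nrow(ym)) abort("x and y must have the same rows.")
  if (ncomp > qr(xm)$rank) {
    abort(paste0("ncomp = ", ncomp, " exceeds the predictor rank."))
  }
  fit <- nipals_pls(xm, ym, ncomp)
  yhat <- xm %*% fit$B
  rss <- sum((ym - yhat)^2)
  tss <- sum(ym^2) # responses are centered
  structure(list(W = fit$W, P = fit$P, Q = fit$Q, T = fit$T, B = fit$B,
                 ncomp = ncomp, r_squared = 1 - rss / tss,
                 predictors = colnames(xm), responses = colnames(ym),
                 x_center = attr(xm, "scaled:center"),
                 x_scale = attr(xm, "scaled:scale"),
                 y_center = attr(ym, "scaled:center")),
            class = "plsr_fit")
}

prepare_predictors <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(as.data.frame(x)[, vapply(x, is.numeric, logical(1)),
                                    drop = FALSE])
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    n_imp <- sum(is.na(x))
    fp_log("plsr", mean_imputed = n_imp)
    for (j in seq_len(ncol(x))) {
      x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  sds <- apply(x, 2, sd)
  if (any(sds < 1e-12)) {
    abort(paste0("Zero-variance predictor: ",
                 paste(colnames(x)[sds < 1e-12], collapse = ", ")))
  }
  scale(x)
}

prepare_responses <- function(y) {
  if (is.data.frame(y) && "subject_id" %in% names(y)) {
    y <- membership_matrix(y)
  } else {
    y <- as.matrix(y)
  }
  storage.mode(y) <- "double"
  scale(y, scale = FALSE)
}

#' Select the number of PLSR components by cross-validated Q-squared
#'
#' Splits subjects into seeded disjoint folds, fits each candidate number
#' of components on the training folds, and scores held-out prediction
#' error, `Q^2(A) = 1 - PRESS(A) / TSS`. The returned `A` is the most
#' parsimonious near-optimum: larger candidates are adopted only when they
#' improve `Q^2` by more than `min_improvement` (cross-validated error
#' curves flatten at the true dimensionality, and the plain argmax chases
#' noise-level gains from extra components).
#'
#' @param x,y As in [plsr_fit()].
#' @param folds Number of cross-validation folds (default 10).
#' @param a_max Largest candidate `A`.
#' @param seed Integer seed for the fold split.
#' @param min_improvement Minimum `Q^2` gain required to accept a larger
#'   `A` (default 0.01).
#' @return List with `a_best` and a tibble `q2` of candidate scores.
#' @export
plsr_select_components <- function(x, y, folds = 10, a_max = NULL,
                                   seed = NULL, min_improvement = 0.01) {
  xm <- prepare_predictors(x)
  ym <- prepare_responses(y)
  n <- nrow(xm)
  if (n < folds) abort("Fewer rows than folds.")
  if (is.null(a_max)) a_max <- min(ncol(xm), n - ceiling(n / folds) - 1)
  a_max <- min(a_max, qr(xm)$rank)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  press <- numeric(a_max)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    xtr <- scale(xm[!test, , drop = FALSE])
    ytr <- scale(ym[!test, , drop = FALSE], scale = FALSE)
    xte <- scale(xm[test, , drop = FALSE],
                 center = attr(xtr, "scaled:center"),
                 scale = attr(xtr, "scaled:scale"))
    fit <- nipals_pls(xtr, ytr, a_max)
    # Reconstruct predictions at each truncation A from the same fit.
    for (a in seq_len(a_max)) {
      ba <- fit$W[, seq_len(a), drop = FALSE] %*%
        solve(crossprod(fit$P[, seq_len(a), drop = FALSE],
                        fit$W[, seq_len(a), drop = FALSE]),
              t(fit$Q[, seq_len(a), drop = FALSE]))
      yhat <- xte %*% ba
      yhat <- sweep(yhat, 2, attr(ytr, "scaled:center"), "+")
      press[a] <- press[a] + sum((ym[test, , drop = FALSE] - yhat)^2)
    }
  }
  tss <- sum(ym^2)
  q2 <- 1 - press / tss
  a_best <- 1L
  for (a in seq_len(a_max)[-1]) {
    if (q2[a] - q2[a_best] > min_improvement) a_best <- a
  }
  list(a_best = a_best,
       q2 = tibble(ncomp = seq_len(a_max), q2 = q2))
}

#' Permutation inference for a PLSR model and its coefficients
#'
#' Rows of the response block are permuted jointly `B` times and the model
#' refitted each time. The model p-value is the add-one-smoothed right tail
#' of the null R-squared against the observed one; each coefficient's
#' p-value is the two-sided tail of its null absolute value. All
#' predictor-by-response coefficient p-values form one family for
#' Benjamini-Hochberg adjustment.
#'
#' @param x,y As in [plsr_fit()].
#' @param ncomp Number of components.
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param fdr_alpha Threshold applied to the adjusted values.
#' @return A `plsr_permutation`: the observed `plsr_fit`, `model_p`, and a
#'   coefficient tibble with `p`, `p_fdr` and `significant`.
#' @export
plsr_permutation <- function(x, y, ncomp, B = 10000, seed = NULL,
                             fdr_alpha = 0.05) {
  if (B < 100) warn("B < 100 permutations gives unstable p-values.")
  xm <- prepare_predictors(x)
  ym <- prepare_responses(y)
  fit <- plsr_fit(xm, ym, ncomp)
  n <- nrow(xm)
  tss <- sum(ym^2)
  count_r2 <- 0
  count_coef <- matrix(0, nrow(fit$B), ncol(fit$B))
  abs_obs <- abs(fit$B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      yp <- ym[sample.int(n), , drop = FALSE]
      nf <- nipals_pls(xm, yp, ncomp)
      r2 <- 1 - sum((yp - xm %*% nf$B)^2) / tss
      if (r2 >= fit$r_squared) count_r2 <- count_r2 + 1
      count_coef <- count_coef + (abs(nf$B) >= abs_obs)
    }
  })
  p_coef <- (count_coef + 1) / (B + 1)
  p_fdr <- matrix(p.adjust(p_coef, method = "BH"), nrow(p_coef))
  coef_tbl <- tibble(
    predictor = rep(fit$predictors, times = ncol(fit$B)),
    response = rep(fit$responses, each = nrow(fit$B)),
    estimate = as.vector(fit$B),
    p = as.vector(p_coef),
    p_fdr = as.vector(p_fdr)
  )
  coef_tbl$significant <- coef_tbl$p_fdr < fdr_alpha
  structure(list(fit = fit, model_p = (count_r2 + 1) / (B + 1),
                 coefficients = coef_tbl, B = B, seed = seed,
                 fdr_alpha = fdr_alpha),
            class = "plsr_permutation")
}

#' @export
print.plsr_permutation <- function(x, ...) {
  cat("PLSR permutation report: R^2 =",
      format(x$fit$r_squared, digits = 3),
      ", model p =", format(x$model_p, digits = 4), "(B =", x$B, ")\n")
  cat(sum(x$coefficients$significant), "of", nrow(x$coefficients),
      "coefficients significant at p_fdr <", x$fdr_alpha, "\n")
  invisible(x)
}

#' Tidy PLSR coefficients
#'
#' @param x A `plsr_fit` or `plsr_permutation`.
#' @param ... Unused.
#' @return Tibble of predictor-by-response coefficients (with permutation
#'   p-values when available).
#' @export
tidy.plsr_fit <- function(x, ...) {
  tibble(predictor = rep(x$predictors, times = ncol(x$B)),
         response = rep(x$responses, each = nrow(x$B)),
         estimate = as.vector(x$B))
}

#' @rdname tidy.plsr_fit
#' @export
tidy.plsr_permutation <- function(x, ...) x$coefficients

#' One-row PLSR model summary
#'
#' @param x A `plsr_fit` or `plsr_permutation`.
#' @param ... Unused.
#' @return Tibble with `ncomp`, `r_squared` (and `model_p`, `B` for
#'   permutation reports).
#' @export
glance.plsr_fit <- function(x, ...) {
  tibble(ncomp = x$ncomp, r_squared = x$r_squared)
}

#' @rdname glance.plsr_fit
#' @export
glance.plsr_permutation <- function(x, ...) {
  tibble(ncomp = x$fit$ncomp, r_squared = x$fit$r_squared,
         model_p = x$model_p, B = x$B)
}

#' Benjamini-Hochberg adjusted p-values with rejection flags
#'
#' Step-up adjustment `p_(i) * m / i` with the right-to-left running
#' minimum, capped at 1; monotone in the input order statistics.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Rejection threshold on the adjusted values.
#' @return Tibble with `p`, `p_fdr`, `reject`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  adj <- p.adjust(pvals, method = "BH")
  tibble(p = pvals, p_fdr = adj, reject = adj < alpha)
}

#' One-way ANOVA with Tukey HSD contrasts between profiles
#'
#' Tests mean differences of a per-subject value across primary-profile
#' groups, then reports all pairwise mean differences with
#' studentized-range adjusted p-values. Groups with fewer than two members
#' are excluded with a warning.
#'
#' @param data Data frame.
#' @param value Name of the numeric column to compare.
#' @param group Name of the grouping column (e.g. primary profile).
#' @return List with `anova` (one-row tibble: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`) and `tukey` (tibble of pairwise contrasts).
#' @export
anova_tukey <- function(data, value, group) {
  check_columns(data, c(value, group))
  v <- data[[value]]
  g <- factor(data[[group]])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]
  g <- droplevels(g[ok])
  small <- names(table(g))[table(g) < 2]
  if (length(small) > 0) {
    warn(paste0("Excluding group(s) with < 2 members: ",
                paste(small, collapse = ", ")))
    keep <- !g %in% small
    v <- v[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) abort("Need at least 2 groups with >= 2 members.")
  fit <- aov(v ~ g)
  sm <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit)$g
  list(
    anova = tibble(f_statistic = sm$`F value`[1],
                   df_between = sm$Df[1], df_within = sm$Df[2],
                   p_value = sm$`Pr(>F)`[1]),
    tukey = as_tibble(tuk, rownames = "contrast") |>
      setNames(c("contrast", "difference", "lower", "upper", "p_adj"))
  )
}
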