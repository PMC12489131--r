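# Split-half exploratory factor analysis for the latent cognitive factors
# (verbal ability, executive function/processing speed, memory).

#' Split a table into two balanced halves
#'
#' Random disjoint halves whose sizes differ by at most one, overall and
#' within each stratum, reproducible under the seed. A stratum of size one
#' is assigned deterministically to the first half with a warning.
#'
#' @param data Data frame.
#' @param stratify_by Optional column name to balance over.
#' @param seed Integer seed.
#' @return List of two tibbles `half1`, `half2`.
#' @export
split_half <- function(data, stratify_by = NULL, seed = NULL) {
  n <- nrow(data)
  if (n < 2) abort("Need at least 2 rows to split.")
  strata <- if (is.null(stratify_by)) rep(1L, n) else {
    check_columns(data, stratify_by)
    as.integer(factor(data[[stratify_by]]))
  }
  assign1 <- logical(n)
  with_seed(seed, {
    for (s in unique(strata)) {
      rows <- which(strata == s)
      if (length(rows) == 1) {
        warn(paste0("Stratum of size 1 assigned deterministically to ",
                    "half 1."))
        assign1[rows] <- TRUE
        next
      }
      rows <- sample(rows)
      assign1[rows[seq_len(ceiling(length(rows) / 2))]] <- TRUE
    }
  })
  # Rebalance across strata so the overall sizes differ by <= 1: move the
  # surplus from odd strata if the ceiling rule over-filled half 1.
  excess <- sum(assign1) - ceiling(n / 2)
  if (excess > 0) {
    sizes <- table(strata)
    odd_strata <- as.integer(names(sizes)[sizes %% 2 == 1 & sizes > 1])
    for (s in head(odd_strata, excess)) {
      rows <- which(assign1 & strata == s)
      assign1[rows[length(rows)]] <- FALSE
    }
  }
  list(half1 = as_tibble(data[assign1, , drop = FALSE]),
       half2 = as_tibble(data[!assign1, , drop = FALSE]))
}

#' Fit an exploratory factor model by iterated principal-axis factoring
#'
#' Estimates `q` common factors from the subtest correlation matrix
#' (pairwise-complete) by principal-axis factoring: the diagonal of the
#' correlation matrix is replaced by communality estimates (initialized at
#' the squared multiple correlations), the top-`q` eigenstructure gives the
#' loadings, and the communalities are re-estimated until the largest
#' change falls below `tol`. Loadings are then rotated (`varimax`
#' orthogonal, `promax` oblique, or none), ordered by descending explained
#' variance, and sign-fixed so each factor's largest-magnitude loading is
#' positive. Heywood cases (communality > 1) are clipped with a warning.
#'
#' @param data Data frame holding the subtest columns.
#' @param subtests Character vector of subtest column names.
#' @param q Number of factors (`q < length(subtests)`).
#' @param rotation `"promax"` (default; cognitive factors correlate),
#'   `"varimax"`, or `"none"`.
#' @param max_iter,tol Convergence controls for the communality iteration.
#' @return A `factor_model`: loadings (p x q), uniquenesses, the factor
#'   correlation matrix `Phi` (identity for orthogonal rotations), the
#'   subtest correlation matrix `R`, and metadata.
#' @export
efa_fit <- function(data, subtests, q, rotation = c("promax", "varimax",
                                                    "none"),
                    max_iter = 1000, tol = 1e-6) {
  rotation <- match.arg(rotation)
  p <- length(subtests)
  if (q < 1) abort("q must be >= 1.")
  if (q >= p) abort("Number of factors must be smaller than the number of indicators.")
  x <- feature_matrix(data, subtests)
  sds <- apply(x, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds < 1e-12)) {
    abort(paste0("Constant subtest: ",
                 paste(subtests[!is.finite(sds) | sds < 1e-12],
                       collapse = ", ")))
  }
  r <- cor(x, use = "pairwise.complete.obs")
  ev_r <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_r) <= 1e-10) {
    abort("Subtest correlation matrix is not positive definite.")
  }
  h <- 1 - 1 / diag(solve(r)) # squared multiple correlations
  lambda <- NULL
  for (iter in seq_len(max_iter)) {
    rh <- r
    diag(rh) <- h
    e <- eigen(rh, symmetric = TRUE)
    lam <- e$vectors[, seq_len(q), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(q)], 0)), q)
    h_new <- rowSums(lam^2)
    if (any(h_new > 1)) {
      warn("Heywood case: communality > 1 clipped.")
      h_new <- pmin(h_new, 1 - 1e-6)
    }
    delta <- max(abs(h_new - h))
    h <- h_new
    lambda <- lam
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(paste0("Principal-axis factoring did not converge in ", max_iter,
                 " iterations (last delta = ", format(delta), ")."))
  }
  phi <- diag(q)
  if (q > 1 && rotation == "varimax") {
    rot <- varimax(lambda)
    lambda <- unclass(rot$loadings)
  } else if (q > 1 && rotation == "promax") {
    rot <- promax(lambda)
    lambda <- unclass(rot$loadings)
    rotmat <- rot$rotmat
    phi <- solve(crossprod(rotmat))
    phi <- stats::cov2cor((phi + t(phi)) / 2)
  }
  # Order factors by descending explained variance, fix signs.
  ord <- order(-colSums(lambda^2))
  lambda <- lambda[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  for (j in seq_len(q)) {
    if (lambda[which.max(abs(lambda[, j])), j] < 0) {
      lambda[, j] <- -lambda[, j]
      phi[j, -j] <- -phi[j, -j]
      phi[-j, j] <- -phi[-j, j]
    }
  }
  dimnames(lambda) <- list(subtests, paste0("F", seq_len(q)))
  dimnames(phi) <- list(colnames(lambda), colnames(lambda))
  structure(list(loadings = lambda,
                 uniquenesses = setNames(1 - rowSums((lambda %*% phi) *
                                                       lambda), subtests),
                 Phi = phi, R = r, rotation = rotation,
                 factor_names = colnames(lambda), subtests = subtests,
                 q = q, n_iter = iter),
            class = "factor_model")
}

#' Regression-method (Thurstone) factor scores
#'
#' Scores each subject as `s = z R^-1 S`, where `z` is the standardized
#' subtest row, `R` the subtest correlation matrix and `S` the structure
#' matrix (`loadings %*% Phi` for oblique rotations). A numerically
#' singular `R` is ridge-stabilized (`eps = 1e-8 * trace(R)/p` on the
#' diagonal) with a warning. Scores are standardized before being appended.
#'
#' @param model A `factor_model`.
#' @param data Data frame holding the model's subtests (complete rows are
#'   scored; rows with missing subtests get missing scores).
#' @param names Column names for the appended scores; defaults to the
#'   model's factor names.
#' @return `data` with `q` appended standardized score columns.
#' @export
factor_scores <- function(model, data, names = model$factor_names) {
  stopifnot(inherits(model, "factor_model"))
  x <- feature_matrix(data, model$subtests)
  sds <- apply(x, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds < 1e-12)) {
    abort("Constant subtest: standardization is undefined.")
  }
  z <- scale(x)
  r <- model$R
  structure_mat <- model$loadings %*% model$Phi
  rinv <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(rinv) || kappa(r) > 1e12) {
    warn("Singular subtest correlation matrix; ridge-stabilized inverse.")
    rinv <- solve(r + diag(1e-8 * sum(diag(r)) / ncol(r), ncol(r)))
  }
  s <- z %*% rinv %*% structure_mat
  s <- scale(s)
  attr(s, "scaled:center") <- NULL
  attr(s, "scaled:scale") <- NULL
  colnames(s) <- names
  dplyr::bind_cols(as_tibble(data), as_tibble(s))
}

#' Split-half replication check for a factor model
#'
#' Refits the factor model on the held-out half and reports per-factor
#' Tucker congruence with the first-half loadings — the package's
#' confirmation step standing in for a full confirmatory factor analysis.
#'
#' @param model A `factor_model` fitted on the first half.
#' @param half2 The held-out half.
#' @param threshold Congruence below which replication is flagged.
#' @return Tibble with `factor`, `congruence`, `replicated`.
#' @export
efa_replication <- function(model, half2, threshold = 0.9) {
  refit <- efa_fit(half2, model$subtests, model$q, rotation = model$rotation)
  cong <- tucker_congruence(model$loadings, refit$loadings)
  tibble(factor = model$factor_names, congruence = cong,
         replicated = cong >= threshold)
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Factor model:", x$q, "factors,", length(x$subtests), "subtests,",
      x$rotation, "rotation\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tidy factor loadings
#'
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return Long tibble with `subtest`, `factor`, `loading`, `uniqueness`.
#' @export
tidy.factor_model <- function(x, ...) {
  as_tibble(x$loadings, rownames = "subtest") |>
    tidyr::pivot_longer(-"subtest", names_to = "factor",
                        values_to = "loading") |>
    dplyr::left_join(tibble(subtest = x$subtests,
                            uniqueness = unname(x$uniquenesses)),
                     by = "subtest")
}
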