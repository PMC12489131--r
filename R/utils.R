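# Internal helpers shared across stages.

#' Derive a per-stage random seed from the global run seed
#'
#' Every stochastic stage draws its seed deterministically from the single
#' `RunConfig` seed, so a whole analysis reruns byte-identically without any
#' per-stage seed bookkeeping. The derived seed is a multiplicative-congruence
#' mix of the global seed and a stage label hash, kept below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"fcm"`, `"aswp"`).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(7, "fcm")
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131) %% m
  s <- (abs(seed) %% m) + 1
  out <- (s * 48271 + h * 69621) %% m
  as.integer(out %% (m - 2) + 1)
}

# Evaluate an expression under a local RNG state with the given seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Stage logging: one line with stage name and parameter echo, suppressed
# unless options(fuzzyprofiles.verbose = TRUE).
fp_log <- function(stage, ...) {
  if (isTRUE(getOption("fuzzyprofiles.verbose", FALSE))) {
    kv <- list(...)
    msg <- paste0("[", stage, "] ",
                  paste(names(kv), unlist(lapply(kv, format)),
                        sep = "=", collapse = " "))
    inform(msg)
  }
  invisible(NULL)
}

# Check that `data` contains the named columns; abort naming the missing one.
check_columns <- function(data, cols, what = "column") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing ", what, ifelse(length(missing) > 1, "s", ""), ": ",
                 paste(missing, collapse = ", ")),
          class = "fp_schema_error")
  }
  invisible(TRUE)
}

# Extract a numeric matrix of the named feature columns.
feature_matrix <- function(data, features) {
  check_columns(data, features, "feature column")
  x <- as.matrix(as.data.frame(data)[, features, drop = FALSE])
  if (!is.numeric(x)) abort("Feature columns must be numeric.")
  storage.mode(x) <- "double"
  x
}

# Membership tibbles: first column subject_id, remaining columns one per
# profile. These helpers pull the two parts out.
membership_matrix <- function(u) {
  stopifnot(is.data.frame(u))
  check_columns(u, "subject_id")
  m <- as.matrix(as.data.frame(u)[, setdiff(names(u), "subject_id"),
                                  drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(u$subject_id)
  m
}

membership_tibble <- function(u_mat, subject_id) {
  out <- as_tibble(u_mat)
  out <- dplyr::bind_cols(tibble(subject_id = as.character(subject_id)), out)
  out
}

# Validate membership rows: entries in [0,1], rows sum to 1 within tol.
check_memberships <- function(u_mat, tol = 1e-9) {
  if (any(!is.finite(u_mat))) abort("Non-finite membership values.")
  if (any(u_mat < -tol) || any(u_mat > 1 + tol)) {
    abort("Membership values outside [0, 1].")
  }
  rs <- rowSums(u_mat)
  if (any(abs(rs - 1) > tol)) {
    abort(paste0("Membership rows must sum to 1 (max deviation ",
                 format(max(abs(rs - 1))), ")."))
  }
  invisible(TRUE)
}

# Squared Euclidean cross-distances between rows of x (n x d) and c (k x d).
cross_dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

# Tucker's congruence coefficient between loading matrices, column-wise,
# after greedy column alignment and sign matching.
#' Tucker congruence between two loading matrices
#'
#' Columns of `b` are matched to columns of `a` by maximum absolute
#' congruence (greedy, without replacement) and sign-aligned before the
#' coefficient is computed, so factor order and reflection are immaterial.
#'
#' @param a,b Numeric matrices with the same number of rows.
#' @return Numeric vector, one congruence per column of `a`, in `[0, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b))
  q <- ncol(a)
  cong <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  full <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in seq_len(q)) full[i, j] <- cong(a[, i], b[, j])
  out <- numeric(q)
  used <- logical(q)
  for (i in order(-apply(abs(full), 1, max))) {
    j <- which.max(ifelse(used, -Inf, abs(full[i, ])))
    used[j] <- TRUE
    out[i] <- abs(full[i, j])
  }
  out
}
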