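# Subject-centroid membership graph, average shortest weighted path (ASWP)
# and the permutation test for non-random aggregation of diagnoses.

#' Build the bipartite subject-centroid membership graph
#'
#' Subjects and profile centroids are nodes; each subject is connected to
#' each centroid by an edge carrying its membership value as the weight and
#' a monotone-decreasing transform of it as the traversal distance:
#' `d = 1 - u` (default) or `d = -log(u)`. Zero-membership edges are kept
#' with distance 1 under `one_minus_u` and dropped under `neg_log_u`. The
#' graph is strictly bipartite: subjects only ever connect through
#' centroids, so proximity on the graph encodes shared profile composition.
#'
#' @param u Membership tibble (`subject_id` + one column per profile).
#' @param transform `"one_minus_u"` or `"neg_log_u"`.
#' @return A `membership_graph`: list with the `igraph` object, the
#'   transform, and the subject/profile node names.
#' @export
build_membership_graph <- function(u,
                                   transform = c("one_minus_u",
                                                 "neg_log_u")) {
  transform <- match.arg(transform)
  if (nrow(u) == 0) abort("Empty membership matrix.")
  um <- membership_matrix(u)
  check_memberships(um)
  subjects <- rownames(um)
  profiles <- paste0("profile::", colnames(um))
  edges <- tidyr::expand_grid(subject = subjects, profile = profiles)
  edges$weight <- as.vector(t(um))
  if (transform == "one_minus_u") {
    edges$distance <- 1 - edges$weight
  } else {
    edges <- edges[edges$weight > 0, ]
    edges$distance <- -log(edges$weight)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("subject", "profile", "weight", "distance")],
    directed = FALSE,
    vertices = data.frame(name = c(subjects, profiles),
                          type = rep(c(FALSE, TRUE),
                                     c(length(subjects), length(profiles))))
  )
  structure(list(graph = g, transform = transform, subjects = subjects,
                 profiles = colnames(um)),
            class = "membership_graph")
}

#' Subject-to-subject shortest-path distance matrix
#'
#' All-pairs shortest-path distances between subject nodes (via the
#' centroid layer). Computing this once and passing it to repeated
#' [aswp_permutation_test()] calls on the same graph avoids recomputing
#' the paths per diagnosis.
#'
#' @param graph A `membership_graph`.
#' @return A symmetric numeric matrix over `graph$subjects`.
#' @export
subject_distance_matrix <- function(graph) {
  stopifnot(inherits(graph, "membership_graph"))
  subject_distances(graph)
}

# Subject-to-subject shortest-path distance matrix on the graph.
subject_distances <- function(graph, from = graph$subjects,
                              to = graph$subjects) {
  igraph::distances(graph$graph, v = from, to = to,
                    weights = igraph::E(graph$graph)$distance,
                    algorithm = "dijkstra")
}

#' Average shortest weighted path among a set of subjects
#'
#' The mean, over all unordered pairs of the given subjects, of the
#' shortest-path distance on the membership graph (paths traverse
#' centroids; under the `1 - u` transform a pair sharing a strong profile
#' is two short hops apart). Smaller values mean tighter aggregation.
#'
#' @param graph A `membership_graph`.
#' @param subject_set Character vector of at least two distinct subject ids.
#' @return A single number.
#' @export
aswp <- function(graph, subject_set) {
  stopifnot(inherits(graph, "membership_graph"))
  subject_set <- as.character(subject_set)
  if (anyDuplicated(subject_set)) abort("Duplicate subject ids in set.")
  unknown <- setdiff(subject_set, graph$subjects)
  if (length(unknown) > 0) {
    abort(paste0("Unknown subject id(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (length(subject_set) < 2) abort("Need at least 2 subjects.")
  d <- subject_distances(graph, from = subject_set, to = subject_set)
  mean(d[upper.tri(d)])
}

#' Permutation test for non-random aggregation on the membership graph
#'
#' Compares the observed ASWP of the flagged subjects with a null
#' distribution built from `B` uniformly drawn subject subsets of the same
#' size. Both tails are reported with the add-one smoothing
#' `p = (count + 1) / (B + 1)`: under the `1 - u` distance, a *small* ASWP
#' means the flagged subjects sit close together on the graph (aggregate in
#' specific profiles), so `p_left` is the compactness tail.
#'
#' @param graph A `membership_graph`.
#' @param labels Logical/0-1 vector over `graph$subjects` (in that order),
#'   or a character vector of flagged subject ids.
#' @param B Number of permutations (default 5000).
#' @param seed Integer seed.
#' @param label_name Optional name recorded in the result.
#' @param dist_matrix Optional precomputed [subject_distance_matrix()],
#'   reused across repeated tests on the same graph.
#' @return An `aswp_result`: observed ASWP, null samples, `p_left`,
#'   `p_right`, `B`, `n_labeled`.
#' @export
aswp_permutation_test <- function(graph, labels, B = 5000, seed = NULL,
                                  label_name = NULL, dist_matrix = NULL) {
  stopifnot(inherits(graph, "membership_graph"))
  if (is.character(labels)) {
    flagged <- unique(labels)
  } else {
    if (length(labels) != length(graph$subjects)) {
      abort("labels must align with graph subjects.")
    }
    flagged <- graph$subjects[which(as.logical(labels))]
  }
  n <- length(graph$subjects)
  n_lab <- length(flagged)
  if (n_lab < 2) abort("Need at least 2 flagged subjects.")
  if (n_lab > n) abort("More flagged subjects than graph subjects.")
  d_all <- dist_matrix %||% subject_distances(graph)
  idx <- match(flagged, graph$subjects)
  pair_mean <- function(ix) {
    m <- length(ix)
    sub <- d_all[ix, ix]
    (sum(sub) - sum(diag(sub))) / (m * (m - 1))
  }
  observed <- pair_mean(idx)
  null <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      null[b] <- pair_mean(sample.int(n, n_lab))
    }
  })
  structure(list(observed = observed, null = null,
                 p_left = (sum(null <= observed) + 1) / (B + 1),
                 p_right = (sum(null >= observed) + 1) / (B + 1),
                 B = B, n_labeled = n_lab, seed = seed,
                 label_name = label_name %||% "labeled"),
            class = "aswp_result")
}

#' @export
print.aswp_result <- function(x, ...) {
  cat("ASWP permutation test (", x$label_name, "): observed = ",
      format(x$observed, digits = 4), ", n = ", x$n_labeled,
      ", B = ", x$B, "\n", sep = "")
  cat("  p_left (compact) = ", format(x$p_left, digits = 4),
      ", p_right (dispersed) = ", format(x$p_right, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Tidy an ASWP permutation result
#'
#' @param x An `aswp_result`.
#' @param ... Unused.
#' @return One-row tibble with the observed statistic, both tail p-values,
#'   and the null mean.
#' @export
tidy.aswp_result <- function(x, ...) {
  tibble(label = x$label_name, aswp = x$observed,
         null_mean = mean(x$null), p_left = x$p_left, p_right = x$p_right,
         n_labeled = x$n_labeled, B = x$B)
}

#' Any-diagnosis (PSYPATHO) indicator
#'
#' Flags subjects carrying at least one psychiatric diagnosis: 1 if any
#' available flag is 1 (missing flags ignored), 0 if all available flags
#' are 0, missing when every flag is missing.
#'
#' @param data Data frame with 0/1/missing diagnosis columns.
#' @param diagnoses Diagnosis column names.
#' @return Integer vector (0/1/`NA`) aligned with `data` rows.
#' @export
psypatho_index <- function(data, diagnoses) {
  if (length(diagnoses) < 1) abort("Need at least one diagnosis column.")
  check_columns(data, diagnoses)
  m <- as.matrix(as.data.frame(data)[, diagnoses, drop = FALSE])
  any1 <- rowSums(m == 1, na.rm = TRUE) > 0
  allna <- rowSums(!is.na(m)) == 0
  out <- as.integer(any1)
  out[allna] <- NA_integer_
  out
}

#' Distribution of diagnoses across primary profiles
#'
#' For each diagnosis, the percentage of flagged subjects whose primary
#' (argmax-membership) profile is each profile; each diagnosis row sums
#' to 100.
#'
#' @param u Membership tibble.
#' @param data Data frame aligned with `u` holding the diagnosis columns.
#' @param diagnoses Diagnosis column names.
#' @return Tibble with `diagnosis`, `profile`, `n`, `percent`.
#' @export
diagnosis_profile_distribution <- function(u, data, diagnoses) {
  check_columns(data, diagnoses)
  um <- membership_matrix(u)
  prof <- colnames(um)[max.col(um, ties.method = "first")]
  out <- list()
  for (dx in diagnoses) {
    flag <- data[[dx]]
    rows <- which(!is.na(flag) & flag == 1)
    if (length(rows) == 0) {
      warn(paste0("Diagnosis '", dx, "' has zero cases."))
      next
    }
    counts <- table(factor(prof[rows], levels = colnames(um)))
    out[[dx]] <- tibble(diagnosis = dx, profile = names(counts),
                        n = as.integer(counts),
                        percent = 100 * as.integer(counts) / length(rows))
  }
  dplyr::bind_rows(out)
}

#' Write a membership graph to GraphML
#'
#' Edge weights and distances are stored as edge attributes at full
#' precision, so a re-imported graph reproduces shortest paths exactly.
#'
#' @param graph A `membership_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "membership_graph"))
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}
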