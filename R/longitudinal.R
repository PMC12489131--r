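# Primary-profile assignment, cross-timepoint stability, movement ratios
# and trajectory (Sankey) tables.

#' Primary profile per subject
#'
#' The profile with each subject's highest membership value; exact ties are
#' resolved to the lowest profile index and flagged.
#'
#' @param u Membership tibble.
#' @return Tibble with `subject_id`, `profile` (factor over the profile
#'   labels), `profile_index`, `tie`.
#' @export
main_profile <- function(u) {
  um <- membership_matrix(u)
  check_memberships(um)
  idx <- max.col(um, ties.method = "first")
  mx <- um[cbind(seq_len(nrow(um)), idx)]
  tie <- unname(rowSums(um == mx) > 1)
  tibble(subject_id = rownames(um),
         profile = factor(colnames(um)[idx], levels = colnames(um)),
         profile_index = as.integer(idx),
         tie = tie)
}

#' Cross-timepoint transition summary
#'
#' Crosses primary-profile assignments at two timepoints over the subjects
#' present at both (complete cases). Reports the k x k from/to counts
#' matrix, the stability percentage `100 * trace / n`, and the per-origin
#' movement ratio — the fraction of a profile's members whose primary
#' profile differs at the next timepoint.
#'
#' @param assignments_t1,assignments_t2 Tibbles from [main_profile()] (or
#'   any tibbles with `subject_id` and `profile`).
#' @return A `transition_summary`: list with `counts`,
#'   `stability_percent`, `movement` (tibble with `profile`, `n_origin`,
#'   `n_moved`, `ratio`, `display`), and `n_complete`.
#' @export
transition_summary <- function(assignments_t1, assignments_t2) {
  check_columns(assignments_t1, c("subject_id", "profile"))
  check_columns(assignments_t2, c("subject_id", "profile"))
  ids <- intersect(assignments_t1$subject_id, assignments_t2$subject_id)
  if (length(ids) == 0) abort("No subjects present at both timepoints.")
  p1 <- assignments_t1$profile[match(ids, assignments_t1$subject_id)]
  p2 <- assignments_t2$profile[match(ids, assignments_t2$subject_id)]
  levels_all <- union(levels(factor(p1)), levels(factor(p2)))
  p1 <- factor(as.character(p1), levels = levels_all)
  p2 <- factor(as.character(p2), levels = levels_all)
  counts <- table(from = p1, to = p2)
  n <- length(ids)
  stay <- sum(diag(counts))
  origin <- rowSums(counts)
  moved <- origin - diag(counts)
  ratio <- ifelse(origin > 0, moved / origin, NA_real_)
  movement <- tibble(profile = rownames(counts),
                     n_origin = as.integer(origin),
                     n_moved = as.integer(moved),
                     ratio = as.numeric(ratio),
                     display = format_movement_ratio(as.numeric(ratio)))
  structure(list(counts = unclass(counts),
                 stability_percent = 100 * stay / n,
                 movement = movement, n_complete = n),
            class = "transition_summary")
}

#' Format a movement ratio as "ratio (percent)"
#'
#' Pairs the two-decimal ratio with the two-decimal percentage, e.g.
#' `0.5491` becomes `"0.55 (54.91%)"`.
#'
#' @param ratio Numeric vector in `[0, 1]`.
#' @return Character vector.
#' @export
format_movement_ratio <- function(ratio) {
  ifelse(is.na(ratio), NA_character_,
         sprintf("%.2f (%.2f%%)", ratio, 100 * ratio))
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("Transition summary over", x$n_complete, "complete cases\n")
  cat("Stability:", sprintf("%.2f%%", x$stability_percent),
      "remained in the same primary profile\n")
  cat("Movement ratios:\n")
  print(as.data.frame(x$movement))
  invisible(x)
}

#' Tidy a transition summary into a long from/to tibble
#'
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `n`.
#' @export
tidy.transition_summary <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)) |>
    setNames(c("from", "to", "n")) |>
    dplyr::mutate(n = as.integer(.data$n))
}

#' One-row transition stability summary
#'
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return Tibble with `n_complete`, `stability_percent`, `moved_percent`.
#' @export
glance.transition_summary <- function(x, ...) {
  tibble(n_complete = x$n_complete,
         stability_percent = x$stability_percent,
         moved_percent = 100 - x$stability_percent)
}

#' Trajectory paths across three timepoints (Sankey table)
#'
#' Counts each observed primary-profile path across the timepoints over the
#' subjects present at all of them. The marginal flows between consecutive
#' timepoints equal the corresponding [transition_summary()] counts.
#'
#' @param ... Two or more [main_profile()] tibbles, in timepoint order.
#' @return Tibble with one column per timepoint (`t1`, `t2`, ...) and `n`,
#'   sorted by decreasing count.
#' @export
trajectory_paths <- function(...) {
  assignments <- list(...)
  if (length(assignments) == 1 && is.list(assignments[[1]]) &&
      !is.data.frame(assignments[[1]])) {
    assignments <- assignments[[1]]
  }
  stopifnot(length(assignments) >= 2)
  ids <- Reduce(intersect, lapply(assignments, function(a) a$subject_id))
  if (length(ids) == 0) abort("No subjects present at all timepoints.")
  cols <- lapply(assignments, function(a) {
    as.character(a$profile[match(ids, a$subject_id)])
  })
  names(cols) <- paste0("t", seq_along(cols))
  dplyr::count(as_tibble(cols), dplyr::across(dplyr::everything()),
               name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
}
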