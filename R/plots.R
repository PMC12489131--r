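# ggplot2 views of fitted objects. Minimal renderings: the underlying
# tables are the primary deliverable (see the tidy() methods).

#' Plot profile centroids as grouped bars
#'
#' One panel per profile showing the standardized centroid value of each
#' feature — the tabular counterpart of the per-profile radar view.
#'
#' @param object A `profile_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile_model <- function(object, ...) {
  d <- tidy(object)
  d$feature <- factor(d$feature, levels = object$features)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$centroid,
                                  fill = .data$feature)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~profile) +
    ggplot2::labs(x = NULL, y = "Centroid (sd units)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the silhouette profile of candidate cluster counts
#'
#' @param object A `k_selection` from [select_k()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$k,
                                              y = .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_best, linetype = 2) +
    ggplot2::labs(x = "Number of profiles k", y = "Mean silhouette") +
    ggplot2::theme_minimal()
}

#' Plot an ASWP permutation null with the observed statistic
#'
#' @param object An `aswp_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aswp_result <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "ASWP under the null", y = "Count",
                  title = paste0(object$label_name, ": p_left = ",
                                 format(object$p_left, digits = 3))) +
    ggplot2::theme_minimal()
}

#' Plot a transition summary as a from/to flow tile map
#'
#' @param object A `transition_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transition_summary <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Profile at next timepoint",
                  y = "Profile at first timepoint") +
    ggplot2::theme_minimal()
}

#' Plot PLSR coefficients as a predictor-by-profile heatmap
#'
#' Significant cells (when permutation p-values are available) are starred.
#'
#' @param object A `plsr_fit` or `plsr_permutation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plsr_permutation <- function(object, ...) {
  d <- tidy(object)
  d$star <- ifelse(d$significant, "*", "")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$response, y = .data$predictor,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star)) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "Profile membership", y = "Predictor",
                  fill = "Coefficient") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.plsr_permutation
#' @export
autoplot.plsr_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$response, y = .data$predictor,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "Profile membership", y = "Predictor",
                  fill = "Coefficient") +
    ggplot2::theme_minimal()
}
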