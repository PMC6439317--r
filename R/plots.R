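# ggplot2 views of the main result types. Each autoplot() returns a ggplot
# the caller can restyle.

#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_hline geom_vline
#'   geom_histogram geom_abline labs theme_minimal scale_y_log10
NULL

#' Plot the variance decomposition of a mixed-model fit
#'
#' @param object An `fe_mm_fit`.
#' @param ... Unused.
#' @return A ggplot: one bar per variance component's share of the total.
#' @export
autoplot.fe_mm_fit <- function(object, ...) {
  vp <- variance_proportions(object)
  ggplot(vp, aes(x = .data$component, y = .data$proportion)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "share of total variance",
         title = "Expression variance decomposition") +
    theme_minimal()
}

#' Plot binned differential-expression z-scores
#'
#' @param object A `fe_de` tibble from [detect_de()].
#' @param ... Unused.
#' @return A ggplot of within-bin z against mean expression, with the call
#'   threshold marked.
#' @export
autoplot.fe_de <- function(object, ...) {
  thr <- attr(object, "z_threshold") %||% 3.1
  d <- dplyr::mutate(object,
                     log_mean = log10((.data$mean_hfe + .data$mean_lfe) / 2 + 1))
  ggplot(d, aes(x = .data$log_mean, y = .data$z, colour = .data$call)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    labs(x = "log10(mean FPKM + 1)", y = "within-bin z",
         title = paste("Binned DE,", unique(d$tissue)[1])) +
    theme_minimal()
}

#' Plot RIF score space
#'
#' @param object A `fe_rif` tibble from [compute_rif()].
#' @param ... Unused.
#' @return A ggplot of z1 against z2, key regulators highlighted.
#' @export
autoplot.fe_rif <- function(object, ...) {
  thr <- attr(object, "z_threshold") %||% 1.96
  ggplot(dplyr::filter(object, .data$scored),
         aes(x = .data$z1, y = .data$z2, colour = .data$is_key)) +
    geom_point() +
    geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    geom_vline(xintercept = c(-thr, thr), linetype = "dashed") +
    labs(x = "RIF1 (z)", y = "RIF2 (z)", colour = "key regulator",
         title = "Regulatory impact factors") +
    theme_minimal()
}

#' Plot the degree distribution of a co-expression network
#'
#' @param object A `fe_network`.
#' @param ... Unused.
#' @return A ggplot histogram of node degree.
#' @export
autoplot.fe_network <- function(object, ...) {
  ggplot(object$nodes, aes(x = .data$degree)) +
    geom_histogram(bins = 30, fill = "steelblue") +
    labs(x = "connections per gene", y = "genes",
         title = sprintf("Degree distribution (|r| >= %.2f)", object$min_abs_r)) +
    theme_minimal()
}

#' Plot differential connectivity between condition networks
#'
#' @param object A `fe_diffcon` tibble.
#' @param ... Unused.
#' @return A ggplot of scaled HFE vs scaled LFE connectivity; significant
#'   genes highlighted.
#' @export
autoplot.fe_diffcon <- function(object, ...) {
  ggplot(object, aes(x = .data$scaled_lfe, y = .data$scaled_hfe,
                     colour = .data$is_significant)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "scaled connectivity, LFE", y = "scaled connectivity, HFE",
         colour = "significant",
         title = "Differential connectivity") +
    theme_minimal()
}

#' Plot enrichment results
#'
#' @param object A `fe_enrichment` tibble.
#' @param top Number of best sets to display.
#' @param ... Unused.
#' @return A ggplot dotplot of the top sets by adjusted p-value.
#' @export
autoplot.fe_enrichment <- function(object, top = 15, ...) {
  d <- head(object, top)
  ggplot(d, aes(x = -log10(.data$p_adj),
                y = stats::reorder(.data$set, -.data$p_adj),
                size = .data$k, colour = .data$significant)) +
    geom_point() +
    labs(x = expression(-log[10]~adjusted~p), y = NULL, size = "overlap",
         title = "Gene-set enrichment") +
    theme_minimal()
}

#' Plot the permutation null of a region-overlap test
#'
#' @param object A `fe_permtest`.
#' @param ... Unused.
#' @return A ggplot histogram of null overlap counts with the observed count
#'   marked.
#' @export
autoplot.fe_permtest <- function(object, ...) {
  ggplot(tibble(null = object$null_counts), aes(x = .data$null)) +
    geom_histogram(bins = 30, fill = "grey70") +
    geom_vline(xintercept = object$observed, colour = "red") +
    labs(x = "overlapping query regions (null)", y = "permutations",
         title = sprintf("Observed %d vs expected %.1f (p = %.3g)",
                         object$observed, object$expected, object$p_value)) +
    theme_minimal()
}
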