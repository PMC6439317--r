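#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each gene set, tests over-representation of the query genes with an
#' upper-tail hypergeometric test \eqn{P(X \ge k)} where `k` is the
#' query/set overlap, `K` the set size within the background, `n` the query
#' size and `N` the background size; p-values are Benjamini-Hochberg
#' adjusted across the tested sets.
#'
#' @param query Character vector of genes of interest; must be a subset of
#'   `background`.
#' @param background Character vector, the gene universe (e.g. all genes
#'   passing the expression floor).
#' @param sets Named list of gene sets (see [read_gmt()]); each set is
#'   intersected with the background before testing.
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @return A `fe_enrichment` tibble sorted by p-value: `set`, `k`, `K`,
#'   `n`, `N`, `p_value`, `p_adj`, `significant`.
#' @export
#' @examples
#' sets <- list(A = c("g1", "g2", "g3"))
#' hypergeometric_enrichment(c("g1", "g2"), paste0("g", 1:10), sets)
hypergeometric_enrichment <- function(query, background, sets, alpha = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) {
    abort("Empty background.", class = "feconet_invalid_input")
  }
  query <- unique(query)
  if (!all(query %in% background)) {
    abort("`query` must be a subset of `background`.",
          class = "feconet_invalid_input")
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  N <- length(background); n <- length(query)
  rows <- purrr::imap(sets, function(members, nm) {
    members <- intersect(unique(members), background)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = nm, k = k, K = K, n = n, N = N, p_value = p)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adj = p.adjust(.data$p_value, method = "BH"),
                  significant = .data$p_adj < alpha) |>
    dplyr::arrange(.data$p_value, .data$set)
  structure(out, class = c("fe_enrichment", class(out)), alpha = alpha)
}

#' Percentage of hits, rounded half-up
#'
#' Printed overlap/success rates: `100 * n_hit / n_total` rounded half away
#' from zero to `decimals` places.
#'
#' @param n_hit,n_total Counts with `0 <= n_hit <= n_total`, `n_total > 0`.
#' @param decimals Decimal places of the printed percentage.
#' @return The rounded percentage.
#' @export
#' @examples
#' overlap_rate(86, 136)   # 63
#' overlap_rate(114, 621)  # 18
overlap_rate <- function(n_hit, n_total, decimals = 0) {
  n_hit <- check_count(n_hit, "n_hit", 0)
  n_total <- check_count(n_total, "n_total", 1)
  decimals <- check_count(decimals, "decimals", 0)
  if (n_hit > n_total) {
    abort("`n_hit` cannot exceed `n_total`.", class = "feconet_invalid_input")
  }
  round_half_up(100 * n_hit / n_total, decimals)
}
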