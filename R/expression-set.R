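#' Bundle an expression matrix with its sample metadata
#'
#' An `expr_set` couples a genes x samples matrix of non-negative expression
#' values (FPKM unless noted) with a per-sample metadata table giving the
#' sequencing library, tissue and condition (e.g. HFE/LFE feed-efficiency
#' group) of every column. All downstream stages (normalization, DE calling,
#' RIF scoring, network building) consume this container.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). Values must be finite and >= 0
#'   unless `log2 = TRUE`.
#' @param samples Data frame with columns `sample_id`, `library`, `tissue`,
#'   `condition`; one row per column of `values`, any order.
#' @param log2 Logical; `TRUE` marks the matrix as log2-scale (negative
#'   values allowed).
#'
#' @return An object of class `expr_set`: a list with elements `values`
#'   (matrix, metadata-aligned columns) and `samples` (tibble).
#' @export
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- tibble::tibble(sample_id = paste0("s", 1:4),
#'                        library = paste0("lib", 1:4),
#'                        tissue = c("liver", "liver", "muscle", "muscle"),
#'                        condition = c("HFE", "LFE", "HFE", "LFE"))
#' es <- expression_set(m, meta)
expression_set <- function(values, samples, log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "feconet_invalid_argument")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    abort("`values` must have at least one gene and one sample.",
          class = "feconet_empty_input")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs gene rownames and sample colnames.",
          class = "feconet_invalid_argument")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicate gene IDs in `values`.", class = "feconet_invalid_argument")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicate sample IDs in `values`.", class = "feconet_invalid_argument")
  }
  if (any(!is.finite(values))) {
    abort("Expression values must be finite.", class = "feconet_invalid_argument")
  }
  if (!log2 && any(values < 0)) {
    abort("Expression values must be non-negative on the linear scale.",
          class = "feconet_domain_error")
  }
  samples <- as_tibble(samples)
  need <- c("sample_id", "library", "tissue", "condition")
  if (!all(need %in% names(samples))) {
    abort(paste("`samples` must have columns:", paste(need, collapse = ", ")),
          class = "feconet_invalid_argument")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("Duplicate sample IDs in metadata.", class = "feconet_invalid_argument")
  }
  if (!setequal(samples$sample_id, colnames(values))) {
    missing_meta <- setdiff(colnames(values), samples$sample_id)
    missing_expr <- setdiff(samples$sample_id, colnames(values))
    abort(paste0("Sample sets disagree. Missing from metadata: ",
                 paste(missing_meta, collapse = ", "),
                 "; missing from matrix: ",
                 paste(missing_expr, collapse = ", ")),
          class = "feconet_validation_error")
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  structure(list(values = values, samples = samples, log2 = isTRUE(log2)),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2" else "linear"))
  cat(sprintf("  tissues: %s\n", paste(unique(x$samples$tissue), collapse = ", ")))
  cat(sprintf("  conditions: %s\n", paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Turn an expression set into a long tibble
#'
#' @param x An `expr_set`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `sample_id`, `library`, `tissue`,
#'   `condition`, `value`.
#' @export
tidy.expr_set <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
  dplyr::left_join(long, x$samples, by = "sample_id") |>
    dplyr::select("gene", "sample_id", "library", "tissue", "condition", "value")
}

#' Subset an expression set by gene and/or sample
#'
#' @param expr An `expr_set`.
#' @param genes Character vector of gene IDs to keep (default all).
#' @param samples Character vector of sample IDs to keep (default all).
#' @return The subsetted `expr_set`.
#' @export
subset_expression <- function(expr, genes = NULL, samples = NULL) {
  stopifnot(inherits(expr, "expr_set"))
  genes <- genes %||% rownames(expr$values)
  samples <- samples %||% colnames(expr$values)
  bad <- setdiff(genes, rownames(expr$values))
  if (length(bad)) {
    abort(paste("Unknown gene IDs:", paste(head(bad, 5), collapse = ", ")),
          class = "feconet_invalid_argument")
  }
  bad <- setdiff(samples, colnames(expr$values))
  if (length(bad)) {
    abort(paste("Unknown sample IDs:", paste(head(bad, 5), collapse = ", ")),
          class = "feconet_invalid_argument")
  }
  expression_set(expr$values[genes, samples, drop = FALSE],
                 expr$samples[expr$samples$sample_id %in% samples, ],
                 log2 = expr$log2)
}

#' Drop genes below an average-expression floor
#'
#' Genes whose grand mean across *all* samples (all tissues pooled) is lower
#' than `min_mean` FPKM are discarded; the boundary value itself is kept
#' because the rule drops strictly below the floor.
#'
#' @param expr An `expr_set` on the linear (FPKM) scale.
#' @param min_mean Expression floor in FPKM (default 0.2).
#' @return The filtered `expr_set`.
#' @export
filter_low_expression <- function(expr, min_mean = 0.2) {
  stopifnot(inherits(expr, "expr_set"))
  check_number(min_mean, "min_mean", min = 0)
  keep <- rowMeans(expr$values) >= min_mean
  if (!any(keep)) {
    abort("No genes pass the expression floor.", class = "feconet_empty_input")
  }
  expression_set(expr$values[keep, , drop = FALSE], expr$samples, log2 = expr$log2)
}

#' Log2-transform expression values with a pseudo-count
#'
#' `value -> log2(value + offset)`; monotone and invertible (see
#' [unlog_transform()]). The default offset of 1 maps zero FPKM to zero.
#'
#' @param expr An `expr_set` on the linear scale.
#' @param offset Pseudo-count added before taking logs; must be > 0 because
#'   zeros occur in FPKM matrices.
#' @return An `expr_set` flagged as log2 scale.
#' @export
log_transform <- function(expr, offset = 1) {
  stopifnot(inherits(expr, "expr_set"))
  if (expr$log2) abort("Already on the log2 scale.", class = "feconet_invalid_argument")
  check_number(offset, "offset", min = .Machine$double.xmin)
  if (any(expr$values < 0)) {
    abort("Negative expression values cannot be log-transformed.",
          class = "feconet_domain_error")
  }
  out <- log2(expr$values + offset)
  es <- expression_set(out, expr$samples, log2 = TRUE)
  attr(es, "offset") <- offset
  es
}

#' Invert [log_transform()]
#'
#' @param expr A log2-scale `expr_set` produced by [log_transform()].
#' @param offset Pseudo-count used in the forward transform (defaults to the
#'   recorded one).
#' @return An `expr_set` on the linear scale.
#' @export
unlog_transform <- function(expr, offset = NULL) {
  stopifnot(inherits(expr, "expr_set"), expr$log2)
  offset <- offset %||% attr(expr, "offset") %||% 1
  expression_set(pmax(2^expr$values - offset, 0), expr$samples, log2 = FALSE)
}
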