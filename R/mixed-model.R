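#' Fit the expression-normalization mixed model by EM-REML
#'
#' Models the log2 expression of gene j in sample s (library i, tissue k,
#' condition l) as
#' \deqn{Y_{ijkl} = \mu + L_i + G_j + GT_{jk} + GP_{jl} + e_{ijkl}}
#' with a fixed library effect and independent random gene, gene x tissue
#' and gene x condition effects. Variance components are estimated by
#' REML via EM iterations; the reported effect solutions are the
#' generalized-least-squares estimates (fixed) and BLUPs (random) at the
#' converged components.
#'
#' Because every gene is observed in the same samples and genes are
#' conditionally independent given the library effects, the restricted
#' likelihood factorizes over genes around one sample-level covariance
#' matrix \eqn{V = \sigma^2_G J + \sigma^2_{GT} B_T + \sigma^2_{GP} B_P +
#' \sigma^2_e I}. The EM updates are evaluated in that S x S
#' parameterization, which is algebraically identical to EM on the full
#' mixed-model equations but costs O(S^2 G) per iteration. EM keeps all
#' components non-negative; a component driven to the boundary is pinned at
#' zero.
#'
#' The library fixed effect is identified by a sum-to-zero constraint, so
#' `mu` is the grand mean of the per-library means.
#'
#' @param logexpr A log2-scale `expr_set` (see [log_transform()]).
#' @param tol Convergence tolerance on the relative change of every variance
#'   component.
#' @param max_iter Maximum EM iterations; `converged` is `FALSE` if reached
#'   with relative change still above `tol`.
#' @param init Optional starting values, named numeric of length 4
#'   (gene, gene_tissue, gene_condition, residual).
#' @return An object of class `fe_mm_fit`: list with `mu`,
#'   `library_solutions` (tibble), `gene_solutions` (named vector),
#'   `gene_tissue_solutions` (genes x tissues matrix),
#'   `gene_condition_solutions` (genes x conditions matrix),
#'   `variance_components` (named vector: gene, gene_tissue, gene_condition,
#'   residual), `n_iterations`, `converged`, `reml_loglik`, plus the design
#'   bookkeeping used by [compute_nme()].
#' @export
fit_mixed_model <- function(logexpr, tol = 1e-6, max_iter = 500, init = NULL) {
  stopifnot(inherits(logexpr, "expr_set"))
  if (!logexpr$log2) {
    abort("fit_mixed_model() expects log2-scale expression; see log_transform().",
          class = "feconet_invalid_argument")
  }
  check_number(tol, "tol", min = 0)
  max_iter <- check_count(max_iter, "max_iter", 1)
  meta <- logexpr$samples
  tissues <- sort(unique(meta$tissue))
  conditions <- sort(unique(meta$condition))
  libraries <- sort(unique(meta$library))
  if (length(tissues) < 2L || length(conditions) != 2L || length(libraries) < 2L) {
    abort("Need >= 2 libraries, >= 2 tissues and exactly 2 conditions.",
          class = "feconet_invalid_argument")
  }
  Y <- t(logexpr$values)                      # S x G
  S <- nrow(Y); G <- ncol(Y)
  if (S < 4L) abort("Too few samples.", class = "feconet_invalid_argument")

  A <- model.matrix(~ 0 + factor(meta$library, levels = libraries))   # S x p
  colnames(A) <- libraries
  ZT <- model.matrix(~ 0 + factor(meta$tissue, levels = tissues))     # S x T
  ZP <- model.matrix(~ 0 + factor(meta$condition, levels = conditions)) # S x 2
  J <- matrix(1, S, S)
  BT <- tcrossprod(ZT)
  BP <- tcrossprod(ZP)
  I_S <- diag(S)

  ybar <- rowMeans(Y)
  tot <- var(as.vector(Y - matrix(ybar, S, G)))
  if (!is.finite(tot) || tot <= 0) tot <- var(as.vector(Y))
  theta <- init %||% setNames(rep(tot / 4, 4),
                              c("gene", "gene_tissue", "gene_condition", "residual"))
  if (theta[["residual"]] <= 0) theta[["residual"]] <- tot / 4 + 1e-8

  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    V <- theta[["gene"]] * J + theta[["gene_tissue"]] * BT +
      theta[["gene_condition"]] * BP + theta[["residual"]] * I_S
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      abort("Sample covariance matrix is numerically singular; check the design and starting values.",
            class = "feconet_numerical_rank_error")
    }
    Vi <- chol2inv(ch)
    ViA <- Vi %*% A
    M <- crossprod(A, ViA)                     # p x p
    chM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(chM)) {
      abort("Library design is rank-deficient after absorbing constraints.",
            class = "feconet_numerical_rank_error")
    }
    Minv <- chol2inv(chM)
    beta <- drop(Minv %*% crossprod(ViA, ybar))        # per-library means
    R <- Y - as.vector(A %*% beta)                                 # S x G residuals
    U <- Vi %*% R                                       # V^{-1} r_j columns
    # REML projection restricted to one gene: P0 = Vi - (1/G) ViA Minv A'Vi
    P0 <- Vi - (ViA %*% Minv %*% t(ViA)) / G

    upd <- theta
    # gene effect (Z = 1_S)
    w <- colSums(U)
    tr <- sum(P0)
    upd[["gene"]] <- (theta[["gene"]]^2 * sum(w^2) +
                        G * theta[["gene"]] - theta[["gene"]]^2 * G * tr) / G
    # gene x tissue (Z = tissue indicators)
    W <- crossprod(ZT, U)                               # T x G
    tr <- sum(vapply(seq_along(tissues), function(k) {
      rows <- which(meta$tissue == tissues[k]); sum(P0[rows, rows])
    }, 0))
    qT <- G * length(tissues)
    upd[["gene_tissue"]] <- (theta[["gene_tissue"]]^2 * sum(W^2) +
                               qT * theta[["gene_tissue"]] -
                               theta[["gene_tissue"]]^2 * G * tr) / qT
    # gene x condition
    W <- crossprod(ZP, U)                               # 2 x G
    tr <- sum(vapply(seq_along(conditions), function(l) {
      rows <- which(meta$condition == conditions[l]); sum(P0[rows, rows])
    }, 0))
    qP <- G * 2
    upd[["gene_condition"]] <- (theta[["gene_condition"]]^2 * sum(W^2) +
                                  qP * theta[["gene_condition"]] -
                                  theta[["gene_condition"]]^2 * G * tr) / qP
    # residual
    trP <- G * sum(diag(Vi)) - sum(diag(Minv %*% (crossprod(ViA))))
    upd[["residual"]] <- (theta[["residual"]]^2 * sum(U^2) +
                            G * S * theta[["residual"]] -
                            theta[["residual"]]^2 * trP) / (G * S)

    upd[upd < 0] <- 0                                   # boundary pin
    # convergence on the scale of the total variance, so a component sitting
    # at (or creeping toward) zero cannot stall the relative criterion
    rel <- abs(upd - theta) / max(sum(theta), 1e-8)
    theta <- upd
    if (max(rel) < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }

  # Solutions at the converged components.
  V <- theta[["gene"]] * J + theta[["gene_tissue"]] * BT +
    theta[["gene_condition"]] * BP + theta[["residual"]] * I_S
  Vi <- chol2inv(chol(V))
  ViA <- Vi %*% A
  M <- crossprod(A, ViA)
  Minv <- chol2inv(chol(M))
  beta <- drop(Minv %*% crossprod(ViA, ybar))
  R <- Y - as.vector(A %*% beta)
  U <- Vi %*% R
  mu <- mean(beta)
  lib_sol <- tibble(library = libraries, estimate = unname(beta - mu))
  gene_sol <- setNames(theta[["gene"]] * colSums(U), colnames(Y))
  gt_sol <- t(theta[["gene_tissue"]] * crossprod(ZT, U))     # G x T
  dimnames(gt_sol) <- list(colnames(Y), tissues)
  gp_sol <- t(theta[["gene_condition"]] * crossprod(ZP, U))  # G x 2
  dimnames(gp_sol) <- list(colnames(Y), conditions)
  quad <- sum(R * U)
  reml_ll <- -0.5 * (G * 2 * sum(log(diag(chol(V)))) +
                       determinant(M, logarithm = TRUE)$modulus + quad)

  structure(list(
    mu = mu,
    library_solutions = lib_sol,
    gene_solutions = gene_sol,
    gene_tissue_solutions = gt_sol,
    gene_condition_solutions = gp_sol,
    variance_components = theta,
    n_iterations = n_iter,
    converged = converged,
    reml_loglik = as.numeric(reml_ll),
    tissues = tissues,
    conditions = conditions,
    n_genes = G,
    n_samples = S
  ), class = "fe_mm_fit")
}

#' @export
print.fe_mm_fit <- function(x, ...) {
  cat(sprintf("<fe_mm_fit> %d genes, %d samples; %s after %d EM iterations\n",
              x$n_genes, x$n_samples,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(round(x$variance_components, 6))
  invisible(x)
}

#' Tidy the variance components of a mixed-model fit
#'
#' @param x An `fe_mm_fit`.
#' @param ... Unused.
#' @return Tibble with `component`, `variance`, `proportion`.
#' @export
tidy.fe_mm_fit <- function(x, ...) variance_proportions(x)

#' @rdname tidy.fe_mm_fit
#' @export
glance.fe_mm_fit <- function(x, ...) {
  vc <- x$variance_components
  tibble(
    n_genes = x$n_genes, n_samples = x$n_samples,
    n_iterations = x$n_iterations, converged = x$converged,
    reml_loglik = x$reml_loglik,
    total_variance = sum(vc),
    explained_share = sum(vc[c("gene", "gene_tissue", "gene_condition")]) / sum(vc)
  )
}

#' Normalized mean expression (NME) from mixed-model solutions
#'
#' NME is a linear combination of the random-effect solutions (BLUPs):
#' mode `"gene"` returns \eqn{\hat G_j}; `"gene_tissue"` (the default, used
#' for tissue-specificity calls) returns \eqn{\hat G_j + \hat{GT}_{jk}};
#' `"gene_tissue_condition"` adds \eqn{\hat{GP}_{jl}} and returns one column
#' per tissue/condition pair.
#'
#' @param fit An `fe_mm_fit`.
#' @param mode Which solutions to combine.
#' @param allow_unconverged Proceed even if the fit did not converge.
#' @return Numeric matrix (genes x columns, log2 units) with attributes
#'   `mode` and `provenance`.
#' @export
compute_nme <- function(fit,
                        mode = c("gene_tissue", "gene", "gene_tissue_condition"),
                        allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "fe_mm_fit"))
  mode <- match.arg(mode)
  if (!fit$converged && !allow_unconverged) {
    abort("Fit did not converge; pass allow_unconverged = TRUE to override.",
          class = "feconet_invalid_argument")
  }
  g <- fit$gene_solutions
  out <- switch(mode,
    gene = matrix(g, ncol = 1, dimnames = list(names(g), "gene")),
    gene_tissue = fit$gene_tissue_solutions + g,
    gene_tissue_condition = {
      cols <- expand.grid(tissue = fit$tissues, condition = fit$conditions,
                          stringsAsFactors = FALSE)
      m <- vapply(seq_len(nrow(cols)), function(i) {
        g + fit$gene_tissue_solutions[, cols$tissue[i]] +
          fit$gene_condition_solutions[, cols$condition[i]]
      }, numeric(length(g)))
      colnames(m) <- paste(cols$tissue, cols$condition, sep = "|")
      rownames(m) <- names(g)
      m
    }
  )
  attr(out, "mode") <- mode
  attr(out, "provenance") <- switch(mode,
    gene = "G", gene_tissue = "G + GT", gene_tissue_condition = "G + GT + GP")
  out
}

#' Share of expression variance per model component
#'
#' @param fit An `fe_mm_fit`.
#' @return Tibble with `component`, `variance`, `proportion`; proportions
#'   sum to one.
#' @export
variance_proportions <- function(fit) {
  vc <- if (inherits(fit, "fe_mm_fit")) fit$variance_components else fit
  stopifnot(is.numeric(vc), length(vc) == 4L)
  total <- sum(vc)
  if (total <= 0) {
    abort("All variance components are zero.", class = "feconet_degenerate_variance")
  }
  tibble(component = names(vc), variance = unname(vc),
         proportion = unname(vc) / total)
}
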