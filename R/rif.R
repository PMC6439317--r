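#' Phenotypic impact factor of a target gene
#'
#' `PIF = ((e_H + e_L) / 2) * (e_H - e_L)`: average abundance times the
#' between-condition expression difference. Swapping the conditions negates
#' it. Vectorized.
#'
#' @param mean_hfe,mean_lfe Mean expression per condition.
#' @return Numeric PIF values.
#' @export
#' @examples
#' compute_pif(4, 2)  # 6
compute_pif <- function(mean_hfe, mean_lfe) {
  stopifnot(is.numeric(mean_hfe), is.numeric(mean_lfe))
  ((mean_hfe + mean_lfe) / 2) * (mean_hfe - mean_lfe)
}

# Pearson correlation matrix regulators x targets with zero-variance
# columns/rows mapped to correlation 0 (warned once by the caller).
cor_zero_safe <- function(x, y) {
  sx <- apply(x, 2, sd); sy <- apply(y, 2, sd)
  r <- suppressWarnings(cor(x, y))
  r[!is.finite(r)] <- 0
  zero <- any(sx == 0) || any(sy == 0)
  list(r = r, had_zero_variance = zero)
}

#' Regulatory impact factor (RIF) scores per tissue
#'
#' Scores each candidate regulator against a target-gene set within one or
#' more tissues. With `e_j` the target's condition mean and `r_ij` the
#' within-condition Pearson correlation between regulator i and target j
#' over that tissue's samples:
#' \deqn{RIF1_i = \frac{1}{n_t}\sum_j PIF_j\,(r_{ij}^{H} - r_{ij}^{L})^2}
#' \deqn{RIF2_i = \frac{1}{n_t}\sum_j \left[(e_j^H r_{ij}^H)^2 -
#'   (e_j^L r_{ij}^L)^2\right]}
#' RIF1 rewards differential co-expression weighted by the target's
#' phenotypic impact; RIF2 rewards change in the regulator's ability to
#' predict target abundance. Regulators whose mean expression over the
#' tissue's samples falls below the mean of all genes expressed there are
#' excluded before scoring (`scored = FALSE`). A regulator that is also a
#' target never contributes its self-pair. Zero-variance expression within
#' a condition contributes correlation 0 (with a warning). Raw scores are
#' z-standardized across the scored regulators within each tissue.
#'
#' @param expr An `expr_set` (raw FPKM scale in routine use).
#' @param regulators Character vector of candidate regulator gene IDs.
#' @param targets Character vector of target gene IDs.
#' @param tissues Tissues to score (default: all in the metadata); each
#'   needs >= 3 samples per condition.
#' @param z_threshold Key-regulator threshold in SD units used to set
#'   `is_key` (default 1.96, two-sided P < 0.05).
#' @return A `fe_rif` tibble: `regulator`, `tissue`, `mean_expr`, `scored`,
#'   `n_targets`, `rif1`, `rif2`, `z1`, `z2`, `is_key`.
#' @export
compute_rif <- function(expr, regulators, targets, tissues = NULL,
                        z_threshold = 1.96) {
  stopifnot(inherits(expr, "expr_set"))
  check_number(z_threshold, "z_threshold", 0)
  regulators <- unique(regulators)
  targets <- unique(targets)
  universe <- rownames(expr$values)
  missing <- setdiff(c(regulators, targets), universe)
  if (length(missing)) {
    abort(paste("Genes absent from expression data:",
                paste(head(missing, 5), collapse = ", ")),
          class = "feconet_invalid_argument")
  }
  if (length(targets) == 0L || length(regulators) == 0L) {
    return(structure(tibble(regulator = character(), tissue = character(),
                            mean_expr = numeric(), scored = logical(),
                            n_targets = integer(), rif1 = numeric(),
                            rif2 = numeric(), z1 = numeric(), z2 = numeric(),
                            is_key = logical()),
                     class = c("fe_rif", class(tibble()))))
  }
  meta <- expr$samples
  tissues <- tissues %||% sort(unique(meta$tissue))
  had_zero <- FALSE

  per_tissue <- purrr::map(tissues, function(tis) {
    sel <- meta$tissue == tis
    if (!any(sel)) {
      abort(sprintf("Tissue '%s' not in metadata.", tis),
            class = "feconet_unknown_tissue")
    }
    h_cols <- meta$sample_id[sel & meta$condition == "HFE"]
    l_cols <- meta$sample_id[sel & meta$condition == "LFE"]
    if (length(h_cols) < 3L || length(l_cols) < 3L) {
      abort(sprintf("Tissue '%s' needs >= 3 samples per condition.", tis),
            class = "feconet_invalid_argument")
    }
    tis_cols <- meta$sample_id[sel]
    tis_mean <- rowMeans(expr$values[, tis_cols, drop = FALSE])
    floor_val <- mean(tis_mean)
    mean_expr <- tis_mean[regulators]
    scored <- mean_expr >= floor_val

    eH <- rowMeans(expr$values[targets, h_cols, drop = FALSE])
    eL <- rowMeans(expr$values[targets, l_cols, drop = FALSE])
    pif <- compute_pif(eH, eL)

    kept <- regulators[scored]
    rif1 <- rif2 <- setNames(rep(NA_real_, length(regulators)), regulators)
    if (length(kept)) {
      XH_r <- t(expr$values[kept, h_cols, drop = FALSE])
      XH_t <- t(expr$values[targets, h_cols, drop = FALSE])
      XL_r <- t(expr$values[kept, l_cols, drop = FALSE])
      XL_t <- t(expr$values[targets, l_cols, drop = FALSE])
      cH <- cor_zero_safe(XH_r, XH_t)
      cL <- cor_zero_safe(XL_r, XL_t)
      had_zero <<- had_zero || cH$had_zero_variance || cL$had_zero_variance
      rH <- cH$r; rL <- cL$r
      # drop self-pairs: regulator scored against itself contributes nothing
      self <- outer(kept, targets, "==")
      w1 <- matrix(pif, nrow(self), ncol(self), byrow = TRUE) * (rH - rL)^2
      w2 <- (matrix(eH, nrow(self), ncol(self), byrow = TRUE) * rH)^2 -
        (matrix(eL, nrow(self), ncol(self), byrow = TRUE) * rL)^2
      w1[self] <- NA; w2[self] <- NA
      rif1[kept] <- rowMeans(w1, na.rm = TRUE)
      rif2[kept] <- rowMeans(w2, na.rm = TRUE)
    }
    zstd <- function(x) {
      ok <- !is.na(x)
      if (sum(ok) < 2L) return(ifelse(ok, 0, NA_real_))
      s <- sd(x[ok])
      if (!is.finite(s) || s == 0) return(ifelse(ok, 0, NA_real_))
      (x - mean(x[ok])) / s
    }
    n_t <- length(targets) - ifelse(regulators %in% targets, 1L, 0L)
    tibble(
      regulator = regulators, tissue = tis,
      mean_expr = unname(mean_expr), scored = unname(scored),
      n_targets = n_t,
      rif1 = unname(rif1), rif2 = unname(rif2),
      z1 = unname(zstd(rif1)), z2 = unname(zstd(rif2))
    )
  })
  if (had_zero) {
    warn("Zero-variance expression within a condition: affected correlations set to 0.")
  }
  out <- dplyr::bind_rows(per_tissue) |>
    dplyr::mutate(is_key = (abs(.data$z1) >= z_threshold |
                              abs(.data$z2) >= z_threshold) &
                    !is.na(.data$z1))
  structure(out, class = c("fe_rif", class(out)), z_threshold = z_threshold)
}

#' Call key regulators from RIF scores
#'
#' Returns the union, across tissues and across both RIF metrics, of
#' regulators whose standardized score deviates at least `z_threshold` SDs
#' from the regulator population mean (1.96 corresponds to two-sided
#' P < 0.05). All raw scores equal within a tissue means zero SD, hence no
#' calls from that tissue.
#'
#' @param scores A `fe_rif` tibble from [compute_rif()].
#' @param z_threshold Threshold in SD units.
#' @return Character vector of key-regulator gene IDs (possibly empty).
#' @export
call_key_regulators <- function(scores, z_threshold = 1.96) {
  check_number(z_threshold, "z_threshold", 0)
  if (nrow(scores) == 0L) return(character())
  hit <- scores |>
    dplyr::filter(.data$scored,
                  pmax(abs(.data$z1), abs(.data$z2), na.rm = TRUE) >= z_threshold)
  sort(unique(hit$regulator))
}
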