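#' Binned standard-deviation differential-expression calls
#'
#' For one tissue, the HFE and LFE group means of every gene are computed on
#' the supplied scale (raw FPKM by default — NME is reserved for
#' tissue-specificity) and subtracted (HFE minus LFE). Genes are ranked by
#' their mean expression over all of that tissue's samples and split into
#' `n_bins` quantile bins of near-equal size (ties broken by gene ID for
#' determinism), and each difference is standardized against its bin's mean
#' and sample SD. A gene is called differentially expressed when the
#' standardized difference strictly exceeds `z_threshold` in absolute value
#' (3.1 SD corresponds to a two-sided normal P < 0.001); a bin with zero SD
#' yields no calls.
#'
#' @param expr An `expr_set` (linear FPKM scale unless you deliberately pass
#'   log2 values).
#' @param tissue Tissue to test; both conditions need >= 2 samples there.
#' @param n_bins Number of expression bins (default 5).
#' @param z_threshold Call threshold in within-bin SD units (default 3.1).
#' @return A `fe_de` tibble: `gene`, `tissue`, `mean_hfe`, `mean_lfe`,
#'   `diff`, `bin`, `bin_mean`, `bin_sd`, `z`, `call` (one of `up_in_HFE`,
#'   `up_in_LFE`, `not_DE`).
#' @export
detect_de <- function(expr, tissue, n_bins = 5, z_threshold = 3.1) {
  stopifnot(inherits(expr, "expr_set"))
  n_bins <- check_count(n_bins, "n_bins", 1)
  check_number(z_threshold, "z_threshold", 0)
  meta <- expr$samples
  if (!tissue %in% meta$tissue) {
    abort(sprintf("Tissue '%s' not in metadata.", tissue),
          class = "feconet_unknown_tissue")
  }
  sel <- meta$tissue == tissue
  conds <- sort(unique(meta$condition[sel]))
  if (!all(c("HFE", "LFE") %in% conds)) {
    abort("Both HFE and LFE must be present in the tissue.",
          class = "feconet_invalid_argument")
  }
  h_cols <- meta$sample_id[sel & meta$condition == "HFE"]
  l_cols <- meta$sample_id[sel & meta$condition == "LFE"]
  if (length(h_cols) < 2L || length(l_cols) < 2L) {
    abort("Need >= 2 samples per condition in the tissue.",
          class = "feconet_invalid_argument")
  }
  vals <- expr$values
  if (nrow(vals) < n_bins) {
    abort("Fewer genes than bins.", class = "feconet_binning_error")
  }
  mean_hfe <- rowMeans(vals[, h_cols, drop = FALSE])
  mean_lfe <- rowMeans(vals[, l_cols, drop = FALSE])
  tissue_mean <- rowMeans(vals[, meta$sample_id[sel], drop = FALSE])
  out <- tibble(
    gene = rownames(vals), tissue = tissue,
    mean_hfe = unname(mean_hfe), mean_lfe = unname(mean_lfe),
    diff = unname(mean_hfe - mean_lfe),
    tissue_mean = unname(tissue_mean)
  )
  ord <- order(out$tissue_mean, out$gene)
  bin <- integer(nrow(out))
  bin[ord] <- ceiling(seq_len(nrow(out)) * n_bins / nrow(out))
  out$bin <- bin
  out <- out |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(bin_mean = mean(.data$diff), bin_sd = sd(.data$diff)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      z = dplyr::if_else(.data$bin_sd > 0,
                         (.data$diff - .data$bin_mean) / .data$bin_sd,
                         NA_real_),
      call = dplyr::case_when(
        is.na(.data$z) ~ "not_DE",
        .data$z > z_threshold ~ "up_in_HFE",
        .data$z < -z_threshold ~ "up_in_LFE",
        TRUE ~ "not_DE"
      )
    ) |>
    dplyr::select(-"tissue_mean")
  structure(out, class = c("fe_de", class(out)),
            n_bins = n_bins, z_threshold = z_threshold)
}

#' Call tissue-specific genes from an NME matrix
#'
#' A gene is specific to tissue `t` when its NME there exceeds the
#' population mean by `sd_multiplier` population SDs *and* its NME is
#' strictly below zero in every other tissue. By default the population
#' mean/SD are taken over the full gene x tissue NME matrix
#' (`scope = "global"`); `scope = "per_tissue"` uses each tissue column's
#' own statistics instead.
#'
#' @param nme Genes x tissues NME matrix from
#'   [compute_nme()]`(fit, "gene_tissue")`.
#' @param sd_multiplier Threshold in population SD units (default 1).
#' @param scope Population used for the mean/SD.
#' @return Annotation fragment tibble: `gene`, `category` ("TS"), `tissue`.
#'   A constant NME matrix (zero SD) yields no calls.
#' @export
call_tissue_specific <- function(nme, sd_multiplier = 1,
                                 scope = c("global", "per_tissue")) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(nme), ncol(nme) >= 2L)
  check_number(sd_multiplier, "sd_multiplier", 0)
  if (scope == "global") {
    s <- sd(as.vector(nme))
    thr <- rep(mean(nme) + sd_multiplier * s, ncol(nme))
    if (is.na(s) || s == 0) return(tibble(gene = character(), category = character(),
                                          tissue = character()))
  } else {
    s <- apply(nme, 2, sd)
    thr <- colMeans(nme) + sd_multiplier * s
    thr[is.na(s) | s == 0] <- Inf
  }
  frags <- purrr::map(seq_len(ncol(nme)), function(k) {
    high <- nme[, k] > thr[k]
    others_neg <- rowSums(nme[, -k, drop = FALSE] < 0) == (ncol(nme) - 1L)
    g <- rownames(nme)[high & others_neg]
    tibble(gene = g, category = rep("TS", length(g)),
           tissue = rep(colnames(nme)[k], length(g)))
  })
  dplyr::bind_rows(frags)
}

#' Build an annotation fragment from DE results
#'
#' @param de One or more `fe_de` tibbles (rows are bound together).
#' @return Fragment tibble (`gene`, `category` = "DE", `tissue`) with one
#'   row per DE gene x tissue.
#' @export
de_fragment <- function(de) {
  de <- dplyr::bind_rows(de)
  de |>
    dplyr::filter(.data$call != "not_DE") |>
    dplyr::transmute(.data$gene, category = "DE", .data$tissue)
}

#' Build an annotation fragment from a plain gene vector
#'
#' @param genes Character vector of gene IDs.
#' @param category Category code (e.g. "REG").
#' @return Fragment tibble (`gene`, `category`, `tissue` = NA).
#' @export
category_fragment <- function(genes, category) {
  tibble(gene = unique(genes), category = category, tissue = NA_character_)
}

#' Merge selection categories into one annotation with Venn counts
#'
#' Takes the per-category fragments (DE, TS, SNP, SEC, REG), unions the
#' flags per gene, collapses duplicate records of a gene keeping the record
#' with the highest grand-mean expression, removes genes whose grand mean
#' across all samples is zero, and tabulates per-category totals and all
#' exclusive Venn intersections.
#'
#' @param fragments List of fragment tibbles (or one bound tibble) with
#'   columns `gene`, `category`, `tissue`, optionally `grand_mean` for
#'   records carrying their own expression summary.
#' @param expr The `expr_set` defining the gene universe and grand means.
#' @param nme Optional NME matrix used to record each gene's tissue of
#'   maximum expression.
#' @return List with `annotation` (tibble: `gene`, logical flags `de`,
#'   `snp`, `ts`, `sec`, `reg`, `tissues_de`, `tissue_ts`, `tissue_max`,
#'   `grand_mean`), `totals` (category counts) and `venn` (exclusive
#'   intersection counts).
#' @export
merge_categories <- function(fragments, expr, nme = NULL) {
  stopifnot(inherits(expr, "expr_set"))
  frag <- dplyr::bind_rows(fragments)
  if (nrow(frag) == 0L) {
    return(list(
      annotation = tibble(gene = character(), de = logical(), snp = logical(),
                          ts = logical(), sec = logical(), reg = logical(),
                          tissues_de = character(), tissue_ts = character(),
                          tissue_max = character(), grand_mean = numeric()),
      totals = tibble(category = character(), n = integer()),
      venn = tibble(combo = character(), n = integer())
    ))
  }
  universe <- rownames(expr$values)
  bad <- setdiff(frag$gene, universe)
  if (length(bad)) {
    abort(paste("Fragment genes outside the expression universe:",
                paste(head(bad, 5), collapse = ", ")),
          class = "feconet_invalid_argument")
  }
  gm <- rowMeans(expr$values)
  if (!"grand_mean" %in% names(frag)) frag$grand_mean <- NA_real_
  frag$grand_mean <- dplyr::coalesce(frag$grand_mean, unname(gm[frag$gene]))

  ann <- frag |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      de = "DE" %in% .data$category,
      snp = "SNP" %in% .data$category,
      ts = "TS" %in% .data$category,
      sec = "SEC" %in% .data$category,
      reg = "REG" %in% .data$category,
      tissues_de = paste(sort(unique(.data$tissue[.data$category == "DE"])),
                         collapse = ","),
      tissue_ts = dplyr::first(.data$tissue[.data$category == "TS"],
                               default = NA_character_),
      grand_mean = max(.data$grand_mean),   # duplicate records: keep highest
      .groups = "drop"
    ) |>
    dplyr::filter(.data$grand_mean > 0)     # zero-mean genes removed

  if (!is.null(nme)) {
    tm <- tibble(gene = rownames(nme),
                 tissue_max = colnames(nme)[max.col(nme, ties.method = "first")])
    ann <- dplyr::left_join(ann, tm, by = "gene")
  } else {
    ann$tissue_max <- NA_character_
  }
  ann <- dplyr::select(ann, "gene", "de", "snp", "ts", "sec", "reg",
                       "tissues_de", "tissue_ts", "tissue_max", "grand_mean")

  flags <- c("de", "snp", "ts", "sec", "reg")
  totals <- tibble(
    category = toupper(flags),
    n = vapply(flags, function(f) sum(ann[[f]]), 0L, USE.NAMES = FALSE)
  ) |> dplyr::filter(.data$n > 0)
  combo <- apply(as.matrix(ann[flags]), 1, function(r) {
    paste(toupper(flags[as.logical(r)]), collapse = "&")
  })
  venn <- tibble(combo = combo) |>
    dplyr::count(.data$combo, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))

  list(annotation = ann, totals = totals, venn = venn)
}
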