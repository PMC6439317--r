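#' Sample layout for a multi-tissue two-group design
#'
#' Default layout mirrors the study design: five tissues sampled from nine
#' high- (HFE) and nine low-feed-efficiency (LFE) animals, with whole
#' missing samples in muscle (17 total) and adrenal gland (15 total); 86
#' samples in all, each its own sequencing library.
#'
#' @param tissues Tissue names.
#' @param n_hfe,n_lfe Samples per tissue in each condition (same length as
#'   `tissues`).
#' @return Sample metadata tibble (`sample_id`, `library`, `tissue`,
#'   `condition`).
#' @export
fe_design <- function(tissues = c("adrenal", "hypothalamus", "liver", "muscle", "pituitary"),
                      n_hfe = c(8, 9, 9, 9, 9),
                      n_lfe = c(7, 9, 9, 8, 9)) {
  stopifnot(length(tissues) == length(n_hfe), length(tissues) == length(n_lfe))
  if (length(tissues) < 2L) {
    abort("Need at least 2 tissues.", class = "feconet_invalid_argument")
  }
  if (any(n_hfe < 2L) || any(n_lfe < 2L)) {
    abort("Need >= 2 replicates per tissue x condition cell.",
          class = "feconet_invalid_argument")
  }
  rows <- purrr::map2(seq_along(tissues), tissues, function(i, t) {
    tibble(
      tissue = t,
      condition = c(rep("HFE", n_hfe[i]), rep("LFE", n_lfe[i])),
      rep = c(seq_len(n_hfe[i]), seq_len(n_lfe[i]))
    )
  })
  design <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%s_%02d", substr(.data$tissue, 1, 3),
                          .data$condition, .data$rep),
      library = paste0("lib_", .data$sample_id)
    ) |>
    dplyr::select("sample_id", "library", "tissue", "condition")
  design
}

#' Configuration of planted structure for the expression simulator
#'
#' Holds the generative parameters: the additive log2-scale variance
#' components of the normalization model, per-library shifts, and the
#' planted differential-expression, tissue-specificity and regulator-module
#' structure used by recovery tests.
#'
#' @param n_genes Total genes simulated.
#' @param mu Baseline log2 expression (log2 FPKM units).
#' @param sigma2_gene,sigma2_gene_tissue,sigma2_gene_condition,sigma2_resid
#'   Variance components (log2^2 units) of the gene, gene x tissue,
#'   gene x condition and residual effects. The default near-zero
#'   gene x condition component reflects how little expression variance the
#'   feed-efficiency contrast explains in tissue panels of this kind.
#' @param library_sd SD of per-library additive shifts (log2 units).
#' @param n_de_per_tissue Planted DE genes per tissue; effects alternate
#'   sign.
#' @param de_effect Absolute planted DE shift (log2 units) added to the HFE
#'   samples of the gene's tissue.
#' @param n_ts_per_tissue Planted tissue-specific genes per tissue.
#' @param ts_effect Gene x tissue effect (log2) in the home tissue of a
#'   planted TS gene.
#' @param ts_other Gene x tissue effect (log2) in all its other tissues
#'   (negative, so NME falls below zero there).
#' @param regulators `NULL`, or a list configuring a regulator experiment:
#'   `n_null` decoy regulators, `n_planted` differential regulators,
#'   `n_targets` targets each, `gamma` (regulator loading on its latent
#'   activity, both conditions), `beta` (target loading, HFE only),
#'   `target_shift` (log2 DE shift of targets in HFE), `home_tissue`, and
#'   `regulator_boost` (log2 added to planted regulators' gene effect so
#'   that the expression-floor rule used by RIF retains them).
#' @return A list of class `sim_truth_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       mu = 3,
                       sigma2_gene = 1.0,
                       sigma2_gene_tissue = 0.5,
                       sigma2_gene_condition = 0.002,
                       sigma2_resid = 0.3,
                       library_sd = 0.1,
                       n_de_per_tissue = 0,
                       de_effect = 1.5,
                       n_ts_per_tissue = 0,
                       ts_effect = 3,
                       ts_other = -1,
                       regulators = NULL) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 10),
    mu = check_number(mu, "mu"),
    sigma2_gene = check_number(sigma2_gene, "sigma2_gene", 0),
    sigma2_gene_tissue = check_number(sigma2_gene_tissue, "sigma2_gene_tissue", 0),
    sigma2_gene_condition = check_number(sigma2_gene_condition, "sigma2_gene_condition", 0),
    sigma2_resid = check_number(sigma2_resid, "sigma2_resid", 0),
    library_sd = check_number(library_sd, "library_sd", 0),
    n_de_per_tissue = check_count(n_de_per_tissue, "n_de_per_tissue", 0),
    de_effect = check_number(de_effect, "de_effect", 0),
    n_ts_per_tissue = check_count(n_ts_per_tissue, "n_ts_per_tissue", 0),
    ts_effect = check_number(ts_effect, "ts_effect"),
    ts_other = check_number(ts_other, "ts_other"),
    regulators = regulators
  )
  if (!is.null(regulators)) {
    defaults <- list(n_null = 50, n_planted = 1, n_targets = 20, gamma = 2,
                     beta = 2, target_shift = 2, home_tissue = "liver",
                     regulator_boost = 3, tissue_shift = 0)
    cfg$regulators <- utils::modifyList(defaults, regulators)
  }
  structure(cfg, class = "sim_truth_config")
}

#' Simulate a multi-tissue expression matrix with planted ground truth
#'
#' The log2-scale signal is built additively as
#' `mu + library + gene + gene:tissue + gene:condition + noise`, matching
#' the normalization model, plus the planted structure from [sim_config()]:
#' DE shifts in chosen tissues (HFE samples only), tissue-specific
#' gene x tissue patterns, and regulator modules in which target genes load
#' on a latent regulator activity in the HFE condition only. The signal is
#' then exponentiated (`2^x`) to an FPKM-like strictly positive scale.
#'
#' @param design Sample metadata from [fe_design()] (or equivalent tibble).
#' @param config A [sim_config()].
#' @param seed Integer seed; identical `(design, config, seed)` give
#'   identical output.
#' @return List with `expr` (an `expr_set`, linear scale) and `truth`, a
#'   list recording planted DE genes (`de_genes`: gene, tissue, effect),
#'   `ts_genes` (gene, tissue), `regulators` (tibble of candidates with
#'   `planted`, `home_tissue`), `targets` (named list per planted
#'   regulator), `variance_components` and `library_effects`.
#' @export
#' @examples
#' sim <- simulate_expression(fe_design(), sim_config(n_genes = 50), seed = 1)
#' dim(sim$expr)
simulate_expression <- function(design = fe_design(),
                                config = sim_config(),
                                seed = NULL) {
  stopifnot(inherits(config, "sim_truth_config"))
  design <- as_tibble(design)
  tissues <- unique(design$tissue)
  conditions <- unique(design$condition)
  if (length(tissues) < 2L || length(conditions) != 2L) {
    abort("Design needs >= 2 tissues and exactly 2 conditions.",
          class = "feconet_invalid_argument")
  }
  cells <- dplyr::count(design, .data$tissue, .data$condition)
  if (any(cells$n < 2L)) {
    abort("Every tissue x condition cell present must have >= 2 replicates.",
          class = "feconet_invalid_argument")
  }
  if (!is.null(config$regulators) &&
      !config$regulators$home_tissue %in% tissues) {
    abort(sprintf("Regulator home tissue '%s' is not in the design.",
                  config$regulators$home_tissue),
          class = "feconet_config_error")
  }

  G <- config$n_genes
  S <- nrow(design)
  genes <- sprintf("gene_%04d", seq_len(G))

  # Reserve disjoint gene blocks for the planted roles.
  n_de <- config$n_de_per_tissue * length(tissues)
  n_ts <- config$n_ts_per_tissue * length(tissues)
  reg <- config$regulators
  n_reg <- if (is.null(reg)) 0L else (reg$n_null + reg$n_planted)
  n_tar <- if (is.null(reg)) 0L else reg$n_planted * reg$n_targets
  if (n_de + n_ts + n_reg + n_tar > G) {
    abort("Planted roles need more genes than `n_genes` provides.",
          class = "feconet_config_error")
  }
  idx <- seq_len(G)
  de_idx <- idx[seq_len(n_de)]
  ts_idx <- idx[n_de + seq_len(n_ts)]
  reg_idx <- idx[n_de + n_ts + seq_len(n_reg)]
  tar_idx <- idx[n_de + n_ts + n_reg + seq_len(n_tar)]

  with_seed(seed, {
    lib_eff <- rnorm(S, 0, config$library_sd)
    g_eff <- rnorm(G, 0, sqrt(config$sigma2_gene))
    gt_eff <- matrix(rnorm(G * length(tissues), 0, sqrt(config$sigma2_gene_tissue)),
                     G, length(tissues), dimnames = list(genes, tissues))
    gp_eff <- matrix(rnorm(G * 2, 0, sqrt(config$sigma2_gene_condition)),
                     G, 2, dimnames = list(genes, conditions))

    # Planted tissue-specificity: override the gene x tissue pattern and pin
    # the gene effect to 0, so expression sits at ts_effect above baseline in
    # the home tissue and ts_other (below baseline) everywhere else.
    ts_genes <- tibble(gene = character(), tissue = character())
    if (n_ts > 0) {
      home <- rep(tissues, each = config$n_ts_per_tissue)
      for (i in seq_along(ts_idx)) {
        g_eff[ts_idx[i]] <- 0
        gt_eff[ts_idx[i], ] <- config$ts_other
        gt_eff[ts_idx[i], home[i]] <- config$ts_effect
      }
      ts_genes <- tibble(gene = genes[ts_idx], tissue = home)
    }

    tiss_of <- design$tissue
    cond_of <- design$condition
    t_col <- match(tiss_of, tissues)
    p_col <- match(cond_of, conditions)

    # Additive log2 signal, genes x samples.
    signal <- matrix(config$mu, G, S, dimnames = list(genes, design$sample_id))
    signal <- signal + matrix(lib_eff, G, S, byrow = TRUE)
    signal <- signal + g_eff
    signal <- signal + gt_eff[, t_col, drop = FALSE]
    signal <- signal + gp_eff[, p_col, drop = FALSE]

    # Planted DE: signed shift on the HFE samples of one tissue.
    de_genes <- tibble(gene = character(), tissue = character(), effect = numeric())
    if (n_de > 0) {
      home <- rep(tissues, each = config$n_de_per_tissue)
      effect <- config$de_effect * rep_len(c(1, -1), n_de)
      for (i in seq_along(de_idx)) {
        cols <- which(tiss_of == home[i] & cond_of == "HFE")
        signal[de_idx[i], cols] <- signal[de_idx[i], cols] + effect[i]
      }
      de_genes <- tibble(gene = genes[de_idx], tissue = home, effect = effect)
    }

    # Regulator modules: latent activity in the home tissue; the regulator
    # loads on it in both conditions, its targets only under HFE, where they
    # also receive a mean shift.
    regulators <- tibble(regulator = character(), planted = logical(),
                         home_tissue = character())
    targets <- list()
    if (n_reg > 0) {
      planted_flag <- c(rep(TRUE, reg$n_planted), rep(FALSE, reg$n_null))
      regulators <- tibble(regulator = genes[reg_idx], planted = planted_flag,
                           home_tissue = reg$home_tissue)
      home_cols <- which(tiss_of == reg$home_tissue)
      hfe_cols <- which(tiss_of == reg$home_tissue & cond_of == "HFE")
      for (i in seq_len(reg$n_planted)) {
        r_row <- reg_idx[i]
        # A planted regulator must be expressed above the all-gene average,
        # otherwise the expression-floor rule would drop it before scoring:
        # pin its baseline gene effect instead of drawing it.
        signal[r_row, ] <- signal[r_row, ] - g_eff[r_row] + reg$regulator_boost
        activity <- rnorm(length(home_cols))
        names(activity) <- design$sample_id[home_cols]
        signal[r_row, home_cols] <- signal[r_row, home_cols] +
          reg$gamma * activity + reg$tissue_shift
        t_rows <- tar_idx[(i - 1) * reg$n_targets + seq_len(reg$n_targets)]
        act_hfe <- activity[design$sample_id[hfe_cols]]
        for (tr in t_rows) {
          signal[tr, hfe_cols] <- signal[tr, hfe_cols] +
            reg$beta * act_hfe + reg$target_shift
        }
        targets[[genes[r_row]]] <- genes[t_rows]
      }
    }

    signal <- signal + matrix(rnorm(G * S, 0, sqrt(config$sigma2_resid)), G, S)
    expr <- expression_set(2^signal, design, log2 = FALSE)

    list(
      expr = expr,
      truth = list(
        de_genes = de_genes,
        ts_genes = ts_genes,
        regulators = regulators,
        targets = targets,
        variance_components = c(
          gene = config$sigma2_gene,
          gene_tissue = config$sigma2_gene_tissue,
          gene_condition = config$sigma2_gene_condition,
          residual = config$sigma2_resid
        ),
        library_effects = tibble(library = design$library, effect = lib_eff),
        config = config
      )
    )
  })
}
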