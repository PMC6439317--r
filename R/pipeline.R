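#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage's tunable parameters with their routine defaults:
#' the 0.2 FPKM expression floor, log2 offset 1, five expression bins with
#' the 3.1 SD differential-expression threshold, the 1 SD
#' tissue-specificity rule, 1.96 SD thresholds for RIF key regulators and
#' differential connectivity, the 0.9 correlation magnitude threshold, and
#' 1000 permutations for region-overlap tests. Unknown arguments are
#' rejected.
#'
#' @param design Sample layout tibble ([fe_design()]).
#' @param sim A [sim_config()] describing the synthetic input (used when no
#'   `expr_file` is given).
#' @param expr_file,meta_file Optional TSV paths; when both are set the
#'   pipeline reads real data instead of simulating.
#' @param snp_file,sec_file Optional one-gene-per-line category lists.
#' @param regulator_file Optional candidate-regulator list; defaults to the
#'   simulation's candidates.
#' @param gmt_file Optional gene-set collection for the enrichment stage.
#' @param min_fpkm Expression floor (FPKM).
#' @param log_offset Pseudo-count for the log2 transform.
#' @param n_bins,de_z Binned-DE parameters.
#' @param ts_sd_multiplier Tissue-specificity threshold (population SDs).
#' @param rif_z Key-regulator threshold (SDs).
#' @param min_abs_r Network correlation magnitude threshold.
#' @param diffcon_z Differential-connectivity threshold (SDs).
#' @param n_perm Permutations for region-overlap testing.
#' @param mm_tol,mm_max_iter Mixed-model convergence controls.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = fe_design(),
                            sim = sim_config(n_genes = 2000,
                                             n_de_per_tissue = 10,
                                             n_ts_per_tissue = 10,
                                             regulators = list()),
                            expr_file = NULL, meta_file = NULL,
                            snp_file = NULL, sec_file = NULL,
                            regulator_file = NULL, gmt_file = NULL,
                            min_fpkm = 0.2, log_offset = 1,
                            n_bins = 5, de_z = 3.1,
                            ts_sd_multiplier = 1,
                            rif_z = 1.96,
                            min_abs_r = 0.9, diffcon_z = 1.96,
                            n_perm = 1000,
                            mm_tol = 1e-6, mm_max_iter = 500) {
  check_number(min_fpkm, "min_fpkm", 0)
  check_number(log_offset, "log_offset", .Machine$double.xmin)
  check_count(n_bins, "n_bins", 1)
  check_number(de_z, "de_z", 0)
  check_number(ts_sd_multiplier, "ts_sd_multiplier", 0)
  check_number(rif_z, "rif_z", 0)
  check_number(min_abs_r, "min_abs_r", 0)
  if (min_abs_r > 1) abort("`min_abs_r` must be <= 1.", class = "feconet_invalid_argument")
  check_number(diffcon_z, "diffcon_z", 0)
  check_count(n_perm, "n_perm", 1)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

write_stage <- function(out_dir, stage, writer) {
  marker <- file.path(out_dir, paste0(stage, ".partial"))
  file.create(marker)
  tryCatch({
    res <- writer()
    unlink(marker)
    res
  }, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "feconet_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline on synthetic or file-based input
#'
#' Chains simulate (or read) -> validate -> filter/log/mixed model/NME ->
#' binned DE per tissue -> tissue specificity -> external categories -> RIF
#' key regulators -> category merge -> PCIT network + statistics ->
#' condition networks + differential connectivity -> optional gene-set
#' enrichment, writing every stage's tables plus a machine-readable run
#' manifest (parameter values, seeds, row counts) into `out_dir`. Reruns
#' with the same config and seed reproduce all outputs; a failed stage
#' leaves a `<stage>.partial` marker next to whatever it wrote.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; per-stage seeds are derived deterministically
#'   from it.
#' @return Invisibly, a list with the main in-memory results (`expr`,
#'   `truth`, `fit`, `nme`, `de`, `annotation`, `rif`, `network`, `stats`,
#'   `diffcon`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "feconet",
                   version = as.character(utils::packageVersion("feconet")),
                   seed = seed,
                   parameters = list(
                     min_fpkm = config$min_fpkm, log_offset = config$log_offset,
                     n_bins = config$n_bins, de_z = config$de_z,
                     ts_sd_multiplier = config$ts_sd_multiplier,
                     rif_z = config$rif_z, min_abs_r = config$min_abs_r,
                     diffcon_z = config$diffcon_z, n_perm = config$n_perm))
  counts <- list()

  # -- input -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$expr_file) && !is.null(config$meta_file)) {
    expr <- write_stage(out_dir, "input", function() {
      issues <- validate_inputs(config$expr_file, config$meta_file)
      if (nrow(issues)) {
        abort(paste("Input validation failed:",
                    paste(issues$check, issues$detail, sep = ": ", collapse = "; ")),
              class = "feconet_validation_error")
      }
      read_expression(config$expr_file, config$meta_file)
    })
  } else {
    sim <- write_stage(out_dir, "simulate", function() {
      s <- simulate_expression(config$design, config$sim,
                               seed = stage_seed(seed, 1))
      write_expression(s$expr, file.path(out_dir, "expression.tsv"))
      write_sample_metadata(s$expr$samples, file.path(out_dir, "metadata.tsv"))
      readr::write_tsv(s$truth$de_genes, file.path(out_dir, "truth_de.tsv"))
      readr::write_tsv(s$truth$ts_genes, file.path(out_dir, "truth_ts.tsv"))
      readr::write_tsv(s$truth$regulators, file.path(out_dir, "truth_regulators.tsv"))
      s
    })
    expr <- sim$expr
    truth <- sim$truth
  }
  counts$samples <- ncol(expr$values)
  counts$genes_input <- nrow(expr$values)

  # -- normalization ---------------------------------------------------
  norm <- write_stage(out_dir, "normalize", function() {
    filtered <- filter_low_expression(expr, config$min_fpkm)
    fit <- fit_mixed_model(log_transform(filtered, config$log_offset),
                           tol = config$mm_tol, max_iter = config$mm_max_iter)
    nme <- compute_nme(fit, "gene_tissue", allow_unconverged = TRUE)
    readr::write_tsv(variance_proportions(fit), file.path(out_dir, "variance_components.tsv"))
    readr::write_tsv(as_tibble(nme, rownames = "gene"), file.path(out_dir, "nme.tsv"))
    list(filtered = filtered, fit = fit, nme = nme)
  })
  counts$genes_expressed <- nrow(norm$filtered$values)

  # -- DE and TS -------------------------------------------------------
  tissues <- sort(unique(expr$samples$tissue))
  de <- write_stage(out_dir, "de", function() {
    res <- purrr::map(tissues, function(t) {
      detect_de(norm$filtered, t, n_bins = config$n_bins,
                z_threshold = config$de_z)
    }) |> dplyr::bind_rows()
    readr::write_tsv(res, file.path(out_dir, "de.tsv"))
    res
  })
  counts$de_calls <- sum(de$call != "not_DE")
  ts <- write_stage(out_dir, "ts", function() {
    frag <- call_tissue_specific(norm$nme, config$ts_sd_multiplier)
    readr::write_tsv(frag, file.path(out_dir, "ts.tsv"))
    frag
  })
  counts$ts_genes <- nrow(ts)

  # -- external categories --------------------------------------------
  universe <- rownames(norm$filtered$values)
  snp <- if (!is.null(config$snp_file)) {
    load_category_list(config$snp_file, "SNP", universe)
  } else {
    tibble(gene = character(), category = character(), tissue = character())
  }
  sec <- if (!is.null(config$sec_file)) {
    load_category_list(config$sec_file, "SEC", universe)
  } else {
    tibble(gene = character(), category = character(), tissue = character())
  }

  # -- RIF -------------------------------------------------------------
  candidates <- if (!is.null(config$regulator_file)) {
    intersect(trimws(readLines(config$regulator_file)), universe)
  } else if (!is.null(truth) && nrow(truth$regulators)) {
    intersect(truth$regulators$regulator, universe)
  } else {
    character()
  }
  target_pool <- setdiff(
    unique(c(de_fragment(de)$gene, ts$gene, snp$gene, sec$gene)), candidates)
  rif <- write_stage(out_dir, "rif", function() {
    if (length(candidates) >= 2 && length(target_pool) >= 2) {
      scores <- compute_rif(norm$filtered, candidates, target_pool,
                            z_threshold = config$rif_z)
      readr::write_tsv(scores, file.path(out_dir, "rif.tsv"))
      scores
    } else {
      compute_rif(norm$filtered, character(), character())
    }
  })
  key_regs <- call_key_regulators(rif, config$rif_z)
  counts$key_regulators <- length(key_regs)

  # -- selection merge -------------------------------------------------
  merged <- write_stage(out_dir, "select", function() {
    m <- merge_categories(
      list(de_fragment(de), ts, snp, sec, category_fragment(key_regs, "REG")),
      norm$filtered, nme = norm$nme)
    readr::write_tsv(m$annotation, file.path(out_dir, "selection.tsv"))
    jsonlite::write_json(list(totals = m$totals, venn = m$venn),
                         file.path(out_dir, "venn.json"))
    m
  })
  counts$selected_genes <- nrow(merged$annotation)

  # -- network ---------------------------------------------------------
  netres <- write_stage(out_dir, "network", function() {
    sel <- merged$annotation$gene
    if (length(sel) < 3L) {
      net <- structure(list(edges = tibble(gene_a = character(),
                                           gene_b = character(), r = numeric()),
                            nodes = tibble(gene = character(), degree = integer()),
                            min_abs_r = config$min_abs_r),
                       class = "fe_network")
      readr::write_tsv(net$edges, file.path(out_dir, "edges.tsv"))
      return(list(net = net, stats = network_stats(net)))
    }
    corr <- correlation_matrix(norm$filtered, genes = sel)
    mask <- pcit(corr)
    net <- build_network(corr, mask, config$min_abs_r)
    stats <- network_stats(net, merged$annotation)
    readr::write_tsv(net$edges, file.path(out_dir, "edges.tsv"))
    readr::write_tsv(net$nodes, file.path(out_dir, "nodes.tsv"))
    export_cytoscape(net, file.path(out_dir, "cytoscape"), merged$annotation)
    list(net = net, stats = stats)
  })
  counts$network_nodes <- nrow(netres$net$nodes)
  counts$network_edges <- nrow(netres$net$edges)

  # -- differential connectivity --------------------------------------
  diffcon <- write_stage(out_dir, "diffcon", function() {
    sel <- merged$annotation$gene
    if (length(sel) < 3L) return(NULL)
    meta <- norm$filtered$samples
    build_cond <- function(cond) {
      s <- meta$sample_id[meta$condition == cond]
      corr <- correlation_matrix(norm$filtered, samples = s, genes = sel)
      build_network(corr, pcit(corr), config$min_abs_r)
    }
    dc <- differential_connectivity(build_cond("HFE"), build_cond("LFE"),
                                    z_threshold = config$diffcon_z,
                                    universe = sel)
    readr::write_tsv(dc, file.path(out_dir, "diffcon.tsv"))
    dc
  })
  counts$diff_connected <- if (is.null(diffcon)) 0L else sum(diffcon$is_significant)

  # -- enrichment ------------------------------------------------------
  enr <- NULL
  if (!is.null(config$gmt_file)) {
    enr <- write_stage(out_dir, "enrich", function() {
      sets <- read_gmt(config$gmt_file)
      query <- intersect(merged$annotation$gene, universe)
      e <- hypergeometric_enrichment(query, universe, sets)
      readr::write_tsv(e, file.path(out_dir, "enrichment.tsv"))
      e
    })
  }

  manifest$counts <- counts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(expr = expr, truth = truth, fit = norm$fit, nme = norm$nme,
                 de = de, ts = ts, rif = rif, key_regulators = key_regs,
                 annotation = merged$annotation, venn = merged$venn,
                 network = netres$net, stats = netres$stats,
                 diffcon = diffcon, enrichment = enr, manifest = manifest))
}
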