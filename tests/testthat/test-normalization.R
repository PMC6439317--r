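make_log_sim <- function(seed, n_genes = 50, ...) {
  sim <- simulate_expression(
    fe_design(tissues = paste0("t", 1:3), n_hfe = c(3, 3, 2), n_lfe = c(3, 2, 3)),
    sim_config(n_genes = n_genes, mu = 8, ...), seed = seed)
  log_transform(sim$expr)
}

test_that("expression floor drops strictly below the threshold", {
  m <- rbind(low = rep(0.19, 6), edge = rep(0.2, 6), high = rep(5, 6))
  colnames(m) <- tiny_meta()$sample_id[1:6]
  es <- tiny_expr(m, tiny_meta()[1:6, ])
  kept <- filter_low_expression(es, 0.2)
  expect_setequal(rownames(kept$values), c("edge", "high"))
  all_above <- filter_low_expression(es, 0.1)
  expect_identical(all_above$values, es$values)
  expect_error(filter_low_expression(
    tiny_expr(m * 0, tiny_meta()[1:6, ]), 0.2), class = "feconet_empty_input")
})

test_that("log transform maps 0 to 0 with offset 1 and round-trips", {
  m <- rbind(a = c(0, 3, 7, 1, 2, 4), b = c(1, 1, 1, 15, 0.5, 2))
  colnames(m) <- tiny_meta()$sample_id[1:6]
  es <- tiny_expr(m, tiny_meta()[1:6, ])
  lg <- log_transform(es, offset = 1)
  expect_equal(lg$values["a", 1], 0)
  expect_equal(lg$values["a", 2], 2)   # log2(3 + 1)
  back <- unlog_transform(lg)
  expect_equal(back$values, es$values, tolerance = 1e-12)
  m[1, 1] <- -1
  expect_error(tiny_expr(m, tiny_meta()[1:6, ]), class = "feconet_domain_error")
})

test_that("adding a constant moves only the intercept, not the random solutions", {
  le <- make_log_sim(11)
  f1 <- fit_mixed_model(le)
  le2 <- le
  le2$values <- le$values + 2.5
  f2 <- fit_mixed_model(le2, init = f1$variance_components)
  # both fits sit at (numerically) the same REML optimum; solutions agree to
  # the EM stopping precision
  expect_equal(f2$mu - f1$mu, 2.5, tolerance = 1e-6)
  expect_equal(f2$gene_solutions, f1$gene_solutions, tolerance = 1e-4)
  expect_equal(f2$gene_tissue_solutions, f1$gene_tissue_solutions, tolerance = 1e-4)
  expect_equal(f2$library_solutions$estimate, f1$library_solutions$estimate,
               tolerance = 1e-4)
})

test_that("random-effect solution sets are centered", {
  fit <- fit_mixed_model(make_log_sim(12))
  expect_lt(abs(mean(fit$gene_solutions)), 1e-6)
  expect_lt(max(abs(colMeans(fit$gene_tissue_solutions))), 0.02)
  expect_lt(max(abs(colMeans(fit$gene_condition_solutions))), 0.02)
  expect_lt(abs(mean(fit$library_solutions$estimate)), 1e-10)
})

test_that("REML components match an independent mixed-model solver", {
  skip_if_not_installed("lme4")
  sim <- simulate_expression(
    fe_design(tissues = paste0("t", 1:3), n_hfe = rep(3, 3), n_lfe = rep(3, 3)),
    sim_config(n_genes = 40, mu = 8, sigma2_gene_condition = 0.2), seed = 21)
  le <- log_transform(sim$expr, offset = 1e-9)
  fit <- fit_mixed_model(le, tol = 1e-10, max_iter = 20000)
  d <- tidy(le)
  lmm <- lme4::lmer(
    value ~ 0 + library + (1 | gene) + (1 | gene:tissue) + (1 | gene:condition),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(lmm))
  ref <- c(gene = vc$vcov[vc$grp == "gene"],
           gene_tissue = vc$vcov[vc$grp == "gene:tissue"],
           gene_condition = vc$vcov[vc$grp == "gene:condition"],
           residual = vc$vcov[vc$grp == "Residual"])
  expect_equal(fit$variance_components[names(ref)], ref, tolerance = 0.01)
})

test_that("a zero gene-by-condition component is recovered at the boundary", {
  sim <- simulate_expression(
    fe_design(tissues = paste0("t", 1:5), n_hfe = rep(2, 5), n_lfe = rep(2, 5)),
    sim_config(n_genes = 200, mu = 8, sigma2_gene_condition = 0), seed = 31)
  fit <- fit_mixed_model(log_transform(sim$expr))
  expect_lte(fit$variance_components[["gene_condition"]], 0.02)
})

test_that("fits are equivariant under gene relabeling", {
  le <- make_log_sim(13, n_genes = 30)
  f1 <- fit_mixed_model(le)
  perm <- rev(seq_len(nrow(le$values)))
  le2 <- expression_set(le$values[perm, ], le$samples, log2 = TRUE)
  f2 <- fit_mixed_model(le2)
  expect_equal(f2$variance_components, f1$variance_components, tolerance = 1e-8)
  expect_equal(f2$gene_solutions[names(f1$gene_solutions)], f1$gene_solutions,
               tolerance = 1e-8)
})

test_that("NME modes combine the random-effect solutions additively", {
  fit <- fit_mixed_model(make_log_sim(14))
  g <- compute_nme(fit, "gene", allow_unconverged = TRUE)
  gt <- compute_nme(fit, "gene_tissue", allow_unconverged = TRUE)
  gtc <- compute_nme(fit, "gene_tissue_condition", allow_unconverged = TRUE)
  expect_equal(gt - as.vector(g), fit$gene_tissue_solutions,
               tolerance = 1e-12, ignore_attr = TRUE)
  for (t in fit$tissues) {
    for (p in fit$conditions) {
      expect_equal(gtc[, paste(t, p, sep = "|")],
                   gt[, t] + fit$gene_condition_solutions[, p],
                   tolerance = 1e-12)
    }
  }
  expect_error(compute_nme(fit, "banana"))
})

test_that("all-zero random solutions give an all-zero NME", {
  fit <- fit_mixed_model(make_log_sim(15, n_genes = 20))
  fit$gene_solutions[] <- 0
  fit$gene_tissue_solutions[] <- 0
  fit$gene_condition_solutions[] <- 0
  expect_true(all(compute_nme(fit, "gene_tissue", allow_unconverged = TRUE) == 0))
})

test_that("variance proportions are shares of the total", {
  vp <- variance_proportions(setNames(c(1, 1, 1, 1),
                                      c("gene", "gene_tissue", "gene_condition", "residual")))
  expect_equal(vp$proportion, rep(0.25, 4))
  vp <- variance_proportions(setNames(c(3, 0, 0, 1),
                                      c("gene", "gene_tissue", "gene_condition", "residual")))
  expect_equal(vp$proportion, c(0.75, 0, 0, 0.25))
  expect_lt(abs(sum(vp$proportion) - 1), 1e-10)
  expect_error(variance_proportions(setNames(rep(0, 4), letters[1:4])),
               class = "feconet_degenerate_variance")
})

test_that("estimated variance shares track the planted shares", {
  props <- sapply(1:5, function(s) {
    sim <- simulate_expression(
      fe_design(tissues = paste0("t", 1:5), n_hfe = rep(2, 5), n_lfe = rep(2, 5)),
      sim_config(n_genes = 200, mu = 8, sigma2_gene = 1, sigma2_gene_tissue = 0.5,
                 sigma2_gene_condition = 0.2, sigma2_resid = 0.3), seed = s)
    variance_proportions(fit_mixed_model(log_transform(sim$expr)))$proportion
  })
  expect_true(all(abs(rowMeans(props) - c(0.5, 0.25, 0.1, 0.15)) <= 0.1))
})
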