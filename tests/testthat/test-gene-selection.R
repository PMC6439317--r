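# Build an expression set realizing prescribed per-gene HFE/LFE differences
# in one tissue (3 + 3 samples), so binned-DE arithmetic is fully controlled.
diff_expr <- function(diffs, base = 10) {
  n <- length(diffs)
  meta <- tiny_meta(tissues = "liver", n_per_cell = 3)
  m <- matrix(base, n, 6,
              dimnames = list(sprintf("g%03d", seq_len(n)), meta$sample_id))
  m[, meta$condition == "HFE"] <- m[, meta$condition == "HFE"] + diffs
  expression_set(m, meta)
}

test_that("a single outlier in a bin of 30 is called at any effect size", {
  for (d in c(2.7, 0.01, 150)) {
    de <- detect_de(diff_expr(c(rep(0, 29), d)), "liver", n_bins = 1)
    z_out <- de$z[de$diff > 0]
    expect_equal(z_out, 29 / 30 / sqrt(870 / 900 / 29), tolerance = 1e-10)
    expect_equal(z_out, 5.29468, tolerance = 1e-4)
    expect_equal(de$call[de$diff > 0], "up_in_HFE")
    expect_true(all(de$call[de$diff == 0] == "not_DE"))
  }
})

test_that("a single outlier in a bin of 10 cannot reach 3.1 SDs", {
  de <- detect_de(diff_expr(c(rep(0, 9), 5)), "liver", n_bins = 1)
  z_out <- de$z[de$diff > 0]
  expect_equal(z_out, 9 / sqrt(10), tolerance = 1e-10)  # (n-1)/sqrt(n) bound
  expect_lt(z_out, 3.1)
  expect_true(all(de$call == "not_DE"))
})

test_that("a zero-variance bin yields no DE calls", {
  de <- detect_de(diff_expr(rep(2, 12)), "liver", n_bins = 1)
  expect_equal(de$bin_sd, rep(0, 12))
  expect_true(all(de$call == "not_DE"))
})

test_that("calls are invariant to positive scaling and common shifts of the diffs", {
  diffs <- c(rep(0, 25), 1, -1, 4, -4, 9)
  base <- detect_de(diff_expr(diffs), "liver", n_bins = 1)
  es <- diff_expr(diffs)
  scaled <- expression_set(es$values * 7, es$samples)
  expect_equal(detect_de(scaled, "liver", n_bins = 1)$z, base$z, tolerance = 1e-9)
  shifted <- es
  shifted$values[, es$samples$condition == "HFE"] <-
    shifted$values[, es$samples$condition == "HFE"] + 3
  expect_equal(detect_de(shifted, "liver", n_bins = 1)$z, base$z, tolerance = 1e-9)
})

test_that("quantile bins are near-equal and deterministic", {
  es <- diff_expr(rep(0, 7))
  es$values <- es$values + seq_len(7)  # distinct tissue means
  de <- detect_de(es, "liver", n_bins = 5)
  sizes <- unname(table(de$bin))
  expect_true(all(sizes %in% c(1L, 2L)))  # floor(7/5) or ceiling(7/5)
  expect_equal(sum(sizes), 7L)
  expect_identical(de$bin, detect_de(es, "liver", n_bins = 5)$bin)
})

test_that("DE errors: unknown tissue and more bins than genes", {
  es <- diff_expr(rep(0, 4))
  expect_error(detect_de(es, "brain"), class = "feconet_unknown_tissue")
  expect_error(detect_de(es, "liver", n_bins = 5), class = "feconet_binning_error")
})

# NME population engineered to mean ~0, SD ~1: 96 filler genes at +/-1.
ts_nme <- function(candidate) {
  filler <- matrix(rep(c(1, -1), each = 48 * 5), 96, 5, byrow = FALSE)
  m <- rbind(matrix(candidate, 1, 5), filler)
  dimnames(m) <- list(c("cand", sprintf("f%02d", 1:96)), paste0("t", 1:5))
  m
}

test_that("tissue-specificity needs one high tissue and all others below zero", {
  frag <- call_tissue_specific(ts_nme(c(3, -0.5, -0.5, -0.5, -0.5)))
  expect_equal(frag$gene, "cand")
  expect_equal(frag$tissue, "t1")
  # strict rule: an other-tissue NME of exactly zero disqualifies
  frag0 <- call_tissue_specific(ts_nme(c(3, 0, -0.5, -0.5, -0.5)))
  expect_false("cand" %in% frag0$gene)
  # constant matrix: zero-SD guard
  const <- matrix(1, 10, 5, dimnames = list(paste0("g", 1:10), paste0("t", 1:5)))
  expect_equal(nrow(call_tissue_specific(const)), 0)
})

test_that("tissue-specificity is invariant to tissue column order", {
  m <- ts_nme(c(3, -0.5, -0.5, -0.5, -0.5))
  frag1 <- call_tissue_specific(m)
  frag2 <- call_tissue_specific(m[, c(3, 1, 5, 2, 4)])
  expect_equal(frag1$gene, frag2$gene)
  expect_equal(frag1$tissue, frag2$tissue)
})

test_that("category lists are matched to the universe with a warning count", {
  path <- withr::local_tempfile(lines = c("g1", "g2"))
  frag <- load_category_list(path, "SNP", universe = c("g1", "g2", "g3"))
  expect_equal(frag$gene, c("g1", "g2"))
  expect_equal(attr(frag, "n_unknown"), 0L)

  path2 <- withr::local_tempfile(lines = c("g1", "gX"))
  expect_warning(
    frag2 <- load_category_list(path2, "SEC", universe = c("g1", "g2")),
    "1 listed")
  expect_equal(frag2$gene, "g1")
  expect_equal(attr(frag2, "n_unknown"), 1L)

  path3 <- withr::local_tempfile(lines = character())
  frag3 <- load_category_list(path3, "SNP", universe = c("g1"))
  expect_equal(nrow(frag3), 0)
})

test_that("merging categories unions flags and tabulates the Venn regions", {
  m <- matrix(5, 3, 6, dimnames = list(c("g1", "g2", "g3"),
                                       tiny_meta()$sample_id[1:6]))
  es <- tiny_expr(m, tiny_meta()[1:6, ])
  frags <- list(category_fragment(c("g1", "g2"), "DE"),
                category_fragment(c("g2", "g3"), "TS"))
  out <- merge_categories(frags, es)
  expect_equal(nrow(out$annotation), 3)
  venn <- setNames(out$venn$n, out$venn$combo)
  expect_equal(unname(venn["DE"]), 1L)
  expect_equal(unname(venn["TS"]), 1L)
  expect_equal(unname(venn["DE&TS"]), 1L)
  expect_equal(out$totals$n[out$totals$category == "DE"], 2L)
})

test_that("duplicate records keep the highest grand mean; zero-mean genes drop", {
  m <- rbind(g1 = rep(c(5, 2), 3), g2 = rep(0, 6), g3 = rep(1, 6))
  colnames(m) <- tiny_meta()$sample_id[1:6]
  es <- tiny_expr(m, tiny_meta()[1:6, ])
  frag <- tibble::tibble(gene = c("g1", "g1", "g2", "g3"),
                         category = c("DE", "SEC", "DE", "DE"),
                         tissue = c("liver", NA, "liver", "liver"),
                         grand_mean = c(5, 2, 0, 1))
  out <- merge_categories(frag, es)
  ann <- out$annotation
  expect_equal(nrow(ann), 2)              # g2 removed (zero mean)
  g1 <- ann[ann$gene == "g1", ]
  expect_equal(g1$grand_mean, 5)          # highest record kept
  expect_true(g1$de && g1$sec)            # flags unioned across records
})
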