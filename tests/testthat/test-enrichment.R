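test_that("hypergeometric p-values match closed-form counts", {
  bg <- paste0("g", 1:20)
  sets <- list(full = paste0("g", 1:5))
  res <- hypergeometric_enrichment(paste0("g", 1:5), bg, sets)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)
  # zero overlap is the certain event
  res0 <- hypergeometric_enrichment(paste0("g", 6:10), bg,
                                    list(disjoint = paste0("g", 1:5)))
  expect_equal(res0$p_value, 1)
  expect_error(hypergeometric_enrichment("g1", character(), sets),
               class = "feconet_invalid_input")
  expect_error(hypergeometric_enrichment("zz", bg, sets),
               class = "feconet_invalid_input")
})

test_that("the reported adjustments equal a hand-applied step-up rule", {
  # independent step-up oracle: sort p, multiply by m/rank, enforce
  # monotonicity from the largest p downward
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(pmin(adj, 1))))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  expect_equal(bh_oracle(c(0.01, 0.02, 0.09)), c(0.03, 0.03, 0.09))
  bg <- paste0("g", 1:50)
  sets <- list(a = paste0("g", 1:10), b = paste0("g", 5:30), c = paste0("g", 40:50))
  res <- hypergeometric_enrichment(paste0("g", 1:10), bg, sets)
  expect_equal(res$p_adj, bh_oracle(res$p_value), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p_value))
  expect_true(all(res$p_adj <= 1))
  expect_true(!is.unsorted(res$p_value))
})

test_that("hypergeometric p is monotone decreasing in the overlap", {
  p <- sapply(0:5, function(k) {
    q <- c(paste0("g", 1:5)[seq_len(k)], paste0("x", 1:5)[seq_len(5 - k)])
    bg <- c(paste0("g", 1:5), paste0("x", 1:15))
    hypergeometric_enrichment(q, bg, list(s = paste0("g", 1:5)))$p_value
  })
  expect_true(all(diff(p) < 0))
})

test_that("overlap rates use half-up rounding on the printed scale", {
  expect_equal(overlap_rate(86, 136), 63)
  expect_equal(overlap_rate(114, 621), 18)
  expect_equal(overlap_rate(0, 10, 1), 0)
  expect_equal(overlap_rate(1, 8), 13)       # 12.5 rounds up, not to even
  expect_equal(overlap_rate(1, 8, 1), 12.5)
  expect_error(overlap_rate(5, 4), class = "feconet_invalid_input")
  expect_error(overlap_rate(1, 0), class = "feconet_invalid_argument")
})

test_that("saturating targets give observed = n_query and p = 1", {
  cs <- c(chr1 = 1e5, chr2 = 5e4)
  target <- tibble::tibble(chrom = names(cs), start = 0L, end = unname(cs))
  query <- simulate_regions(cs, n_query = 30, n_target = 5, seed = 1)$query
  pt <- region_overlap_permutation(query, target, cs, n_perm = 50, seed = 2)
  expect_equal(pt$observed, 30)
  expect_true(all(pt$null_counts == 30))
  expect_equal(pt$p_value, 1)
})

test_that("an empty query yields zero overlap and p = 1", {
  cs <- c(chr1 = 1e5)
  target <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L)
  query <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  pt <- region_overlap_permutation(query, target, cs, n_perm = 20, seed = 1)
  expect_equal(pt$observed, 0)
  expect_equal(pt$p_value, 1)
})

test_that("overlap counting matches brute force and IRanges", {
  cs <- c(chr1 = 2e5, chr2 = 1e5)
  for (s in 1:5) {
    rr <- simulate_regions(cs, n_query = 40, n_target = 25, planted_fraction = 0.3,
                           query_length = 500, target_length = 2000, seed = s)
    pt <- region_overlap_permutation(rr$query, rr$target, cs, n_perm = 1, seed = s)
    expect_equal(pt$observed, overlap_oracle(rr$query, rr$target))
    if (requireNamespace("IRanges", quietly = TRUE)) {
      hits <- sum(vapply(unique(rr$query$chrom), function(ch) {
        q <- rr$query[rr$query$chrom == ch, ]
        t <- rr$target[rr$target$chrom == ch, ]
        qr <- IRanges::IRanges(q$start + 1L, q$end)   # 1-based closed
        tr <- IRanges::IRanges(t$start + 1L, t$end)
        sum(IRanges::countOverlaps(qr, tr) > 0)
      }, 0L))
      expect_equal(pt$observed, hits)
    }
  }
})

test_that("a planted-enrichment fixture is detected with strong fold and p", {
  cs <- c(chr1 = 5e6, chr2 = 5e6)
  rr <- simulate_regions(cs, n_query = 200, n_target = 100,
                         planted_fraction = 0.8, query_length = 1000,
                         target_length = 5000, seed = 10)  # targets ~5% of genome
  pt <- region_overlap_permutation(rr$query, rr$target, cs, n_perm = 500, seed = 11)
  expect_lte(pt$p_value, 0.01)
  expect_gte(pt$fold, 5)
  # deterministic under a fixed seed
  pt2 <- region_overlap_permutation(rr$query, rr$target, cs, n_perm = 500, seed = 11)
  expect_identical(pt$null_counts, pt2$null_counts)
})

test_that("the permutation null mean matches the analytic uniform placement", {
  cs <- c(chr1 = 1e4)
  target <- tibble::tibble(chrom = "chr1", start = 4000L, end = 4500L)
  query <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L)
  pt <- region_overlap_permutation(query, target, cs, n_perm = 10000, seed = 5)
  L <- 200; Cn <- 1e4
  lo <- max(0, 4000 - L + 1); hi <- min(Cn - L, 4500 - 1)
  p_analytic <- (hi - lo + 1) / (Cn - L + 1)
  se <- sqrt(p_analytic * (1 - p_analytic) / 10000)
  expect_lt(abs(mean(pt$null_counts) - p_analytic), 3 * se)
  expect_gte(pt$p_value, 1 / 10001)
})
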