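cor_fixture <- function(values, log2 = TRUE) {
  n <- ncol(values)
  meta <- tibble::tibble(sample_id = paste0("s", seq_len(n)),
                         library = paste0("l", seq_len(n)),
                         tissue = "t1", condition = "HFE")
  colnames(values) <- meta$sample_id
  expression_set(values, meta, log2 = log2)
}

test_that("correlation matrix handles duplicates, negation and zero variance", {
  set.seed(1)
  x <- rnorm(10)
  m <- rbind(a = x, b = x, c = -x, d = rep(1, 10))
  es <- cor_fixture(m)
  expect_warning(r <- correlation_matrix(es), "zero-variance")
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["d", "a"], 0)
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_error(correlation_matrix(es, samples = paste0("s", 1:2)),
               class = "feconet_insufficient_data")
})

test_that("independent genes show only sampling-level correlation at n = 1000", {
  set.seed(2)
  m <- matrix(rnorm(50 * 1000), 50, dimnames = list(paste0("g", 1:50), NULL))
  r <- correlation_matrix(cor_fixture(m))
  expect_lt(max(abs(r[upper.tri(r)])), 0.15)
})

test_that("PCIT reproduces the hand-computed trio", {
  C <- matrix(c(1, 0.65, 0.9,
                0.65, 1, 0.9,
                0.9, 0.9, 1), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  # frozen partials: r_xy.z = -0.8421, r_xz.y = r_yz.x = 0.9509, eps = 1.1362
  r_xy.z <- (0.65 - 0.81) / (1 - 0.81)
  r_xz.y <- (0.9 - 0.65 * 0.9) / sqrt((1 - 0.65^2) * (1 - 0.81))
  expect_equal(r_xy.z, -0.8421053, tolerance = 1e-6)
  expect_equal(r_xz.y, 0.9509502, tolerance = 1e-6)
  eps <- (abs(r_xy.z) / 0.65 + 2 * (r_xz.y / 0.9)) / 3
  expect_equal(eps, 1.1362564, tolerance = 1e-6)
  expect_true(0.65 <= eps * 0.9)  # both flanks, so the x-y edge dies
  mask <- pcit(C)
  expect_false(mask["x", "y"])   # 0.65 <= eps * 0.9 on both flanks
  expect_true(mask["x", "z"])
  expect_true(mask["y", "z"])
  expect_identical(mask, pcit_oracle(C))
})

test_that("an all-zero correlation matrix keeps every pair", {
  C <- diag(4)
  dimnames(C) <- list(paste0("g", 1:4), paste0("g", 1:4))
  mask <- pcit(C)
  expect_true(all(mask[upper.tri(mask)]))
})

test_that("perfect off-diagonal correlations are clipped with a warning", {
  C <- matrix(c(1, 1, 0.5,
                1, 1, 0.5,
                0.5, 0.5, 1), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  expect_warning(mask <- pcit(C), "clipped")
  expect_true(is.logical(mask))
})

test_that("the PCIT mask is symmetric and equivariant under relabeling", {
  set.seed(3)
  m <- matrix(rnorm(12 * 15), 12, dimnames = list(paste0("g", 1:12), NULL))
  C <- correlation_matrix(cor_fixture(m))
  mask <- pcit(C)
  expect_identical(mask, t(mask))
  perm <- sample(12)
  mask_p <- pcit(C[perm, perm])
  expect_identical(mask_p, mask[perm, perm])
})

test_that("PCIT agrees with the exhaustive triple-loop oracle", {
  set.seed(4)
  for (i in 1:8) {
    m <- matrix(rnorm(8 * 12), 8, dimnames = list(paste0("g", 1:8), NULL))
    C <- correlation_matrix(cor_fixture(m))
    expect_identical(pcit(C), pcit_oracle(C))
  }
})

test_that("network edges require both significance and magnitude", {
  C <- matrix(c(1, 0.95, 0.89,
                0.95, 1, 0.2,
                0.89, 0.2, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- build_network(C, min_abs_r = 0.9)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$gene_a, "a")
  expect_equal(net$edges$gene_b, "b")
  # same pair masked non-significant -> absent
  mask <- matrix(TRUE, 3, 3, dimnames = dimnames(C)); diag(mask) <- FALSE
  mask["a", "b"] <- mask["b", "a"] <- FALSE
  expect_equal(nrow(build_network(C, mask, 0.9)$edges), 0)
})

test_that("the optional SD filter only ever removes edges", {
  set.seed(6)
  m <- matrix(rnorm(10 * 8), 10, dimnames = list(paste0("g", 1:10), NULL))
  C <- correlation_matrix(cor_fixture(m))
  plain <- build_network(C, min_abs_r = 0.2)
  filt <- build_network(C, min_abs_r = 0.2, sd_filter = 1)
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  expect_true(all(key(filt) %in% key(plain)))
  expect_lt(nrow(filt$edges), nrow(plain$edges))
  # every kept edge deviates >= 1 SD from the mean surviving correlation
  surv <- C[upper.tri(C)]
  expect_true(all(abs(filt$edges$r - mean(surv)) >= sd(surv) - 1e-12))
})

test_that("raising the magnitude threshold never adds edges", {
  set.seed(5)
  m <- matrix(rnorm(10 * 8), 10, dimnames = list(paste0("g", 1:10), NULL))
  C <- correlation_matrix(cor_fixture(m))
  lo <- build_network(C, min_abs_r = 0.3)
  hi <- build_network(C, min_abs_r = 0.6)
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("network statistics use the whole-connections rounding convention", {
  toy <- structure(list(
    edges = tibble::tibble(gene_a = c("a", "a", "a", "b", "b"),
                           gene_b = c("b", "c", "d", "c", "d"),
                           r = 0.95),
    nodes = tibble::tibble(gene = c("a", "b", "c", "d"),
                           degree = c(3L, 3L, 2L, 2L)),
    min_abs_r = 0.9), class = "fe_network")
  st <- network_stats(toy)
  expect_equal(st$summary$mean_connections, 1L)       # 5/4 rounds to 1
  expect_equal(st$summary$mean_connections_exact, 1.25)
  # at realistic scale: 91,932 edges over 1,317 genes -> 70 per gene
  big <- structure(list(
    edges = tibble::tibble(gene_a = "hub", gene_b = paste0("g", 1:91932), r = 0.9),
    nodes = tibble::tibble(gene = paste0("n", 1:1317), degree = 1L),
    min_abs_r = 0.9), class = "fe_network")
  expect_equal(network_stats(big)$summary$mean_connections, 70L)
})

test_that("category edge fractions count incident and within-category edges", {
  net <- structure(list(
    edges = tibble::tibble(gene_a = c("a", "b"), gene_b = c("b", "c"), r = 0.95),
    nodes = tibble::tibble(gene = c("a", "b", "c"), degree = c(1L, 2L, 1L)),
    min_abs_r = 0.9), class = "fe_network")
  ann <- tibble::tibble(gene = c("a", "b", "c"), de = c(FALSE, TRUE, FALSE),
                        snp = FALSE, ts = FALSE, sec = FALSE, reg = FALSE,
                        tissue_max = "liver")
  st <- network_stats(net, ann)
  de_row <- st$categories[st$categories$category == "DE", ]
  expect_equal(de_row$frac_edges_incident, 1)
  expect_equal(de_row$frac_edges_within, 0)
})

test_that("differential connectivity: identity, antisymmetry and the 2-gene case", {
  net <- function(genes, degrees) structure(list(
    edges = tibble::tibble(gene_a = character(), gene_b = character(),
                           r = numeric()),
    nodes = tibble::tibble(gene = genes, degree = as.integer(degrees)),
    min_abs_r = 0.9), class = "fe_network")
  h <- net(c("A", "B"), c(9, 1))
  same <- differential_connectivity(h, h)
  expect_true(all(same$diff == 0))
  expect_false(any(same$is_significant))

  l <- net(c("A", "B"), c(0, 5))
  dc <- differential_connectivity(h, l)
  expect_equal(dc$scaled_hfe[dc$gene == "A"], 1)
  expect_equal(dc$diff, c(1, 1 / 9 - 1), tolerance = 1e-12)
  expect_equal(abs(dc$z), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_false(any(dc$is_significant))

  swapped <- differential_connectivity(l, h)
  expect_equal(swapped$diff, -dc$diff)
  expect_equal(abs(swapped$z), abs(dc$z))
})

test_that("cytoscape export round-trips through the package reader", {
  C <- matrix(c(1, 0.95, 0.92,
                0.95, 1, 0.1,
                0.92, 0.1, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- build_network(C, min_abs_r = 0.9)
  dir <- withr::local_tempdir()
  export_cytoscape(net, dir)
  expect_equal(length(readLines(file.path(dir, "edges.sif.tsv"))), 3)  # header + 2
  back <- read_cytoscape(dir)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$min_abs_r, net$min_abs_r)

  empty <- structure(list(
    edges = tibble::tibble(gene_a = character(), gene_b = character(),
                           r = numeric()),
    nodes = tibble::tibble(gene = character(), degree = integer()),
    min_abs_r = 0.9), class = "fe_network")
  dir2 <- withr::local_tempdir()
  export_cytoscape(empty, dir2)
  back2 <- read_cytoscape(dir2)
  expect_equal(nrow(back2$edges), 0)
  expect_equal(nrow(back2$nodes), 0)
})
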