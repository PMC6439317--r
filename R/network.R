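#' Pairwise Pearson correlation over a sample subset
#'
#' @param expr An `expr_set`.
#' @param samples Optional sample IDs to use (default all); >= 3 required.
#' @param genes Optional gene IDs (default all).
#' @param log2 Correlate log2(value + 1) instead of the stored scale.
#' @return Symmetric genes x genes correlation matrix, diagonal 1.
#'   Zero-variance genes yield rows/columns of 0 (with a warning).
#' @export
correlation_matrix <- function(expr, samples = NULL, genes = NULL, log2 = FALSE) {
  stopifnot(inherits(expr, "expr_set"))
  samples <- samples %||% colnames(expr$values)
  genes <- genes %||% rownames(expr$values)
  if (length(samples) < 3L) {
    abort("Need >= 3 samples to correlate.", class = "feconet_insufficient_data")
  }
  m <- expr$values[genes, samples, drop = FALSE]
  if (log2) m <- log2(m + 1)
  sds <- apply(m, 1, sd)
  r <- suppressWarnings(cor(t(m)))
  if (any(sds == 0)) {
    warn(sprintf("%d zero-variance gene(s); their correlations set to 0.",
                 sum(sds == 0)))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' PCIT significance mask for a correlation matrix
#'
#' Partial Correlation and Information Theory edge filtering: for every
#' gene trio (x, y, z) the three first-order partial correlations
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}}
#' define a trio tolerance
#' \deqn{\varepsilon = \frac{1}{3}\left(\frac{|r_{xy.z}|}{|r_{xy}|} +
#'   \frac{|r_{xz.y}|}{|r_{xz}|} + \frac{|r_{yz.x}|}{|r_{yz}|}\right)}
#' and the edge (x, y) is flagged non-significant if some third gene z
#' satisfies \eqn{|r_{xy}| \le \varepsilon |r_{xz}|} and
#' \eqn{|r_{xy}| \le \varepsilon |r_{yz}|} with a strictly positive
#' comparator. Direct correlations below `zero_tol` in magnitude contribute
#' ratio 0 to the tolerance (0/0 guard) and are never eliminated themselves
#' (the magnitude threshold of [build_network()] removes them instead).
#' Off-diagonal correlations of magnitude 1 are clipped to `1 - 1e-12`
#' before the partials, with a warning.
#'
#' @param corr Symmetric correlation matrix (diagonal 1), e.g. from
#'   [correlation_matrix()].
#' @param zero_tol Magnitude below which a direct correlation is treated as
#'   zero inside tolerance ratios.
#' @return Symmetric logical matrix; `TRUE` marks pairs whose correlation
#'   survives PCIT (diagonal `FALSE`).
#' @export
pcit <- function(corr, zero_tol = 1e-8) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  n <- nrow(corr)
  if (n < 2L) abort("Need >= 2 genes.", class = "feconet_invalid_argument")
  if (max(abs(corr - t(corr))) > 1e-12) {
    abort("Correlation matrix must be symmetric.", class = "feconet_invalid_argument")
  }
  C <- (corr + t(corr)) / 2
  off <- abs(C) >= 1; diag(off) <- FALSE
  if (any(off)) {
    warn("Off-diagonal |r| = 1 clipped to 1 - 1e-12 before partial correlations.")
    C[off] <- sign(C[off]) * (1 - 1e-12)
  }
  diag(C) <- 1
  mask <- matrix(TRUE, n, n, dimnames = dimnames(corr))
  diag(mask) <- FALSE
  if (n == 2L) return(mask)

  absC <- abs(C)
  safe_div <- function(num, den) ifelse(den < zero_tol, 0, num / den)
  one_minus_C2 <- pmax(1 - C^2, 0)
  eliminated <- matrix(FALSE, n, n)
  for (z in seq_len(n)) {
    cz <- C[, z]
    dz <- sqrt(pmax(1 - cz^2, 0))
    # r_xy.z for all (x, y)
    p1 <- (C - tcrossprod(cz)) / tcrossprod(dz)
    a1 <- safe_div(abs(p1), absC)
    # r_xz.y: condition on y (columns)
    czx <- matrix(cz, n, n)            # cz[x] by row
    czy <- matrix(cz, n, n, byrow = TRUE)
    denom <- sqrt(one_minus_C2 * matrix(pmax(1 - cz^2, 0), n, n, byrow = TRUE))
    p2 <- (czx - C * czy) / denom
    a2 <- safe_div(abs(p2), abs(czx))
    # r_yz.x: condition on x (rows)
    denom <- sqrt(one_minus_C2 * matrix(pmax(1 - cz^2, 0), n, n))
    p3 <- (czy - C * czx) / denom
    a3 <- safe_div(abs(p3), abs(czy))
    eps <- (a1 + a2 + a3) / 3
    e1 <- eps * abs(czx)
    e2 <- eps * abs(czy)
    elim <- (absC <= e1) & (absC <= e2) & (pmax(e1, e2) > 0)
    elim[z, ] <- FALSE
    elim[, z] <- FALSE
    diag(elim) <- FALSE
    elim[!is.finite(eps)] <- FALSE
    eliminated <- eliminated | elim
  }
  mask & !(eliminated | t(eliminated))
}

#' Build a co-expression network from correlations and a significance mask
#'
#' Edges are the gene pairs that are PCIT-significant *and* have
#' `|r| >= min_abs_r`; nodes are the genes incident to at least one edge.
#'
#' @param corr Correlation matrix.
#' @param mask Logical significance mask conforming to `corr` (default: all
#'   pairs significant).
#' @param min_abs_r Correlation magnitude threshold (default 0.9).
#' @param sd_filter Optional secondary acceptance rule on the
#'   PCIT-surviving correlations: keep only edges whose correlation deviates
#'   at least this many SDs from the mean of all surviving pairwise
#'   correlations (e.g. 2). Disabled (`NULL`) by default because the
#'   magnitude threshold is the primary filter in routine use.
#' @return A `fe_network`: list with `edges` (tibble `gene_a`, `gene_b`,
#'   `r`; `gene_a < gene_b` lexicographically), `nodes` (tibble `gene`,
#'   `degree`) and `min_abs_r`.
#' @export
build_network <- function(corr, mask = NULL, min_abs_r = 0.9, sd_filter = NULL) {
  stopifnot(is.matrix(corr))
  check_number(min_abs_r, "min_abs_r", 0)
  n <- nrow(corr)
  mask <- mask %||% {
    m <- matrix(TRUE, n, n); diag(m) <- FALSE; m
  }
  stopifnot(identical(dim(mask), dim(corr)))
  keep <- mask & abs(corr) >= min_abs_r & upper.tri(corr)
  if (!is.null(sd_filter)) {
    surv <- corr[mask & upper.tri(corr)]
    if (length(surv) > 1L && sd(surv) > 0) {
      keep <- keep & (abs(corr - mean(surv)) >= sd_filter * sd(surv))
    }
  }
  idx <- which(keep, arr.ind = TRUE)
  g <- rownames(corr)
  a <- g[idx[, 1]]; b <- g[idx[, 2]]
  swap <- a > b
  edges <- tibble(
    gene_a = ifelse(swap, b, a),
    gene_b = ifelse(swap, a, b),
    r = corr[idx]
  ) |> dplyr::arrange(.data$gene_a, .data$gene_b)
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = sort(g)))
  nodes <- tibble(gene = names(deg), degree = as.integer(deg)) |>
    dplyr::filter(.data$degree > 0)
  structure(list(edges = edges, nodes = nodes, min_abs_r = min_abs_r),
            class = "fe_network")
}

#' @export
print.fe_network <- function(x, ...) {
  cat(sprintf("<fe_network> %d nodes, %d edges (|r| >= %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$min_abs_r))
  invisible(x)
}

#' @rdname build_network
#' @param x A `fe_network`.
#' @param ... Unused.
#' @export
tidy.fe_network <- function(x, ...) x$edges

#' @rdname build_network
#' @export
glance.fe_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         min_abs_r = x$min_abs_r,
         mean_connections = if (nrow(x$nodes)) nrow(x$edges) / nrow(x$nodes) else 0)
}

#' Summary statistics of a co-expression network
#'
#' Reports node/edge counts, mean connections per gene (edge count divided
#' by node count, reported both exactly and rounded to the nearest integer,
#' the convention used when quoting whole connections per gene), per-gene
#' degree, the fraction of edges incident to each annotation category and
#' between two genes of the same category, and the highest-degree nodes.
#'
#' @param net A `fe_network`.
#' @param annotation Optional annotation tibble from [merge_categories()]
#'   (logical flag columns `de`, `snp`, `ts`, `sec`, `reg`, plus
#'   `tissue_max`).
#' @param top_k How many hub genes to list.
#' @return List with `summary` (one-row tibble), `degree` (tibble),
#'   `categories` (tibble, when annotation given) and `top_hubs` (tibble).
#' @export
network_stats <- function(net, annotation = NULL, top_k = 10) {
  stopifnot(inherits(net, "fe_network"))
  n_nodes <- nrow(net$nodes); n_edges <- nrow(net$edges)
  mean_exact <- if (n_nodes > 0) n_edges / n_nodes else 0
  summary <- tibble(
    n_nodes = n_nodes, n_edges = n_edges,
    mean_connections = as.integer(round_half_up(mean_exact)),
    mean_connections_exact = mean_exact
  )
  degree <- net$nodes
  categories <- NULL
  if (!is.null(annotation) && n_edges > 0) {
    flags <- intersect(c("de", "snp", "ts", "sec", "reg"), names(annotation))
    categories <- purrr::map(flags, function(f) {
      in_cat <- annotation$gene[annotation[[f]]]
      ia <- net$edges$gene_a %in% in_cat
      ib <- net$edges$gene_b %in% in_cat
      nodes_in <- intersect(net$nodes$gene, in_cat)
      deg_in <- net$nodes$degree[net$nodes$gene %in% in_cat]
      tibble(
        category = toupper(f),
        n_nodes = length(nodes_in),
        n_edges_incident = sum(ia | ib),
        frac_edges_incident = sum(ia | ib) / n_edges,
        n_edges_within = sum(ia & ib),
        frac_edges_within = sum(ia & ib) / n_edges,
        mean_degree = if (length(deg_in)) mean(deg_in) else 0
      )
    }) |> dplyr::bind_rows()
  }
  top_hubs <- dplyr::arrange(net$nodes, dplyr::desc(.data$degree), .data$gene) |>
    head(top_k)
  if (!is.null(annotation)) {
    top_hubs <- dplyr::left_join(top_hubs,
                                 annotation[, c("gene", "tissue_max")],
                                 by = "gene")
  }
  list(summary = summary, degree = degree, categories = categories,
       top_hubs = top_hubs)
}

#' Differential connectivity between condition-specific networks
#'
#' Each gene's degree is scaled by the maximum degree within its network so
#' connectivity runs from 0 to 1, the LFE value is subtracted from the HFE
#' value, and the differences are standardized across genes; genes whose
#' standardized difference deviates at least `z_threshold` SDs from the
#' mean are significant. Genes missing from a network get degree 0; an
#' empty network contributes scaled degree 0 everywhere.
#'
#' @param net_hfe,net_lfe `fe_network`s built over the same gene universe.
#' @param z_threshold Significance threshold in SD units (default 1.96).
#' @param universe Optional gene universe (default: union of both node
#'   sets).
#' @return A `fe_diffcon` tibble: `gene`, `degree_hfe`, `degree_lfe`,
#'   `scaled_hfe`, `scaled_lfe`, `diff`, `z`, `is_significant`.
#' @export
differential_connectivity <- function(net_hfe, net_lfe, z_threshold = 1.96,
                                      universe = NULL) {
  stopifnot(inherits(net_hfe, "fe_network"), inherits(net_lfe, "fe_network"))
  check_number(z_threshold, "z_threshold", 0)
  universe <- universe %||% sort(union(net_hfe$nodes$gene, net_lfe$nodes$gene))
  deg <- function(net) {
    d <- setNames(rep(0L, length(universe)), universe)
    d[net$nodes$gene[net$nodes$gene %in% universe]] <-
      net$nodes$degree[net$nodes$gene %in% universe]
    d
  }
  dh <- deg(net_hfe); dl <- deg(net_lfe)
  sh <- if (max(dh) > 0) dh / max(dh) else dh * 0
  sl <- if (max(dl) > 0) dl / max(dl) else dl * 0
  diff <- sh - sl
  s <- sd(diff)
  z <- if (is.na(s) || s == 0) rep(0, length(diff)) else (diff - mean(diff)) / s
  out <- tibble(
    gene = universe,
    degree_hfe = unname(dh), degree_lfe = unname(dl),
    scaled_hfe = unname(sh), scaled_lfe = unname(sl),
    diff = unname(diff), z = unname(z),
    is_significant = abs(unname(z)) >= z_threshold
  )
  structure(out, class = c("fe_diffcon", class(out)), z_threshold = z_threshold)
}

#' Export / import a network for graph viewers
#'
#' Writes a SIF-style edge table (`gene_a`, `interaction`, `gene_b`, `r`)
#' and a node-attribute TSV (degree plus any annotation columns given:
#' category flags map to node shapes, `tissue_max` to color, NME to size in
#' viewers such as Cytoscape). `read_cytoscape()` restores the network
#' losslessly.
#'
#' @param net A `fe_network`.
#' @param dir Output directory (created if needed).
#' @param annotation Optional node-annotation tibble joined on `gene`.
#' @return `export_cytoscape()`: the directory, invisibly.
#' @export
export_cytoscape <- function(net, dir, annotation = NULL) {
  stopifnot(inherits(net, "fe_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort("Cannot create export directory.", class = "feconet_io_error")
  edges <- dplyr::mutate(net$edges, interaction = "co") |>
    dplyr::select("gene_a", "interaction", "gene_b", "r")
  readr::write_tsv(edges, file.path(dir, "edges.sif.tsv"))
  nodes <- net$nodes
  if (!is.null(annotation)) {
    nodes <- dplyr::left_join(nodes, annotation, by = "gene")
  }
  readr::write_tsv(nodes, file.path(dir, "nodes.tsv"))
  readr::write_tsv(tibble(key = "min_abs_r", value = net$min_abs_r),
                   file.path(dir, "provenance.tsv"))
  invisible(dir)
}

#' @rdname export_cytoscape
#' @export
read_cytoscape <- function(dir) {
  edges <- readr::read_tsv(file.path(dir, "edges.sif.tsv"), show_col_types = FALSE,
                           col_types = readr::cols(gene_a = "c", interaction = "c",
                                                   gene_b = "c", r = "d"))
  nodes <- readr::read_tsv(file.path(dir, "nodes.tsv"), show_col_types = FALSE)
  prov <- readr::read_tsv(file.path(dir, "provenance.tsv"), show_col_types = FALSE)
  structure(list(
    edges = dplyr::select(edges, "gene_a", "gene_b", "r"),
    nodes = dplyr::mutate(nodes[, c("gene", "degree")],
                          degree = as.integer(.data$degree)),
    min_abs_r = as.numeric(prov$value[prov$key == "min_abs_r"])
  ), class = "fe_network")
}
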