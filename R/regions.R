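# Genomic region sets are tibbles (chrom, start, end), 0-based half-open,
# carried alongside a named vector of chromosome sizes.

check_regions <- function(regions, chrom_sizes, name = "regions") {
  regions <- as_tibble(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions)) {
    if (any(regions$start < 0) || any(regions$start >= regions$end)) {
      abort(sprintf("`%s` must satisfy 0 <= start < end.", name),
            class = "feconet_invalid_argument")
    }
    unknown <- setdiff(regions$chrom, names(chrom_sizes))
    if (length(unknown)) {
      abort(sprintf("`%s` uses chromosomes absent from chrom_sizes: %s",
                    name, paste(unknown, collapse = ", ")),
            class = "feconet_invalid_argument")
    }
    if (any(regions$end > chrom_sizes[regions$chrom])) {
      abort(sprintf("`%s` has intervals beyond the chromosome end.", name),
            class = "feconet_placement_error")
    }
  }
  regions
}

# Merge overlapping/adjacent intervals per chromosome; returns a list of
# (starts, ends) sorted so that ends are increasing. Used by the overlap
# counter so membership queries are a single binary search.
merge_intervals <- function(regions) {
  split(regions[, c("start", "end")], regions$chrom) |>
    lapply(function(d) {
      o <- order(d$start)
      s <- d$start[o]; e <- d$end[o]
      keep_s <- s[1]; merged_s <- c(); merged_e <- c()
      cur_s <- s[1]; cur_e <- e[1]
      if (length(s) > 1) {
        for (i in 2:length(s)) {
          if (s[i] <= cur_e) {
            cur_e <- max(cur_e, e[i])
          } else {
            merged_s <- c(merged_s, cur_s); merged_e <- c(merged_e, cur_e)
            cur_s <- s[i]; cur_e <- e[i]
          }
        }
      }
      list(start = c(merged_s, cur_s), end = c(merged_e, cur_e))
    })
}

# Number of query intervals overlapping (>= 1 bp) any target interval.
# Overlap of [qs, qe) with merged target list: the first target with
# end > qs must have start < qe.
count_query_overlaps <- function(q_chrom, q_start, q_end, merged) {
  n <- length(q_start)
  if (n == 0L) return(0L)
  hits <- logical(n)
  for (ch in unique(q_chrom)) {
    m <- merged[[ch]]
    i <- which(q_chrom == ch)
    if (is.null(m)) next
    pos <- findInterval(q_start[i], m$end) + 1L  # first end > qs
    ok <- pos <= length(m$start)
    ok[ok] <- m$start[pos[ok]] < q_end[i][ok]
    hits[i] <- ok
  }
  sum(hits)
}

#' Simulate query/target genomic region sets with planted overlap
#'
#' Target intervals are placed uniformly at random (chromosome chosen
#' proportional to its length). A fraction `planted_fraction` of query
#' intervals is placed so that each overlaps a randomly chosen target by at
#' least one base; the remainder is placed uniformly. Fixture generator for
#' the overlap permutation test.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param n_query,n_target Interval counts.
#' @param planted_fraction Fraction of query intervals planted inside
#'   targets, in `[0, 1]`.
#' @param query_length,target_length Interval lengths (bp).
#' @param seed Integer seed.
#' @return List with tibbles `query` and `target` (`chrom`, `start`, `end`,
#'   `name`).
#' @export
simulate_regions <- function(chrom_sizes, n_query = 200, n_target = 100,
                             planted_fraction = 0, query_length = 1000L,
                             target_length = 5000L, seed = NULL) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  n_query <- check_count(n_query, "n_query", 0)
  n_target <- check_count(n_target, "n_target", 1)
  pf <- check_number(planted_fraction, "planted_fraction", 0)
  if (pf > 1) abort("`planted_fraction` must be <= 1.", class = "feconet_invalid_argument")
  if (max(query_length, target_length) > max(chrom_sizes)) {
    abort("Interval length exceeds every chromosome.",
          class = "feconet_placement_error")
  }
  place_uniform <- function(n, len) {
    ok <- chrom_sizes >= len
    sz <- chrom_sizes[ok]
    ch <- sample(names(sz), n, replace = TRUE, prob = sz)
    start <- floor(runif(n) * (sz[ch] - len + 1))
    tibble(chrom = ch, start = as.integer(start), end = as.integer(start + len))
  }
  with_seed(seed, {
    target <- place_uniform(n_target, target_length)
    target$name <- sprintf("target_%04d", seq_len(n_target))
    n_planted <- round(pf * n_query)
    planted <- NULL
    if (n_planted > 0) {
      pick <- sample.int(n_target, n_planted, replace = TRUE)
      ts <- target$start[pick]; te <- target$end[pick]
      ch <- target$chrom[pick]
      lo <- pmax(0L, ts - query_length + 1L)
      hi <- pmin(te - 1L, chrom_sizes[ch] - query_length)
      start <- floor(lo + runif(n_planted) * (hi - lo + 1))
      planted <- tibble(chrom = ch, start = as.integer(start),
                        end = as.integer(start + query_length))
    }
    free <- if (n_query - n_planted > 0) {
      place_uniform(n_query - n_planted, query_length)
    } else {
      NULL
    }
    query <- dplyr::bind_rows(planted, free)
    query$name <- sprintf("query_%04d", seq_len(nrow(query)))
    list(query = check_regions(query, chrom_sizes, "query"),
         target = check_regions(target, chrom_sizes, "target"))
  })
}

#' Permutation test of query/target region overlap
#'
#' Counts how many query intervals overlap (>= 1 bp) at least one target
#' interval, then rebuilds the null `n_perm` times by placing every query
#' interval uniformly at random on its own chromosome with its length
#' preserved. Reports the expected overlap under the null, the
#' observed/expected fold change, and the add-one empirical p-value
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param query,target Region tibbles (`chrom`, `start`, `end`).
#' @param chrom_sizes Named integer vector of chromosome lengths shared by
#'   both sets.
#' @param n_perm Number of permutations (>= 1; 1000 in routine use).
#' @param seed Integer seed; the report is deterministic under a fixed seed.
#' @return A `fe_permtest` list: `observed`, `expected`, `fold`, `p_value`,
#'   `n_perm`, `n_query`, `null_counts`.
#' @export
region_overlap_permutation <- function(query, target, chrom_sizes,
                                       n_perm = 1000, seed = NULL) {
  query <- check_regions(query, chrom_sizes, "query")
  target <- check_regions(target, chrom_sizes, "target")
  n_perm <- check_count(n_perm, "n_perm", 1)
  if (nrow(query) && any(query$end - query$start > chrom_sizes[query$chrom])) {
    abort("Query interval longer than its chromosome.",
          class = "feconet_placement_error")
  }
  merged <- if (nrow(target)) merge_intervals(target) else list()
  observed <- count_query_overlaps(query$chrom, query$start, query$end, merged)
  len <- query$end - query$start
  max_start <- chrom_sizes[query$chrom] - len
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      s <- floor(runif(nrow(query)) * (max_start + 1))
      count_query_overlaps(query$chrom, s, s + len, merged)
    }, 0L)
  })
  if (nrow(query) == 0L) {
    observed <- 0L
    null_counts <- rep(0L, n_perm)
  }
  expected <- mean(null_counts)
  structure(list(
    observed = observed,
    expected = expected,
    fold = if (expected > 0) observed / expected else ifelse(observed > 0, Inf, NA_real_),
    p_value = (1 + sum(null_counts >= observed)) / (n_perm + 1),
    n_perm = n_perm,
    n_query = nrow(query),
    null_counts = null_counts
  ), class = "fe_permtest")
}

#' @export
print.fe_permtest <- function(x, ...) {
  cat(sprintf(
    "<fe_permtest> observed %d / %d query regions overlap targets\n  expected by chance %.1f (fold %.2f), empirical p = %.4g (%d permutations)\n",
    x$observed, x$n_query, x$expected, x$fold, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname region_overlap_permutation
#' @param x A `fe_permtest`.
#' @param ... Unused.
#' @export
glance.fe_permtest <- function(x, ...) {
  tibble(observed = x$observed, expected = x$expected, fold = x$fold,
         p_value = x$p_value, n_perm = x$n_perm, n_query = x$n_query)
}
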