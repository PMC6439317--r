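# Shared fixtures and independent oracles.

# Small deterministic expression set: 2 tissues x (3 HFE + 3 LFE) samples.
tiny_meta <- function(tissues = c("liver", "muscle"), n_per_cell = 3) {
  grid <- expand.grid(rep = seq_len(n_per_cell),
                      condition = c("HFE", "LFE"),
                      tissue = tissues, stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%s_%d", substr(grid$tissue, 1, 3),
                        grid$condition, grid$rep),
    library = sprintf("lib%02d", seq_len(nrow(grid))),
    tissue = grid$tissue,
    condition = grid$condition
  )
}

tiny_expr <- function(values, meta = NULL, log2 = FALSE) {
  meta <- meta %||% tiny_meta()
  expression_set(values, meta, log2 = log2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal triple-loop PCIT oracle, written independently of the package
# implementation: scalar arithmetic straight from the trio formulas.
pcit_oracle <- function(C, zero_tol = 1e-8) {
  n <- nrow(C)
  C <- (C + t(C)) / 2
  off <- abs(C) >= 1
  diag(off) <- FALSE
  C[off] <- sign(C[off]) * (1 - 1e-12)
  diag(C) <- 1
  pc <- function(i, j, k) {
    (C[i, j] - C[i, k] * C[j, k]) /
      sqrt((1 - C[i, k]^2) * (1 - C[j, k]^2))
  }
  ratio <- function(p, d) if (abs(d) < zero_tol) 0 else abs(p) / abs(d)
  elim <- matrix(FALSE, n, n)
  for (x in seq_len(n - 1)) {
    for (y in seq((x + 1), n)) {
      for (z in seq_len(n)) {
        if (z == x || z == y) next
        eps <- (ratio(pc(x, y, z), C[x, y]) +
                  ratio(pc(x, z, y), C[x, z]) +
                  ratio(pc(y, z, x), C[y, z])) / 3
        e1 <- eps * abs(C[x, z])
        e2 <- eps * abs(C[y, z])
        if (abs(C[x, y]) <= e1 && abs(C[x, y]) <= e2 && max(e1, e2) > 0) {
          elim[x, y] <- TRUE
          elim[y, x] <- TRUE
          break
        }
      }
    }
  }
  mask <- !elim
  diag(mask) <- FALSE
  dimnames(mask) <- dimnames(C)
  mask
}

# Brute-force region overlap count: for each query, scan every target.
overlap_oracle <- function(query, target) {
  hits <- 0L
  for (i in seq_len(nrow(query))) {
    q <- query[i, ]
    any_hit <- FALSE
    for (j in seq_len(nrow(target))) {
      t <- target[j, ]
      if (q$chrom == t$chrom && q$start < t$end && t$start < q$end) {
        any_hit <- TRUE
        break
      }
    }
    hits <- hits + any_hit
  }
  hits
}
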