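# Readers and writers for the plain-text formats shared by all stages.
# Every writer round-trips through its reader without loss.

#' Write / read an expression matrix as TSV
#'
#' First column `gene`, remaining columns one per sample (header = sample
#' IDs).
#'
#' @param expr An `expr_set`.
#' @param path Output TSV path.
#' @return `write_expression()` returns `path` invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_set"))
  as_tibble(expr$values, rownames = "gene") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_expression
#' @param meta_path Path of the matching metadata TSV (see
#'   [write_sample_metadata()]).
#' @param log2 Whether the stored values are log2-scale.
#' @return `read_expression()` returns an `expr_set`.
#' @export
read_expression <- function(path, meta_path, log2 = FALSE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  expression_set(m, read_sample_metadata(meta_path), log2 = log2)
}

#' Write / read per-sample metadata as TSV
#'
#' Columns: `sample_id`, `library`, `tissue`, `condition`.
#'
#' @param samples Tibble of sample metadata.
#' @param path TSV path.
#' @export
write_sample_metadata <- function(samples, path) {
  readr::write_tsv(samples[, c("sample_id", "library", "tissue", "condition")], path)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is line-oriented: set name, description, then tab-separated member
#' gene IDs. Empty sets are rejected and set names must be unique.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: named list of character vectors with a
#'   `description` attribute per element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    abort(sprintf("GMT line(s) %s have no members.",
                  paste(which(bad), collapse = ", ")),
          class = "feconet_io_error")
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    abort("Duplicate gene-set names in GMT.", class = "feconet_io_error")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genomic region sets (BED, 0-based half-open)
#'
#' Only the first three BED columns (chrom, start, end) plus an optional
#' name column are used.
#'
#' @param path BED path.
#' @return `read_bed()`: tibble with columns `chrom`, `start`, `end` and,
#'   when present, `name`.
#' @export
read_bed <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(tab) < 3L) abort("BED needs >= 3 columns.", class = "feconet_io_error")
  out <- tibble(chrom = as.character(tab[[1]]),
                start = as.integer(tab[[2]]),
                end = as.integer(tab[[3]]))
  if (ncol(tab) >= 4L) out$name <- as.character(tab[[4]])
  if (any(out$start >= out$end)) {
    abort("BED intervals must satisfy start < end (0-based half-open).",
          class = "feconet_io_error")
  }
  out
}

#' @rdname read_bed
#' @param regions Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  readr::write_tsv(regions[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Read / write chromosome sizes (two-column TSV)
#'
#' @param path chrom.sizes path (columns: chrom, size).
#' @return `read_chrom_sizes()`: named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "size"),
                         show_col_types = FALSE)
  setNames(as.integer(tab$size), tab$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes Named integer vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  readr::write_tsv(tibble(chrom = names(sizes), size = unname(sizes)),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a one-gene-per-line category list
#'
#' Used for externally curated categories such as genes harboring
#' feed-efficiency-associated SNPs or genes encoding plasma-secreted
#' proteins. IDs absent from the expression universe are tolerated with a
#' warning that reports their count.
#'
#' @param path Text file, one gene ID per line (blank lines ignored).
#' @param category Category code, one of `"SNP"` or `"SEC"`.
#' @param universe Character vector of gene IDs present in the expression
#'   data.
#' @return Annotation fragment: tibble with columns `gene`, `category`,
#'   `tissue` (NA); attribute `n_unknown` records how many listed IDs were
#'   not in the universe.
#' @export
load_category_list <- function(path, category = c("SNP", "SEC"), universe) {
  category <- match.arg(category)
  ids <- unique(trimws(readLines(path)))
  ids <- ids[nzchar(ids)]
  unknown <- setdiff(ids, universe)
  if (length(unknown)) {
    warn(sprintf("%d listed gene ID(s) not in the expression universe.",
                 length(unknown)))
  }
  found <- intersect(ids, universe)
  out <- tibble(gene = found, category = rep(category, length(found)),
                tissue = rep(NA_character_, length(found)))
  attr(out, "n_unknown") <- length(unknown)
  out
}

#' Validate an expression/metadata file pair
#'
#' Checks gene/sample ID uniqueness, metadata completeness, value
#' non-negativity and finiteness, and agreement between matrix columns and
#' metadata rows, without constructing an `expr_set` (so all problems are
#' reported at once rather than failing at the first).
#'
#' @param expr_path Expression TSV path (as written by [write_expression()]).
#' @param meta_path Metadata TSV path.
#' @return Tibble report with columns `check`, `detail`; zero rows when the
#'   pair is well-formed.
#' @export
validate_inputs <- function(expr_path, meta_path) {
  tab <- readr::read_tsv(expr_path, show_col_types = FALSE)
  meta <- read_sample_metadata(meta_path)
  issues <- list()
  add <- function(check, detail) {
    issues[[length(issues) + 1L]] <<- tibble(check = check, detail = detail)
  }
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    add("duplicate_gene_id", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    add("duplicate_sample_id",
        paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  miss_meta <- setdiff(colnames(m), meta$sample_id)
  if (length(miss_meta)) add("sample_missing_from_metadata", paste(miss_meta, collapse = ", "))
  miss_expr <- setdiff(meta$sample_id, colnames(m))
  if (length(miss_expr)) add("sample_missing_from_matrix", paste(miss_expr, collapse = ", "))
  incomplete <- meta$sample_id[!stats::complete.cases(meta[, c("library", "tissue", "condition")])]
  if (length(incomplete)) add("incomplete_metadata", paste(incomplete, collapse = ", "))
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    add("negative_or_nonfinite_value",
        paste(sprintf("%s @ %s", genes[bad[, 1]], colnames(m)[bad[, 2]]),
              collapse = ", "))
  }
  if (length(issues)) dplyr::bind_rows(issues) else tibble(check = character(), detail = character())
}
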