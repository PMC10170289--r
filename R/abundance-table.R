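#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Internal representation: an abundance table is a tibble whose first column is
# `sample_id` (character) and whose remaining columns are numeric feature
# abundances. A `"abund_state"` attribute tracks the processing stage
# ("raw", "relative", "transformed"); validators check values, not the label.

abund_matrix <- function(data) {
  if (!is.data.frame(data) || !"sample_id" %in% names(data)) {
    abort("abundance table must be a data frame with a `sample_id` column")
  }
  feat <- setdiff(names(data), "sample_id")
  if (length(feat) == 0) abort("abundance table has no feature columns")
  m <- as.matrix(data[feat])
  if (!is.numeric(m)) abort("feature columns must all be numeric")
  rownames(m) <- data$sample_id
  m
}

as_abund_tbl <- function(m, state = NULL) {
  out <- dplyr::bind_cols(
    tibble(sample_id = rownames(m)),
    as_tibble(m, .name_repair = "minimal")
  )
  if (!is.null(state)) attr(out, "abund_state") <- state
  out
}

abund_state <- function(data) attr(data, "abund_state") %||% NA_character_

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %s identifier(s): %s", what,
                  paste(dup, collapse = ", ")))
  }
  invisible(ids)
}

check_nonnegative <- function(m) {
  bad <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(sprintf(
      "negative abundance %g at sample '%s', feature '%s'",
      m[i, j], rownames(m)[i], colnames(m)[j]))
  }
  invisible(m)
}

#' Read a sample-by-feature abundance table
#'
#' Reads a UTF-8 tab-separated abundance table with a header row. The first
#' column (or row, with `orientation = "features-as-rows"`) holds identifiers;
#' all remaining cells must be non-negative reals. Empty cells and `"NA"` are
#' read as missing and left as `NA` (impute with [min_impute()] before
#' downstream statistics); they are never silently zeroed.
#'
#' @param path Path to a tab-separated text file.
#' @param orientation `"samples-as-rows"` (canonical) or `"features-as-rows"`,
#'   in which case the table is transposed on read.
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per feature, rows and columns in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\ttaxA\ttaxB", "s1\t1\t2", "s2\t3\t4"), tf)
#' read_abundance_table(tf)
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples-as-rows",
                                                 "features-as-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tb <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE))
  pr <- readr::problems(tb)
  if (nrow(pr) > 0) {
    abort(sprintf(
      "malformed table %s: %d parsing problem(s); first at row %d: expected %s, got %s",
      path, nrow(pr), pr$row[1], pr$expected[1], pr$actual[1]))
  }
  if (ncol(tb) < 2) abort("table needs an identifier column plus >=1 feature column")
  names(tb)[1] <- if (orientation == "samples-as-rows") "sample_id" else "feature_id"
  ids <- as.character(tb[[1]])
  check_unique_ids(ids, if (orientation == "samples-as-rows") "sample" else "feature")
  check_unique_ids(names(tb)[-1], if (orientation == "samples-as-rows") "feature" else "sample")
  m <- as.matrix(tb[-1])
  rownames(m) <- ids
  if (orientation == "features-as-rows") m <- t(m)
  check_nonnegative(m)
  as_abund_tbl(m, state = "raw")
}

#' Write an abundance table to tab-separated text
#'
#' Values are written with shortest round-trip precision, so
#' `read_abundance_table(write_abundance_table(x, f))` reproduces `x` exactly.
#'
#' @param data Abundance tibble (`sample_id` + feature columns).
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_abundance_table <- function(data, path) {
  abund_matrix(data)  # validates shape
  readr::write_tsv(data, path, progress = FALSE)
  invisible(data)
}

#' Read a sample-metadata table
#'
#' @param path Tab-separated file with columns `sample_id` and `group`.
#' @return Tibble with character `sample_id` and `group`.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  if (!all(c("sample_id", "group") %in% names(md))) {
    abort("metadata must have columns `sample_id` and `group`")
  }
  check_unique_ids(md$sample_id, "sample")
  tibble(sample_id = md$sample_id, group = md$group)
}

# Join group labels onto samples, failing loudly on any unmatched sample.
match_groups <- function(sample_ids, metadata) {
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort("metadata must have columns `sample_id` and `group`")
  }
  check_unique_ids(metadata$sample_id, "metadata sample")
  miss <- setdiff(sample_ids, metadata$sample_id)
  if (length(miss) > 0) {
    abort(sprintf("sample(s) missing from metadata: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
  metadata$group[match(sample_ids, metadata$sample_id)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
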