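# Delimiter from an explicit argument or the file extension (.csv -> comma,
# anything else -> tab).
infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) {
    if (delim %in% c("tab", "\t")) return("\t")
    if (delim %in% c("comma", ",")) return(",")
    stop_zassoc("delim must be 'tab' or 'comma'", "zassoc_error_parse")
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a contingency table from delimited text
#'
#' Expects a rectangular layout: first row = column labels, first column =
#' row labels, numeric body, UTF-8. The delimiter is inferred from the
#' extension (`.csv` comma, otherwise tab) unless given explicitly.
#'
#' @param path file path.
#' @param delim `"tab"` or `"comma"`, overriding the extension-based guess.
#' @return A validated `contingency_table`.
#' @export
read_table_file <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop_zassoc(paste0("file not found: ", path), "zassoc_error_parse")
  }
  sep <- infer_delim(path, delim)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop_zassoc("table file needs a header row and at least one data row",
                "zassoc_error_parse")
  }
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1]]
  # Header may or may not carry a leading stub over the row-label column.
  body <- cells[-1]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    stop_zassoc(sprintf("ragged rows: widths %s",
                        paste(unique(widths), collapse = ", ")),
                "zassoc_error_parse")
  }
  n <- widths[1] - 1L
  if (n < 1L) {
    stop_zassoc("each data row needs a label and at least one value",
                "zassoc_error_parse")
  }
  col_labels <- if (length(header) == n + 1L) header[-1] else header
  if (length(col_labels) != n) {
    stop_zassoc(sprintf(
      "header has %d column labels but data rows have %d value columns",
      length(col_labels), n), "zassoc_error_parse")
  }
  row_labels <- vapply(body, `[[`, character(1), 1L)
  counts <- matrix(NA_real_, length(body), n)
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][-1]))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop_zassoc(sprintf(
        "non-numeric cell '%s' at row '%s', column '%s'",
        body[[i]][bad[1] + 1L], row_labels[i], col_labels[bad[1]]),
        "zassoc_error_parse")
    }
    counts[i, ] <- vals
  }
  make_table(counts, row_labels, col_labels)
}

#' Write a contingency table as delimited text
#'
#' Inverse of [read_table_file()]: header row of column labels (with an
#' empty leading stub), one row per table row with its label first.
#' Round-trips counts exactly via full-precision formatting.
#'
#' @param table a `contingency_table`.
#' @param path output file path (or `""` for stdout).
#' @param delim `"tab"` or `"comma"`, overriding the extension-based guess.
#' @return `path`, invisibly.
#' @export
write_table_file <- function(table, path, delim = NULL) {
  table <- as_contingency_table(table)
  sep <- infer_delim(path, delim)
  fmt <- function(x) {
    vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                                 trim = TRUE), character(1))
  }
  lines <- c(
    paste(c("", colnames(table)), collapse = sep),
    vapply(seq_len(nrow(table)), function(i) {
      paste(c(rownames(table)[i], fmt(unclass(table)[i, ])), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a grouping map from a two-column file
#'
#' Expects two delimited columns — category label, group label — with no
#' header. Coverage against a concrete table axis is checked later, when the
#' grouping is applied by [collapse()].
#'
#' @param path file path.
#' @param axis `"rows"` or `"cols"`: which table axis the grouping targets.
#' @param delim `"tab"` or `"comma"`, overriding the extension-based guess.
#' @return A [grouping_map()].
#' @export
read_grouping <- function(path, axis = c("rows", "cols"), delim = NULL) {
  axis <- match.arg(axis)
  if (!file.exists(path)) {
    stop_zassoc(paste0("file not found: ", path), "zassoc_error_parse")
  }
  sep <- infer_delim(path, delim)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop_zassoc("grouping file is empty", "zassoc_error_parse")
  }
  cells <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(cells) != 2L)) {
    bad <- which(lengths(cells) != 2L)[1]
    stop_zassoc(sprintf("grouping line %d does not have exactly 2 fields",
                        bad), "zassoc_error_parse")
  }
  cats <- vapply(cells, `[[`, character(1), 1L)
  grps <- vapply(cells, `[[`, character(1), 2L)
  if (anyDuplicated(cats)) {
    stop_zassoc(paste0("duplicate categories in grouping file: ",
                       paste(unique(cats[duplicated(cats)]), collapse = ", ")),
                "zassoc_error_coverage")
  }
  grouping_map(stats::setNames(grps, cats), axis)
}
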