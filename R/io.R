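## Tabular I/O. All tables are UTF-8, tab-separated, "." decimal separator,
## missing values spelled "NA". Probe order follows the annotation file and
## sample order follows the sample sheet everywhere downstream.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = "NA", comment.char = "#"),
    error = function(e) format_error("cannot parse %s: %s", path, conditionMessage(e)))
  df
}

#' Read a probe annotation table
#'
#' Expects a tab-separated file with header columns `probe_id`,
#' `gene_symbol`, `is_imprinted_gene`, `imprint_direction`.
#'
#' @param path file path.
#' @return A validated [probe_annotation()].
#' @export
read_annotation <- function(path) {
  probe_annotation(read_tsv_checked(path))
}

#' Write a probe annotation table
#'
#' @param annotation a `probe_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "probe_annotation"))
  write_tsv_plain(as.data.frame(annotation), path)
}

#' Read a sample sheet
#'
#' @param path tab-separated file with columns `sample_id`, `line_id`,
#'   `sample_class`, `replicate_index`.
#' @return A validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(read_tsv_checked(path))
}

#' Write a sample sheet
#'
#' @param samples a `sample_sheet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  stopifnot(inherits(samples, "sample_sheet"))
  write_tsv_plain(as.data.frame(samples), path)
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a probe x sample numeric matrix
#'
#' Two dialects are supported. `plain_tsv`: a header row of sample ids, a
#' first column of probe ids. `geo_series_matrix`: the GEO series-matrix
#' text export, where metadata lines start with `!`, the data block sits
#' between the `!series_matrix_table_begin` and `!series_matrix_table_end`
#' markers, and identifiers may be wrapped in double quotes (which are
#' stripped). Non-numeric cells become `NA`.
#'
#' @param path file path.
#' @param dialect `"plain_tsv"` (default) or `"geo_series_matrix"`.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_matrix <- function(path, dialect = c("plain_tsv", "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (dialect == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
      format_error("%s: series-matrix table markers missing or empty table", path)
    lines <- lines[(begin + 1):(end - 1)]
  } else {
    lines <- lines[!grepl("^#", lines)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) format_error("%s: empty table", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(cells)
  if (length(unique(width)) != 1)
    format_error("%s: ragged rows (widths %s)", path,
                 paste(unique(width), collapse = ", "))
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(cells[[1]])
  body <- cells[-1]
  probe_ids <- unquote(vapply(body, `[[`, character(1), 1))
  if (anyDuplicated(probe_ids))
    format_error("%s: duplicated probe id %s", path, probe_ids[duplicated(probe_ids)][1])
  vals <- vapply(body, function(r) suppressWarnings(as.numeric(unquote(r[-1]))),
                 numeric(length(header) - 1))
  m <- if (is.null(dim(vals))) matrix(vals, nrow = length(body), byrow = TRUE)
       else t(vals)
  dimnames(m) <- list(probe_ids, header[-1])
  m
}

#' Write a probe x sample matrix as plain TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @param id_column name for the probe-id column (first header cell).
#' @param digits significant digits used for formatting (default 10).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "probe_id", digits = 10) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(v) {
    out <- formatC(v, digits = digits, format = "g")
    out[is.na(v)] <- "NA"
    out
  }
  body <- apply(m, 1, fmt)
  body <- if (is.null(dim(body))) matrix(body, nrow = nrow(m)) else t(body)
  lines <- c(paste(c(id_column, colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## write_report ------------------------------------------------------------

report_header <- function(kind, params = list()) {
  pv <- as.character(utils::packageVersion("methimprint"))
  pstr <- if (length(params) == 0) "none" else
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(v) paste(format(v), collapse = ","), "")),
          collapse = "; ")
  c(sprintf("# methimprint %s report: %s", pv, kind),
    sprintf("# parameters: %s", pstr))
}

#' Write a deterministic tab-separated report for a pipeline product
#'
#' Every report starts with two `#` comment lines naming the pipeline
#' version, the product kind and the parameters recorded on the object,
#' followed by a header row and one data row per record. Writing the same
#' object twice produces byte-identical files.
#'
#' @param x a pipeline product (`imprinted_site_set`, `state_matrix`,
#'   `consistency_report`, `differential_table`, `fold_regulation_table`,
#'   `discordance_sweep` table, dendrogram, or plain data.frame).
#' @param path output file path.
#' @param ... passed to methods.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

write_report_frame <- function(df, path, kind, params = list()) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      v <- df[[j]]
      s <- formatC(v, digits = 10, format = "g")
      s[is.na(v)] <- "NA"
      df[[j]] <- s
    }
  }
  lines <- c(report_header(kind, params),
             paste(names(df), collapse = "\t"))
  if (nrow(df) > 0) {
    cells <- vapply(df, as.character, character(nrow(df)))
    cells <- if (is.null(dim(cells))) matrix(cells, nrow = nrow(df)) else cells
    cells[is.na(cells)] <- "NA"
    lines <- c(lines, apply(cells, 1, paste, collapse = "\t"))
  }
  ok <- tryCatch({ writeLines(lines, path, useBytes = TRUE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) mi_error("cannot write report to %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' @export
write_report.data.frame <- function(x, path, kind = "table", params = list(), ...) {
  write_report_frame(x, path, kind, params)
}

#' @export
write_report.default <- function(x, path, ...) {
  mi_error("no report writer for class %s", paste(class(x), collapse = "/"))
}
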