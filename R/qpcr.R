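## Delta-delta-Ct analysis for PCR arrays: housekeeping-normalized relative
## expression 2^-ddCt, reported as fold-regulation (down-changes as the
## negative reciprocal, e.g. fold-change 0.25 -> -4), plus the up/down
## scatter classification used to compare ES-cell groups plate-to-plate.

#' Construct and validate a Ct table
#'
#' One row per (gene, group, replicate plate) with the measured threshold
#' cycle. Not-detected wells carry `NA` and are imputed to a ceiling cycle
#' before averaging. Each group must include at least one housekeeping gene.
#'
#' @param df data.frame with columns `gene_symbol`, `group`, `replicate`,
#'   `ct` (cycles in `[0, 40]` or NA), `is_housekeeping` (logical).
#' @return The validated data.frame with class `ct_table`.
#' @export
ct_table <- function(df) {
  required <- c("gene_symbol", "group", "replicate", "ct", "is_housekeeping")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    format_error("ct table missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$gene_symbol <- as.character(df$gene_symbol)
  df$group <- as.character(df$group)
  df$replicate <- as.integer(df$replicate)
  df$ct <- as.numeric(df$ct)
  if (is.character(df$is_housekeeping))
    df$is_housekeeping <- parse_logical_column(df$is_housekeeping, "is_housekeeping")
  if (any(df$ct < 0 | df$ct > 40, na.rm = TRUE))
    format_error("ct values must lie in [0, 40] cycles (NA = not detected)")
  hk_flags <- tapply(df$is_housekeeping, df$gene_symbol, function(z) length(unique(z)))
  if (any(hk_flags > 1))
    format_error("gene %s has inconsistent is_housekeeping flags",
                 names(hk_flags)[hk_flags > 1][1])
  for (g in unique(df$group))
    if (!any(df$is_housekeeping[df$group == g]))
      format_error("group %s has no housekeeping gene", g)
  rownames(df) <- NULL
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a Ct table from TSV
#'
#' @param path tab-separated file with the [ct_table()] columns.
#' @return A validated `ct_table`.
#' @export
read_ct_table <- function(path) ct_table(read_tsv_checked(path))

#' Per-gene delta-Ct for one group
#'
#' `dCt(gene) = mean ct(gene) - mean ct(housekeeping genes)`, with means
#' over replicate plates. Not-detected wells are imputed to `nd_ceiling`
#' cycles before averaging; the housekeeping mean is the mean of the
#' housekeeping genes' per-gene mean Cts.
#'
#' @param ct a `ct_table`.
#' @param group group label present in the table.
#' @param nd_ceiling imputation cycle for not-detected wells (default 35).
#' @return Named numeric vector of delta-Ct values, one per gene.
#' @export
delta_ct <- function(ct, group, nd_ceiling = 35) {
  stopifnot(inherits(ct, "ct_table"))
  sub <- ct[ct$group == group, , drop = FALSE]
  if (nrow(sub) == 0) mi_error("group %s not present in ct table", group)
  hk <- sub[sub$is_housekeeping, , drop = FALSE]
  if (all(is.na(hk$ct)))
    mi_error("all housekeeping wells not detected in group %s", group)
  sub$ct[is.na(sub$ct)] <- nd_ceiling
  gene_mean <- tapply(sub$ct, sub$gene_symbol, mean)
  hk_mean <- mean(gene_mean[unique(sub$gene_symbol[sub$is_housekeeping])])
  out <- gene_mean - hk_mean
  out[order(names(out))]
}

#' Fold change and fold regulation from paired delta-Ct values
#'
#' `fold_change = 2^-(dCt_test - dCt_reference)`; fold regulation equals
#' the fold change when it is at least 1 and its negative reciprocal
#' otherwise, so a fold change of 0.25 reads as -4.
#'
#' @param dct_test,dct_reference delta-Ct values (vectors recycle).
#' @return List with numeric elements `fold_change` and `fold_regulation`.
#' @export
fold_regulation <- function(dct_test, dct_reference) {
  if (any(!is.finite(dct_test)) || any(!is.finite(dct_reference)))
    mi_error("delta-Ct inputs must be finite")
  fc <- 2^-(dct_test - dct_reference)
  fr <- ifelse(fc >= 1, fc, -1 / fc)
  list(fold_change = fc, fold_regulation = fr)
}

#' Full fold-regulation table between two groups
#'
#' Runs [delta_ct()] on both groups and [fold_regulation()] per shared
#' non-housekeeping gene.
#'
#' @param ct a `ct_table`.
#' @param test,reference group labels (test relative to reference).
#' @param nd_ceiling imputation ceiling passed to [delta_ct()].
#' @return data.frame of class `fold_regulation_table` with columns
#'   `gene_symbol`, `dct_test`, `dct_reference`, `ddct`, `fold_change`,
#'   `fold_regulation`; attributes record the group labels and ceiling.
#' @export
fold_regulation_table <- function(ct, test, reference, nd_ceiling = 35) {
  dt <- delta_ct(ct, test, nd_ceiling)
  dr <- delta_ct(ct, reference, nd_ceiling)
  hk <- unique(ct$gene_symbol[ct$is_housekeeping])
  genes <- setdiff(intersect(names(dt), names(dr)), hk)
  if (length(genes) == 0) mi_error("no shared non-housekeeping genes between groups")
  fr <- fold_regulation(dt[genes], dr[genes])
  out <- data.frame(gene_symbol = genes, dct_test = unname(dt[genes]),
                    dct_reference = unname(dr[genes]),
                    ddct = unname(dt[genes] - dr[genes]),
                    fold_change = unname(fr$fold_change),
                    fold_regulation = unname(fr$fold_regulation),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "test") <- test
  attr(out, "reference") <- reference
  attr(out, "nd_ceiling") <- nd_ceiling
  class(out) <- c("fold_regulation_table", "data.frame")
  out
}

#' Classify genes as up-, down- or unregulated
#'
#' `up` when fold regulation is at least `threshold`, `down` when at most
#' `-threshold`, otherwise `unchanged`. At threshold 1 no gene can be
#' unchanged since |fold regulation| >= 1 by construction.
#'
#' @param table a `fold_regulation_table`.
#' @param threshold fold-regulation magnitude cutoff, `>= 1` (default 4).
#' @return The table with a `direction` column appended; attribute
#'   `direction_counts` carries the summary.
#' @export
classify_scatter <- function(table, threshold = 4) {
  stopifnot(inherits(table, "fold_regulation_table"))
  if (threshold < 1) mi_error("threshold must be >= 1")
  dir <- ifelse(table$fold_regulation >= threshold, "up",
                ifelse(table$fold_regulation <= -threshold, "down", "unchanged"))
  out <- table
  out$direction <- dir
  attr(out, "threshold") <- threshold
  attr(out, "direction_counts") <- table(factor(dir, levels = c("up", "down", "unchanged")))
  out
}

#' @export
write_report.fold_regulation_table <- function(x, path, ...) {
  write_report_frame(as.data.frame(x), path, "fold_regulation_table",
                     list(test = attr(x, "test"), reference = attr(x, "reference"),
                          nd_ceiling = attr(x, "nd_ceiling"),
                          threshold = attr(x, "threshold")))
}
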