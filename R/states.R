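## Three-state methylation calling per cell line and the imprinted-locus
## filter: imprinted-gene probes are retained when at least (N_tissue - d)
## tissue samples call "partial" — the methylation pattern expected of an
## imprinted DMR in biparental tissue — where d is the allowed discordance.

#' Aggregate technical replicates to line-level beta values
#'
#' Per (probe, line), the arithmetic mean of the line's replicate beta
#' values; missing values are dropped, and the cell is missing only when
#' all replicates are missing. Aggregation precedes state calling so that
#' a single call is made per line.
#'
#' @param beta a `beta_matrix` (normally normalized).
#' @param samples a `sample_sheet`; control classes are excluded from the
#'   line grid.
#' @return Object of class `line_beta`: list with `beta` (probe x line
#'   matrix) and `line_class` (named character vector).
#' @export
aggregate_replicates <- function(beta, samples) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(samples, "sample_sheet"))
  keep <- samples[!(samples$sample_class %in% control_classes()), , drop = FALSE]
  keep <- keep[keep$sample_id %in% colnames(beta$beta), , drop = FALSE]
  lines <- unique(keep$line_id)
  if (length(lines) == 0) mi_error("no non-control samples present in beta matrix")
  agg <- vapply(lines, function(ln) {
    ids <- keep$sample_id[keep$line_id == ln]
    if (length(ids) == 0) mi_error("line %s has zero samples", ln)
    v <- rowMeans(beta$beta[, ids, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(nrow(beta$beta)))
  agg <- matrix(agg, nrow = nrow(beta$beta),
                dimnames = list(rownames(beta$beta), lines))
  line_class <- vapply(lines, function(ln)
    unique(keep$sample_class[keep$line_id == ln]), character(1))
  structure(list(beta = agg, line_class = line_class), class = "line_beta")
}

#' Call three-state methylation per (probe, line)
#'
#' beta <= `t_low` is called `unmethylated`, beta >= `t_high` `methylated`,
#' anything strictly between is `partial`; missing beta gives `failed`.
#' Boundary values go to the definitive states. The thresholds are not
#' published for the original analysis; (0.3, 0.7) is the conventional
#' symmetric default and must be recalibrated for real-data reproduction.
#'
#' @param line_beta a `line_beta` grid from [aggregate_replicates()].
#' @param t_low,t_high thresholds with `0 < t_low < t_high < 1`.
#' @return Object of class `state_matrix`: list with `states` (probe x line
#'   character matrix), `t_low`, `t_high`, `aggregation`, `line_class`.
#' @export
call_states <- function(line_beta, t_low = 0.3, t_high = 0.7) {
  stopifnot(inherits(line_beta, "line_beta"))
  if (!(t_low > 0 && t_high < 1 && t_low < t_high))
    mi_error("thresholds must satisfy 0 < t_low < t_high < 1")
  b <- line_beta$beta
  st <- matrix("partial", nrow = nrow(b), ncol = ncol(b), dimnames = dimnames(b))
  st[b <= t_low] <- "unmethylated"
  st[b >= t_high] <- "methylated"
  st[is.na(b)] <- "failed"
  structure(list(states = st, t_low = t_low, t_high = t_high,
                 aggregation = "replicate_mean", line_class = line_beta$line_class),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  tab <- table(factor(x$states, levels = methylation_states()))
  cat(sprintf("state_matrix: %d probes x %d lines (t_low=%g, t_high=%g); %s\n",
              nrow(x$states), ncol(x$states), x$t_low, x$t_high,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

tissue_lines_of <- function(states) {
  names(states$line_class)[states$line_class == "tissue"]
}

#' Filter imprinted-gene probes by tissue partial methylation
#'
#' Retains exactly the probes annotated to imprinted genes for which at
#' least `N_tissue - d` tissue lines are in state `partial`, where `d` is
#' the allowed discordance (d = 0 demands 5/5 agreement in the study
#' design, d = 1 allows 4/5). Failed tissue calls count as non-partial,
#' i.e. against retention.
#'
#' @param states a `state_matrix`.
#' @param annotation a `probe_annotation` over the same probes.
#' @param samples the `sample_sheet` (identifies tissue lines).
#' @param d allowed discordance, integer in `[0, N_tissue]`.
#' @return Object of class `imprinted_site_set`: list with `d`, `probe_ids`,
#'   `n_sites`, `n_genes`, `gene_symbol` (per retained probe), `states`
#'   (retained probe x line submatrix) and `n_tissue`.
#' @export
tissue_partial_filter <- function(states, annotation, samples, d = 0L) {
  stopifnot(inherits(states, "state_matrix"), inherits(annotation, "probe_annotation"),
            inherits(samples, "sample_sheet"))
  tl <- intersect(lines_in_group(samples, "tissue"), colnames(states$states))
  if (length(tl) == 0) mi_error("no tissue lines in state matrix")
  n_tissue <- length(tl)
  d <- as.integer(d)
  if (d < 0L || d > n_tissue) mi_error("d must lie in [0, %d]", n_tissue)
  common <- intersect(annotation$probe_id, rownames(states$states))
  ann <- annotation[match(common, annotation$probe_id), , drop = FALSE]
  imp_probes <- ann$probe_id[ann$is_imprinted_gene]
  n_partial <- rowSums(states$states[imp_probes, tl, drop = FALSE] == "partial")
  retained <- imp_probes[n_partial >= n_tissue - d]
  genes <- ann$gene_symbol[match(retained, ann$probe_id)]
  structure(list(d = d, probe_ids = retained, n_sites = length(retained),
                 n_genes = length(unique(genes)), gene_symbol = genes,
                 states = states$states[retained, , drop = FALSE],
                 n_tissue = n_tissue),
            class = "imprinted_site_set")
}

#' @export
print.imprinted_site_set <- function(x, ...) {
  cat(sprintf("imprinted_site_set: %d sites representing %d imprinted genes (d=%d, %d tissue lines)\n",
              x$n_sites, x$n_genes, x$d, x$n_tissue))
  invisible(x)
}

#' @export
write_report.imprinted_site_set <- function(x, path, ...) {
  df <- data.frame(probe_id = x$probe_ids, gene_symbol = x$gene_symbol,
                   stringsAsFactors = FALSE)
  if (x$n_sites > 0) df <- cbind(df, as.data.frame(x$states, stringsAsFactors = FALSE))
  write_report_frame(df, path, "imprinted_site_set",
                     list(d = x$d, n_sites = x$n_sites, n_genes = x$n_genes,
                          n_tissue = x$n_tissue))
}

#' Sweep the discordance parameter
#'
#' Runs [tissue_partial_filter()] for every `d` from 0 to `d_max` and
#' tabulates site and gene counts, which are non-decreasing in `d`.
#'
#' @inheritParams tissue_partial_filter
#' @param d_max largest discordance to evaluate (`<= N_tissue`).
#' @return data.frame with columns `d`, `n_sites`, `n_genes`.
#' @export
discordance_sweep <- function(states, annotation, samples, d_max) {
  rows <- lapply(0:d_max, function(d) {
    s <- tissue_partial_filter(states, annotation, samples, d)
    data.frame(d = d, n_sites = s$n_sites, n_genes = s$n_genes)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("discordance_sweep", "data.frame")
  out
}

#' Definitive-call fraction over a site set and line group
#'
#' Over all (retained site, group line) calls, returns
#' (unmethylated + methylated) / (unmethylated + methylated + partial).
#' Failed calls are excluded from numerator and denominator. A high value
#' in a uniparental group marks loss of the biparental partial pattern at
#' imprinted loci.
#'
#' @param states a `state_matrix`.
#' @param sites an `imprinted_site_set` (or character vector of probe ids).
#' @param samples the `sample_sheet`.
#' @param group sample-class token or vector of line ids.
#' @return Fraction in `[0, 1]`.
#' @export
definitive_fraction <- function(states, sites, samples, group) {
  stopifnot(inherits(states, "state_matrix"), inherits(samples, "sample_sheet"))
  probes <- if (inherits(sites, "imprinted_site_set")) sites$probe_ids else as.character(sites)
  if (length(probes) == 0) mi_error("site set is empty")
  lines <- intersect(lines_in_group(samples, group), colnames(states$states))
  if (length(lines) == 0) mi_error("group has no lines in the state matrix")
  calls <- states$states[probes, lines, drop = FALSE]
  n_def <- sum(calls %in% c("unmethylated", "methylated"))
  n_partial <- sum(calls == "partial")
  if (n_def + n_partial == 0)
    mi_error("definitive_fraction undefined: no non-failed calls in group")
  n_def / (n_def + n_partial)
}

#' Baseline-subtract a definitive fraction against tissue
#'
#' Normalizes a group's definitive fraction with the tissue lines as the
#' unmethylated baseline, read as simple subtraction:
#' `group_fraction - tissue_fraction`. May be negative.
#'
#' @param group_fraction,tissue_fraction fractions in `[0, 1]`.
#' @return Difference in `[-1, 1]`.
#' @export
baseline_normalize_fraction <- function(group_fraction, tissue_fraction) {
  stopifnot(group_fraction >= 0, group_fraction <= 1,
            tissue_fraction >= 0, tissue_fraction <= 1)
  group_fraction - tissue_fraction
}
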