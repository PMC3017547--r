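## Group-level analyses: uniparental-origin consistency of the parthenote
## lines, differential methylation of imprinted genes between ES-cell
## groups, correlation-based sample clustering, and the correlation vs
## discordance curves contrasting all sites with imprinted sites.

resolve_lines <- function(line_class, group) {
  if (length(group) == 1 && group %in% sample_classes()) {
    out <- names(line_class)[line_class == group]
  } else {
    out <- intersect(as.character(group), names(line_class))
    if (length(out) < length(group))
      mi_error("unknown line id(s): %s",
               paste(setdiff(group, names(line_class)), collapse = ", "))
  }
  if (length(out) == 0) mi_error("group resolves to zero lines")
  out
}

group_modal_state <- function(states, probes, lines) {
  vapply(probes, function(p) {
    calls <- states$states[p, lines]
    calls <- calls[calls != "failed"]
    if (length(calls) == 0) return("failed")
    tab <- table(calls)
    winners <- names(tab)[tab == max(tab)]
    # ties are non-definitive by construction: resolve to partial
    if (length(winners) > 1) "partial" else winners
  }, character(1))
}

#' Test consistency of parthenote calls with uniparental maternal origin
#'
#' For each retained imprinted site whose parthenote-group call is
#' definitive (methylated or unmethylated), checks the call against the
#' annotated parental imprint direction: a maternally methylated DMR in a
#' maternal-only (parthenote) genome should be fully methylated, a
#' paternally methylated DMR fully unmethylated. The group call is the
#' modal state over the group's non-failed line calls (ties resolve to
#' partial, i.e. non-definitive). Sites with unknown direction are excluded
#' and counted separately.
#'
#' @param sites an `imprinted_site_set`.
#' @param states the `state_matrix` the sites were derived from.
#' @param annotation a `probe_annotation` carrying imprint directions.
#' @param parthenote_group class token (default `"parthenote_esc"`) or line ids.
#' @return Object of class `consistency_report`: `n_definitive_sites`,
#'   `n_consistent`, `consistency_fraction`, `n_unknown_direction`, `detail`
#'   data.frame.
#' @export
maternal_consistency <- function(sites, states, annotation,
                                 parthenote_group = "parthenote_esc") {
  stopifnot(inherits(sites, "imprinted_site_set"), inherits(states, "state_matrix"),
            inherits(annotation, "probe_annotation"))
  if (sites$n_sites == 0) mi_error("site set is empty")
  lines <- resolve_lines(states$line_class, parthenote_group)
  dir <- annotation$imprint_direction[match(sites$probe_ids, annotation$probe_id)]
  if (all(dir == "unknown"))
    mi_error(paste("all imprint directions are unknown;",
                   "supply a direction-annotated probe table"))
  known <- dir != "unknown"
  obs <- group_modal_state(states, sites$probe_ids, lines)
  definitive <- known & obs %in% c("unmethylated", "methylated")
  consistent <- definitive &
    ((dir == "maternally_methylated" & obs == "methylated") |
     (dir == "paternally_methylated" & obs == "unmethylated"))
  detail <- data.frame(probe_id = sites$probe_ids, imprint_direction = dir,
                       parthenote_state = obs, definitive = definitive,
                       consistent = ifelse(definitive, consistent, NA),
                       stringsAsFactors = FALSE, row.names = NULL)
  n_def <- sum(definitive)
  structure(list(n_definitive_sites = n_def, n_consistent = sum(consistent),
                 consistency_fraction = if (n_def > 0) sum(consistent) / n_def else NA_real_,
                 n_unknown_direction = sum(!known), detail = detail),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency_report: %d/%d definitive sites consistent with uniparental origin (%.1f%%); %d direction-unknown sites excluded\n",
              x$n_consistent, x$n_definitive_sites,
              100 * x$consistency_fraction, x$n_unknown_direction))
  invisible(x)
}

#' @export
write_report.consistency_report <- function(x, path, ...) {
  write_report_frame(x$detail, path, "consistency_report",
                     list(n_definitive_sites = x$n_definitive_sites,
                          n_consistent = x$n_consistent,
                          consistency_fraction = x$consistency_fraction,
                          n_unknown_direction = x$n_unknown_direction))
}

#' Differential methylation of imprinted genes between two groups
#'
#' Compares line-level beta values of imprinted genes between two line
#' groups. Under `gene_mean` a gene is differential when the absolute
#' difference of its mean beta (over the gene's probes and the group's
#' lines) between groups reaches `delta`; under `any_probe`, when any
#' single probe's group-mean difference does. Genes whose probes are all
#' missing in either group are excluded (count reported).
#'
#' @param line_beta a `line_beta` grid.
#' @param annotation a `probe_annotation`.
#' @param group_a,group_b class tokens or line-id vectors.
#' @param delta effect-size threshold on the beta scale, in (0, 1).
#' @param aggregation `"gene_mean"` or `"any_probe"`.
#' @return Object of class `differential_table`: data.frame with columns
#'   `gene_symbol`, `difference` (a minus b, signed, per the aggregation
#'   rule), `is_differential`; attributes record `delta`, `aggregation` and
#'   `n_excluded`.
#' @export
differential_imprinted <- function(line_beta, annotation, group_a, group_b,
                                   delta = 0.2,
                                   aggregation = c("gene_mean", "any_probe")) {
  stopifnot(inherits(line_beta, "line_beta"), inherits(annotation, "probe_annotation"))
  aggregation <- match.arg(aggregation)
  if (!(delta > 0 && delta < 1)) mi_error("delta must lie in (0, 1)")
  la <- resolve_lines(line_beta$line_class, group_a)
  lb <- resolve_lines(line_beta$line_class, group_b)
  ann <- annotation[annotation$is_imprinted_gene, , drop = FALSE]
  genes <- unique(ann$gene_symbol)
  diff_of <- function(g) {
    probes <- intersect(ann$probe_id[ann$gene_symbol == g], rownames(line_beta$beta))
    if (length(probes) == 0) return(NA_real_)
    ma <- line_beta$beta[probes, la, drop = FALSE]
    mb <- line_beta$beta[probes, lb, drop = FALSE]
    if (aggregation == "gene_mean") {
      a <- mean(ma, na.rm = TRUE); b <- mean(mb, na.rm = TRUE)
      if (is.nan(a) || is.nan(b)) return(NA_real_)
      a - b
    } else {
      pa <- rowMeans(ma, na.rm = TRUE); pb <- rowMeans(mb, na.rm = TRUE)
      dd <- pa - pb
      dd <- dd[!is.na(dd)]
      if (length(dd) == 0) return(NA_real_)
      dd[which.max(abs(dd))]
    }
  }
  diffs <- vapply(genes, diff_of, numeric(1))
  excluded <- is.na(diffs)
  if (any(excluded))
    warning(sprintf("%d imprinted gene(s) excluded for missing data", sum(excluded)))
  out <- data.frame(gene_symbol = genes[!excluded], difference = diffs[!excluded],
                    is_differential = abs(diffs[!excluded]) >= delta,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "delta") <- delta
  attr(out, "aggregation") <- aggregation
  attr(out, "n_excluded") <- sum(excluded)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' @export
write_report.differential_table <- function(x, path, ...) {
  write_report_frame(as.data.frame(x), path, "differential_table",
                     list(delta = attr(x, "delta"), aggregation = attr(x, "aggregation"),
                          n_excluded = attr(x, "n_excluded")))
}

#' Pairwise sample correlation matrix over beta values
#'
#' Pearson (default) or Spearman correlation between sample columns,
#' computed per pair over probes non-missing in both samples; pairs with
#' fewer than two shared probes become missing cells with a warning.
#'
#' @param beta a `beta_matrix`.
#' @param probes optional probe-id subset (e.g. an imprinted site set).
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation_matrix <- function(beta, probes = NULL,
                                      method = c("pearson", "spearman")) {
  stopifnot(inherits(beta, "beta_matrix"))
  method <- match.arg(method)
  b <- beta$beta
  if (!is.null(probes)) {
    if (inherits(probes, "imprinted_site_set")) probes <- probes$probe_ids
    b <- b[intersect(probes, rownames(b)), , drop = FALSE]
  }
  if (ncol(b) < 2) mi_error("need at least two samples")
  cc <- suppressWarnings(stats::cor(b, use = "pairwise.complete.obs", method = method))
  shared <- crossprod(!is.na(b))
  if (any(shared < 2)) {
    warning(sprintf("%d sample pair(s) share fewer than 2 probes; cells set missing",
                    sum(shared[upper.tri(shared)] < 2)))
    cc[shared < 2] <- NA_real_
  }
  diag(cc) <- 1
  cc
}

#' Hierarchical clustering of samples from a correlation matrix
#'
#' Agglomerative clustering under distance `1 - correlation` with average
#' linkage. Samples are ordered lexicographically before clustering so that
#' ties in merge heights resolve deterministically.
#'
#' @param correlations complete symmetric correlation matrix.
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(correlations) {
  if (anyNA(correlations)) mi_error("correlation matrix has missing cells")
  ord <- order(colnames(correlations))
  d <- stats::as.dist(1 - correlations[ord, ord])
  stats::hclust(d, method = "average")
}

#' Correlation vs reference-group discordance curves
#'
#' For each allowed discordance `k` from 0 to `k_max`, selects the sites at
#' which at least `n - k` of the `n` reference-group lines share the same
#' state call, then correlates every non-control sample's beta values with
#' the reference-group mean beta over those sites. With
#' `site_mode = "imprinted_sites"` the site universe is restricted to
#' imprinted-gene probes, which drives uniparental and biparental ES lines
#' further apart than the all-sites universe does.
#'
#' @param beta a normalized `beta_matrix`.
#' @param states the matching `state_matrix`.
#' @param annotation a `probe_annotation`.
#' @param samples the `sample_sheet`.
#' @param reference_group class token (default `"parthenote_esc"`) or line ids.
#' @param k_max largest allowed discordance (default `n - 1`).
#' @param site_mode `"all_sites"` or `"imprinted_sites"`.
#' @param method correlation method, passed to [stats::cor()].
#' @return data.frame with columns `k`, `n_sites`, `sample_id`,
#'   `sample_class`, `correlation`.
#' @export
discordance_correlation_curve <- function(beta, states, annotation, samples,
                                          reference_group = "parthenote_esc",
                                          k_max = NULL,
                                          site_mode = c("all_sites", "imprinted_sites"),
                                          method = "pearson") {
  stopifnot(inherits(beta, "beta_matrix"), inherits(states, "state_matrix"),
            inherits(annotation, "probe_annotation"), inherits(samples, "sample_sheet"))
  site_mode <- match.arg(site_mode)
  ref_lines <- resolve_lines(states$line_class, reference_group)
  n_ref <- length(ref_lines)
  if (n_ref < 2) mi_error("reference group needs at least 2 lines")
  if (is.null(k_max)) k_max <- n_ref - 1L
  if (k_max > n_ref) mi_error("k_max cannot exceed the reference group size")
  universe <- rownames(states$states)
  if (site_mode == "imprinted_sites")
    universe <- intersect(universe,
                          annotation$probe_id[annotation$is_imprinted_gene])
  calls <- states$states[universe, ref_lines, drop = FALSE]
  max_agree <- apply(calls, 1, function(r) {
    r <- r[r != "failed"]
    if (length(r) == 0) 0L else max(table(r))
  })
  ref_samples <- intersect(samples_in_group(samples, reference_group), colnames(beta$beta))
  eval_samples <- samples[!(samples$sample_class %in% control_classes()) &
                            samples$sample_id %in% colnames(beta$beta), , drop = FALSE]
  rows <- list()
  for (k in 0:k_max) {
    sel <- universe[max_agree >= n_ref - k]
    if (length(sel) < 2) {
      warning(sprintf("k=%d: fewer than 2 sites selected; row set missing", k))
      rows[[length(rows) + 1]] <- data.frame(
        k = k, n_sites = length(sel), sample_id = eval_samples$sample_id,
        sample_class = eval_samples$sample_class, correlation = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    ref_mean <- rowMeans(beta$beta[sel, ref_samples, drop = FALSE], na.rm = TRUE)
    cors <- vapply(eval_samples$sample_id, function(s) {
      suppressWarnings(stats::cor(beta$beta[sel, s], ref_mean,
                                  use = "pairwise.complete.obs", method = method))
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      k = k, n_sites = length(sel), sample_id = eval_samples$sample_id,
      sample_class = eval_samples$sample_class, correlation = cors,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
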