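## End-to-end convenience wrapper: signals -> beta -> control-anchored
## normalization -> replicate aggregation -> state calls -> imprinted-site
## filter, with the headline summary statistics computed along the way.

#' Run the full imprinting pipeline on one dataset
#'
#' @param signals a [signal_matrix()].
#' @param samples the `sample_sheet`.
#' @param annotation the `probe_annotation`.
#' @param alpha beta-value pseudocount, see [compute_beta()].
#' @param eps_range control-anchor separation, see [build_control_profile()].
#' @param t_low,t_high state-calling thresholds, see [call_states()].
#' @param d tissue discordance for the imprinted-site filter.
#' @return List of class `imprinting_pipeline` with elements `beta_raw`,
#'   `profile`, `beta_norm`, `line_beta`, `states`, `sites`, `sweep`, and a
#'   `summary` list (site/gene counts, per-group definitive fractions and
#'   their tissue-baselined versions, consistency report).
#' @export
run_imprinting_pipeline <- function(signals, samples, annotation,
                                    alpha = 0, eps_range = 0.3,
                                    t_low = 0.3, t_high = 0.7, d = 0L) {
  beta_raw <- compute_beta(signals, alpha = alpha)
  profile <- build_control_profile(beta_raw, samples, eps_range = eps_range)
  beta_norm <- range_scale_normalize(beta_raw, profile)
  lb <- aggregate_replicates(beta_norm, samples)
  states <- call_states(lb, t_low = t_low, t_high = t_high)
  sites <- tissue_partial_filter(states, annotation, samples, d = d)
  n_tis <- sites$n_tissue
  sweep <- discordance_sweep(states, annotation, samples, d_max = n_tis)

  summary <- list(n_sites = sites$n_sites, n_genes = sites$n_genes, d = d)
  if (sites$n_sites > 0) {
    frac <- function(group) tryCatch(
      definitive_fraction(states, sites, samples, group), error = function(e) NA_real_)
    tf <- frac("tissue")
    pf <- frac("parthenote_esc")
    hf <- frac("conventional_esc")
    summary$definitive_fraction <- c(tissue = tf, parthenote_esc = pf,
                                     conventional_esc = hf)
    summary$baselined_fraction <- c(
      parthenote_esc = if (is.na(pf) || is.na(tf)) NA_real_
                       else baseline_normalize_fraction(pf, tf),
      conventional_esc = if (is.na(hf) || is.na(tf)) NA_real_
                         else baseline_normalize_fraction(hf, tf))
    summary$consistency <- tryCatch(
      maternal_consistency(sites, states, annotation), error = function(e) NULL)
  }
  structure(list(beta_raw = beta_raw, profile = profile, beta_norm = beta_norm,
                 line_beta = lb, states = states, sites = sites, sweep = sweep,
                 summary = summary,
                 params = list(alpha = alpha, eps_range = eps_range,
                               t_low = t_low, t_high = t_high, d = d)),
            class = "imprinting_pipeline")
}

#' @export
print.imprinting_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf("imprinting_pipeline: %d sites / %d imprinted genes at d=%d\n",
              s$n_sites, s$n_genes, s$d))
  if (!is.null(s$definitive_fraction)) {
    df <- s$definitive_fraction
    cat(sprintf("  definitive fraction: tissue=%.3f parthenote=%.3f conventional=%.3f\n",
                df["tissue"], df["parthenote_esc"], df["conventional_esc"]))
  }
  if (!is.null(s$consistency))
    cat(sprintf("  uniparental consistency: %d/%d definitive sites (%.0f%%)\n",
                s$consistency$n_consistent, s$consistency$n_definitive_sites,
                100 * s$consistency$consistency_fraction))
  invisible(x)
}

## state-matrix serialization (CLI round trip) -----------------------------

#' Write a state matrix as a report table
#'
#' @param x a `state_matrix`.
#' @param path output file path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_report.state_matrix <- function(x, path, ...) {
  df <- data.frame(probe_id = rownames(x$states),
                   as.data.frame(x$states, stringsAsFactors = FALSE),
                   check.names = FALSE)
  write_report_frame(df, path, "state_matrix",
                     list(t_low = x$t_low, t_high = x$t_high,
                          aggregation = x$aggregation))
}

#' Read a state matrix written by [write_report.state_matrix()]
#'
#' Line classes are recovered from the sample sheet; thresholds are parsed
#' back from the report's parameter header.
#'
#' @param path file path.
#' @param samples the `sample_sheet` the states were called from.
#' @return A `state_matrix`.
#' @export
read_state_matrix <- function(path, samples) {
  stopifnot(inherits(samples, "sample_sheet"))
  header <- readLines(path, n = 2)
  get_par <- function(name, default) {
    m <- regmatches(header[2], regexec(sprintf("%s=([0-9.eE+-]+)", name), header[2]))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else default
  }
  df <- read_tsv_checked(path)
  if (!"probe_id" %in% names(df)) format_error("%s: missing probe_id column", path)
  st <- as.matrix(df[setdiff(names(df), "probe_id")])
  rownames(st) <- df$probe_id
  bad <- setdiff(unique(as.vector(st)), methylation_states())
  if (length(bad) > 0) format_error("%s: unknown state token %s", path, bad[1])
  line_class <- vapply(colnames(st), function(ln) {
    cls <- unique(samples$sample_class[samples$line_id == ln])
    if (length(cls) != 1) format_error("line %s absent from sample sheet", ln)
    cls
  }, character(1))
  structure(list(states = st, t_low = get_par("t_low", 0.3),
                 t_high = get_par("t_high", 0.7),
                 aggregation = "replicate_mean", line_class = line_class),
            class = "state_matrix")
}
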