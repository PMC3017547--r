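## Beta-value computation and control-anchored range-scaling normalization.
## beta = methylated / (methylated + unmethylated); each probe is then
## linearly rescaled so that the fully-unmethylated control anchor maps to
## 0 and the fully-methylated anchor to 1, with the half-methylated control
## retained as an internal QC check.

#' Compute beta values from paired channel signals
#'
#' beta = methylated / (methylated + unmethylated + alpha) per cell. The
#' pseudocount `alpha` defaults to 0, matching the plain ratio; `alpha =
#' 100` is the common stabilizing convention for real intensities. Cells
#' whose denominator is 0 become missing.
#'
#' @param signals a [signal_matrix()].
#' @param alpha non-negative pseudocount added to the denominator.
#' @return A raw [beta_matrix()].
#' @export
compute_beta <- function(signals, alpha = 0) {
  stopifnot(inherits(signals, "signal_matrix"))
  if (alpha < 0) mi_error("alpha must be non-negative")
  denom <- signals$methylated + signals$unmethylated + alpha
  b <- signals$methylated / denom
  b[denom == 0] <- NA_real_
  beta_matrix(b, normalized = FALSE)
}

#' Build the per-probe control profile
#'
#' For each probe, averages the beta values of the fully-methylated,
#' fully-unmethylated and half-methylated control replicates into the three
#' normalization anchors. A probe is `usable` only when all anchors are
#' non-missing and the full/zero anchors are separated by at least
#' `eps_range` — otherwise the per-probe rescaling is ill-conditioned and
#' the probe is dropped from normalized output.
#'
#' @param beta a raw `beta_matrix`.
#' @param samples a `sample_sheet` containing all three control classes.
#' @param eps_range minimum required `beta_full - beta_zero` separation.
#' @return A data.frame of class `control_profile` with columns `probe_id`,
#'   `beta_full`, `beta_zero`, `beta_half`, `usable`.
#' @export
build_control_profile <- function(beta, samples, eps_range = 0.3) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(samples, "sample_sheet"))
  anchor_mean <- function(cls) {
    ids <- samples$sample_id[samples$sample_class == cls]
    if (length(ids) == 0) mi_error("control class %s has no samples", cls)
    ids <- intersect(ids, colnames(beta$beta))
    if (length(ids) == 0) mi_error("control class %s absent from beta matrix", cls)
    rowMeans(beta$beta[, ids, drop = FALSE], na.rm = TRUE)
  }
  full <- anchor_mean("control_full_methyl")
  zero <- anchor_mean("control_unmethyl")
  half <- anchor_mean("control_half_methyl")
  full[is.nan(full)] <- NA_real_
  zero[is.nan(zero)] <- NA_real_
  half[is.nan(half)] <- NA_real_
  usable <- !is.na(full) & !is.na(zero) & !is.na(half) & (full - zero >= eps_range)
  out <- data.frame(probe_id = rownames(beta$beta), beta_full = full,
                    beta_zero = zero, beta_half = half, usable = usable,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "eps_range") <- eps_range
  class(out) <- c("control_profile", "data.frame")
  out
}

#' Range-scale beta values against the control anchors
#'
#' Per usable probe, every beta value is mapped through
#' `(beta - beta_zero) / (beta_full - beta_zero)` and clipped into `[0, 1]`,
#' so the unmethylated control sits at 0 and the fully methylated control at
#' 1. Unusable probes become all-missing. Normalizing an already-normalized
#' matrix is rejected.
#'
#' @param beta a raw `beta_matrix`.
#' @param profile a `control_profile` over the same probe universe.
#' @return A normalized `beta_matrix` carrying the anchors used.
#' @export
range_scale_normalize <- function(beta, profile) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(profile, "control_profile"))
  if (beta$normalized) mi_error("beta matrix is already normalized")
  if (!identical(rownames(beta$beta), profile$probe_id))
    mi_error("control profile and beta matrix cover different probe universes")
  span <- profile$beta_full - profile$beta_zero
  scaled <- (beta$beta - profile$beta_zero) / span
  scaled[!profile$usable, ] <- NA_real_
  scaled <- pmin(pmax(scaled, 0), 1)
  beta_matrix(scaled, normalized = TRUE, anchors = profile)
}

#' QC probes against the half-methylated control
#'
#' After range scaling, the half-methylated control (an equal mix of fully
#' methylated and fully unmethylated DNA) should land near 0.5 at every
#' usable probe. Probes whose normalized half-control mean deviates from
#' 0.5 by more than `tol` are flagged.
#'
#' @param normalized a normalized `beta_matrix`.
#' @param profile the `control_profile` used for normalization.
#' @param samples the `sample_sheet`.
#' @param tol maximum tolerated absolute deviation from 0.5.
#' @return data.frame with columns `probe_id`, `half_control_mean`,
#'   `deviation`, `flagged`.
#' @export
control_qc <- function(normalized, profile, samples, tol = 0.05) {
  stopifnot(inherits(normalized, "beta_matrix"), inherits(samples, "sample_sheet"))
  if (!normalized$normalized) mi_error("control_qc expects a normalized beta matrix")
  ids <- intersect(samples$sample_id[samples$sample_class == "control_half_methyl"],
                   colnames(normalized$beta))
  if (length(ids) == 0) mi_error("no half-methylated control samples in matrix")
  half_mean <- rowMeans(normalized$beta[, ids, drop = FALSE], na.rm = TRUE)
  half_mean[is.nan(half_mean)] <- NA_real_
  dev <- abs(half_mean - 0.5)
  data.frame(probe_id = rownames(normalized$beta),
             half_control_mean = half_mean, deviation = dev,
             flagged = !is.na(dev) & dev > tol,
             stringsAsFactors = FALSE, row.names = NULL)
}
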