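#' @keywords internal
"_PACKAGE"

## Controlled vocabularies used throughout the pipeline.

#' Sample classes recognized by the pipeline
#'
#' The seven sample classes of the study design: the two ES-cell classes
#' under comparison, primary cell lines, somatic tissues, and the three
#' normalization control classes (fully methylated SssI-treated DNA,
#' fully unmethylated whole-genome-amplified DNA, and their 1:1 mixture).
#'
#' @return Character vector of valid `sample_class` tokens.
#' @export
sample_classes <- function() {
  c("conventional_esc", "parthenote_esc", "primary_cell", "tissue",
    "control_full_methyl", "control_unmethyl", "control_half_methyl")
}

#' Parental imprint directions
#'
#' @return Character vector of valid `imprint_direction` tokens.
#' @export
imprint_directions <- function() {
  c("maternally_methylated", "paternally_methylated", "unknown")
}

#' Three-state methylation call vocabulary (plus the failure flag)
#'
#' @return Character vector of valid state tokens.
#' @export
methylation_states <- function() {
  c("unmethylated", "partial", "methylated", "failed")
}

control_classes <- function() {
  c("control_full_methyl", "control_unmethyl", "control_half_methyl")
}

## condition helpers -------------------------------------------------------

format_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("methimprint_format_error", "methimprint_error")))
}

mi_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = "methimprint_error"))
}

## ProbeAnnotation ---------------------------------------------------------

#' Construct and validate a probe annotation table
#'
#' A probe annotation maps each array probe to a gene symbol, flags whether
#' that gene is an imprinted gene, and (for imprinted genes) records the
#' parental direction of the imprint: `maternally_methylated` means the
#' maternal allele carries the methylation mark, so a uniparental maternal
#' (parthenote) genome is expected fully methylated there;
#' `paternally_methylated` implies the opposite.
#'
#' @param df data.frame with columns `probe_id`, `gene_symbol`,
#'   `is_imprinted_gene` (logical), `imprint_direction`.
#' @return The validated data.frame with class `probe_annotation`.
#' @export
probe_annotation <- function(df) {
  required <- c("probe_id", "gene_symbol", "is_imprinted_gene", "imprint_direction")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    format_error("annotation is missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$probe_id <- as.character(df$probe_id)
  df$gene_symbol <- as.character(df$gene_symbol)
  df$imprint_direction <- as.character(df$imprint_direction)
  if (is.character(df$is_imprinted_gene))
    df$is_imprinted_gene <- parse_logical_column(df$is_imprinted_gene, "is_imprinted_gene")
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0)
    format_error("duplicated probe_id in annotation: %s", dup[1])
  bad <- setdiff(unique(df$imprint_direction), imprint_directions())
  if (length(bad) > 0)
    format_error("unknown imprint_direction token: %s", bad[1])
  if (any(df$imprint_direction != "unknown" & !df$is_imprinted_gene))
    format_error("imprint_direction may be non-unknown only for imprinted-gene probes")
  rownames(df) <- NULL
  class(df) <- c("probe_annotation", "data.frame")
  df
}

parse_logical_column <- function(x, name) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "true", "1")] <- TRUE
  out[x %in% c("FALSE", "false", "0")] <- FALSE
  if (anyNA(out))
    format_error("column %s contains non-boolean token: %s", name,
                 x[which(is.na(out))[1]])
  out
}

#' Number of distinct imprinted genes in an annotation
#'
#' @param annotation a `probe_annotation`.
#' @return Integer count of distinct imprinted gene symbols.
#' @export
n_imprinted_genes <- function(annotation) {
  stopifnot(inherits(annotation, "probe_annotation"))
  length(unique(annotation$gene_symbol[annotation$is_imprinted_gene]))
}

#' @export
print.probe_annotation <- function(x, ...) {
  cat(sprintf("probe_annotation: %d probes, %d imprinted genes (%d imprinted-gene probes)\n",
              nrow(x), n_imprinted_genes(x), sum(x$is_imprinted_gene)))
  NextMethod()
}

## SampleSheet -------------------------------------------------------------

#' Construct and validate a sample sheet
#'
#' Assigns each assayed sample (one array) to a cell line, a sample class
#' and a technical-replicate index. Technical replicates of a line share
#' `line_id` and differ in `replicate_index`.
#'
#' @param df data.frame with columns `sample_id`, `line_id`, `sample_class`,
#'   `replicate_index`.
#' @return The validated data.frame with class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "line_id", "sample_class", "replicate_index")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    format_error("sample sheet is missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$sample_id <- as.character(df$sample_id)
  df$line_id <- as.character(df$line_id)
  df$sample_class <- as.character(df$sample_class)
  df$replicate_index <- as.integer(df$replicate_index)
  if (anyDuplicated(df$sample_id))
    format_error("duplicated sample_id: %s", df$sample_id[duplicated(df$sample_id)][1])
  key <- paste(df$line_id, df$replicate_index)
  if (anyDuplicated(key))
    format_error("duplicated (line_id, replicate_index): %s", key[duplicated(key)][1])
  bad <- setdiff(unique(df$sample_class), sample_classes())
  if (length(bad) > 0)
    format_error("unknown sample_class token: %s", bad[1])
  if (any(df$replicate_index < 1L))
    format_error("replicate_index must be a positive integer")
  cls_per_line <- tapply(df$sample_class, df$line_id, function(z) length(unique(z)))
  if (any(cls_per_line > 1))
    format_error("line %s is assigned more than one sample_class",
                 names(cls_per_line)[cls_per_line > 1][1])
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Samples belonging to a class or an explicit line set
#'
#' Resolves a group specification to sample ids. A group may be a sample
#' class token (e.g. `"tissue"`) or a character vector of line ids.
#'
#' @param samples a `sample_sheet`.
#' @param group sample-class token or vector of line ids.
#' @return Character vector of sample ids.
#' @export
samples_in_group <- function(samples, group) {
  stopifnot(inherits(samples, "sample_sheet"))
  if (length(group) == 1 && group %in% sample_classes()) {
    ids <- samples$sample_id[samples$sample_class == group]
  } else {
    unknown <- setdiff(group, samples$line_id)
    if (length(unknown) > 0)
      mi_error("unknown line id(s) in group: %s", paste(unknown, collapse = ", "))
    ids <- samples$sample_id[samples$line_id %in% group]
  }
  ids
}

#' Line ids belonging to a class or explicit line set
#'
#' @inheritParams samples_in_group
#' @return Character vector of line ids.
#' @export
lines_in_group <- function(samples, group) {
  unique(samples$line_id[samples$sample_id %in% samples_in_group(samples, group)])
}

#' @export
print.sample_sheet <- function(x, ...) {
  tab <- table(x$sample_class)
  cat(sprintf("sample_sheet: %d samples, %d lines (%s)\n", nrow(x),
              length(unique(x$line_id)),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  NextMethod()
}

## SignalMatrix ------------------------------------------------------------

#' Construct a paired methylated/unmethylated signal matrix
#'
#' @param methylated,unmethylated numeric probe x sample matrices with
#'   identical dimnames; fluorescence intensities, non-negative.
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(methylated, unmethylated) {
  methylated <- as.matrix(methylated)
  unmethylated <- as.matrix(unmethylated)
  if (!identical(dimnames(methylated), dimnames(unmethylated)) ||
      !identical(dim(methylated), dim(unmethylated)))
    mi_error("methylated and unmethylated grids must share probe and sample labels")
  if (is.null(rownames(methylated)) || is.null(colnames(methylated)))
    mi_error("signal matrices must carry probe rownames and sample colnames")
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    mi_error("signal intensities must be non-negative")
  structure(list(methylated = methylated, unmethylated = unmethylated),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d probes x %d samples\n",
              nrow(x$methylated), ncol(x$methylated)))
  invisible(x)
}

## BetaMatrix --------------------------------------------------------------

#' Construct a beta-value matrix
#'
#' beta is the fraction of methylated signal at a probe,
#' methylated / (methylated + unmethylated), in `[0, 1]`.
#'
#' @param beta numeric probe x sample matrix in `[0, 1]` (NA allowed).
#' @param normalized logical; TRUE only after control-anchored range scaling.
#' @param anchors optional `control_profile` recording the per-probe
#'   normalization anchors used.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, normalized = FALSE, anchors = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    mi_error("beta matrix must carry probe rownames and sample colnames")
  rng <- suppressWarnings(range(beta, na.rm = TRUE))  # all-NA allowed
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    mi_error("beta values must lie in [0, 1]")
  structure(list(beta = beta, normalized = isTRUE(normalized), anchors = anchors),
            class = "beta_matrix")
}

#' Subset a beta matrix to selected samples
#'
#' @param beta a `beta_matrix`.
#' @param sample_ids sample ids to keep (e.g. from [samples_in_group()]);
#'   alternatively a `sample_sheet`, in which case the control classes are
#'   dropped and all other samples kept.
#' @return A `beta_matrix` over the selected columns, flags preserved.
#' @export
subset_samples <- function(beta, sample_ids) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (inherits(sample_ids, "sample_sheet")) {
    ss <- sample_ids
    sample_ids <- ss$sample_id[!(ss$sample_class %in% control_classes())]
  }
  keep <- intersect(colnames(beta$beta), sample_ids)
  if (length(keep) == 0) mi_error("no matching samples to keep")
  beta_matrix(beta$beta[, keep, drop = FALSE],
              normalized = beta$normalized, anchors = beta$anchors)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%s; %d missing cells)\n",
              nrow(x$beta), ncol(x$beta),
              if (x$normalized) "control-normalized" else "raw",
              sum(is.na(x$beta))))
  invisible(x)
}
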