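## Synthetic-data generator emulating the study design: biparental samples
## (tissues, primary cells, conventional ES lines) are partially methylated
## at true imprinted DMRs, the uniparental parthenote lines are driven to
## the maternal-allele state, and triplicate fully/un/half-methylated
## control samples anchor the per-probe normalization.

#' Simulation configuration
#'
#' Defaults encode the study design scaled down: 27,578 CpG sites reduced to
#' 5,000; 47 imprinted genes of which only a fraction of probes are true
#' imprinted DMRs (CpG sites assigned to imprinted genes are not necessarily
#' imprinted); 5 tissue samples; 2 conventional and 5 parthenote ES lines
#' with 2 technical replicates each; each control class run in triplicate.
#'
#' @param n_probes total probes on the synthetic array.
#' @param n_imprinted_genes number of imprinted genes (study annotation: 47).
#' @param probes_per_imprinted_gene probes assigned to each imprinted gene.
#' @param dmr_fraction fraction of imprinted-gene probes that are true DMRs.
#' @param maternal_direction_fraction fraction of imprinted genes whose DMR
#'   is maternally methylated.
#' @param n_tissue,n_primary_lines number of tissue and primary-cell samples
#'   (one array each).
#' @param n_hesc_lines,n_phesc_lines number of conventional and parthenote
#'   ES lines.
#' @param replicates_per_line technical replicates per ES line.
#' @param control_triplicates replicates per control class.
#' @param kappa beta-distribution concentration of the measurement noise
#'   around the true methylation mean; `Inf` yields noise-free data.
#' @param total_intensity_log_mean,total_intensity_log_sd log-normal
#'   parameters of the per-cell total fluorescence intensity (arbitrary units).
#' @param background_low,background_high,background_weight_low two-component
#'   background methylation mixture for non-DMR probes: low/high component
#'   means and the weight of the low component.
#' @param esc_hyper_fraction,esc_hyper_shift fraction of non-imprinted
#'   background probes at which both ES-cell classes are hypermethylated
#'   relative to tissue and primary cells, and the size of that upward
#'   shift on the beta scale. This plants the ES-vs-somatic methylation
#'   structure that makes ES samples cluster together; set the fraction to
#'   0 for a generator in which all non-DMR probes share one mean across
#'   classes.
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 5000L,
                       n_imprinted_genes = 47L,
                       probes_per_imprinted_gene = 4L,
                       dmr_fraction = 0.5,
                       maternal_direction_fraction = 0.6,
                       n_tissue = 5L,
                       n_hesc_lines = 2L,
                       n_phesc_lines = 5L,
                       n_primary_lines = 4L,
                       replicates_per_line = 2L,
                       control_triplicates = 3L,
                       kappa = 50,
                       total_intensity_log_mean = 9.0,
                       total_intensity_log_sd = 0.4,
                       background_low = 0.1,
                       background_high = 0.9,
                       background_weight_low = 0.7,
                       esc_hyper_fraction = 0.1,
                       esc_hyper_shift = 0.3,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_imprinted_genes = as.integer(n_imprinted_genes),
              probes_per_imprinted_gene = as.integer(probes_per_imprinted_gene),
              dmr_fraction = dmr_fraction,
              maternal_direction_fraction = maternal_direction_fraction,
              n_tissue = as.integer(n_tissue),
              n_hesc_lines = as.integer(n_hesc_lines),
              n_phesc_lines = as.integer(n_phesc_lines),
              n_primary_lines = as.integer(n_primary_lines),
              replicates_per_line = as.integer(replicates_per_line),
              control_triplicates = as.integer(control_triplicates),
              kappa = kappa,
              total_intensity_log_mean = total_intensity_log_mean,
              total_intensity_log_sd = total_intensity_log_sd,
              background_low = background_low,
              background_high = background_high,
              background_weight_low = background_weight_low,
              esc_hyper_fraction = esc_hyper_fraction,
              esc_hyper_shift = esc_hyper_shift,
              seed = as.integer(seed))
  with(cfg, {
    if (n_probes < 1L || n_imprinted_genes < 1L || probes_per_imprinted_gene < 1L)
      mi_error("probe/gene counts must be positive")
    if (n_imprinted_genes * probes_per_imprinted_gene > n_probes)
      mi_error("n_imprinted_genes x probes_per_imprinted_gene exceeds n_probes")
    if (dmr_fraction < 0 || dmr_fraction > 1)
      mi_error("dmr_fraction must lie in [0, 1]")
    if (maternal_direction_fraction < 0 || maternal_direction_fraction > 1)
      mi_error("maternal_direction_fraction must lie in [0, 1]")
    if (!(kappa > 0)) mi_error("kappa must be positive (or Inf)")
    if (n_tissue < 1L || control_triplicates < 1L)
      mi_error("n_tissue and control_triplicates must be >= 1")
    if (background_low < 0 || background_high > 1 || background_low > background_high)
      mi_error("background mixture means must satisfy 0 <= low <= high <= 1")
    if (background_weight_low < 0 || background_weight_low > 1)
      mi_error("background_weight_low must lie in [0, 1]")
    if (esc_hyper_fraction < 0 || esc_hyper_fraction > 1 || esc_hyper_shift < 0)
      mi_error("esc_hyper_fraction must lie in [0, 1] and esc_hyper_shift be >= 0")
  })
  class(cfg) <- "sim_config"
  cfg
}

sim_sample_sheet <- function(cfg) {
  rows <- list()
  add <- function(line, class, rep) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sprintf("%s_r%d", line, rep), line_id = line,
      sample_class = class, replicate_index = rep, stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_tissue)) add(sprintf("TIS%02d", i), "tissue", 1L)
  for (i in seq_len(cfg$n_primary_lines)) add(sprintf("PRM%02d", i), "primary_cell", 1L)
  for (i in seq_len(cfg$n_hesc_lines))
    for (r in seq_len(cfg$replicates_per_line)) add(sprintf("ES%02d", i), "conventional_esc", r)
  for (i in seq_len(cfg$n_phesc_lines))
    for (r in seq_len(cfg$replicates_per_line)) add(sprintf("PE%02d", i), "parthenote_esc", r)
  for (r in seq_len(cfg$control_triplicates)) add("CTRL_FULL", "control_full_methyl", r)
  for (r in seq_len(cfg$control_triplicates)) add("CTRL_ZERO", "control_unmethyl", r)
  for (r in seq_len(cfg$control_triplicates)) add("CTRL_HALF", "control_half_methyl", r)
  sample_sheet(do.call(rbind, rows))
}

#' Simulate a complete synthetic methylation experiment
#'
#' Builds the probe annotation, sample sheet and planted ground truth, then
#' draws observed beta values from a beta distribution with the true
#' methylation mean and concentration `kappa` (exactly the mean when `kappa`
#' is infinite), draws per-cell total intensities log-normally, and splits
#' them into methylated and unmethylated channel signals. True imprinted
#' DMRs have mean 0.5 in all biparental classes and mean 1 (maternally
#' methylated) or 0 (paternally methylated) in the parthenote class; control
#' samples have true means 1, 0 and 0.5 at every probe. Identical seeds give
#' identical output.
#'
#' @param config a [sim_config()].
#' @return List of class `methylation_simulation` with elements `signals`
#'   ([signal_matrix()]), `samples` ([sample_sheet()]), `annotation`
#'   ([probe_annotation()]), `truth` (ground-truth data.frame) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)

  n_imp <- cfg$n_imprinted_genes * cfg$probes_per_imprinted_gene
  imp_gene <- rep(sprintf("IMPG%03d", seq_len(cfg$n_imprinted_genes)),
                  each = cfg$probes_per_imprinted_gene)
  n_bg <- cfg$n_probes - n_imp
  # background density ~2 probes per gene, echoing 27,578 sites / ~14,500 genes
  bg_gene <- sprintf("GENE%05d", ceiling(seq_len(n_bg) / 2))
  probe_id <- sprintf("cg%07d", seq_len(cfg$n_probes))
  gene_symbol <- c(imp_gene, bg_gene)
  is_imp <- c(rep(TRUE, n_imp), rep(FALSE, n_bg))

  gene_dir <- ifelse(stats::runif(cfg$n_imprinted_genes) < cfg$maternal_direction_fraction,
                     "maternally_methylated", "paternally_methylated")
  probe_dir_gene <- rep(gene_dir, each = cfg$probes_per_imprinted_gene)
  is_dmr <- c(stats::runif(n_imp) < cfg$dmr_fraction, rep(FALSE, n_bg))
  direction <- rep("unknown", cfg$n_probes)
  direction[seq_len(n_imp)][is_dmr[seq_len(n_imp)]] <-
    probe_dir_gene[is_dmr[seq_len(n_imp)]]

  annotation <- probe_annotation(data.frame(
    probe_id = probe_id, gene_symbol = gene_symbol,
    is_imprinted_gene = is_imp, imprint_direction = direction,
    stringsAsFactors = FALSE))

  bg_mean <- ifelse(stats::runif(cfg$n_probes) < cfg$background_weight_low,
                    cfg$background_low, cfg$background_high)
  mean_somatic <- ifelse(is_dmr, 0.5, bg_mean)
  # ES-specific hypermethylation at a background-probe subset (never at
  # imprinted-gene probes, so the imprint filter is unaffected)
  es_hyper <- !is_imp & !is_dmr &
    stats::runif(cfg$n_probes) < cfg$esc_hyper_fraction
  bg_es <- ifelse(es_hyper, pmin(bg_mean + cfg$esc_hyper_shift, 1), bg_mean)
  mean_esc <- ifelse(is_dmr, 0.5, bg_es)
  mean_parthenote <- ifelse(is_dmr,
                            ifelse(direction == "maternally_methylated", 1, 0),
                            bg_es)
  truth <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                      is_true_dmr = is_dmr, imprint_direction = direction,
                      mean_tissue = mean_somatic,
                      mean_primary_cell = mean_somatic,
                      mean_conventional_esc = mean_esc,
                      mean_parthenote_esc = mean_parthenote,
                      stringsAsFactors = FALSE)
  class(truth) <- c("ground_truth", "data.frame")

  samples <- sim_sample_sheet(cfg)
  true_mean <- true_mean_matrix(truth, samples)

  if (is.infinite(cfg$kappa)) {
    beta_star <- true_mean
  } else {
    eps <- .Machine$double.eps
    m <- pmin(pmax(true_mean, eps), 1 - eps)   # keep beta shapes proper
    beta_star <- matrix(stats::rbeta(length(m), m * cfg$kappa, (1 - m) * cfg$kappa),
                        nrow = nrow(m), dimnames = dimnames(m))
  }
  total <- matrix(stats::rlnorm(length(beta_star),
                                meanlog = cfg$total_intensity_log_mean,
                                sdlog = cfg$total_intensity_log_sd),
                  nrow = nrow(beta_star), dimnames = dimnames(beta_star))
  signals <- signal_matrix(methylated = beta_star * total,
                           unmethylated = (1 - beta_star) * total)

  structure(list(signals = signals, samples = samples,
                 annotation = annotation, truth = truth, config = cfg),
            class = "methylation_simulation")
}

#' Per-(probe, sample) true methylation means implied by a ground truth
#'
#' @param truth a `ground_truth` table.
#' @param samples a `sample_sheet`.
#' @return Numeric probe x sample matrix of true means.
#' @export
true_mean_matrix <- function(truth, samples) {
  stopifnot(inherits(samples, "sample_sheet"))
  class_mean <- function(cls) {
    switch(cls,
           tissue = truth$mean_tissue,
           primary_cell = truth$mean_primary_cell,
           conventional_esc = truth$mean_conventional_esc,
           parthenote_esc = truth$mean_parthenote_esc,
           control_full_methyl = rep(1, nrow(truth)),
           control_unmethyl = rep(0, nrow(truth)),
           control_half_methyl = rep(0.5, nrow(truth)))
  }
  m <- vapply(samples$sample_class, class_mean, numeric(nrow(truth)))
  dimnames(m) <- list(truth$probe_id, samples$sample_id)
  m
}

#' Planted true-DMR probe set
#'
#' The exact set of probes planted as imprinted DMRs, for comparison with
#' the pipeline's recovered imprinted site set.
#'
#' @param truth a `ground_truth` table.
#' @param annotation the matching `probe_annotation`.
#' @return Character vector of true-DMR probe ids (annotation order).
#' @export
truth_site_set <- function(truth, annotation) {
  stopifnot(inherits(annotation, "probe_annotation"))
  if (!setequal(truth$probe_id, annotation$probe_id))
    mi_error("truth and annotation cover different probe sets")
  ord <- truth[match(annotation$probe_id, truth$probe_id), ]
  ord$probe_id[ord$is_true_dmr]
}

#' @export
print.methylation_simulation <- function(x, ...) {
  cat(sprintf("methylation_simulation: %d probes x %d samples (kappa=%s, seed=%d); %d true DMRs\n",
              x$config$n_probes, nrow(x$samples), format(x$config$kappa),
              x$config$seed, sum(x$truth$is_true_dmr)))
  invisible(x)
}

## dataset I/O -------------------------------------------------------------

#' Write a simulated dataset to a directory
#'
#' Writes `signals.tsv` (paired channels as `<sample>.M` / `<sample>.U`
#' columns), `samples.tsv`, `annotation.tsv` and `truth.tsv` in the
#' package's tab-separated dialect.
#'
#' @param sim a `methylation_simulation`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "methylation_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_signals(sim$signals, file.path(dir, "signals.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_tsv_plain(as.data.frame(sim$truth), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write paired channel signals to a single TSV
#'
#' @param signals a `signal_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  stopifnot(inherits(signals, "signal_matrix"))
  m <- cbind(signals$methylated, signals$unmethylated)
  colnames(m) <- c(paste0(colnames(signals$methylated), ".M"),
                   paste0(colnames(signals$unmethylated), ".U"))
  write_matrix(m, path)
}

#' Read paired channel signals written by [write_signals()]
#'
#' @param path file path.
#' @return A [signal_matrix()].
#' @export
read_signals <- function(path) {
  m <- read_matrix(path)
  mcols <- grep("\\.M$", colnames(m), value = TRUE)
  ucols <- grep("\\.U$", colnames(m), value = TRUE)
  ids_m <- sub("\\.M$", "", mcols)
  ids_u <- sub("\\.U$", "", ucols)
  if (!setequal(ids_m, ids_u) || length(mcols) == 0)
    format_error("%s: expected paired <sample>.M / <sample>.U columns", path)
  meth <- m[, mcols, drop = FALSE]; colnames(meth) <- ids_m
  unmeth <- m[, ucols, drop = FALSE][, match(ids_m, ids_u), drop = FALSE]
  colnames(unmeth) <- ids_m
  signal_matrix(meth, unmeth)
}

#' Read a ground-truth table written by [write_dataset()]
#'
#' @param path file path.
#' @return A `ground_truth` data.frame.
#' @export
read_truth <- function(path) {
  df <- read_tsv_checked(path)
  req <- c("probe_id", "gene_symbol", "is_true_dmr", "imprint_direction",
           "mean_tissue", "mean_primary_cell", "mean_conventional_esc",
           "mean_parthenote_esc")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    format_error("truth table missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (is.character(df$is_true_dmr))
    df$is_true_dmr <- parse_logical_column(df$is_true_dmr, "is_true_dmr")
  class(df) <- c("ground_truth", "data.frame")
  df
}
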