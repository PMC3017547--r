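# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdirs.

tiny_config <- function(...) {
  defaults <- list(n_probes = 400L, n_imprinted_genes = 10L,
                   probes_per_imprinted_gene = 3L, kappa = 200, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_sim <- function(...) simulate_dataset(tiny_config(...))

# a minimal sample sheet: one line per class label given
mini_sheet <- function(classes, lines = NULL) {
  if (is.null(lines)) lines <- sprintf("L%02d", seq_along(classes))
  sample_sheet(data.frame(sample_id = paste0(lines, "_r1"), line_id = lines,
                          sample_class = classes, replicate_index = 1L,
                          stringsAsFactors = FALSE))
}

# line-level beta grid built directly (bypasses replicate aggregation)
mini_line_beta <- function(beta, line_class) {
  stopifnot(identical(colnames(beta), names(line_class)))
  structure(list(beta = beta, line_class = line_class), class = "line_beta")
}

# beta values that call cleanly at thresholds (0.3, 0.7)
BETA_UNMETH <- 0.1
BETA_PARTIAL <- 0.5
BETA_METH <- 0.9

state_beta <- function(state) {
  switch(state, unmethylated = BETA_UNMETH, partial = BETA_PARTIAL,
         methylated = BETA_METH, failed = NA_real_)
}

# build a state_matrix from a character grid of state tokens
mini_states <- function(states, line_class) {
  b <- matrix(vapply(states, state_beta, numeric(1)), nrow = nrow(states),
              dimnames = dimnames(states))
  call_states(mini_line_beta(b, line_class), t_low = 0.3, t_high = 0.7)
}
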