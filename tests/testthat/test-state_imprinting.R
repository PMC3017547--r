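test_that("replicate aggregation means line replicates, tolerating missing", {
  ss <- sample_sheet(data.frame(
    sample_id = c("A_r1", "A_r2", "B_r1", "B_r2"),
    line_id = c("A", "A", "B", "B"),
    sample_class = "parthenote_esc", replicate_index = c(1L, 2L, 1L, 2L)))
  b <- beta_matrix(matrix(c(0.4, 0.6, NA, 0.7), 1,
                          dimnames = list("cg01", ss$sample_id)),
                   normalized = TRUE)
  lb <- aggregate_replicates(b, ss)
  expect_equal(unname(lb$beta[1, ]), c(0.5, 0.7))
  expect_equal(unname(lb$line_class), c("parthenote_esc", "parthenote_esc"))

  # brute-force oracle on a random grid
  set.seed(9)
  sim <- tiny_sim(kappa = 20, seed = 9)
  pl <- run_imprinting_pipeline(sim$signals, sim$samples, sim$annotation)
  lb2 <- pl$line_beta
  keep <- sim$samples[!(sim$samples$sample_class %in%
                          c("control_full_methyl", "control_unmethyl",
                            "control_half_methyl")), ]
  for (ln in sample(colnames(lb2$beta), 3)) {
    ids <- keep$sample_id[keep$line_id == ln]
    for (p in sample(rownames(lb2$beta), 5)) {
      v <- pl$beta_norm$beta[p, ids]
      exp_val <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      expect_equal(lb2$beta[p, ln], exp_val)
    }
  }
})

test_that("state calls respect thresholds with definitive boundaries", {
  lb <- mini_line_beta(matrix(c(0.2, 0.5, 0.8, 0.3, 0.7, NA), 6, 1,
                              dimnames = list(sprintf("cg%02d", 1:6), "L1")),
                       c(L1 = "tissue"))
  st <- call_states(lb, 0.3, 0.7)
  expect_equal(unname(st$states[, 1]),
               c("unmethylated", "partial", "methylated",
                 "unmethylated", "methylated", "failed"))
  expect_error(call_states(lb, 0.7, 0.3), "thresholds")
})

tissue5 <- function() {
  lines <- sprintf("T%d", 1:5)
  ss <- mini_sheet(rep("tissue", 5), lines)
  list(lines = lines, sheet = ss,
       line_class = stats::setNames(rep("tissue", 5), lines))
}

test_that("tissue filter retains 5/5 at d=0 and 4/5 only at d>=1", {
  tx <- tissue5()
  ann <- probe_annotation(data.frame(
    probe_id = c("cg01", "cg02", "cg03"),
    gene_symbol = c("H19", "SNRPN", "ACTB"),
    is_imprinted_gene = c(TRUE, TRUE, FALSE),
    imprint_direction = "unknown"))
  grid <- rbind(cg01 = rep("partial", 5),
                cg02 = c(rep("partial", 4), "methylated"),
                cg03 = rep("partial", 5))
  colnames(grid) <- tx$lines
  st <- mini_states(grid, tx$line_class)
  s0 <- tissue_partial_filter(st, ann, tx$sheet, d = 0)
  expect_equal(s0$probe_ids, "cg01")          # cg03 not an imprinted gene
  s1 <- tissue_partial_filter(st, ann, tx$sheet, d = 1)
  expect_setequal(s1$probe_ids, c("cg01", "cg02"))
  expect_equal(s1$n_genes, 2)
})

test_that("tissue filter equals exhaustive enumeration over all 3^5 patterns x d", {
  tx <- tissue5()
  states3 <- c("unmethylated", "partial", "methylated")
  patterns <- as.matrix(expand.grid(rep(list(states3), 5),
                                    stringsAsFactors = FALSE))
  rownames(patterns) <- sprintf("cg%03d", seq_len(nrow(patterns)))
  colnames(patterns) <- tx$lines
  ann <- probe_annotation(data.frame(
    probe_id = rownames(patterns),
    gene_symbol = sprintf("G%03d", seq_len(nrow(patterns))),
    is_imprinted_gene = TRUE, imprint_direction = "unknown"))
  st <- mini_states(patterns, tx$line_class)
  for (d in 0:5) {
    got <- tissue_partial_filter(st, ann, tx$sheet, d = d)$probe_ids
    # independent brute force over the raw patterns
    want <- rownames(patterns)[vapply(seq_len(nrow(patterns)), function(i)
      sum(patterns[i, ] == "partial") >= 5 - d, logical(1))]
    expect_identical(got, want)
  }
  # retained-set nesting across d
  sets <- lapply(0:5, function(d) tissue_partial_filter(st, ann, tx$sheet, d)$probe_ids)
  for (i in 1:5) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  expect_error(tissue_partial_filter(st, ann, tx$sheet, d = 6), "must lie")
})

test_that("failed tissue calls count against retention", {
  tx <- tissue5()
  ann <- probe_annotation(data.frame(probe_id = "cg01", gene_symbol = "H19",
                                     is_imprinted_gene = TRUE,
                                     imprint_direction = "unknown"))
  grid <- matrix(c(rep("partial", 4), "failed"), 1, dimnames = list("cg01", tx$lines))
  st <- mini_states(grid, tx$line_class)
  expect_equal(tissue_partial_filter(st, ann, tx$sheet, 0)$n_sites, 0)
  expect_equal(tissue_partial_filter(st, ann, tx$sheet, 1)$n_sites, 1)
})

test_that("discordance sweep is monotone and collapses on noise-free full-DMR data", {
  sim <- tiny_sim(kappa = 20, seed = 4)
  pl <- run_imprinting_pipeline(sim$signals, sim$samples, sim$annotation)
  sw <- pl$sweep
  expect_true(all(diff(sw$n_sites) >= 0))
  expect_true(all(diff(sw$n_genes) >= 0))
  # d = N_tissue retains every imprinted-gene probe with non-failed calls
  n_imp_probes <- sum(sim$annotation$is_imprinted_gene)
  expect_equal(sw$n_sites[sw$d == 5], n_imp_probes)

  pure <- tiny_sim(kappa = Inf, dmr_fraction = 1)
  plp <- run_imprinting_pipeline(pure$signals, pure$samples, pure$annotation)
  expect_equal(length(unique(plp$sweep$n_sites)), 1)   # identical rows at all d
  expect_equal(length(unique(plp$sweep$n_genes)), 1)
})

test_that("definitive fraction counts calls, reproducing the 45-of-92 example", {
  lines <- c("PE1", "PE2")
  ss <- mini_sheet(rep("parthenote_esc", 2), lines)
  lc <- stats::setNames(rep("parthenote_esc", 2), lines)
  # 92 sites x 2 lines; line PE1: 45 definitive + 47 partial, line PE2 failed
  st_grid <- cbind(c(rep("methylated", 20), rep("unmethylated", 25), rep("partial", 47)),
                   rep("failed", 92))
  dimnames(st_grid) <- list(sprintf("cg%03d", 1:92), lines)
  st <- mini_states(st_grid, lc)
  frac <- definitive_fraction(st, rownames(st_grid), ss, "parthenote_esc")
  expect_equal(frac, 45 / 92)
  expect_equal(round(100 * frac), 49)   # the headline percentage

  # invariance to site and line ordering
  perm <- sample(rownames(st_grid))
  expect_equal(definitive_fraction(st, perm, ss, "parthenote_esc"), 45 / 92)
  expect_equal(definitive_fraction(st, rownames(st_grid), ss, rev(lines)), 45 / 92)

  # degenerate cases
  all_part <- mini_states(matrix("partial", 2, 1, dimnames = list(c("a", "b"), "PE1")),
                          c(PE1 = "parthenote_esc"))
  ss1 <- mini_sheet("parthenote_esc", "PE1")
  expect_equal(definitive_fraction(all_part, c("a", "b"), ss1, "parthenote_esc"), 0)
  all_def <- mini_states(matrix("methylated", 2, 1, dimnames = list(c("a", "b"), "PE1")),
                         c(PE1 = "parthenote_esc"))
  expect_equal(definitive_fraction(all_def, c("a", "b"), ss1, "parthenote_esc"), 1)
  all_fail <- mini_states(matrix("failed", 2, 1, dimnames = list(c("a", "b"), "PE1")),
                          c(PE1 = "parthenote_esc"))
  expect_error(definitive_fraction(all_fail, c("a", "b"), ss1, "parthenote_esc"),
               "undefined")
})

test_that("tissue-baseline subtraction behaves and saturates on noise-free DMRs", {
  expect_equal(baseline_normalize_fraction(0.49, 0), 0.49)
  expect_equal(baseline_normalize_fraction(0.3, 0.3), 0)
  expect_lt(baseline_normalize_fraction(0.1, 0.4), 0)

  sim <- tiny_sim(kappa = Inf)
  pl <- run_imprinting_pipeline(sim$signals, sim$samples, sim$annotation)
  pf <- definitive_fraction(pl$states, pl$sites, sim$samples, "parthenote_esc")
  tf <- definitive_fraction(pl$states, pl$sites, sim$samples, "tissue")
  expect_equal(baseline_normalize_fraction(pf, tf), 1.0)
})
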