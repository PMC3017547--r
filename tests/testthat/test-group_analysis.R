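consistency_fixture <- function(dirs, pe_states) {
  n <- length(dirs)
  probes <- sprintf("cg%02d", seq_len(n))
  tx_lines <- sprintf("T%d", 1:5)
  pe_lines <- c("PE1", "PE2")
  ann <- probe_annotation(data.frame(
    probe_id = probes, gene_symbol = sprintf("G%02d", seq_len(n)),
    is_imprinted_gene = TRUE, imprint_direction = dirs))
  grid <- cbind(matrix("partial", n, 5, dimnames = list(probes, tx_lines)),
                matrix(rep(pe_states, 2), n, 2, dimnames = list(probes, pe_lines)))
  lc <- stats::setNames(c(rep("tissue", 5), rep("parthenote_esc", 2)),
                        c(tx_lines, pe_lines))
  ss <- mini_sheet(c(rep("tissue", 5), rep("parthenote_esc", 2)),
                   c(tx_lines, pe_lines))
  st <- mini_states(grid, lc)
  sites <- tissue_partial_filter(st, ann, ss, d = 0)
  list(ann = ann, states = st, sites = sites)
}

test_that("consistency follows the direction/state definition", {
  fx <- consistency_fixture(
    dirs = c("maternally_methylated", "paternally_methylated",
             "paternally_methylated", "maternally_methylated", "unknown"),
    pe_states = c("methylated",    # maternal + methylated -> consistent
                  "unmethylated",  # paternal + unmethylated -> consistent
                  "methylated",    # paternal + methylated -> inconsistent
                  "partial",       # not definitive -> excluded
                  "methylated"))   # unknown direction -> excluded
  rep <- maternal_consistency(fx$sites, fx$states, fx$ann)
  expect_equal(rep$n_definitive_sites, 3)
  expect_equal(rep$n_consistent, 2)
  expect_equal(rep$consistency_fraction, 2 / 3)
  expect_equal(rep$n_unknown_direction, 1)
  # counts partition: consistent + inconsistent = definitive
  det <- rep$detail[rep$detail$definitive, ]
  expect_equal(sum(det$consistent) + sum(!det$consistent), rep$n_definitive_sites)
})

test_that("all-unknown directions raise an instructive error", {
  fx <- consistency_fixture(dirs = rep("unknown", 3),
                            pe_states = rep("methylated", 3))
  expect_error(maternal_consistency(fx$sites, fx$states, fx$ann),
               "direction")
})

test_that("noise-free parthenote data is 100% consistent with maternal imprinting", {
  sim <- tiny_sim(kappa = Inf)
  pl <- run_imprinting_pipeline(sim$signals, sim$samples, sim$annotation)
  rep <- maternal_consistency(pl$sites, pl$states, sim$annotation)
  expect_gt(rep$n_definitive_sites, 0)
  expect_equal(rep$consistency_fraction, 1.0)
})

test_that("differential imprinted-gene calls respect groups, delta and symmetry", {
  sim <- tiny_sim(kappa = Inf)
  pl <- run_imprinting_pipeline(sim$signals, sim$samples, sim$annotation)
  lb <- pl$line_beta

  # identical groups: no differential genes at any delta
  same <- differential_imprinted(lb, sim$annotation, "parthenote_esc",
                                 "parthenote_esc", delta = 0.05)
  expect_equal(sum(same$is_differential), 0)

  # truth oracle: with any_probe and delta 0.2, exactly the imprinted genes
  # containing at least one planted DMR are flagged (parthenote shift 0.5)
  tab <- differential_imprinted(lb, sim$annotation, "parthenote_esc",
                                "conventional_esc", delta = 0.2,
                                aggregation = "any_probe")
  dmr_genes <- unique(sim$truth$gene_symbol[sim$truth$is_true_dmr])
  expect_setequal(tab$gene_symbol[tab$is_differential], dmr_genes)

  # swap symmetry: differences negate, calls identical
  swap <- differential_imprinted(lb, sim$annotation, "conventional_esc",
                                 "parthenote_esc", delta = 0.2,
                                 aggregation = "any_probe")
  m <- match(tab$gene_symbol, swap$gene_symbol)
  expect_equal(tab$difference, -swap$difference[m])
  expect_equal(tab$is_differential, swap$is_differential[m])

  # near-1 delta flags nothing (noise-free max |difference| is 0.5)
  hard <- differential_imprinted(lb, sim$annotation, "parthenote_esc",
                                 "conventional_esc", delta = 0.999,
                                 aggregation = "any_probe")
  expect_equal(sum(hard$is_differential), 0)
  expect_error(differential_imprinted(lb, sim$annotation, "parthenote_esc",
                                      "conventional_esc", delta = 0), "delta")
})

test_that("sample correlations match a scalar-loop oracle and edge identities", {
  set.seed(5)
  b <- matrix(runif(200), 40, 5,
              dimnames = list(sprintf("cg%02d", 1:40), sprintf("S%d", 1:5)))
  b[3, 2] <- NA
  bm <- beta_matrix(b)
  cc <- sample_correlation_matrix(bm)
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- !is.na(b[, i]) & !is.na(b[, j])
    expect_equal(cc[i, j], stats::cor(b[ok, i], b[ok, j]))
  }
  expect_equal(unname(diag(cc)), rep(1, 5))

  dup <- beta_matrix(cbind(A = b[, 1], B = b[, 1]))
  expect_equal(sample_correlation_matrix(dup)["A", "B"], 1)
  comp <- beta_matrix(cbind(A = b[, 1], B = 1 - b[, 1]))
  expect_equal(sample_correlation_matrix(comp)["A", "B"], -1)

  # pairs sharing < 2 probes become missing, with a warning
  sparse <- matrix(NA_real_, 3, 2, dimnames = list(c("a", "b", "c"), c("X", "Y")))
  sparse[, 1] <- c(0.1, 0.5, NA)
  sparse[, 2] <- c(NA, NA, 0.3)
  expect_warning(cs <- sample_correlation_matrix(beta_matrix(sparse)), "fewer than 2")
  expect_true(is.na(cs["X", "Y"]))
})

test_that("clustering joins identical samples first and is order-invariant", {
  set.seed(6)
  v <- runif(30)
  b <- beta_matrix(cbind(A = v, B = v, C = 1 - v) |>
                     (\(m) { rownames(m) <- sprintf("cg%02d", 1:30); m })())
  hc <- hierarchical_cluster(sample_correlation_matrix(b))
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("A", "B"))
  # heights non-negative and non-decreasing (agglomerative, average linkage)
  expect_true(all(hc$height >= -1e-12))
  expect_true(all(diff(hc$height) >= -1e-12))

  sim <- tiny_sim(n_probes = 2000, kappa = 100, seed = 12)
  pl <- run_imprinting_pipeline(sim$signals, sim$samples, sim$annotation)
  bio <- subset_samples(pl$beta_norm, sim$samples)
  cc <- sample_correlation_matrix(bio)
  hc1 <- hierarchical_cluster(cc)
  perm <- sample(colnames(cc))
  hc2 <- hierarchical_cluster(cc[perm, perm])
  # identical tree up to leaf-order isomorphism: same merge heights and
  # same pairwise cophenetic distances
  expect_equal(hc1$height, hc2$height)
  d1 <- as.matrix(stats::cophenetic(hc1)); d2 <- as.matrix(stats::cophenetic(hc2))
  expect_equal(d1[rownames(d1), colnames(d1)], d2[rownames(d1), colnames(d1)])

  ccNA <- cc; ccNA[1, 2] <- NA
  expect_error(hierarchical_cluster(ccNA), "missing")
})

test_that("discordance-correlation curves behave at the vacuous end and separate groups", {
  sim <- tiny_sim(n_probes = 1000, kappa = 200, seed = 3)
  pl <- run_imprinting_pipeline(sim$signals, sim$samples, sim$annotation)
  bio <- subset_samples(pl$beta_norm, sim$samples)

  cv <- discordance_correlation_curve(bio, pl$states, sim$annotation,
                                      sim$samples, site_mode = "all_sites",
                                      k_max = 4)
  # k = n - 1 is near-vacuous; k = n selects every non-failed site
  cv_full <- discordance_correlation_curve(bio, pl$states, sim$annotation,
                                           sim$samples, k_max = 5)
  n_universe <- nrow(pl$states$states)
  expect_equal(unique(cv_full$n_sites[cv_full$k == 5]), n_universe)
  # site counts never decrease with k
  ks <- unique(cv$k)
  ns <- vapply(ks, function(k) cv$n_sites[cv$k == k][1], numeric(1))
  expect_true(all(diff(ns) >= 0))

  # reference-group members track their own mean tightly at k = 0
  pe0 <- cv$correlation[cv$k == 0 & cv$sample_class == "parthenote_esc"]
  expect_true(all(pe0 > 0.9))

  # imprinted-site curves separate phESC from hESC more than all-site curves
  gap <- function(mode) {
    x <- discordance_correlation_curve(bio, pl$states, sim$annotation,
                                       sim$samples, site_mode = mode, k_max = 4)
    mean(x$correlation[x$sample_class == "parthenote_esc"], na.rm = TRUE) -
      mean(x$correlation[x$sample_class == "conventional_esc"], na.rm = TRUE)
  }
  expect_gt(gap("imprinted_sites"), gap("all_sites"))
})
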