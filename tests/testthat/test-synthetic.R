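test_that("noiseless MID tables equal the forward model exactly", {
  spec <- mid_sim_spec(D_true = 0.27, g_true = 0.6, noise_sd = 0,
                       n_samples = 3)
  tab <- generate_mid_dataset(spec)
  want <- simulate_analyte_mid(0.27, 0.6)
  for (i in 1:3)
    expect_equal(as.numeric(tab[i, -(1:2)]), unname(want), tolerance = 0)
  # D = 0 with any g gives the natural-abundance MID
  tab0 <- generate_mid_dataset(mid_sim_spec(D_true = 0, g_true = 0.5,
                                            noise_sd = 0, n_samples = 1))
  expect_equal(as.numeric(tab0[1, -(1:2)]),
               unname(natural_abundance_mid("C16", 11)), tolerance = 1e-14)
})

test_that("MID generation is seed-deterministic and rows stay simplex", {
  s <- mid_sim_spec(n_samples = 3, seed = 11)
  expect_identical(generate_mid_dataset(s), generate_mid_dataset(s))
  tab <- generate_mid_dataset(mid_sim_spec(n_samples = 20, noise_sd = 0.005,
                                           seed = 4))
  m <- as.matrix(tab[, -(1:2)])
  expect_true(all(m >= 0))
  expect_equal(rowSums(m), rep(1, 20), tolerance = 1e-12)
})

test_that("absurd MID noise is rejected with advice", {
  expect_error(generate_mid_dataset(mid_sim_spec(noise_sd = 5, seed = 5)),
               "smaller noise_sd")
})

test_that("count tables are deterministic with planted group structure", {
  spec <- community_sim_spec(seed = 8)
  t1 <- generate_count_tables(spec)
  t2 <- generate_count_tables(spec)
  expect_identical(t1$abundance$counts, t2$abundance$counts)
  expect_identical(t1$expression$counts, t2$expression$counts)
  expect_equal(sort(unique(t1$metadata$group)), c("control", "ethanol"))
  expect_equal(nrow(t1$abundance$counts), 14L)
  # integer nonnegative counts
  expect_true(all(t1$abundance$counts >= 0))
  expect_true(all(t1$abundance$counts == round(t1$abundance$counts)))
  # expression carries rpoA/acs/adh per bin with lengths (rpoA = 1 kb)
  genes <- t1$expression$annotations$gene
  expect_setequal(unique(genes), c("rpoA", "acs", "adh"))
  rpoa_feats <- rownames(t1$expression$annotations)[genes == "rpoA"]
  expect_true(all(t1$expression$lengths[rpoa_feats] == 1000))
})

test_that("planted effects reach significance; too-few taxa error", {
  tabs <- generate_count_tables(community_sim_spec(seed = 1))
  lr <- log_ratio(tabs$abundance,
                  select_features(tabs$abundance, "label", "Bacteroidetes"),
                  select_features(tabs$abundance, "label", "Enterococcaceae"),
                  pseudocount = 1)
  gt <- group_test(lr, sample_groups(tabs$metadata))
  expect_lt(gt$p_value, 0.05)
  taxa <- default_taxa()[-(5:6), ]  # drop both Enterococcaceae
  expect_error(generate_count_tables(
    community_sim_spec(taxa = taxa,
                       effects = setNames(rep(0, nrow(taxa)), taxa$name))),
    "Enterococcaceae")
})

test_that("acs is upregulated against the rpoA frame; adh is not", {
  pvals <- vapply(1:20, function(s) {
    tabs <- generate_count_tables(community_sim_spec(seed = s))
    ex <- rpk_normalize(tabs$expression)
    g <- sample_groups(tabs$metadata)
    p_acs <- group_test(log_ratio(ex, select_features(ex, "gene", "acs"),
                                  select_features(ex, "gene", "rpoA"),
                                  pseudocount = 1), g)$p_value
    p_adh <- group_test(log_ratio(ex, select_features(ex, "gene", "adh"),
                                  select_features(ex, "gene", "rpoA"),
                                  pseudocount = 1), g)$p_value
    c(p_acs, p_adh)
  }, numeric(2))
  expect_gte(mean(pvals[1, ] < 0.05), 0.9)   # planted acs effect detected
  expect_lte(mean(pvals[2, ] < 0.05), 0.3)   # adh null mostly quiet
})

test_that("SCFA tables plant the acetate fold and nothing else", {
  analytes <- c("acetate", "butyrate", "caproate", "heptanoate",
                "isobutyrate", "isovalerate", "propionate", "valerate")
  folds <- vapply(1:20, function(s) {
    tab <- generate_scfa_table(n_per_group = 7, acetate_fold = 4, seed = s)
    expect_true(all(analytes %in% names(tab)))
    expect_true(all(tab[analytes] > 0))
    mean(tab$acetate[tab$group == "ethanol"]) /
      mean(tab$acetate[tab$group == "control"])
  }, numeric(1))
  expect_gte(mean(folds >= 3 & folds <= 5), 0.95)
  # null configuration: rejection near the nominal level across analytes
  ps <- unlist(lapply(1:25, function(s) {
    tab <- generate_scfa_table(acetate_fold = 1, seed = s)
    vapply(analytes, function(a)
      group_test(setNames(tab[[a]], tab$sample),
                 setNames(tab$group, tab$sample))$p_value, numeric(1))
  }))
  expect_lt(mean(ps < 0.05), 0.12)
  expect_warning(generate_scfa_table(n_per_group = 1, seed = 1),
                 "impossible")
  expect_error(generate_scfa_table(acetate_fold = 0))
})

test_that("generators are pure functions of spec and seed", {
  expect_identical(generate_scfa_table(seed = 3), generate_scfa_table(seed = 3))
  expect_false(identical(generate_scfa_table(seed = 3),
                         generate_scfa_table(seed = 4)))
  g1 <- generate_toy_gem("cometabolism")
  g2 <- generate_toy_gem("cometabolism")
  expect_identical(g1$model, g2$model)
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(99); before <- .Random.seed
  invisible(generate_count_tables(community_sim_spec(seed = 5)))
  invisible(generate_mid_dataset(mid_sim_spec(seed = 5)))
  invisible(generate_scfa_table(seed = 5))
  expect_identical(.Random.seed, before)
})
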