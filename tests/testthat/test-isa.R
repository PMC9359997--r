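test_that("synthesized MID reduces to natural abundance when D = 0", {
  expect_equal(synthesized_mid(0, n_tracked = 11),
               natural_abundance_mid("C16", n_tracked = 11),
               tolerance = 1e-14)
})

test_that("pure-tracer label counts follow the binomial closed form", {
  # carbon-only, purity 1, no natural 13C: label count ~ Binomial(8, D)
  s <- synthesized_mid(0.5, precursor_unit(tracer_purity = 1), 8, "C16",
                       n_tracked = 8,
                       abundances = isotope_abundances(C13 = 0))
  expect_equal(unname(s), dbinom(0:8, 8, 0.5), tolerance = 1e-14)
  expect_equal(unname(s[1]), 0.00390625, tolerance = 1e-12)
})

test_that("convolution equals exhaustive enumeration over unit assignments", {
  unit <- precursor_unit()
  cases <- list(
    list(D = 0.5, n_units = 2L, formula = "C4"),
    list(D = 0.27, n_units = 8L, formula = "C16"),
    list(D = 0.8, n_units = 8L, formula = "C20"),
    list(D = 0.35, n_units = 4L, formula = "C9H2O1"))
  for (cs in cases) {
    got <- synthesized_mid(cs$D, unit, cs$n_units, cs$formula,
                           n_tracked = cs$n_units + 3L)
    want <- enum_synthesized_mid(cs$D, unit, cs$n_units, cs$formula,
                                 n_tracked = cs$n_units + 3L)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("the measured-analyte model is an exact mixture in g", {
  A <- synthesized_mid(0.4)
  B <- natural_abundance_mid("C16", n_tracked = 11)
  for (g in c(0, 0.3, 1))
    expect_equal(simulate_analyte_mid(0.4, g), g * A + (1 - g) * B,
                 tolerance = 1e-14)
  # no new synthesis, or unlabelled synthesis, both give natural abundance
  expect_equal(simulate_analyte_mid(0.7, 0), B, tolerance = 1e-14)
  expect_equal(simulate_analyte_mid(0, 1), B, tolerance = 1e-14)
})

test_that("aggregate heavy mass increases strictly with D", {
  mass <- vapply(seq(0, 1, by = 0.1), function(D) {
    m <- synthesized_mid(D)
    sum((seq_along(m) - 1) * m)
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("noise-free fits recover the generating parameters", {
  f <- fit_isa(simulate_analyte_mid(0.27, 0.6))
  expect_lt(abs(f$D - 0.27), 1e-6)
  expect_lt(abs(f$g - 0.6), 1e-6)
  expect_identical(f$status, "ok")
  expect_equal(unname(coef(f)), c(f$D, f$g))
  expect_equal(residuals(f), f$measured - fitted(f))
  expect_output(print(summary(f)), "tracer contribution")
})

test_that("a natural-abundance MID is flagged unidentifiable", {
  f <- fit_isa(natural_abundance_mid("C16", n_tracked = 11))
  expect_lt(f$g, 1e-3)
  expect_identical(f$status, "unidentifiable")
})

test_that("fits are deterministic and degrade gracefully with noise", {
  m <- withr::with_seed(42, {
    x <- simulate_analyte_mid(0.3, 0.5) + rnorm(12, 0, 0.003)
    x <- pmax(x, 0); x / sum(x)
  })
  f1 <- fit_isa(m, seed = 7)
  f2 <- fit_isa(m, seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_lt(abs(f1$D - 0.3), 0.05)
})

test_that("bootstrap intervals cover the point estimate", {
  m <- withr::with_seed(1, {
    x <- simulate_analyte_mid(0.3, 0.6) + rnorm(12, 0, 0.002)
    x <- pmax(x, 0); x / sum(x)
  })
  f <- fit_isa(m, n_starts = 4, bootstrap = 30, seed = 2)
  expect_true(f$ci_D[1] <= f$D && f$D <= f$ci_D[2])
  expect_true(f$ci_g[1] <= f$g && f$g <= f$ci_g[2])
})

test_that("tracer contribution percentage follows the stated convention", {
  expect_equal(as.numeric(tracer_contribution_percent(0)), 0)
  expect_equal(as.numeric(tracer_contribution_percent(0.24)), 24)
  one <- tracer_contribution_percent(1, unit = precursor_unit(tracer_purity = 1))
  expect_equal(as.numeric(one), 100)
  adj <- tracer_contribution_percent(0.24, "purity-adjusted",
                                     unit = precursor_unit(tracer_purity = 0.96))
  expect_equal(as.numeric(adj), 25)
})

test_that("table-level fitting carries identifiers through", {
  tab <- generate_mid_dataset(mid_sim_spec(D_true = 0.2, g_true = 0.5,
                                           noise_sd = 0, n_samples = 2))
  res <- fit_isa_table(tab, n_starts = 4)
  expect_equal(res$sample, c("s1", "s2"))
  expect_equal(res$D, c(0.2, 0.2), tolerance = 1e-5)
  expect_error(fit_isa_table(tab["sample"]), "M0")
  expect_error(fit_isa(c(1)), "at least 2")
})
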