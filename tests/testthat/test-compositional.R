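make_ft <- function(counts, ...) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("f", seq_len(ncol(counts)))
  feature_table(counts, ...)
}

test_that("RPK divides by kilobases and preserves structure", {
  ft <- make_ft(matrix(c(500, 100), 1, 2),
                lengths = c(f1 = 2000, f2 = 1000))
  r <- rpk_normalize(ft)
  expect_equal(unname(r$counts[1, ]), c(250, 100))
  ft2 <- ft; ft2$lengths <- ft$lengths * 2
  expect_equal(rpk_normalize(ft2)$counts, r$counts / 2)
  expect_error(rpk_normalize(make_ft(matrix(1, 1, 1))), "lengths")
})

test_that("log-ratios obey the definition and compositional invariance", {
  counts <- matrix(c(80, 20, 40, 10), 2, 2, byrow = TRUE)
  ft <- make_ft(counts)
  lr <- log_ratio(ft, "f1", "f2")
  expect_equal(lr$value, c(log(4), log(4)), tolerance = 1e-14)
  # identity ratio
  expect_equal(log_ratio(ft, c("f1", "f2"), c("f1", "f2"),
                         allow_overlap = TRUE)$value, c(0, 0))
  # per-sample rescaling leaves values unchanged
  counts2 <- counts; counts2[2, ] <- counts2[2, ] * 10
  expect_equal(log_ratio(make_ft(counts2), "f1", "f2")$value, lr$value,
               tolerance = 1e-14)
  expect_error(log_ratio(ft, "f1", "f1"), "overlap")
  expect_error(log_ratio(ft, character(), "f2"), "non-empty")
})

test_that("zero denominators exclude samples loudly, not silently", {
  counts <- matrix(c(80, 20, 40, 0), 2, 2, byrow = TRUE)
  lr <- log_ratio(make_ft(counts), "f1", "f2")
  expect_equal(nrow(lr), 1L)
  expect_identical(attr(lr, "excluded_samples"), "s2")
  # a pseudocount keeps every sample
  lr2 <- log_ratio(make_ft(counts), "f1", "f2", pseudocount = 1)
  expect_equal(nrow(lr2), 2L)
})

test_that("group tests match hand enumeration and handle edge cases", {
  # {1,2,3} vs {4,5,6}: most extreme of the 20 assignments, two-sided
  gt <- group_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(gt$p_value, 0.1, tolerance = 1e-12)
  expect_equal(gt$p_value, wilcox_enum_oracle(c(1, 2, 3), c(4, 5, 6)))
  # identical values in both groups
  gt2 <- suppressWarnings(
    group_test(rep(1, 6), rep(c("a", "b"), each = 3)))
  expect_equal(gt2$p_value, 1)
  expect_error(group_test(1:6, rep("a", 6)), "2 groups")
  expect_error(group_test(1:3, c("a", "a", "b")), "2 samples")
})

test_that("exact Wilcoxon p agrees with rank-permutation enumeration", {
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = sample(c(0, 2), 1))
    gt <- group_test(c(a, b), rep(c("x", "y"), c(n1, n2)))
    expect_equal(gt$p_value, wilcox_enum_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("multiplicity adjustment spans the group pairs", {
  set.seed(2)
  x <- rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  gt <- group_test(x, g)
  expect_equal(nrow(gt), 3L)
  expect_equal(gt$p_adjusted, p.adjust(gt$p_value, "BH"))
  tk <- group_test(x, g, adjust = "tukey")
  expect_true(all(tk$p_adjusted >= 0 & tk$p_adjusted <= 1))
})

test_that("Aitchison distance has the closed form for 2-part compositions", {
  a <- 0.3; b <- 0.8
  counts <- rbind(c(a, 1 - a), c(b, 1 - b)) * 1000
  d <- aitchison_distance(make_ft(counts), pseudocount = 0)
  want <- abs(log(a / (1 - a)) - log(b / (1 - b))) / sqrt(2)
  expect_equal(as.numeric(d), want, tolerance = 1e-12)
})

test_that("Aitchison distance is scale- and perturbation-invariant", {
  set.seed(5)
  counts <- matrix(rlnorm(40), 4, 10)
  d0 <- aitchison_distance(make_ft(counts), pseudocount = 0)
  # per-sample depth rescaling
  scaled <- counts * runif(4, 0.5, 20)
  expect_equal(as.numeric(aitchison_distance(make_ft(scaled), 0)),
               as.numeric(d0), tolerance = 1e-12)
  # common componentwise perturbation
  pert <- sweep(counts, 2, runif(10, 0.1, 5), "*")
  expect_equal(as.numeric(aitchison_distance(make_ft(pert), 0)),
               as.numeric(d0), tolerance = 1e-12)
})

test_that("identical samples are at distance zero", {
  counts <- rbind(c(5, 5, 10), c(5, 5, 10))
  expect_equal(as.numeric(aitchison_distance(make_ft(counts))), 0)
})

test_that("dense-limit ordination equals ordinary CLR-PCA", {
  set.seed(9)
  counts <- matrix(rpois(80, 50) + 1, 8, 10)
  ft <- make_ft(counts)
  ord <- ordinate(ft, rank = 2)
  pc <- prcomp(clr_transform(ft, pseudocount = 0), center = TRUE)
  for (k in 1:2) {
    ref <- pc$x[, k]
    got <- ord$scores[, k]
    expect_equal(abs(cor(got, ref)), 1, tolerance = 1e-9)
    expect_equal(sd(got), sd(ref), tolerance = 1e-6)
  }
  expect_true(all(diff(ord$proportion_explained) <= 1e-12))
})

test_that("ordination is equivariant under sample permutation", {
  set.seed(10)
  counts <- matrix(rpois(60, 30), 6, 10)
  counts[sample(60, 8)] <- 0
  ft <- counts; rownames(ft) <- paste0("s", 1:6); colnames(ft) <- paste0("f", 1:10)
  ord <- ordinate(ft, 2)
  perm <- c(3, 1, 2, 6, 5, 4)
  ord2 <- ordinate(ft[perm, ], 2)
  expect_equal(ord2$scores, ord$scores[perm, ], tolerance = 1e-6)
  expect_error(ordinate(ft, 6), "rank")
})

test_that("completion reconstruction error is non-increasing in rank", {
  set.seed(12)
  tabs <- generate_count_tables(community_sim_spec(seed = 12))
  X <- tabs$abundance$counts
  errs <- vapply(1:4, function(r) {
    ord <- ordinate(X, r)
    rec <- ord$scores %*% t(ord$loadings)
    lX <- log(X); lX[!is.finite(lX)] <- NA
    lX <- sweep(lX, 1, rowMeans(lX, na.rm = TRUE))
    lX <- sweep(lX, 2, colMeans(lX, na.rm = TRUE))
    sqrt(mean((lX - rec)^2, na.rm = TRUE))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("planted two-group structure separates on the first axis", {
  hits <- vapply(1:10, function(s) {
    tabs <- generate_count_tables(community_sim_spec(seed = s))
    ord <- ordinate(tabs$abundance, 2)
    g <- tabs$metadata$group
    x <- ord$scores[, 1]
    # positive silhouette-like margin: between-group mean gap exceeds
    # within-group spread
    abs(mean(x[g == "ethanol"]) - mean(x[g == "control"])) >
      mean(c(sd(x[g == "ethanol"]), sd(x[g == "control"])))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PERMANOVA pseudo-F matches vegan and p matches enumeration", {
  skip_if_not_installed("vegan")
  set.seed(21)
  counts <- matrix(rlnorm(60, 3), 6, 10)
  g <- rep(c("a", "b"), each = 3)
  d <- aitchison_distance(make_ft(counts))
  res <- permanova(d, g, exhaustive = TRUE)
  vg <- vegan::adonis2(d ~ g, permutations = 999)
  expect_equal(res$pseudo_F, vg$F[1], tolerance = 1e-10)
  expect_equal(res$n_permutations, choose(6, 3))
  # sampled p agrees with the exhaustive exceedance within Monte-Carlo error
  res2 <- permanova(d, g, n_permutations = 9999, seed = 3)
  expect_lt(abs(res2$p_value - res$p_value),
            3 * sqrt(res$p_value * (1 - res$p_value) / 9999) + 2e-4)
})

test_that("PERMANOVA handles the no-structure degenerate case", {
  d <- matrix(1, 6, 6); diag(d) <- 0
  res <- permanova(d, rep(c("a", "b"), each = 3), exhaustive = TRUE)
  expect_equal(res$p_value, 1)
  expect_error(permanova(d[1:5, 1:6], rep("a", 6), 99), "square")
  expect_error(permanova(d, rep("a", 6), 99), "2 groups")
})

test_that("pathway aggregation takes max over copies, mean over reactions", {
  counts <- matrix(c(3, 7, 2, 4), 1, 4,
                   dimnames = list("s1", c("gA1", "gA2", "gB", "gC")))
  pmap <- data.frame(gene = c("gA1", "gA2", "gB", "gC"),
                     reaction = c("R1", "R1", "R2", "R3"),
                     pathway = c("P1", "P1", "P1", "P2"))
  agg <- pathway_aggregate(counts, pmap)
  expect_equal(agg["s1", "P1"], mean(c(max(3, 7), 2)))  # copies {3,7} -> 7
  expect_equal(agg["s1", "P2"], 4)                      # pass-through
  pmap2 <- data.frame(gene = c("gB", "gC"), reaction = c("R2", "R3"),
                      pathway = c("P1", "P1"))
  expect_equal(pathway_aggregate(counts, pmap2)["s1", "P1"], 3)  # mean {2,4}
  expect_error(pathway_aggregate(counts,
                                 data.frame(gene = "zz", reaction = "R",
                                            pathway = "P")), "matches")
})

test_that("feature-table constructor validates its indices", {
  counts <- matrix(1, 2, 2, dimnames = list(c("s1", "s2"), c("f1", "f2")))
  expect_error(feature_table(counts - 5), "nonnegative")
  expect_error(feature_table(counts,
                             annotations = data.frame(row.names = "f9",
                                                      x = 1)),
               "annotation")
  expect_error(feature_table(counts, lengths = c(f1 = 100, f2 = -1)),
               "positive")
  expect_error(feature_table(unname(counts)), "dimnames|rownames")
})
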