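# Compositional microbiome statistics downstream of count tables: RPK
# normalization, reference-frame log-ratios, Wilcoxon group tests,
# CLR/Aitchison machinery, robust-CLR ordination with matrix completion,
# permutation PERMANOVA, and pathway aggregation.

#' Construct a feature table
#'
#' Samples x features count (or normalized) matrix with optional feature
#' annotations, feature lengths (bp, for RPK) and sample metadata.
#'
#' @param counts Numeric samples x features matrix, no negative entries;
#'   dimnames required.
#' @param annotations Optional data frame, one row per feature (rownames =
#'   feature ids), e.g. taxonomy labels or gene symbols.
#' @param lengths Optional named numeric vector of feature lengths in bp.
#' @param metadata Optional data frame, one row per sample (rownames =
#'   sample ids), e.g. group labels.
#' @return Object of class `"feature_table"`.
#' @export
feature_table <- function(counts, annotations = NULL, lengths = NULL,
                          metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and feature colnames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!is.null(annotations)) {
    if (!setequal(rownames(annotations), colnames(counts)))
      stop("annotation rownames must match count columns")
    annotations <- annotations[colnames(counts), , drop = FALSE]
  }
  if (!is.null(lengths)) {
    if (!setequal(names(lengths), colnames(counts)))
      stop("length names must match count columns")
    lengths <- lengths[colnames(counts)]
    if (any(lengths <= 0)) stop("feature lengths must be positive")
  }
  if (!is.null(metadata)) {
    if (!setequal(rownames(metadata), rownames(counts)))
      stop("metadata rownames must match count rows")
    metadata <- metadata[rownames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, annotations = annotations,
                 lengths = lengths, metadata = metadata),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature table: %d samples x %d features%s%s\n",
              nrow(x$counts), ncol(x$counts),
              if (!is.null(x$lengths)) ", with lengths" else "",
              if (!is.null(x$metadata)) ", with metadata" else ""))
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "feature_table")) x$counts else as.matrix(x)
}

#' Reads-per-kilobase normalization
#'
#' Divides each feature's counts by its length in kilobases; annotations
#' and metadata are preserved.
#'
#' @param table A [feature_table()] with lengths.
#' @return The RPK-normalized `"feature_table"`.
#' @examples
#' ft <- feature_table(matrix(500, 1, 1, dimnames = list("s1", "g1")),
#'                     lengths = c(g1 = 2000))
#' rpk_normalize(ft)$counts
#' @export
rpk_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$lengths))
    stop("RPK normalization needs feature lengths")
  table$counts <- sweep(table$counts, 2, table$lengths / 1000, "/")
  table
}

#' Select feature ids by annotation value
#'
#' @param table A [feature_table()] with annotations.
#' @param column Annotation column name.
#' @param value Value(s) to match.
#' @return Character vector of feature ids.
#' @export
select_features <- function(table, column, value) {
  stopifnot(inherits(table, "feature_table"), !is.null(table$annotations))
  if (!column %in% names(table$annotations))
    stop("no annotation column '", column, "'")
  colnames(table$counts)[table$annotations[[column]] %in% value]
}

#' Reference-frame log-ratio
#'
#' Per-sample natural log of the ratio of summed numerator counts to summed
#' denominator counts (e.g. Bacteroidetes taxa over Enterococcaceae taxa,
#' or a gene of interest over the rpoA housekeeping reference). The
#' statistic is invariant to per-sample sequencing depth. With
#' `pseudocount = 0` (default), samples whose numerator or denominator
#' aggregate is zero are excluded and reported, never silently dropped.
#'
#' @param table A [feature_table()] or samples x features matrix.
#' @param numerator,denominator Character vectors of feature ids; must be
#'   non-empty and disjoint unless `allow_overlap`.
#' @param pseudocount Nonnegative value added to each count before
#'   aggregation (breaks exact depth invariance; 0 keeps the exclusion
#'   policy instead).
#' @param allow_overlap Permit overlapping sets (e.g. numerator inside
#'   denominator).
#' @return Object of class `"log_ratio_series"`: data frame with columns
#'   `sample` and `value`, with excluded samples in
#'   `attr(, "excluded_samples")`.
#' @export
log_ratio <- function(table, numerator, denominator, pseudocount = 0,
                      allow_overlap = FALSE) {
  counts <- as_count_matrix(table)
  if (!length(numerator) || !length(denominator))
    stop("numerator and denominator sets must be non-empty")
  if (!allow_overlap && length(intersect(numerator, denominator)))
    stop("numerator and denominator sets overlap")
  missing <- setdiff(c(numerator, denominator), colnames(counts))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  num <- rowSums(counts[, numerator, drop = FALSE] + pseudocount)
  den <- rowSums(counts[, denominator, drop = FALSE] + pseudocount)
  ok <- num > 0 & den > 0
  out <- data.frame(sample = rownames(counts)[ok],
                    value = log(num[ok] / den[ok]), row.names = NULL)
  structure(out, class = c("log_ratio_series", "data.frame"),
            numerator_set = numerator, denominator_set = denominator,
            excluded_samples = rownames(counts)[!ok],
            pseudocount = pseudocount)
}

#' @export
print.log_ratio_series <- function(x, ...) {
  cat(sprintf("log-ratio series (%d numerator / %d denominator features)\n",
              length(attr(x, "numerator_set")),
              length(attr(x, "denominator_set"))))
  print.data.frame(x, row.names = FALSE)
  exc <- attr(x, "excluded_samples")
  if (length(exc))
    cat("excluded (zero aggregate):", paste(exc, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise two-sided Wilcoxon rank-sum group tests
#'
#' Compares a numeric statistic (typically a [log_ratio()] series or an
#' SCFA concentration column) between every pair of groups with the
#' two-sided Wilcoxon rank-sum test: exact when the combined sample size is
#' at most 20 and there are no ties, normal approximation with tie and
#' continuity correction otherwise. P values are adjusted across the group
#' pairs, by Benjamini-Hochberg by default; `adjust = "tukey"` instead
#' reports Tukey HSD adjusted p values from a one-way ANOVA on the same
#' values (a literal reading of "Wilcoxon with Tukey HSD post hoc", offered
#' as an alternative because that printed pairing is not a standard
#' procedure).
#'
#' @param x Numeric vector (named by sample) or a `"log_ratio_series"`.
#' @param groups Group labels: a factor/character vector aligned with `x`,
#'   or named by sample.
#' @param adjust Multiplicity adjustment: `"BH"` (default), `"holm"`,
#'   `"bonferroni"`, `"none"`, or `"tukey"`.
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `statistic` (Wilcoxon W), `p_value`, `p_adjusted`.
#' @export
group_test <- function(x, groups, adjust = c("BH", "holm", "bonferroni",
                                             "none", "tukey")) {
  adjust <- match.arg(adjust)
  if (inherits(x, "log_ratio_series")) {
    vals <- stats::setNames(x$value, x$sample)
  } else vals <- x
  if (!is.null(names(vals)) && !is.null(names(groups)))
    groups <- groups[names(vals)]
  else if (!is.null(names(vals)) && is.null(names(groups)) &&
           length(groups) != length(vals))
    stop("cannot align groups with values")
  groups <- as.factor(as.vector(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("need at least 2 samples per group")
  pairs <- utils::combn(levels(groups), 2L)
  res <- apply(pairs, 2L, function(pr) {
    a <- vals[groups == pr[1]]
    b <- vals[groups == pr[2]]
    exact <- (length(a) + length(b)) <= 20L &&
      !anyDuplicated(c(a, b))
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                             correct = TRUE)
    p <- wt$p.value
    if (!is.finite(p)) p <- 1  # completely tied data carry no evidence
    c(statistic = unname(wt$statistic), p_value = p)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = unname(res["statistic", ]),
                    p_value = unname(res["p_value", ]),
                    row.names = NULL)
  if (adjust == "tukey") {
    fit <- stats::aov(vals ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    key <- paste(out$group2, out$group1, sep = "-")
    key2 <- paste(out$group1, out$group2, sep = "-")
    idx <- ifelse(key %in% rownames(tk), key, key2)
    out$p_adjusted <- tk[idx, "p adj"]
  } else {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  }
  attr(out, "adjust") <- adjust
  out
}

#' Centered log-ratio transform
#'
#' @param x Samples x features matrix (or [feature_table()]).
#' @param pseudocount Added to every entry before logging; must be positive
#'   unless all entries already are.
#' @return Samples x features matrix of CLR values (rows centered).
#' @export
clr_transform <- function(x, pseudocount = 1) {
  m <- as_count_matrix(x) + pseudocount
  if (any(m <= 0)) stop("need pseudocount > 0 or all-positive values")
  lm <- log(m)
  sweep(lm, 1, rowMeans(lm))
}

#' Aitchison distance matrix
#'
#' Euclidean distance between CLR-transformed compositions; scale-invariant
#' (per-sample depth cancels) and perturbation-invariant.
#'
#' @inheritParams clr_transform
#' @return A `stats::dist` object over samples.
#' @export
aitchison_distance <- function(x, pseudocount = 1) {
  stats::dist(clr_transform(x, pseudocount))
}

# robust CLR: log of nonzero entries, zeros as missing; centered per sample
# then per feature over the observed entries
rclr_transform <- function(counts) {
  m <- as_count_matrix(counts)
  lm <- log(m)
  lm[!is.finite(lm)] <- NA
  lm <- sweep(lm, 1, rowMeans(lm, na.rm = TRUE))
  sweep(lm, 2, colMeans(lm, na.rm = TRUE))
}

#' Robust-CLR ordination with low-rank matrix completion
#'
#' A compositional biplot ordination: robust-CLR transform (zeros treated
#' as missing), iterative rank-`rank` SVD completion of the missing cells,
#' and a final truncated SVD. On a zero-free table the completion is a
#' no-op and the result coincides with ordinary CLR principal component
#' analysis. This is a deliberately simple stand-in for OptSpace-based
#' robust Aitchison PCA: same transform and the same low-rank idea, judged
#' structurally (group separation), not coordinate-for-coordinate.
#'
#' @param table A [feature_table()] or samples x features matrix.
#' @param rank Number of ordination axes (>= 1, < min(dim)).
#' @param max_iter,tol Completion iteration controls.
#' @return Object of class `"ordination"`: `scores` (samples x rank),
#'   `loadings` (features x rank), `proportion_explained`.
#' @export
ordinate <- function(table, rank = 2L, max_iter = 200L, tol = 1e-8) {
  X <- rclr_transform(table)
  if (rank < 1L || rank >= min(dim(X)))
    stop("rank must be in [1, min(n_samples, n_features) - 1]")
  miss <- is.na(X)
  X[miss] <- 0
  for (it in seq_len(max_iter)) {
    s <- svd(X, nu = rank, nv = rank)
    Xr <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    delta <- max(abs(X[miss] - Xr[miss]), 0)
    X[miss] <- Xr[miss]
    if (!any(miss) || delta < tol) break
  }
  s <- svd(X)
  d <- s$d[seq_len(rank)]
  scores <- s$u[, seq_len(rank), drop = FALSE] %*% diag(d, rank)
  loadings <- s$v[, seq_len(rank), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive per axis
  for (k in seq_len(rank)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(rank)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(rank)))
  structure(list(scores = scores, loadings = loadings,
                 proportion_explained = d^2 / sum(s$d^2)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d axes; proportion explained %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$proportion_explained),
                    collapse = ", ")))
  invisible(x)
}

permanova_F <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  a <- length(lev)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ssa <- sst - ssw
  (ssa / (a - 1)) / (ssw / (n - a))
}

#' Permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a distance matrix: pseudo-F from among- vs
#' within-group sums of squared distances, with a permutation p value
#' `(1 + #{permuted F >= observed F}) / (n_permutations + 1)`. With
#' `exhaustive = TRUE` (two groups only) every distinct assignment of the
#' group sizes to samples is enumerated and the p value is the exact
#' exceedance fraction.
#'
#' @param d A `stats::dist` or square symmetric distance matrix.
#' @param groups Group labels (>= 2 groups).
#' @param n_permutations Number of random label permutations (default 999).
#' @param seed Seed for the permutations.
#' @param exhaustive Enumerate all distinct two-group assignments instead
#'   of sampling.
#' @return Object of class `"permanova_result"`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`, `method`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L,
                      exhaustive = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("'d' must be a square symmetric distance matrix")
  groups <- as.vector(groups)
  if (length(groups) != nrow(d)) stop("groups length must match distances")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  d2 <- d^2
  f_obs <- permanova_F(d2, groups)
  if (exhaustive) {
    lev <- unique(groups)
    if (length(lev) != 2L)
      stop("exhaustive enumeration implemented for 2 groups")
    n1 <- sum(groups == lev[1])
    combos <- utils::combn(length(groups), n1)
    f_all <- apply(combos, 2, function(idx) {
      g <- rep(lev[2], length(groups))
      g[idx] <- lev[1]
      permanova_F(d2, g)
    })
    p <- mean(f_all >= f_obs - 1e-12)
    n_eff <- ncol(combos)
  } else {
    f_perm <- withr::with_seed(seed, vapply(seq_len(n_permutations),
      function(i) permanova_F(d2, sample(groups)), numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_permutations + 1)
    n_eff <- n_permutations
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = n_eff,
                 seed = if (exhaustive) NA_integer_ else seed,
                 method = if (exhaustive) "exhaustive" else "sampled"),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations): pseudo-F = %.3f, p = %.4g\n",
              x$method, x$n_permutations, x$pseudo_F, x$p_value))
  invisible(x)
}

#' Aggregate gene-level values to pathways
#'
#' Reproduces the two-step rule used for pathway abundance and expression:
#' within each reaction, multi-copy genes are collapsed by taking the most
#' abundant (maximum) copy per sample; each pathway is then the average of
#' its reactions.
#'
#' @param table A [feature_table()] or samples x genes matrix (counts or
#'   RPK values).
#' @param pathway_map Data frame with columns `gene`, `reaction`,
#'   `pathway`.
#' @return Samples x pathways matrix.
#' @export
pathway_aggregate <- function(table, pathway_map) {
  counts <- as_count_matrix(table)
  stopifnot(all(c("gene", "reaction", "pathway") %in% names(pathway_map)))
  map <- pathway_map[pathway_map$gene %in% colnames(counts), ]
  if (!nrow(map)) stop("no pathway_map gene matches the table")
  rxn_ids <- unique(map[, c("reaction", "pathway")])
  rxn_vals <- sapply(rxn_ids$reaction, function(r) {
    genes <- map$gene[map$reaction == r]
    apply(counts[, genes, drop = FALSE], 1, max)
  })
  if (is.null(dim(rxn_vals)))
    rxn_vals <- matrix(rxn_vals, nrow = nrow(counts),
                       dimnames = list(rownames(counts), rxn_ids$reaction))
  out <- sapply(unique(rxn_ids$pathway), function(p) {
    rxns <- rxn_ids$reaction[rxn_ids$pathway == p]
    rowMeans(rxn_vals[, rxns, drop = FALSE])
  })
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(counts),
                  dimnames = list(rownames(counts), unique(rxn_ids$pathway)))
  out
}
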