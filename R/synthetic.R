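# Seeded generators for every input the pipeline consumes: MID tables,
# community count tables (abundance + expression + metadata), SCFA
# concentration tables, and desk-scale metabolic-model fixtures. All
# generators are pure functions of their spec including the seed.

#' Specification for a synthetic MID dataset
#'
#' @param formula Analyte formula (default the palmitate C16 carbon
#'   skeleton).
#' @param n_units Condensed precursor units (8 acetyl-CoA per palmitate).
#' @param D_true,g_true Planted ISA parameters, in \[0, 1\].
#' @param noise_sd Additive Gaussian noise sd on the MID fractions
#'   (per-channel measurement error; the noisy vector is clipped at 0 and
#'   renormalized).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param unit A [precursor_unit()].
#' @return Object of class `"mid_sim_spec"`.
#' @export
mid_sim_spec <- function(formula = "C16", n_units = 8L, D_true = 0.27,
                         g_true = 0.6, noise_sd = 0.003, n_samples = 6L,
                         seed = 1L, unit = precursor_unit()) {
  stopifnot(D_true >= 0, D_true <= 1, g_true >= 0, g_true <= 1,
            noise_sd >= 0, n_units >= 1, n_samples >= 1)
  structure(list(formula = formula, n_units = as.integer(n_units),
                 D_true = D_true, g_true = g_true, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 unit = unit),
            class = "mid_sim_spec")
}

#' Generate a table of per-sample mass isotopomer distributions
#'
#' Each sample is the forward-model MID at the planted `(D_true, g_true)`
#' plus additive Gaussian noise, clipped at zero and renormalized. With
#' `noise_sd = 0` every row equals [simulate_analyte_mid()] exactly.
#'
#' @param spec A [mid_sim_spec()].
#' @return Data frame with columns `sample`, `tissue`, `M0`..`Mn`.
#' @examples
#' generate_mid_dataset(mid_sim_spec(n_samples = 3, noise_sd = 0))
#' @export
generate_mid_dataset <- function(spec) {
  stopifnot(inherits(spec, "mid_sim_spec"))
  base <- simulate_analyte_mid(spec$D_true, spec$g_true, spec$unit,
                               spec$n_units, spec$formula)
  n <- length(base)
  rows <- withr::with_seed(spec$seed, lapply(seq_len(spec$n_samples),
    function(i) base + stats::rnorm(n, 0, spec$noise_sd)))
  frac_neg <- mean(unlist(rows) < 0)
  if (frac_neg > 0.5)
    stop("noise_sd = ", spec$noise_sd, " drives ", round(100 * frac_neg),
         "% of MID entries below zero; use a smaller noise_sd")
  mids <- t(vapply(rows, function(r) { r <- pmax(r, 0); r / sum(r) },
                   numeric(n)))
  colnames(mids) <- names(base)
  data.frame(sample = paste0("s", seq_len(spec$n_samples)),
             tissue = "synthetic", mids)
}

#' Default taxon panel for the community simulator
#'
#' Twelve genome bins: four Bacteroidetes, two Enterococcaceae, six other
#' commensals, with baseline natural-log relative abundances typical of
#' mouse cecum communities.
#'
#' @return Data frame with columns `name`, `label`, `base_log_abundance`.
#' @export
default_taxa <- function() {
  data.frame(
    name = c("Bacteroides_uniformis", "Bacteroides_fragilis",
             "Prevotella_copri", "Parabacteroides_distasonis",
             "Enterococcus_faecalis", "Enterococcus_faecium",
             "Lactobacillus_johnsonii", "Clostridium_sp",
             "Faecalibaculum_rodentium", "Akkermansia_muciniphila",
             "Dubosiella_newyorkensis", "Escherichia_coli"),
    label = c(rep("Bacteroidetes", 4), rep("Enterococcaceae", 2),
              "Firmicutes", "Firmicutes", "Firmicutes", "Verrucomicrobia",
              "Firmicutes", "Proteobacteria"),
    base_log_abundance = c(0.9, 0.6, 0.2, 0.0, -0.6, -0.9,
                           0.4, 0.1, -0.2, -0.8, -0.3, -1.2))
}

default_effects <- function(taxa) {
  stats::setNames(ifelse(taxa$label == "Bacteroidetes", 1.5,
                         ifelse(taxa$label == "Enterococcaceae", -1.5, 0)),
                  taxa$name)
}

#' Specification for a synthetic two-group community dataset
#'
#' @param n_per_group Samples per condition (default 7, i.e. 14 total).
#' @param taxa Data frame as [default_taxa()].
#' @param effects Named per-taxon log2 fold change (ethanol vs control);
#'   default +1.5 for Bacteroidetes taxa, -1.5 for Enterococcaceae, 0
#'   elsewhere.
#' @param depth_range Sequencing-depth interval (counts per sample).
#' @param dispersion Natural-log sd of per-sample per-taxon abundance
#'   variation.
#' @param seed Integer seed.
#' @return Object of class `"community_sim_spec"`.
#' @export
community_sim_spec <- function(n_per_group = 7L, taxa = default_taxa(),
                               effects = default_effects(taxa),
                               depth_range = c(20000, 50000),
                               dispersion = 0.5, seed = 1L) {
  stopifnot(n_per_group >= 2, all(depth_range > 0), dispersion > 0,
            all(names(effects) %in% taxa$name) || is.null(names(effects)))
  if (is.null(names(effects))) names(effects) <- taxa$name
  structure(list(n_per_group = as.integer(n_per_group), taxa = taxa,
                 effects = effects, depth_range = depth_range,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "community_sim_spec")
}

# genes carried by every bin in the expression table: the rpoA reference
# frame (1 kb by convention), AMP acetyl-CoA synthetase (planted
# upregulation in the ethanol group), and alcohol dehydrogenase (null)
community_genes <- function() {
  data.frame(gene = c("rpoA", "acs", "adh"),
             length = c(1000L, 1950L, 1040L),
             base_log_expression = c(0.5, 0, 0),
             log2fc_ethanol = c(0, 2, 0))
}

#' Generate synthetic bin-abundance and gene-expression count tables
#'
#' Counts are drawn as log-normal latent abundances (baseline + planted
#' group effect + per-sample noise) passed through multinomial sampling at
#' a per-sample depth, reproducing the compositional, zero-inflated
#' structure of real bin tables. The expression table carries, per bin, the
#' `rpoA` housekeeping gene (no planted effect), `acs` (AMP acetyl-CoA
#' synthetase; planted upregulation in the ethanol group) and `adh`
#' (alcohol dehydrogenase; no planted effect), each with a gene length so
#' RPK normalization is exercised.
#'
#' @param spec A [community_sim_spec()].
#' @return List with elements `abundance` and `expression` (both
#'   [feature_table()]s) and `metadata` (data frame of sample and group).
#' @examples
#' tabs <- generate_count_tables(community_sim_spec(seed = 3))
#' tabs$metadata
#' @export
generate_count_tables <- function(spec) {
  stopifnot(inherits(spec, "community_sim_spec"))
  taxa <- spec$taxa
  for (lab in c("Bacteroidetes", "Enterococcaceae"))
    if (sum(taxa$label == lab) < 2L)
      stop("need at least 2 taxa labelled '", lab, "' for the group contrast")
  n <- 2L * spec$n_per_group
  group <- rep(c("control", "ethanol"), each = spec$n_per_group)
  samples <- paste0(substr(group, 1, 3), rep(seq_len(spec$n_per_group), 2))
  effects <- spec$effects[taxa$name]
  effects[is.na(effects)] <- 0
  genes <- community_genes()

  withr::with_seed(spec$seed, {
    depths <- sample(seq(spec$depth_range[1], spec$depth_range[2]), n,
                     replace = TRUE)
    abundance <- matrix(0L, n, nrow(taxa),
                        dimnames = list(samples, taxa$name))
    latents <- matrix(0, n, nrow(taxa))
    for (i in seq_len(n)) {
      lat <- taxa$base_log_abundance +
        (group[i] == "ethanol") * effects * log(2) +
        stats::rnorm(nrow(taxa), 0, spec$dispersion)
      latents[i, ] <- lat
      p <- exp(lat) / sum(exp(lat))
      abundance[i, ] <- stats::rmultinom(1, depths[i], p)
    }
    feat <- as.vector(outer(genes$gene, taxa$name,
                            function(g, t) paste(t, g, sep = "|")))
    expr <- matrix(0L, n, length(feat), dimnames = list(samples, feat))
    for (i in seq_len(n)) {
      lat <- as.vector(outer(seq_len(nrow(genes)), seq_len(nrow(taxa)),
        function(gi, ti) latents[i, ti] + genes$base_log_expression[gi] +
          (group[i] == "ethanol") * genes$log2fc_ethanol[gi] * log(2))) +
        stats::rnorm(length(feat), 0, spec$dispersion / 2)
      p <- exp(lat) / sum(exp(lat))
      expr[i, ] <- stats::rmultinom(1, depths[i], p)
    }
  })

  ab_annot <- data.frame(feature = taxa$name, label = taxa$label,
                         row.names = taxa$name)
  ex_annot <- data.frame(
    feature = colnames(expr),
    taxon = rep(taxa$name, each = nrow(genes)),
    label = rep(taxa$label, each = nrow(genes)),
    gene = rep(genes$gene, nrow(taxa)),
    row.names = colnames(expr))
  ex_len <- stats::setNames(rep(genes$length, nrow(taxa)), colnames(expr))
  metadata <- data.frame(sample = samples, group = group,
                         row.names = samples)
  list(abundance = feature_table(abundance, annotations = ab_annot,
                                 metadata = metadata),
       expression = feature_table(expr, annotations = ex_annot,
                                  lengths = ex_len, metadata = metadata),
       metadata = metadata)
}

#' Generate a synthetic SCFA concentration table
#'
#' Eight short-chain fatty acids with log-normal measurement variation;
#' acetate carries a planted group-mean fold change (default the 4x serum
#' acetate increase in ethanol-fed animals), all others are null.
#'
#' @param n_per_group Samples per group (warning if 1: no test possible).
#' @param acetate_fold Planted acetate group-mean ratio (> 0).
#' @param noise_cv Coefficient of variation of each measurement.
#' @param seed Integer seed.
#' @return Data frame: `sample`, `group`, then one column per analyte
#'   (concentrations, arbitrary micromolar-scale units).
#' @examples
#' head(generate_scfa_table(seed = 2))
#' @export
generate_scfa_table <- function(n_per_group = 7L, acetate_fold = 4,
                                noise_cv = 0.2, seed = 1L) {
  stopifnot(acetate_fold > 0, n_per_group >= 1, noise_cv >= 0)
  if (n_per_group < 2L)
    warning("n_per_group = 1: group tests are impossible on this table")
  base <- c(acetate = 200, butyrate = 15, caproate = 2, heptanoate = 1,
            isobutyrate = 5, isovalerate = 5, propionate = 20, valerate = 3)
  n <- 2L * n_per_group
  group <- rep(c("control", "ethanol"), each = n_per_group)
  sdlog <- sqrt(log(1 + noise_cv^2))
  conc <- withr::with_seed(seed, {
    m <- sapply(names(base), function(a) {
      mu <- log(base[a]) - sdlog^2 / 2 +
        (a == "acetate") * (group == "ethanol") * log(acetate_fold)
      stats::rlnorm(n, mu, sdlog)
    })
    m
  })
  data.frame(sample = paste0(substr(group, 1, 3), rep(seq_len(n_per_group), 2)),
             group = group, conc)
}

#' Generate a desk-scale metabolic-model fixture
#'
#' Three templates with known analytic behaviour:
#' \describe{
#'   \item{`linear_chain`}{one substrate taken up at bound `b` and
#'     converted to biomass precursor at yield `y`; optimum `b * y`.}
#'   \item{`two_substrate`}{two substrates feeding one precursor with a
#'     capacity bottleneck on one route; optimum known in closed form and
#'     checkable by LP vertex enumeration.}
#'   \item{`cometabolism`}{a fermenter that grows on glycerol but not on
#'     acetate alone — acetate enters only through an ATP-consuming
#'     ACS-like reaction to acetyl-CoA, and the network has no route from
#'     acetyl-CoA alone to the phosphoenolpyruvate and ATP that biomass
#'     also requires — yet grows strictly faster on glycerol + acetate.
#'     Under the default 100 mmol C/gDW/hr cap the analytic optima are
#'     G/90 on glycerol alone and 3G/210 with acetate (G = 100/3 the molar
#'     glycerol bound).}
#' }
#'
#' @param template One of `"linear_chain"`, `"two_substrate"`,
#'   `"cometabolism"`.
#' @param perturbations Optional named list of `c(lower, upper)` bound
#'   overrides, keyed by reaction id.
#' @return List with the `"metabolic_model"` (`model`), the stored
#'   closed-form `optimum` under the fixture's shipped bounds (`NA` for
#'   `cometabolism`, whose optima depend on the applied medium), and a
#'   `notes` string.
#' @examples
#' generate_toy_gem("linear_chain")$optimum
#' @export
generate_toy_gem <- function(template = c("linear_chain", "two_substrate",
                                          "cometabolism"),
                             perturbations = NULL) {
  templates <- c("linear_chain", "two_substrate", "cometabolism")
  if (!is.character(template) || !template[1] %in% templates)
    stop("unknown template '", template[1], "'; available: ",
         paste(templates, collapse = ", "))
  template <- match.arg(template)
  rx <- function(st, lb = 0, ub = DEFAULT_BOUND)
    list(metabolites = st, lower_bound = lb, upper_bound = ub)
  out <- switch(template,
    linear_chain = {
      mets <- data.frame(id = c("glc", "x"),
                         formula = c("C6H12O6", NA),
                         compartment = "c")
      rxns <- list(
        EX_glc = rx(c(glc = -1), lb = -10),
        CONV = rx(c(glc = -1, x = 0.5)),
        BIOMASS = rx(c(x = -1)))
      list(model = metabolic_model(mets, rxns, "BIOMASS", "linear_chain"),
           optimum = 10 * 0.5,
           notes = "uptake bound 10, yield 0.5 => growth 5")
    },
    two_substrate = {
      mets <- data.frame(id = c("a", "b", "x"),
                         formula = c("C6H12O6", "C3H8O3", NA),
                         compartment = "c")
      rxns <- list(
        EX_a = rx(c(a = -1), lb = -10),
        EX_b = rx(c(b = -1), lb = -5),
        CONVA = rx(c(a = -1, x = 1), ub = 8),
        CONVB = rx(c(b = -1, x = 2)),
        BIOMASS = rx(c(x = -1)))
      list(model = metabolic_model(mets, rxns, "BIOMASS", "two_substrate"),
           optimum = 8 * 1 + 5 * 2,
           notes = "CONVA capacity 8 caps substrate a; optimum 8 + 10 = 18")
    },
    cometabolism = {
      mets <- data.frame(
        id = c("glyc", "ac", "lac", "co2", "pep", "pyr", "accoa",
               "atp", "nadh"),
        formula = c("C3H8O3", "C2H3O2", "C3H5O3", "CO2", "C3H2O6P",
                    "C3H3O3", "C23H34N7O17P3S", "C10H12N5O13P3",
                    "C21H27N7O14P2"),
        compartment = "c")
      rxns <- list(
        EX_glyc = rx(c(glyc = -1)),
        EX_ac = rx(c(ac = -1)),
        EX_lac = rx(c(lac = -1)),
        EX_co2 = rx(c(co2 = -1)),
        GLYC2PEP = rx(c(glyc = -1, pep = 1)),
        PK = rx(c(pep = -1, pyr = 1, atp = 2)),
        PDH = rx(c(pyr = -1, accoa = 1, nadh = 1, co2 = 1)),
        LDH = rx(c(pyr = -1, nadh = -1, lac = 1)),
        ACS = rx(c(ac = -1, atp = -2, accoa = 1)),
        ATPM = rx(c(atp = -1)),
        BIOMASS = rx(c(accoa = -30, pep = -30, atp = -60)))
      list(model = metabolic_model(mets, rxns, "BIOMASS", "cometabolism"),
           optimum = NA_real_,
           notes = paste("no growth on acetate alone (ACS needs ATP and",
                         "biomass needs PEP, both glycerol-derived);",
                         "acetate strictly boosts growth on glycerol"))
    })
  if (!is.null(perturbations)) {
    for (rid in names(perturbations)) {
      if (!rid %in% names(out$model$reactions))
        stop("perturbation targets unknown reaction '", rid, "'")
      out$model$reactions[[rid]]$lower_bound <- perturbations[[rid]][1]
      out$model$reactions[[rid]]$upper_bound <- perturbations[[rid]][2]
    }
    validate_model(out$model)
    out$optimum <- NA_real_  # stored optimum holds for shipped bounds only
  }
  out
}
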