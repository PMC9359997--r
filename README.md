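# acetotrace

Tools for studying how gut microbial communities respond to host ethanol
consumption **through acetate** rather than by metabolizing ethanol
directly. The liver oxidizes most ingested ethanol to acetate; gut
microbes — Bacteroidetes in particular — can scavenge that acetate,
activating it to acetyl-CoA via AMP-forming acetyl-CoA synthetase (the
"acetate switch" toward dissimilation). `acetotrace` implements the four
quantitative strands needed to test this picture, starting from count
tables, MID tables and metabolic models (no raw-read processing):

- **Isotopomer spectral analysis (ISA).** Palmitate is the condensation
  of 8 acetyl-CoA units. From a measured mass isotopomer distribution
  (MID) the package fits the two ISA parameters by bounded least squares
  against the forward model
  `MID(D, g) = g · Poly₈(D) + (1 − g) · Nat`:
  `D`, the fraction of the lipogenic acetyl-CoA pool carrying one tracer
  ¹³C, and `g`, the fraction of the analyte newly synthesized during
  labelling. Exact convolution arithmetic, multi-start optimization with
  a profile polish, bootstrap intervals, and an explicit
  "unidentifiable" flag for information-free inputs.
- **FBA carbon-source screen.** Flux balance analysis
  (max biomass s.t. `S v = 0`, bounds) on COBRA-JSON / SBML-FBC models,
  with the one-at-a-time screen: each carbon source capped at
  100 mmol C/gDW/hr (molar bound = 100 / carbon count), run with and
  without acetate; growth < 0.001 hr⁻¹ means no growth, an increase
  ≥ 0.0001 hr⁻¹ means an acetate effect.
- **Compositional statistics.** RPK normalization, reference-frame
  log-ratios (e.g. a gene against the rpoA housekeeping frame),
  pairwise exact Wilcoxon tests with BH adjustment, Aitchison distances,
  robust-CLR ordination with low-rank completion, permutation PERMANOVA
  (seeded or exhaustive), and pathway aggregation (max over gene copies,
  mean over reactions).
- **Thermodynamics.** `ΔG = ΔG°′ + RT ln Q` over an editable constants
  table, with strict-threshold feasibility classification — e.g. anoxic
  ethanol oxidation to acetate + 2 H₂ is endergonic at standard
  activities and worsens as hydrogen accumulates.
- **Synthetic data.** Seeded generators for every input: MID tables,
  two-group community abundance/expression tables (log-normal latents →
  multinomial counts, planted Bacteroidetes/Enterococcaceae and acs
  effects), SCFA tables with a planted 4× acetate fold, and toy
  metabolic models with closed-form optima.

## Worked example

```r
library(acetotrace)

## ISA: simulate a labelled palmitate MID table and fit it
mids <- generate_mid_dataset(mid_sim_spec(D_true = 0.27, g_true = 0.6,
                                          noise_sd = 0.003,
                                          n_samples = 3, seed = 7))
fit <- fit_isa(as.numeric(mids[1, -(1:2)]))
fit
#> Isotopomer spectral analysis fit
#>   D (precursor tracer fraction): 0.2722
#>   g (fraction newly synthesized): 0.5927
#>   RSS: 1.705e-04   status: ok
tracer_contribution_percent(fit)   # 27.2% of lipogenic acetyl-CoA from tracer
```

The fit recovers the planted parameters: about 27% of the lipogenic
acetyl-CoA pool is tracer-derived and about 59% of the palmitate pool
was newly synthesized during labelling.

```r
## FBA: screen carbon sources with and without acetate
scr <- cometabolism_screen(generate_toy_gem("cometabolism")$model,
                           c("glyc", "ac"))
scr
#> carbon-source screen (2 sources; no-growth < 0.001 /hr, effect >= 0.0001 /hr)
#>  carbon_source growth_without_acetate growth_with_acetate grows_without
#>             ac                0.00000             0.00000         FALSE
#>           glyc                0.37037             0.47619          TRUE
#>  grows_with acetate_effect
#>       FALSE          FALSE
#>        TRUE           TRUE
```

The fixture organism cannot grow on acetate alone (acetate entry costs
ATP and biomass also needs PEP, both glycerol-derived), but acetate
raises growth on glycerol by 0.106 hr⁻¹ — a co-metabolism effect.

```r
## Compositional statistics on a synthetic 7+7 community
tabs <- generate_count_tables(community_sim_spec(seed = 1))
permanova(aitchison_distance(tabs$abundance), tabs$metadata$group,
          999, seed = 1)
#> PERMANOVA (sampled, 999 permutations): pseudo-F = 12.184, p = 0.001

lr <- log_ratio(tabs$abundance,
                select_features(tabs$abundance, "label", "Bacteroidetes"),
                select_features(tabs$abundance, "label", "Enterococcaceae"),
                pseudocount = 1)
group_test(lr, setNames(tabs$metadata$group, tabs$metadata$sample))
#>    group1  group2 statistic      p_value   p_adjusted
#> 1 control ethanol         0 0.0005827506 0.0005827506
```

The planted community shift is detected both multivariately (pseudo-F =
12.2, p = 0.001) and by the Bacteroidetes/Enterococcaceae log-ratio
(exact Wilcoxon p = 0.00058).

```r
## Thermodynamics: anoxic ethanol oxidation to acetate
ethanol_oxidation_example()
#> ethanol + h2o -> acetate + h+ + 2 h2
#>   T = 310.15 K; dG0' = 7.92 kJ/mol; dG = 7.92 kJ/mol (unfavorable)
```

## Package layout

- `R/` — implementation (`isa`, `gem`/`fba`/`lp`, `compositional`,
  `thermo`, `synthetic` modules).
- `inst/extdata/gibbs_dg0f.tsv` — editable thermodynamic constants.
- `vignettes/acetotrace-methods.Rmd` — the models, conventions, defaults
  and limitations, in detail.
- `tests/testthat/` — unit, property and acceptance tests, including
  exhaustive-enumeration and vertex-enumeration oracles.
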