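---
title: "Methods: isotope tracing, co-metabolism screening and compositional statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope tracing, co-metabolism screening and compositional statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetotrace)
```

# The scientific problem

A host that drinks ethanol oxidizes most of it to acetate in the liver.
The question this package's machinery addresses is how the gut microbial
community responds: does it metabolize ethanol directly (via alcohol
dehydrogenase), or does it instead scavenge the resulting acetate,
activating it to acetyl-CoA through AMP-forming acetyl-CoA synthetase
(the "acetate switch" toward dissimilation)? Four quantitative strands
support that distinction, and each is one module here:

1. **Isotopomer spectral analysis (ISA)** of `[1-13C]`-labelled substrate
   incorporation into palmitate, quantifying how much of the lipogenic
   acetyl-CoA pool carries tracer carbon.
2. **Flux balance analysis (FBA)** on a genome-scale metabolic model,
   screening carbon sources one at a time with and without acetate to
   find co-metabolism partners (e.g. glycerol).
3. **Compositional statistics** on metagenomic bin-abundance and
   metatranscriptomic count tables: reference-frame log-ratios,
   Aitchison distances, robust-CLR ordination, PERMANOVA.
4. **Thermodynamic feasibility** of anaerobic conversions such as
   ethanol oxidation to acetate plus hydrogen.

All four run on synthetic data produced by the package's seeded
generators, so every property of the pipeline is testable without any
sequencing archive or instrument output.

# The ISA model

Palmitate (C16:0) is built by condensing 8 acetyl-CoA units. During a
labelling window, a fraction $D$ of the lipogenic acetyl-CoA pool derives
from the tracer; because oxidation of `[1-13C]` ethanol preserves the
labelled carbon into acetate C1, each tracer-derived unit carries exactly
one $^{13}$C at the tracer's isotopic purity (default 0.99). A fraction
$g$ of the measured palmitate pool was newly synthesized during the
window; the rest is pre-existing material at natural isotope abundance.

The forward model of the measured mass isotopomer distribution (MID) is

$$
\mathrm{MID}(D, g) \;=\; g \cdot \mathrm{Poly}_8(D) \;+\; (1-g)\cdot \mathrm{Nat},
$$

where $\mathrm{Poly}_8(D)$ convolves 8 independent unit distributions
(tracer-derived with probability $D$, natural otherwise) with the
natural-abundance distribution of any formula atoms outside the condensed
units, and $\mathrm{Nat}$ is the natural-abundance MID of the analyte.
All isotope bookkeeping is by exact discrete convolution of per-atom
nominal-mass-shift distributions; the implementation is verified against
exhaustive enumeration of all isotopic states to $10^{-12}$.

Two analyte conventions are supported, because chromatography measures
fatty acid methyl esters: the default C16 carbon skeleton, and a
full-formula mode (e.g. `C17H34O2`, including the derivatization methyl).
Which convention an upstream workflow used is rarely recorded, so both
are exposed and the choice is stored with the fit.

## Estimation

`fit_isa()` minimizes the residual sum of squares between the measured
and simulated MID over $(D, g) \in [0,1]^2$. The objective can be shallow
in $D$ when $g$ is small, so the optimizer uses 10 bounded L-BFGS-B runs
from a fixed-seed Latin hypercube, followed by a polish step that
exploits the model's exact linearity in $g$: for any $D$ the
least-squares $g$ has a closed form, and the profiled one-dimensional
objective is refined by golden-section search. This recovers noise-free
parameters to better than $10^{-6}$ across a $10\times10$ grid of
$(D, g) \in [0.05, 0.95]^2$ (checked in the test suite).

A fit against an information-free MID — one indistinguishable from
natural abundance — leaves $D$ meaningless; the fit is flagged
`status = "unidentifiable"` (flat objective profile in $D$, or $g$ at
zero) rather than reported silently. Optional residual-resampling
bootstrap intervals are available. No correction is applied for tracer
recycling through the TCA cycle; TCA intermediate enrichment is low in
the motivating setting and is reported descriptively there, not through
ISA — a documented limitation.

The headline scale conversion is `tracer_contribution_percent()`:
$100 \times D$ under the default pool-fraction convention, i.e. the
percentage of lipogenic acetyl-CoA (equivalently, of carbon in newly
synthesized fatty acid) arising from the tracer.

# FBA and the acetate co-metabolism screen

`fba()` maximizes the biomass objective over steady-state fluxes
($S v = 0$, bounds in mmol/gDW/hr) by linear programming. The package
carries its own dense two-phase simplex with Bland's anti-cycling rule:
exact on the desk-scale models it targets, deterministic in the objective
value, and validated against an independent vertex-enumeration oracle in
the tests. Only the objective value is used for classification — flux
vectors are reported but alternate optima are ubiquitous and never
compared.

`apply_medium()` encodes the screening medium convention: basal nutrients
(vitamins, minerals, ammonia, sulfide, phosphate) get unbounded influx;
each selected carbon source is capped at 100 mmol **C**/gDW/hr, i.e. a
molar bound of $100 / (\text{carbon count})$ — the division equalizes
carbon supply across sources, matching the "mmol C" unit (glycerol, C3,
gets 33.3 mmol/gDW/hr; acetate, C2, gets 50). All other carbon influxes
are closed; secretion stays open. The same cap rule is applied to acetate
when it is co-activated; both the cap and the rule are configurable since
the convention is a modelling choice.

`cometabolism_screen()` then runs each source alone and with acetate, and
classifies with the two stated thresholds: growth below 0.001 hr$^{-1}$
is *no growth*; an increase of at least 0.0001 hr$^{-1}$ upon acetate
activation is an *acetate effect*. Growth values are rounded to
$10^{-12}$ before comparison so solver noise cannot flip a
classification, and relaxation monotonicity (opening an exchange can
never lower the optimum) is asserted on every row.

The package bundles no genome-scale reconstruction; any COBRA-style JSON
or SBML L3/FBC model can be supplied. Desk-scale validation uses the
`cometabolism` fixture: an anaerobic fermenter whose acetate entry
requires ATP (ACS) and whose biomass also requires PEP, both obtainable
only from glycerol — so it cannot grow on acetate alone, grows on
glycerol at $G/90$ (with $G$ the molar glycerol bound), and grows at
$3G/210$ with acetate added, an analytic gain of $2G/630 \times 3$.
Reproducing a specific published organism's predictions requires that
organism's model as input.

# Compositional statistics

Sequencing counts are compositional: only ratios are identified. The
module therefore works in log-ratio space throughout.

- **RPK**: counts divided by feature length in kilobases, applied before
  expression comparisons. The synthetic expression tables attach real
  lengths (rpoA fixed at 1 kb by convention) so this step is exercised.
- **Reference-frame log-ratios** (`log_ratio()`): per sample,
  $\ln(\sum \text{numerator} / \sum \text{denominator})$ — e.g.
  Bacteroidetes taxa over Enterococcaceae taxa, or a gene of interest
  over the rpoA housekeeping frame. Depth-invariant by construction.
  With pseudocount 0, samples with a zero aggregate are excluded *and
  reported*; a pseudocount of 1 is the documented alternative for
  zero-laden tables (it trades exact depth invariance for completeness).
  Taxon sets are selected by annotation match (phylum, family, gene
  symbol), not by loading-based automatic selection, which is not
  reproducible from a figure.
- **Group tests** (`group_test()`): pairwise two-sided Wilcoxon rank-sum,
  exact for combined $n \le 20$ without ties (verified against full
  rank-permutation enumeration), normal approximation with tie and
  continuity correction otherwise. Multiplicity is Benjamini–Hochberg by
  default; "Wilcoxon with Tukey HSD post hoc" is not a standard pairing,
  so a Tukey HSD (on an ANOVA of the same values) is offered only as an
  explicit alternative flag rather than guessed at.
- **Aitchison distance**: Euclidean distance of CLR-transformed
  compositions, pseudocount 1 by default; scale- and
  perturbation-invariant to $10^{-12}$ (tested).
- **Ordination** (`ordinate()`): robust-CLR (zeros as missing, centered
  per sample then per observed feature) followed by iterative rank-$r$
  SVD completion and a truncated SVD. On a zero-free table this reduces
  exactly to CLR principal component analysis. It is a deliberately
  simple relative of OptSpace-based robust Aitchison PCA: judged
  structurally (planted two-group structure separates on axis 1; dense
  limit equals CLR-PCA), never coordinate-for-coordinate against another
  implementation. Axis signs are fixed deterministically
  (largest-magnitude loading positive).
- **PERMANOVA** (`permanova()`): one-factor pseudo-F from among- versus
  within-group sums of squared distances;
  $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm}+1)$ with 999 seeded
  permutations by default (a well-defined $p$ floor), or exhaustive
  enumeration of all distinct two-group assignments for small designs.
  The pseudo-F agrees with vegan's `adonis2` to $10^{-10}$ in the tests;
  the permutation machinery is in-package because the exhaustive mode
  and the seeded convention are part of the contract.
- **Pathway aggregation** (`pathway_aggregate()`): within a reaction,
  multi-copy genes collapse to the most abundant copy per sample; a
  pathway is the mean of its reactions.

# Thermodynamics

`delta_g0_prime()` is the stoichiometric sum of standard transformed
formation energies; `delta_g()` adds $RT \ln Q$ with $R = 8.314$ J/mol/K
and activities relative to standard state (gases as partial pressure / 1
bar; water fixed at activity 1). `feasibility()` is strict:
$\Delta G = 0$ is equilibrium, not a driving force, so the boundary
classifies as unfavorable. The shipped constants table
(`gibbs_dg0f.tsv`) is an illustrative Alberty-style set at pH 7 and
298.15 K, editable per entry, and the temperature used in $RT \ln Q$ is
the user's; the module's contract is the calculation, not a specific
constants provenance. The worked example — ethanol + H$_2$O $\to$
acetate$^-$ + H$^+$ + 2 H$_2$ — is endergonic (+7.9 kJ/mol at unit
activities with the shipped constants) and hydrogen accumulation only
drives it further uphill, consistent with the qualitative claim that
anoxic ethanol oxidation to acetate is unfavorable; each ten-fold rise in
a single product activity adds $RT\ln 10 \approx 5.94$ kJ/mol at 310.15
K.

# What the synthetic generators emulate

The generators define the study conditions under which all properties are
checked; their defaults were chosen once, as realistic values, and the
tests are run at those values.

- **MID tables**: forward-model MIDs plus additive Gaussian per-channel
  noise (sd 0.003, a typical GC-MS fractional-abundance error), clipped
  at zero and renormalized. The additive-then-renormalize convention is a
  generator convention, not a claim about the instrument. Defaults
  $D = 0.27$, $g = 0.6$ mirror the strongest tissue signal scale.
- **Community tables**: 12 genome bins (4 Bacteroidetes, 2
  Enterococcaceae, 6 other commensals) with log-normal latent abundances
  (dispersion 0.5 on the natural log) passed through multinomial sampling
  at a uniform 20–50k depth — the standard compositional emulation that
  reproduces the zero pattern of real bin tables. Planted effects:
  $+1.5\ \log_2$ on Bacteroidetes and $-1.5$ on Enterococcaceae
  (abundance), and $+2\ \log_2$ on the `acs` gene against a stable `rpoA`
  reference (expression), with `adh` null. Group size 7+7 mirrors an
  N = 14 metatranscriptomics cohort; per-group counts for every assay in
  the motivating setting are not published, so they are configurable
  rather than asserted.
- **SCFA tables**: eight analytes, log-normal with CV 0.2, acetate times
  4 in the ethanol group, all others null.
- **Toy models**: see above; `linear_chain` and `two_substrate` ship
  their closed-form optima alongside.

What passing these tests does *not* show: real MIDs have correlated,
channel-dependent errors; real bin tables have far more taxa, stronger
zero inflation, and effects on many correlated clades; real expression
involves thousands of ORFs. The tests demonstrate correctness of the
computations and calibration of the statistics under the stated model,
not performance on any particular sequencing archive.

# Numerical choices

- MIDs are truncated at $n_{units} \times labels + 3$ by default
  ($\ge 99.99\%$ of natural-abundance mass) and renormalized; every
  emitted MID sums to 1 within $10^{-9}$.
- Natural $^{13}$C abundance 0.0107; all abundances live in one editable
  table (`isotope_abundances()`).
- Optimizer bounds are honored with an explicit clamp against
  floating-point rounding at 0 and 1.
- The simplex uses feasibility tolerance $10^{-9}$; FBA growth values are
  rounded to $10^{-12}$ before threshold comparison.
- PERMANOVA exceedance uses a $10^{-12}$ slack on $F_{perm} \ge F_{obs}$
  so exact ties count as exceedances.
- Completely tied group-test data yield $p = 1$ by the documented ties
  policy.
- Test and acceptance problem sizes (5- or 10-point grids, 100-seed
  power runs, 200-seed level runs, 999 permutations) are the package's
  own choices balancing Monte-Carlo resolution against a suite that runs
  in about two minutes.

# Known limitations

- ISA fits a single $g$ per sample (one harvest time); no time-resolved
  $g(t)$.
- No spectral deconvolution or instrument-side isotope correction; the
  package starts at MID tables.
- The simplex is dense and meant for desk-scale models (tens to a few
  hundred reactions), not for whole-genome reconstructions at scale.
- The ordination is not a drop-in DEICODE replacement; agreement is
  structural, not coordinate-level.
- The thermodynamic constants are illustrative; study-grade use should
  supply measured or curated formation energies and in-situ activities.
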