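# Independent oracles used across the suite. These deliberately avoid the
# package's convolution / simplex code paths: MIDs by exhaustive
# enumeration of isotopic states, FBA by enumeration of basic feasible
# solutions, Wilcoxon by full rank-permutation enumeration.

# exhaustive MID of an unlabelled molecule: enumerate every atom's isotope
# state (feasible for ~20 atoms with binary isotopes)
enum_natural_mid <- function(formula, n_tracked = NULL,
                             abundances = acetotrace::isotope_abundances()) {
  counts <- acetotrace::parse_formula(formula)
  per_atom <- list()
  for (el in names(counts))
    per_atom <- c(per_atom, rep(list(abundances[[el]]), counts[el]))
  shifts <- lapply(per_atom, function(p) seq_along(p) - 1L)
  grid <- expand.grid(shifts, KEEP.OUT.ATTRS = FALSE)
  w <- rep(1, nrow(grid))
  for (j in seq_along(per_atom))
    w <- w * per_atom[[j]][grid[[j]] + 1L]
  tot <- Reduce(`+`, grid)
  out <- vapply(0:max(tot), function(k) sum(w[tot == k]), numeric(1))
  if (!is.null(n_tracked)) out <- out[seq_len(n_tracked + 1L)]
  out / sum(out)
}

# exhaustive synthesized-polymer MID: per-unit shift probabilities by
# explicit enumeration over (origin, atom states), polymer by enumeration
# over all unit-shift tuples, remaining formula atoms enumerated per atom
enum_synthesized_mid <- function(D, unit, n_units, formula,
                                 n_tracked = NULL,
                                 abundances = acetotrace::isotope_abundances()) {
  p <- abundances$C[2]
  nc <- unit$n_carbons
  tl <- unit$tracer_labels
  pur <- unit$tracer_purity
  unit_probs <- numeric(nc + 1L)
  states <- as.matrix(expand.grid(rep(list(0:1), nc)))
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    pr_nat <- prod(ifelse(s == 1, p, 1 - p))
    pr_trc <- prod(ifelse(s[seq_len(tl)] == 1, pur, 1 - pur)) *
      (if (nc > tl) prod(ifelse(s[(tl + 1):nc] == 1, p, 1 - p)) else 1)
    k <- sum(s) + 1L
    unit_probs[k] <- unit_probs[k] + (1 - D) * pr_nat + D * pr_trc
  }
  tuples <- as.matrix(expand.grid(rep(list(0:nc), n_units)))
  w <- apply(tuples, 1, function(t) prod(unit_probs[t + 1L]))
  tot <- rowSums(tuples)
  poly <- vapply(0:(n_units * nc), function(k) sum(w[tot == k]), numeric(1))

  counts <- acetotrace::parse_formula(formula)
  counts["C"] <- counts["C"] - n_units * nc
  stopifnot(counts["C"] >= 0)
  rest <- counts[counts > 0]
  if (length(rest)) {
    per_atom <- list()
    for (el in names(rest))
      per_atom <- c(per_atom, rep(list(abundances[[el]]), rest[el]))
    shifts <- lapply(per_atom, function(q) seq_along(q) - 1L)
    grid <- expand.grid(shifts, KEEP.OUT.ATTRS = FALSE)
    wr <- rep(1, nrow(grid))
    for (j in seq_along(per_atom))
      wr <- wr * per_atom[[j]][grid[[j]] + 1L]
    rtot <- Reduce(`+`, grid)
    rest_dist <- vapply(0:max(rtot), function(k) sum(wr[rtot == k]),
                        numeric(1))
    full <- numeric(length(poly) + length(rest_dist) - 1L)
    for (i in seq_along(poly))
      full[i:(i + length(rest_dist) - 1L)] <-
        full[i:(i + length(rest_dist) - 1L)] + poly[i] * rest_dist
    poly <- full
  }
  if (!is.null(n_tracked)) {
    keep <- min(n_tracked + 1L, length(poly))
    poly <- c(poly[seq_len(keep)], numeric(max(0, n_tracked + 1L - keep)))
  }
  poly / sum(poly)
}

# FBA oracle: enumerate basic feasible solutions of
# max c'v, S v = 0, lb <= v <= ub
fba_vertex_oracle <- function(model, tol = 1e-8) {
  S <- acetotrace::stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  obj <- as.numeric(names(model$reactions) == model$objective)
  qrt <- qr(t(S))
  S <- S[qrt$pivot[seq_len(qrt$rank)], , drop = FALSE]
  m <- nrow(S); n <- ncol(S)
  free <- n - m
  best <- -Inf
  fixsets <- if (free == 0) list(integer(0)) else
    asplit(utils::combn(n, free), 2)
  for (fixset in fixsets) {
    fixset <- as.integer(fixset)
    basic <- setdiff(seq_len(n), fixset)
    B <- S[, basic, drop = FALSE]
    if (m > 0 && abs(det(B)) < 1e-10) next
    n_pat <- if (length(fixset)) 2^length(fixset) else 1
    for (pat in seq_len(n_pat) - 1L) {
      bits <- if (length(fixset))
        bitwAnd(bitwShiftR(pat, seq_along(fixset) - 1L), 1L) else integer(0)
      vfix <- ifelse(bits == 1L, ub[fixset], lb[fixset])
      vb <- if (m > 0)
        solve(B, if (length(fixset)) -S[, fixset, drop = FALSE] %*% vfix
              else rep(0, m))
      else numeric(0)
      v <- numeric(n)
      v[fixset] <- vfix
      v[basic] <- vb
      if (all(v >= lb - tol) && all(v <= ub + tol))
        best <- max(best, sum(obj * v))
    }
  }
  best
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (R's two-sided convention: twice the smaller tail, capped)
wilcox_enum_oracle <- function(a, b) {
  n1 <- length(a)
  vals <- c(a, b)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(vals), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(w_all <= w_obs + 1e-12)
  hi <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

sample_groups <- function(md) stats::setNames(md$group, md$sample)

null_community_spec <- function(seed)
  acetotrace::community_sim_spec(
    seed = seed,
    effects = stats::setNames(rep(0, nrow(acetotrace::default_taxa())),
                              acetotrace::default_taxa()$name))

# tiny SBML L3+FBC document mirroring the linear_chain fixture
linear_chain_sbml <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="linear_chain_sbml">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="glc" compartment="c" fbc:chemicalFormula="C6H12O6"
               hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="x" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_ex" value="-10" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_def" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_glc" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_ex" fbc:upperFluxBound="ub_def">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="CONV" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_def">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="x" stoichiometry="0.5" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_def">
        <listOfReactants>
          <speciesReference species="x" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>'
}
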