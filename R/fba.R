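# Flux balance analysis: maximize the biomass objective over steady-state
# fluxes (S v = 0, lb <= v <= ub) by linear programming, plus the
# one-at-a-time carbon-source screen with and without an acetate
# co-substrate.

#' Flux balance analysis
#'
#' Maximizes the flux through the model's objective (biomass) reaction
#' subject to steady state (\eqn{S v = 0}) and the reaction bounds. Solved
#' as a bounded-variable linear program (variables shifted to
#' \eqn{x = v - lb \ge 0}); the objective value is deterministic, while the
#' flux vector may be any optimal vertex.
#'
#' @param model A `"metabolic_model"`.
#' @param tol Solver feasibility tolerance.
#' @return Object of class `"flux_solution"`: `status` (`"optimal"`,
#'   `"infeasible"`, or `"unconverged"`), `growth_rate` (objective value in
#'   1/hr; `NA` unless optimal), and `fluxes` (named vector).
#' @examples
#' m <- generate_toy_gem("linear_chain")
#' fba(m$model)
#' @export
fba <- function(model, tol = 1e-9) {
  validate_model(model)
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  lb[!is.finite(lb)] <- -1e6
  ub[!is.finite(ub)] <- 1e6
  obj <- as.numeric(names(model$reactions) == model$objective)

  # shift to x = v - lb >= 0: maximize obj'x s.t. S x = -S lb, x <= ub - lb
  sol <- lp_max(obj, S, -as.vector(S %*% lb), ub - lb, tol = tol)
  status <- sol$status
  fluxes <- if (status == "optimal")
    stats::setNames(sol$x + lb, names(model$reactions))
  else stats::setNames(rep(NA_real_, length(lb)), names(model$reactions))
  if (status == "optimal") {
    resid <- max(abs(S %*% fluxes))
    if (resid > 1e-6)
      stop("steady-state violation in LP solution (max |S v| = ", resid, ")")
  }
  structure(list(status = status,
                 growth_rate = if (status == "optimal")
                   unname(fluxes[model$objective]) else NA_real_,
                 fluxes = fluxes, objective = model$objective),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("FBA solution: %s; growth rate = %s /hr\n", x$status,
              format(x$growth_rate, digits = 6)))
  invisible(x)
}

#' Configure the growth medium of a model
#'
#' Opens the basal-nutrient exchanges (unbounded influx), caps each listed
#' carbon source's influx at `carbon_influx_cap` mmol C/gDW/hr — i.e. a
#' molar bound of cap divided by the metabolite's carbon count, equalizing
#' carbon supply across sources — closes the influx of every other
#' carbon-containing metabolite, and leaves secretion unrestricted.
#' Idempotent: all bounds are absolute assignments.
#'
#' @param model A `"metabolic_model"`.
#' @param basal Metabolite ids of basal nutrients (vitamins, minerals,
#'   ammonia, sulfide, phosphate...); influx unbounded.
#' @param carbon_sources Metabolite ids of the carbon sources to enable.
#' @param carbon_influx_cap Total carbon influx allowance per source, in
#'   mmol C/gDW/hr (default 100).
#' @return The modified `"metabolic_model"`.
#' @export
apply_medium <- function(model, basal = character(),
                         carbon_sources = character(),
                         carbon_influx_cap = 100) {
  ex <- exchange_reactions(model)  # rxn id -> metabolite id
  met2ex <- stats::setNames(names(ex), ex)
  carbons <- metabolite_carbons(model)
  missing <- setdiff(c(basal, carbon_sources), names(met2ex))
  if (length(missing))
    stop("no exchange reaction for metabolite(s): ",
         paste(missing, collapse = ", "))
  for (met in ex) {
    rid <- met2ex[[met]]
    r <- model$reactions[[rid]]
    r$upper_bound <- max(r$upper_bound, DEFAULT_BOUND)  # secretion open
    if (met %in% carbon_sources) {
      if (carbons[[met]] == 0L)
        stop("carbon source '", met, "' has zero carbons")
      r$lower_bound <- -carbon_influx_cap / carbons[[met]]
    } else if (met %in% basal) {
      r$lower_bound <- -DEFAULT_BOUND
    } else if (carbons[[met]] > 0L) {
      r$lower_bound <- 0
    }
    model$reactions[[rid]] <- r
  }
  model
}

#' Classify growth and acetate effect from two growth rates
#'
#' Pure threshold rules of the screen: growth below the no-growth threshold
#' (0.001/hr) is "no growth"; the co-substrate had an effect if it raised
#' the growth rate by at least the effect threshold (0.0001/hr). Growth
#' values are rounded to 1e-12 before comparison so solver noise cannot
#' flip a classification.
#'
#' @param growth_without,growth_with Growth rates (1/hr) without and with
#'   the co-substrate.
#' @param no_growth_threshold Minimum growth rate counted as growth.
#' @param effect_threshold Minimum growth-rate increase counted as an
#'   effect.
#' @return List with `grows_without`, `grows_with`, `acetate_effect`.
#' @examples
#' classify_growth(0.0009, 0.0009 + 0.00011)
#' @export
classify_growth <- function(growth_without, growth_with,
                            no_growth_threshold = 0.001,
                            effect_threshold = 0.0001) {
  g0 <- round(growth_without, 12)
  g1 <- round(growth_with, 12)
  list(grows_without = g0 >= no_growth_threshold,
       grows_with = g1 >= no_growth_threshold,
       acetate_effect = round(g1 - g0, 12) >= effect_threshold)
}

#' One-at-a-time carbon-source co-metabolism screen
#'
#' For each candidate carbon source: run FBA on the basal medium plus that
#' source alone, then again with the co-substrate (acetate) exchange also
#' opened under the same per-metabolite carbon cap, and classify growth and
#' the co-substrate effect with [classify_growth()]. Opening an exchange is
#' a constraint relaxation, so `growth_with >= growth_without` is asserted
#' on every row (up to solver tolerance).
#'
#' @param model A `"metabolic_model"` containing the co-substrate with an
#'   exchange reaction.
#' @param carbon_sources Metabolite ids to screen, one at a time.
#' @param basal Metabolite ids of the basal medium.
#' @param co_substrate Metabolite id of the co-substrate (acetate).
#' @param carbon_influx_cap mmol C/gDW/hr cap per source (default 100).
#' @inheritParams classify_growth
#' @param tol Solver tolerance.
#' @return Data frame of class `"screen_result"`, one row per source,
#'   sorted by source name: `carbon_source`, `growth_without_acetate`,
#'   `growth_with_acetate`, `grows_without`, `grows_with`,
#'   `acetate_effect`. A warning is attached (attribute `"warning"`) if no
#'   source supports growth.
#' @examples
#' m <- generate_toy_gem("cometabolism")$model
#' cometabolism_screen(m, c("glyc", "ac"))
#' @export
cometabolism_screen <- function(model, carbon_sources, basal = character(),
                                co_substrate = "ac", carbon_influx_cap = 100,
                                no_growth_threshold = 0.001,
                                effect_threshold = 0.0001, tol = 1e-9) {
  ex_mets <- unname(exchange_reactions(model))
  if (!co_substrate %in% ex_mets)
    stop("co-substrate '", co_substrate, "' has no exchange reaction")
  carbon_sources <- sort(unique(carbon_sources))
  rows <- lapply(carbon_sources, function(src) {
    m0 <- apply_medium(model, basal, src, carbon_influx_cap)
    m1 <- apply_medium(model, basal, unique(c(src, co_substrate)),
                       carbon_influx_cap)
    f0 <- fba(m0, tol)
    f1 <- fba(m1, tol)
    g0 <- if (f0$status == "optimal") f0$growth_rate else 0
    g1 <- if (f1$status == "optimal") f1$growth_rate else 0
    if (g1 < g0 - 1e-6)
      stop("relaxation monotonicity violated for source '", src,
           "': ", g1, " < ", g0)
    cls <- classify_growth(g0, g1, no_growth_threshold, effect_threshold)
    data.frame(carbon_source = src, growth_without_acetate = g0,
               growth_with_acetate = g1,
               grows_without = cls$grows_without,
               grows_with = cls$grows_with,
               acetate_effect = cls$acetate_effect)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screen_result", "data.frame")
  attr(out, "thresholds") <- c(no_growth = no_growth_threshold,
                               effect = effect_threshold)
  if (!any(out$grows_without | out$grows_with)) {
    warn <- "no screened condition supports growth; check the basal medium"
    attr(out, "warning") <- warn
    warning(warn)
  }
  out
}

#' @export
print.screen_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("carbon-source screen (%d sources; no-growth < %g /hr, effect >= %g /hr)\n",
              nrow(x), th["no_growth"], th["effect"]))
  print.data.frame(x, row.names = FALSE, digits = 6)
  if (!is.null(attr(x, "warning"))) cat("warning:", attr(x, "warning"), "\n")
  invisible(x)
}
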