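# Genome-scale metabolic models: a light container mirroring the COBRA JSON
# schema. Reactions are lists with a named stoichiometry vector
# (metabolite id -> signed coefficient), bounds in mmol/gDW/hr, and one
# reaction carries the biomass objective.

DEFAULT_BOUND <- 1000

#' Construct a metabolic model
#'
#' @param metabolites Data frame with columns `id`, `formula`, `compartment`
#'   (formula may be `NA`; carbon counts are parsed from it on demand).
#' @param reactions Named list; each element a list with `metabolites`
#'   (named numeric stoichiometry, products positive), `lower_bound`,
#'   `upper_bound`.
#' @param objective Id of the biomass reaction.
#' @param id Optional model identifier.
#' @return Object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, objective, id = "model") {
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions, objective = objective),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the invariants: all referenced metabolites are defined, exactly
#' one objective reaction exists in the reaction set, exchange reactions
#' touch exactly one metabolite, and bounds satisfy lower <= upper.
#'
#' @param model A `"metabolic_model"`.
#' @return `TRUE` invisibly, or an error locating the problem.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (!all(c("id", "formula", "compartment") %in% names(mets)))
    stop("metabolites must have columns id, formula, compartment")
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids")
  rids <- names(model$reactions)
  if (is.null(rids) || anyDuplicated(rids)) stop("reactions must be uniquely named")
  if (length(model$objective) != 1L || !model$objective %in% rids)
    stop("no objective: model must name exactly one biomass reaction")
  for (rid in rids) {
    r <- model$reactions[[rid]]
    dangling <- setdiff(names(r$metabolites), mets$id)
    if (length(dangling))
      stop("reaction '", rid, "' references undefined metabolite(s): ",
           paste(dangling, collapse = ", "))
    if (length(r$metabolites) == 0L)
      stop("reaction '", rid, "' has empty stoichiometry")
    if (r$lower_bound > r$upper_bound)
      stop("reaction '", rid, "' has lower_bound > upper_bound")
    if (is_exchange(r) && length(r$metabolites) != 1L)
      stop("exchange reaction '", rid, "' must touch exactly one metabolite")
  }
  invisible(TRUE)
}

# exchange = boundary pseudo-reaction: touches a single metabolite
is_exchange <- function(reaction) length(reaction$metabolites) == 1L

#' Exchange reactions of a model
#'
#' @param model A `"metabolic_model"`.
#' @return Named character vector mapping exchange reaction id to the
#'   metabolite it exchanges.
#' @export
exchange_reactions <- function(model) {
  ex <- Filter(is_exchange, model$reactions)
  stats::setNames(vapply(ex, function(r) names(r$metabolites), character(1)),
                  names(ex))
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic model '%s': %d metabolites, %d reactions (%d exchanges)\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              sum(vapply(x$reactions, is_exchange, logical(1)))))
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Carbon counts of model metabolites
#'
#' @param model A `"metabolic_model"`.
#' @return Named integer vector of carbon atoms per metabolite id (0 where
#'   the formula has no carbon; error on unparsable formulas).
#' @export
metabolite_carbons <- function(model) {
  stats::setNames(vapply(seq_len(nrow(model$metabolites)), function(i) {
    f <- model$metabolites$formula[i]
    if (is.na(f) || !nzchar(f)) return(0L)
    carbon_count(f)
  }, integer(1)), model$metabolites$id)
}

#' Stoichiometric matrix
#'
#' @param model A `"metabolic_model"`.
#' @return Dense numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id, names(model$reactions)))
  for (rid in names(model$reactions)) {
    st <- model$reactions[[rid]]$metabolites
    S[names(st), rid] <- st
  }
  S
}

#' Read a metabolic model
#'
#' Reads COBRA-style JSON (metabolites with `id`/`formula`/`compartment`,
#' reactions with `metabolites`/`lower_bound`/`upper_bound` and either an
#' `objective_coefficient` of 1 or a top-level `"objective"` entry) or a
#' minimal SBML Level 3 FBC document.
#'
#' @param path File path.
#' @param format `"cobra-json"` or `"sbml"`; default guessed from the file
#'   extension.
#' @return A `"metabolic_model"`.
#' @export
read_model <- function(path, format = c("guess", "cobra-json", "sbml")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "cobra-json"
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         "cobra-json" = read_model_json(path),
         "sbml" = read_model_sbml(path))
}

read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               compartment = if (is.null(m$compartment)) "c" else m$compartment)))
  objective <- j$objective
  reactions <- list()
  for (r in j$reactions) {
    st <- unlist(r$metabolites)
    reactions[[r$id]] <- list(
      metabolites = st,
      lower_bound = if (is.null(r$lower_bound)) -DEFAULT_BOUND else r$lower_bound,
      upper_bound = if (is.null(r$upper_bound)) DEFAULT_BOUND else r$upper_bound)
    oc <- r$objective_coefficient
    if (!is.null(oc) && oc != 0) objective <- c(objective, r$id)
  }
  objective <- unique(unlist(objective))
  if (length(objective) == 0L)
    stop("no objective: '", path, "' defines no biomass reaction")
  if (length(objective) > 1L)
    stop("multiple objective reactions in '", path, "': ",
         paste(objective, collapse = ", "))
  metabolic_model(mets, reactions, objective,
                  id = if (is.null(j$id)) basename(path) else j$id)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    compartment = xml2::xml_attr(sp, "compartment"))
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- list()
  for (r in rx) {
    rid <- xml2::xml_attr(r, "id")
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(r, paste0("./s:", tag, "/s:speciesReference"), ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", 1))
    lbref <- xml2::xml_attr(r, "fbc:lowerFluxBound", ns = ns)
    ubref <- xml2::xml_attr(r, "fbc:upperFluxBound", ns = ns)
    reactions[[rid]] <- list(
      metabolites = st,
      lower_bound = if (is.na(lbref)) -DEFAULT_BOUND else unname(parval[lbref]),
      upper_bound = if (is.na(ubref)) DEFAULT_BOUND else unname(parval[ubref]))
  }
  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing"))
    stop("no objective: '", path, "' has no fbc objective")
  objective <- xml2::xml_attr(fo, "fbc:reaction", ns = ns)
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  metabolic_model(mets, reactions, objective,
                  id = if (is.na(mid)) basename(path) else mid)
}

#' Write a metabolic model as COBRA-style JSON
#'
#' Round-trips with [read_model()].
#'
#' @param model A `"metabolic_model"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  j <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           formula = model$metabolites$formula[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(names(model$reactions), function(rid) {
      r <- model$reactions[[rid]]
      list(id = rid, metabolites = as.list(r$metabolites),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           objective_coefficient = as.numeric(rid == model$objective))
    }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
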