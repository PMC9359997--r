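#' Parse a chemical formula
#'
#' Turns a Hill-style chemical formula string (e.g. `"C16"`, `"C17H34O2"`,
#' `"C3H8O3"`) into a named integer vector of atom counts.
#'
#' @param formula Character scalar. Element symbols followed by optional
#'   counts; a missing count means 1.
#' @param allowed Optional character vector of permitted element symbols.
#'   Elements outside this set trigger an error naming the offender. The
#'   default `NULL` allows any element symbol.
#' @return Named integer vector of atom counts.
#' @examples
#' parse_formula("C17H34O2")
#' @export
parse_formula <- function(formula, allowed = NULL) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("'formula' must be a single character string")
  s <- gsub("\\s", "", formula)
  if (!nzchar(s)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("unparsable formula: '", formula, "'")
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  out <- tapply(counts, elems, sum)
  out <- stats::setNames(as.integer(out), names(out))
  if (!is.null(allowed)) {
    bad <- setdiff(names(out), allowed)
    if (length(bad))
      stop("unsupported element(s) in formula '", formula, "': ",
           paste(bad, collapse = ", "))
  }
  out
}

#' Count carbon atoms in a formula
#'
#' @param formula Chemical formula string.
#' @return Integer carbon count (0 if the formula has no carbon).
#' @examples
#' carbon_count("C3H8O3")
#' @export
carbon_count <- function(formula) {
  counts <- parse_formula(formula)
  if (is.na(counts["C"])) 0L else unname(counts["C"])
}
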