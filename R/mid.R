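# Mass isotopomer distributions (MIDs) are plain numeric vectors named
# M0..Mn, summing to 1. All isotope bookkeeping works on nominal mass-shift
# distributions: per-atom probability vectors indexed by extra neutrons.

#' Natural isotope abundances
#'
#' One editable table of per-element isotope abundances used throughout the
#' package, expressed as nominal mass-shift distributions (index 0 = the
#' lightest isotope). Values are IUPAC representative abundances; the natural
#' \eqn{^{13}}C fraction defaults to 0.0107.
#'
#' @param C13 Natural \eqn{^{13}}C abundance (overrides the carbon entry;
#'   set to 0 to ignore natural carbon labelling entirely).
#' @return Named list of numeric probability vectors, one per supported
#'   element (C, H, N, O, S, Si).
#' @examples
#' isotope_abundances()$C
#' @export
isotope_abundances <- function(C13 = 0.0107) {
  stopifnot(is.numeric(C13), length(C13) == 1L, C13 >= 0, C13 < 1)
  list(
    C  = c(1 - C13, C13),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
    Si = c(0.92223, 0.04685, 0.03092)
  )
}

# discrete convolution of two mass-shift distributions
conv_shift <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# n-fold self-convolution by binary exponentiation
conv_power <- function(d, n) {
  stopifnot(n >= 0)
  out <- 1
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) out <- conv_shift(out, base)
    base <- conv_shift(base, base)
    n <- n %/% 2
  }
  out
}

mid_names <- function(x) stats::setNames(x, paste0("M", seq_along(x) - 1L))

# truncate a shift distribution at index n_tracked and renormalize
mid_truncate <- function(x, n_tracked = NULL) {
  if (!is.null(n_tracked)) {
    n_keep <- n_tracked + 1L
    if (length(x) > n_keep) x <- x[seq_len(n_keep)]
    else if (length(x) < n_keep) x <- c(x, numeric(n_keep - length(x)))
  }
  s <- sum(x)
  if (s <= 0) stop("cannot normalize a MID with non-positive mass")
  mid_names(x / s)
}

#' Check MID validity
#'
#' @param x Numeric vector of isotopologue fractions M0..Mn.
#' @param tol Tolerance on the unit-sum constraint.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_mid <- function(x, tol = 1e-9) {
  if (!is.numeric(x) || length(x) < 1L) stop("MID must be a numeric vector")
  if (any(x < -tol)) stop("MID has negative entries")
  if (abs(sum(x) - 1) > tol) stop("MID does not sum to 1 (sum = ", sum(x), ")")
  invisible(TRUE)
}

#' Natural-abundance mass isotopomer distribution
#'
#' Isotopologue distribution of an unlabelled molecule, from the multinomial
#' expansion of per-element natural abundances: each atom independently
#' carries extra neutrons with its element's isotope probabilities, and the
#' per-atom distributions are convolved across the whole formula.
#'
#' @param formula Chemical formula string (e.g. `"C16"` for the palmitate
#'   carbon skeleton, `"C17H34O2"` for the methyl-ester derivative).
#' @param n_tracked Highest isotopologue index retained; the distribution is
#'   truncated there and renormalized. `NULL` (default) keeps full support.
#' @param abundances Abundance table as from [isotope_abundances()].
#' @return Named numeric vector M0..Mn summing to 1.
#' @examples
#' natural_abundance_mid("C2")
#' @export
natural_abundance_mid <- function(formula, n_tracked = NULL,
                                  abundances = isotope_abundances()) {
  counts <- parse_formula(formula, allowed = names(abundances))
  d <- 1
  for (el in names(counts))
    d <- conv_shift(d, conv_power(abundances[[el]], counts[el]))
  mid_truncate(d, n_tracked)
}
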