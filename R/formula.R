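# Molecular-formula arithmetic. The element vector is the bookkeeping unit
# behind chemical formula/charge properties and the per-element conservation
# constraints used when balancing reactions.

.kg_env <- new.env(parent = emptyenv())

#' Most-abundant-isotope masses
#'
#' Returns the bundled element mass table (most abundant isotope, Da),
#' shipped as a versioned plain-text file under `extdata`.
#'
#' @return Named numeric vector: element symbol to monoisotopic mass (Da).
#' @export
element_masses <- function() {
  if (is.null(.kg_env$masses)) {
    path <- system.file("extdata", "isotope_masses_2021.tsv",
                        package = "metabograph", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .kg_env$masses <- stats::setNames(tab$mass, tab$element)
  }
  .kg_env$masses
}

# Tokens that mark a formula as a generic class / polymer rather than a
# concrete species (R-groups, unknowns, 'n' repeats, wildcards, grouping).
GENERIC_SYMBOLS <- c("R", "X")
GENERIC_CHARS <- c("(", ")", "*", ".", "n", "x")

#' Parse a molecular formula into an element count vector
#'
#' Accepts plain Hill-style formulas of the form `(ElementSymbol Count?)+`
#' with positive integer counts (`"C6H12O6"`, `"H2O"`). Repeated element
#' symbols are summed. Generic or polymeric notations (R-groups, `X`,
#' trailing `n`, `*`, parentheses) are rejected with a dedicated condition
#' class so callers can treat the chemical as a class node rather than a
#' species.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts (charge is tracked
#'   separately on the chemical record).
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || is.na(formula) ||
      !nzchar(formula))
    kg_parse_error("formula must be a non-empty string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- if (m[1] == -1) character() else regmatches(formula, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (length(tokens) == 0 || covered != nchar(formula)) {
    # Unmatched residue: decide generic vs malformed.
    residue <- formula
    for (t in tokens) residue <- sub(t, "", residue, fixed = TRUE)
    if (any(vapply(GENERIC_CHARS, grepl, logical(1), x = residue,
                   fixed = TRUE)))
      kg_generic_formula_error(formula)
    kg_parse_error(sprintf("malformed formula '%s'", formula))
  }
  syms <- sub("[0-9]*$", "", tokens)
  if (any(syms %in% GENERIC_SYMBOLS)) kg_generic_formula_error(formula)
  unknown <- setdiff(syms, names(element_masses()))
  if (length(unknown) > 0)
    kg_parse_error(sprintf("unknown element symbol(s) in '%s': %s", formula,
                           paste(unique(unknown), collapse = ", ")))
  counts <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(counts == "", 1L, suppressWarnings(as.integer(counts)))
  if (any(is.na(counts)) || any(counts < 1))
    kg_parse_error(sprintf("malformed count in formula '%s'", formula))
  out <- tapply(counts, syms, sum)
  ev <- stats::setNames(as.integer(out), names(out))
  # Deterministic order: first appearance in the formula.
  ev[unique(syms)]
}

#' Monoisotopic mass of an element vector
#'
#' Sum over elements of count times the most-abundant-isotope mass from the
#' bundled table. The empty vector has mass 0.
#'
#' @param ev Named integer vector of element counts, as returned by
#'   [parse_formula()], or a formula string (parsed first).
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))
monoisotopic_mass <- function(ev) {
  if (is.character(ev)) ev <- parse_formula(ev)
  if (length(ev) == 0) return(0.0)
  masses <- element_masses()
  missing <- setdiff(names(ev), names(masses))
  if (length(missing) > 0)
    kg_validation_error(sprintf("no isotope mass for element(s): %s",
                                paste(missing, collapse = ", ")))
  sum(masses[names(ev)] * as.numeric(ev))
}

# Mass of a chemical entity: the stored property if present, else computed
# from the formula, else NA.
chemical_mass <- function(chem) {
  if (!is.null(chem$monoisotopic_mass) && !is.na(chem$monoisotopic_mass))
    return(chem$monoisotopic_mass)
  if (!is.null(chem$formula)) {
    ev <- tryCatch(parse_formula(chem$formula), kg_error = function(e) NULL)
    if (!is.null(ev)) return(monoisotopic_mass(ev))
  }
  NA_real_
}
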