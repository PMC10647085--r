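#' Parse a molecular-formula string into an empirical formula
#'
#' Turns formula text such as `"C2H6O"` into a named count vector. A missing
#' count means one atom of that element. Counts for an element appearing more
#' than once are summed.
#'
#' @param text a single non-empty formula string, e.g. `"C20H38"`.
#' @return an `empirical_formula`: a named integer vector of element counts,
#'   stored in Hill order (C first, then H, then the rest alphabetically).
#' @examples
#' parse_formula("C2H6O")
#' render_formula(parse_formula("H2O"))
#' @seealso [render_formula()], [formula_matches()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula text must be a single non-empty string", call. = FALSE)
  }
  s <- gsub("[[:space:]]", "", text)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s)) {
    stop(sprintf("cannot parse formula %s", dQuote(text)), call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  elems <- sub("[0-9]*$", "", toks)
  cnts <- as.integer(sub("^[A-Za-z]+", "", toks))
  cnts[is.na(cnts)] <- 1L
  bad <- !is_element(elems)
  if (any(bad)) {
    stop(sprintf("unknown element symbol(s): %s", paste(unique(elems[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(cnts < 1L)) {
    stop("element counts must be >= 1", call. = FALSE)
  }
  counts <- tapply(cnts, elems, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  new_empirical_formula(counts)
}

new_empirical_formula <- function(counts) {
  stopifnot(is.integer(counts), !is.null(names(counts)), all(counts >= 1L))
  structure(counts[hill_order(names(counts))], class = "empirical_formula")
}

# Hill convention: carbon first, hydrogen second, remaining elements
# alphabetically. Without carbon all elements are alphabetical.
hill_order <- function(elems) {
  if ("C" %in% elems) {
    rest <- sort(setdiff(elems, c("C", "H")))
    c("C", intersect("H", elems), rest)
  } else {
    sort(elems)
  }
}

#' Render an empirical formula in Hill notation
#'
#' @param formula an `empirical_formula` from [parse_formula()].
#' @return a single string; counts of one are omitted.
#' @export
render_formula <- function(formula) {
  stopifnot(inherits(formula, "empirical_formula"))
  paste0(names(formula), ifelse(unclass(formula) > 1L, unclass(formula), ""),
         collapse = "")
}

#' @export
format.empirical_formula <- function(x, ...) render_formula(x)

#' @export
print.empirical_formula <- function(x, ...) {
  cat("<empirical_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

formula_count <- function(formula, element) {
  n <- unclass(formula)[element]
  if (is.na(n)) 0L else as.integer(n)
}

#' Test an empirical formula against a homologous-series pattern
#'
#' Patterns express the sum-formula constraints used when auditing chemical
#' classifications: alkanes are CnH2n+2, alkenes CnH2n, alkanols CnH2n+2O.
#' A pattern matches only when the formula has exactly the pattern's element
#' set (an oxygen-bearing formula can never match the alkene pattern) and
#' n >= 1.
#'
#' @param formula an `empirical_formula`.
#' @param pattern one of `"alkane_CnH2n2"`, `"alkene_CnH2n"`,
#'   `"alkanol_CnH2n2O"`, `"bounded_CxHyOz"`.
#' @param x_max,z_max upper bounds (exclusive) on the carbon and oxygen counts
#'   for the `"bounded_CxHyOz"` pattern, which accepts any C/H/O-only formula
#'   with `C < x_max` and `O < z_max` (hydrogen unconstrained, oxygen may be
#'   absent).
#' @return `TRUE` or `FALSE`.
#' @examples
#' formula_matches(parse_formula("C2H4"), "alkene_CnH2n")
#' formula_matches(parse_formula("C20H38"), "alkene_CnH2n")
#' @export
formula_matches <- function(formula, pattern, x_max = NULL, z_max = NULL) {
  stopifnot(inherits(formula, "empirical_formula"))
  pattern <- match.arg(pattern,
                       c("alkane_CnH2n2", "alkene_CnH2n", "alkanol_CnH2n2O",
                         "bounded_CxHyOz"))
  elems <- names(formula)
  nC <- formula_count(formula, "C")
  nH <- formula_count(formula, "H")
  nO <- formula_count(formula, "O")
  switch(pattern,
    alkane_CnH2n2 = setequal(elems, c("C", "H")) && nC >= 1L && nH == 2L * nC + 2L,
    alkene_CnH2n = setequal(elems, c("C", "H")) && nC >= 1L && nH == 2L * nC,
    alkanol_CnH2n2O = setequal(elems, c("C", "H", "O")) && nC >= 1L &&
      nH == 2L * nC + 2L && nO == 1L,
    bounded_CxHyOz = {
      if (is.null(x_max) || is.null(z_max)) {
        stop("bounded_CxHyOz requires x_max and z_max", call. = FALSE)
      }
      all(elems %in% c("C", "H", "O")) && nC >= 1L && nC < x_max && nO < z_max
    }
  )
}

#' Count double bonds in a bond set
#'
#' @param bonds a list of `atomic_bond` objects (see [atomic_bond()]).
#' @return integer count of bonds with order 2.
#' @export
count_double_bonds <- function(bonds) {
  if (length(bonds) == 0L) return(0L)
  sum(vapply(bonds, function(b) b$order == 2L, logical(1)))
}
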