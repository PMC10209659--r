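# Molecular-formula handling. Hill notation (C first, H second, remaining
# elements alphabetical) is the canonical key used throughout the library
# index, so every formula string is normalized through hill_formula() before
# comparison or lookup.

# Standard (average) atomic weights, IUPAC 2021 abridged values.
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
  Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904, Zr = 91.224,
  Mo = 95.95, Ag = 107.87, Sn = 118.71, Sb = 121.76, I = 126.904,
  Ba = 137.33, W = 183.84, Pt = 195.08, Au = 196.97, Hg = 200.59,
  Pb = 207.2, Li = 6.94, Be = 9.012, Ge = 72.63, Cd = 112.41
)

# Elements observed in general GC-MS measurements; the model's node
# feature columns use exactly this order.
ALLOWED_ELEMENTS <- c("C", "O", "N", "B", "F", "P", "S", "Cl", "Si", "Br", "I")

#' Parse a molecular formula string into element counts
#'
#' Accepts any ordering of `Element`/`ElementCount` tokens (e.g. `"C2H6O"`,
#' `"H6C2O"`). Trailing charge markers (`+`, `-`, `2-`, ...) are ignored.
#'
#' @param formula A molecular formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C7H7NO2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  body <- gsub("[0-9]*[+-]+$", "", trimws(formula))
  if (!nzchar(body)) {
    stop("empty molecular formula: ", sQuote(formula), call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", body)[[1]]
  tokens <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*)", body))[[1]]
  if (sum(attr(m, "match.length")) != nchar(body)) {
    stop("cannot parse molecular formula: ", sQuote(formula), call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  out <- tapply(counts, elems, sum)
  storage.mode(out) <- "integer"
  setNames(as.integer(out), names(out))
}

#' Canonicalize a formula to Hill notation
#'
#' Carbon first, hydrogen second, all other elements alphabetical; a count
#' of one is written without a digit. Formulas without carbon list all
#' elements alphabetically (hydrogen included), as Hill convention requires.
#'
#' @param formula A formula string or a named count vector from
#'   [parse_formula()].
#' @return Canonical Hill-notation formula string.
#' @examples
#' hill_formula("H6C2O")  # "C2H6O"
#' @export
hill_formula <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  counts <- counts[counts > 0]
  elems <- names(counts)
  if ("C" %in% elems) {
    rest <- sort(setdiff(elems, c("C", "H")))
    ord <- c("C", intersect("H", elems), rest)
  } else {
    ord <- sort(elems)
  }
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

# Average molecular weight (Da) from element counts; NA if any element is
# not in the weights table.
formula_weight <- function(counts) {
  w <- ATOMIC_WEIGHTS[names(counts)]
  if (anyNA(w)) return(NA_real_)
  sum(w * counts)
}
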