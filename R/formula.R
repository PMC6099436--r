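# Molecular formula parsing and exact-mass arithmetic.

#' Parse a molecular formula string
#'
#' Parses an element-count formula such as \code{"C17H17Cl2N"} into a named
#' integer vector. The grammar is a flat sequence of element symbols (one
#' upper-case letter optionally followed by one lower-case letter) each with
#' an optional decimal count (default 1). Parentheses, isotopes, and charges
#' are not part of the grammar.
#'
#' @param text a single formula string; \code{""} yields the empty formula.
#' @return a named integer vector of element counts with class
#'   \code{"chem_formula"}, in Hill order (C, H, then alphabetical; purely
#'   alphabetical when no carbon is present). The empty formula is a
#'   zero-length vector.
#' @examples
#' parse_formula("C17H17Cl2N")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (text == "") {
    return(structure(integer(0), class = "chem_formula"))
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(text)) {
    stop("malformed formula string: '", text, "'")
  }
  sym <- sub("[0-9]*$", "", matched)
  cnt <- sub("^[A-Za-z]+", "", matched)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  if (anyNA(cnt)) stop("malformed count in formula '", text, "'")
  unknown <- setdiff(sym, names(.MONO_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- tapply(cnt, sym, sum)
  counts <- counts[counts != 0]
  as_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Coerce to a chem_formula
#'
#' Accepts a formula string or a named integer vector of element counts and
#' returns a canonical \code{chem_formula} (Hill-ordered, zero counts
#' dropped). Used throughout the package so user-facing functions take either
#' representation.
#'
#' @param x formula string or named numeric vector of counts.
#' @return a \code{chem_formula}.
#' @export
as_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  stopifnot(is.numeric(x), !is.null(names(x)) || length(x) == 0L)
  x <- x[x != 0]
  if (any(x < 0)) stop("negative element count in formula")
  if (any(x != round(x))) stop("non-integer element count in formula")
  unknown <- setdiff(names(x), names(.MONO_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  v <- stats::setNames(as.integer(x), names(x))
  v <- v[.hill_order(names(v))]
  structure(v, class = "chem_formula")
}

# Hill convention: C first, H second, remaining alphabetical; if no carbon,
# everything alphabetical.
.hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    ord <- c("C", intersect("H", symbols), rest)
  } else {
    ord <- sort(symbols)
  }
  match(ord, symbols)
}

#' Serialize a formula in Hill notation
#'
#' @param f a \code{chem_formula} (or anything \code{\link{as_formula}}
#'   accepts).
#' @return a single string; the empty formula serializes to \code{""}.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
format.chem_formula <- function(x, ...) format_formula(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of the lightest isotope, from
#' the package's frozen atomic mass table.
#'
#' @inheritParams format_formula
#' @return mass in Da; 0 for the empty formula.
#' @examples
#' monoisotopic_mass("H2O")   # 18.0106
#' monoisotopic_mass("CH5N")  # 31.0422, the methylamine neutral loss
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  sum(f * .MONO_MASS[names(f)])
}

#' Theoretical m/z of the protonated molecular ion [M+H]+
#'
#' Neutral monoisotopic mass plus a proton, i.e. plus the H atom mass minus
#' the electron mass. The electron-mass correction (0.00055 Da) matters at
#' the fourth decimal place of high-resolution m/z values.
#'
#' @inheritParams format_formula
#' @return m/z in Da (charge +1).
#' @examples
#' protonated_mz("C17H17Cl2N")  # 306.0811 (sertraline)
#' @export
protonated_mz <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) stop("cannot protonate the empty formula")
  monoisotopic_mass(f) + .PROTON_MASS
}

#' Signed mass error in parts per million
#'
#' \code{(measured - theoretical) / theoretical * 1e6}, the accuracy currency
#' of high-resolution MS.
#'
#' @param theoretical theoretical m/z (> 0).
#' @param measured measured m/z.
#' @return signed ppm error; exactly 0 when the inputs are identical.
#' @examples
#' ppm_error(306.0811, 306.0823)  # +3.9 ppm
#' @export
ppm_error <- function(theoretical, measured) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  (measured - theoretical) / theoretical * 1e6
}

#' Apply a signed element-count delta to a formula
#'
#' The arithmetic behind biotransformation rules: hydroxylation is
#' \code{c(O = 1)}, demethylation \code{c(C = -1, H = -2)}, condensation with
#' phenylalanine \code{c(C = 9, H = 9, N = 1, O = 1)}.
#'
#' @inheritParams format_formula
#' @param delta named numeric vector of signed element-count changes.
#' @return the resulting \code{chem_formula}.
#' @examples
#' apply_delta("C19H23ClN2", c(O = 1))          # hydroxy-clomipramine
#' apply_delta("C19H23ClN2", c(C = -1, H = -2)) # demethyl-clomipramine
#' @export
apply_delta <- function(f, delta) {
  f <- as_formula(f)
  stopifnot(is.numeric(delta))
  if (length(delta) && is.null(names(delta))) stop("delta must be named")
  unknown <- setdiff(names(delta), names(.MONO_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s) in delta: ", paste(unknown, collapse = ", "))
  }
  elems <- union(names(f), names(delta))
  out <- stats::setNames(numeric(length(elems)), elems)
  out[names(f)] <- f
  out[names(delta)] <- out[names(delta)] + delta
  neg <- names(out)[out < 0]
  if (length(neg)) {
    stop("delta would make element count negative: ", paste(neg, collapse = ", "))
  }
  as_formula(out)
}
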