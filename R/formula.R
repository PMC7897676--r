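#' @title Elemental formulas: parsing, algebra and exact mass
#' @description An elemental formula is a named integer vector of element
#'   counts (class \code{chem_formula}); it is the unit of all mass
#'   computation in npsid. Formulas print and round-trip in Hill order
#'   (C, H, then remaining elements alphabetically).
#' @name formulas
NULL

#' Default allowed element set
#'
#' The CHNO set covers all compositions relevant to methoxy-PCP and
#' methcathinone chemistry; restricting the parser to it prevents silent
#' typos (e.g. "C18H27N0" with a zero for an O). Extend via the
#' \code{allowed} argument of [parse_formula()].
#' @keywords internal
DEFAULT_ELEMENTS <- c("C", "H", "N", "O")

#' Construct a formula from element counts
#'
#' Low-level constructor: builds a \code{chem_formula} directly from a
#' named integer vector of counts (zero counts are dropped, Hill order is
#' applied). Most users should call [parse_formula()].
#'
#' @param counts Named non-negative integer vector, e.g.
#'   \code{c(C = 18L, H = 27L, N = 1L, O = 1L)}.
#' @return A \code{chem_formula}.
#' @export
new_chem_formula <- function(counts) {
  counts <- counts[counts > 0]
  stopifnot(all(counts == as.integer(counts)), all(counts >= 0))
  counts <- counts[hill_order(names(counts))]
  structure(as.integer(counts), names = names(counts), class = "chem_formula")
}

hill_order <- function(elements) {
  rest <- setdiff(sort(elements), c("C", "H"))
  match(intersect(c("C", "H", rest), elements), elements)
}

#' Parse an elemental formula string
#'
#' Accepts the usual element-count grammar (\code{"C18H28NO"}) where an
#' omitted count means 1. Element symbols must belong to the allowed set.
#'
#' @param text A single formula string, e.g. \code{"C18H27NO"}.
#' @param allowed Character vector of permitted element symbols.
#' @return A \code{chem_formula}: named integer vector of counts in Hill
#'   order.
#' @export
#' @examples
#' parse_formula("C18H28NO")
#' parse_formula("C23H34NO7")
parse_formula <- function(text, allowed = DEFAULT_ELEMENTS) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop(sprintf("cannot parse formula '%s'", text), call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  bad <- setdiff(sym, allowed)
  if (length(bad)) {
    stop(sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  new_chem_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

#' Formula algebra
#'
#' Elementwise addition and subtraction of element counts. Subtraction that
#' would drive any count negative signals an infeasible-transformation error;
#' this is how chemically impossible biotransformation paths are pruned.
#'
#' @param a,b \code{chem_formula} objects (see [parse_formula()]).
#' @return A \code{chem_formula}.
#' @export
#' @examples
#' add_formula(parse_formula("C17H25NO"), parse_formula("CH2"))
#' subtract_formula(parse_formula("C18H27NO"), parse_formula("CH2"))
add_formula <- function(a, b) {
  els <- union(names(a), names(b))
  counts <- stats::setNames(integer(length(els)), els)
  counts[names(a)] <- counts[names(a)] + unclass(a)
  counts[names(b)] <- counts[names(b)] + unclass(b)
  new_chem_formula(counts)
}

#' @rdname add_formula
#' @export
subtract_formula <- function(a, b) {
  els <- union(names(a), names(b))
  counts <- stats::setNames(integer(length(els)), els)
  counts[names(a)] <- counts[names(a)] + unclass(a)
  counts[names(b)] <- counts[names(b)] - unclass(b)
  if (any(counts < 0)) {
    stop(sprintf("infeasible transformation: %s - %s would give a negative count",
                 format(a), format(b)), call. = FALSE)
  }
  new_chem_formula(counts)
}

formula_count <- function(f, element) {
  i <- match(element, names(f))
  if (is.na(i)) 0L else unclass(f)[[i]]
}

#' Ion species
#'
#' Couples an ion's elemental formula (protons included, e.g. C18H28NO for
#' the MH+ of 3-MeO-PCP, C18H27NO) with its charge. By default the electron
#' mass is subtracted for cations (and added for anions) when computing m/z;
#' this correction is required to reproduce reference MH+ exact masses to
#' 4 decimals (274.2165 for C18H28NO+, not 274.2171).
#'
#' @param formula A \code{chem_formula} or formula string (the ion's
#'   composition, protons included).
#' @param charge Signed integer charge, non-zero; default +1 (protonated
#'   molecule).
#' @param electron_correction Subtract \code{charge} electron masses?
#'   Default \code{TRUE}.
#' @return An object of class \code{ion_species}.
#' @export
#' @examples
#' ion_species("C18H28NO")        # MH+ of 3-MeO-PCP
ion_species <- function(formula, charge = 1L, electron_correction = TRUE) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "chem_formula"))
  charge <- as.integer(charge)
  if (is.na(charge)) stop("charge must be an integer", call. = FALSE)
  structure(list(formula = formula, charge = charge,
                 electron_correction = isTRUE(electron_correction)),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  z <- x$charge
  zs <- if (z == 0) "" else paste0(if (abs(z) > 1) abs(z) else "",
                                   if (z > 0) "+" else "-")
  cat("<ion>", paste0(format(x$formula), zs), "\n")
  invisible(x)
}

#' Protonate a neutral formula
#'
#' Returns the MH+ ion species of a neutral molecule (adds one H, charge +1).
#' @param neutral A \code{chem_formula} or string.
#' @return An \code{ion_species}.
#' @export
#' @examples
#' mh_ion("C18H27NO")
mh_ion <- function(neutral) {
  if (is.character(neutral)) neutral <- parse_formula(neutral)
  ion_species(add_formula(neutral, new_chem_formula(c(H = 1L))), charge = 1L)
}

#' Exact (monoisotopic) mass and m/z
#'
#' Sum of the lightest-isotope exact masses of all atoms, minus
#' \code{charge} electron masses when the electron correction is on, divided
#' by |charge| for ions. Neutral molecules (charge 0 via a bare
#' \code{chem_formula}) return the neutral monoisotopic mass.
#'
#' @param x An \code{ion_species} or \code{chem_formula} (treated as
#'   neutral).
#' @param constants Constants list from [npsid_constants()].
#' @param digits If non-NULL, round (half-even, R convention) to this many
#'   decimals for display; internal computation is full precision.
#' @return Numeric m/z (Da per unit charge).
#' @export
#' @examples
#' exact_mass(ion_species("C18H28NO"), digits = 4)  # 274.2165
#' exact_mass(ion_species("C11H16NO"), digits = 4)  # 178.1226
exact_mass <- function(x, constants = default_constants(), digits = NULL) {
  if (inherits(x, "chem_formula")) {
    f <- x; z <- 0L; ecorr <- FALSE
  } else if (inherits(x, "ion_species")) {
    f <- x$formula; z <- x$charge; ecorr <- x$electron_correction
    if (z == 0L) stop("ionic mass computation requires charge != 0", call. = FALSE)
  } else stop("x must be a chem_formula or ion_species", call. = FALSE)
  miss <- setdiff(names(f), names(constants$isotopes))
  if (length(miss)) {
    stop(sprintf("no atomic mass data for element(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  mono <- vapply(names(f), function(el) constants$isotopes[[el]]$mass[1L], 0)
  mass <- sum(mono * unclass(f))
  if (ecorr) mass <- mass - z * constants$electron_mass
  mz <- if (z == 0L) mass else mass / abs(z)
  if (!is.null(digits)) round(mz, digits) else mz
}

#' Mass accuracy in parts per million
#'
#' \eqn{\Delta m = (accurate - exact)/exact \times 10^6}, the standard
#' signed mass-accuracy measure for high-resolution MS.
#'
#' @param accurate Measured (accurate) m/z.
#' @param exact Theoretical (exact) m/z; must be positive.
#' @param digits Decimals for display rounding (default 2, as conventionally
#'   reported); \code{NULL} for full precision.
#' @return Signed ppm error (vectorised over inputs).
#' @export
#' @examples
#' ppm_error(274.2164, 274.2165)  # -0.36
ppm_error <- function(accurate, exact, digits = 2) {
  if (any(exact <= 0)) stop("exact mass must be positive", call. = FALSE)
  p <- (accurate - exact) / exact * 1e6
  if (!is.null(digits)) round(p, digits) else p
}

#' Ring-and-double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1 on a neutral CHNO formula; a valence-based
#' plausibility filter for candidate compositions (integer for closed-shell
#' molecules, half-integer otherwise).
#'
#' @param neutral A \code{chem_formula} or string (neutral molecule).
#' @return Numeric RDBE.
#' @export
#' @examples
#' rdbe("C18H27NO")  # 6
#' rdbe("C11H15NO")  # 5
rdbe <- function(neutral) {
  if (is.character(neutral)) neutral <- parse_formula(neutral)
  formula_count(neutral, "C") - formula_count(neutral, "H") / 2 +
    formula_count(neutral, "N") / 2 + 1
}
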