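#' Atomic mass and isotope abundance constants
#'
#' Loads the bundled isotopic constants table (exact masses in Da and
#' natural abundances as mole fractions) shipped with the package, so that
#' all mass computation is independent of any external library's tables.
#' Per element, isotopes are ordered by increasing mass; the first (lightest)
#' isotope defines the monoisotopic mass. Abundances of each element sum to 1
#' within 1e-6.
#'
#' @param path Optional path to an alternative constants file (tab-separated
#'   with columns \code{element}, \code{isotope}, \code{mass},
#'   \code{abundance}; lines starting with \code{#} are comments).
#' @return A list with elements \code{isotopes} (named list; per element a
#'   data.frame with columns \code{isotope}, \code{mass}, \code{abundance})
#'   and \code{electron_mass} (Da).
#' @export
#' @examples
#' ct <- npsid_constants()
#' ct$isotopes$C
npsid_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atomic_masses.tsv", package = "npsid")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("atomic mass constants file not found", call. = FALSE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("element", "isotope", "mass", "abundance") %in% names(tab)))
  if (any(tab$mass <= 0)) stop("isotope masses must be positive", call. = FALSE)
  iso <- split(tab[c("isotope", "mass", "abundance")], tab$element)
  iso <- lapply(iso, function(d) {
    d <- d[order(d$mass), , drop = FALSE]
    rownames(d) <- NULL
    if (abs(sum(d$abundance) - 1) > 1e-6) {
      stop("isotope abundances must sum to 1 within 1e-6", call. = FALSE)
    }
    d
  })
  list(isotopes = iso, electron_mass = 0.000548579909065)
}

# memoised default table; constants are immutable for a given install
.npsid_env <- new.env(parent = emptyenv())

default_constants <- function() {
  if (is.null(.npsid_env$constants)) {
    .npsid_env$constants <- npsid_constants()
  }
  .npsid_env$constants
}
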