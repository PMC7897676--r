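#' @title Elemental composition search from accurate mass
#' @description Identify an unknown powder constituent from the accurate
#'   m/z of its protonated molecule: exhaustively enumerate neutral CHNO
#'   compositions over per-element count ranges, keep those whose MH+ exact
#'   m/z lies within a ppm window of the observation and whose
#'   ring-and-double-bond equivalents (RDBE) are plausible, and rank by
#'   mass accuracy.
#' @name powder_id
NULL

#' Composition search space
#'
#' @param elements Named list of \code{c(min, max)} integer count ranges per
#'   element, e.g. \code{list(C = c(0, 20), H = c(0, 40), N = c(0, 2),
#'   O = c(0, 4))}.
#' @param ppm_tol Mass tolerance in ppm (> 0); default 3.
#' @param rdbe_range RDBE bounds on the neutral formula; default
#'   \code{c(0, 25)} (integer and half-integer values both allowed).
#' @return A \code{composition_space} list.
#' @export
composition_space <- function(elements = list(C = c(0L, 20L), H = c(0L, 40L),
                                              N = c(0L, 2L), O = c(0L, 4L)),
                              ppm_tol = 3, rdbe_range = c(0, 25)) {
  if (!length(elements)) stop("element ranges must be non-empty", call. = FALSE)
  for (el in names(elements)) {
    r <- elements[[el]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0) {
      stop(sprintf("bad count range for %s", el), call. = FALSE)
    }
  }
  if (ppm_tol <= 0) stop("ppm tolerance must be positive", call. = FALSE)
  structure(list(elements = elements, ppm_tol = ppm_tol,
                 rdbe_range = rdbe_range), class = "composition_space")
}

#' Search elemental compositions for an observed MH+ m/z
#'
#' Enumerates the full count lattice of the search space, computes each
#' neutral candidate's protonated-ion exact m/z (electron-corrected), and
#' returns candidates within the ppm window and RDBE bounds, ranked by
#' |mass error|. Ties are broken by RIA-fit error (when an experimental
#' isotope pattern is supplied) and then by formula text, so ranks are
#' reproducible.
#'
#' @param observed_mz Accurate m/z of the protonated molecule (> 0).
#' @param space A [composition_space()].
#' @param experimental_pattern Optional \code{isotope_pattern} of the
#'   observed ion, used for RIA-based tie-breaking and reported fit.
#' @param constants Constants list from [npsid_constants()].
#' @return Data.frame with columns \code{rank}, \code{formula} (neutral,
#'   Hill order), \code{mh_mz}, \code{dm_ppm}, \code{rdbe},
#'   \code{ria_error_pct} (NA without a pattern); zero rows if nothing
#'   matches.
#' @export
#' @examples
#' search_compositions(178.1226, composition_space())
search_compositions <- function(observed_mz, space = composition_space(),
                                experimental_pattern = NULL,
                                constants = default_constants()) {
  if (observed_mz <= 0) stop("observed m/z must be positive", call. = FALSE)
  stopifnot(inherits(space, "composition_space"))
  els <- names(space$elements)
  grid <- expand.grid(lapply(space$elements, function(r) seq.int(r[1], r[2])),
                      KEEP.OUT.ATTRS = FALSE)
  mono <- vapply(els, function(el) constants$isotopes[[el]]$mass[1L], 0)
  # MH+ m/z of each neutral candidate, vectorised over the lattice
  h_mass <- constants$isotopes[["H"]]$mass[1L]
  mz <- as.vector(as.matrix(grid) %*% mono[els]) + h_mass -
    constants$electron_mass
  dm <- (observed_mz - mz) / mz * 1e6
  cC <- if ("C" %in% els) grid$C else 0L
  cH <- if ("H" %in% els) grid$H else 0L
  cN <- if ("N" %in% els) grid$N else 0L
  rd <- cC - cH / 2 + cN / 2 + 1
  keep <- abs(dm) <= space$ppm_tol & rd >= space$rdbe_range[1] &
    rd <= space$rdbe_range[2] & rowSums(grid) > 0
  if (!any(keep)) {
    return(data.frame(rank = integer(), formula = character(),
                      mh_mz = numeric(), dm_ppm = numeric(), rdbe = numeric(),
                      ria_error_pct = numeric()))
  }
  grid <- grid[keep, , drop = FALSE]
  hits <- data.frame(
    formula = apply(grid, 1L, function(cnt) {
      format(new_chem_formula(stats::setNames(as.integer(cnt), els)))
    }),
    mh_mz = mz[keep], dm_ppm = dm[keep], rdbe = rd[keep],
    ria_error_pct = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(experimental_pattern)) {
    exp_ria <- ria(experimental_pattern)
    hits$ria_error_pct <- vapply(hits$formula, function(ftxt) {
      calc <- isotope_pattern(mh_ion(parse_formula(ftxt, allowed = els)),
                              n_labels = 2L, constants = constants)
      ria_error(exp_ria, ria(calc), digits = NULL)
    }, 0)
  }
  ria_key <- ifelse(is.na(hits$ria_error_pct), Inf, abs(hits$ria_error_pct))
  ord <- order(abs(hits$dm_ppm), ria_key, hits$formula)
  hits <- hits[ord, , drop = FALSE]
  hits <- cbind(rank = seq_len(nrow(hits)), hits)
  rownames(hits) <- NULL
  hits
}
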