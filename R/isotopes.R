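#' @title Isotope pattern simulation and comparison
#' @description MH+ isotopic patterns (M+0..M+3) computed by full
#'   multinomial convolution of per-element isotope distributions,
#'   aggregated into unit nominal-mass bins. The m/z reported for an M+k
#'   bin is that of the bin's most abundant isotopologue (not an
#'   abundance-weighted centroid): for CHNO ions the M+1/M+2 bins are
#'   dominated by pure 13C substitution, while for oxygen-rich ions the
#'   M+3 bin is typically dominated by the 13C+18O isotopologue -- both
#'   conventions are what high-resolution instruments report for the most
#'   intense centroid in each cluster.
#' @name isotopes
NULL

# per-element enumeration: all isotope-substitution vectors of n atoms with
# total nominal shift <= shift_max. Returns data.frame(shift, dmass, ab)
# with abundance relative to the all-lightest configuration.
element_terms <- function(iso, n, shift_max) {
  k <- nrow(iso)
  d <- round(iso$mass - iso$mass[1L])          # nominal shift per isotope
  out <- list(data.frame(shift = 0, dmass = 0, ab = 1))
  if (k == 1L || n == 0L) return(out[[1L]])
  heavy <- seq.int(2L, k)
  # counts per heavy isotope are bounded by shift_max / d_i
  grids <- lapply(heavy, function(i) 0:min(n, shift_max %/% d[i]))
  combos <- expand.grid(grids)
  res <- lapply(seq_len(nrow(combos)), function(r) {
    ni <- as.integer(combos[r, ])
    if (sum(ni) == 0L || sum(ni) > n) return(NULL)
    shift <- sum(ni * d[heavy])
    if (shift > shift_max) return(NULL)
    # multinomial coefficient n! / ((n - sum ni)! prod ni!)
    coef <- 1
    rem <- n
    for (j in seq_along(ni)) {
      coef <- coef * choose(rem, ni[j])
      rem <- rem - ni[j]
    }
    ab <- coef * prod((iso$abundance[heavy] / iso$abundance[1L])^ni)
    data.frame(shift = shift,
               dmass = sum(ni * (iso$mass[heavy] - iso$mass[1L])),
               ab = ab)
  })
  rbind(out[[1L]], do.call(rbind, res))
}

#' Simulate an isotopic pattern
#'
#' Computes the M+0..M+(n_labels-1) isotopologue pattern of an ion by exact
#' multinomial convolution over its elements, with abundances normalised to
#' M+0 = 1.
#'
#' @param ion An \code{ion_species} (see [ion_species()], [mh_ion()]) or a
#'   \code{chem_formula}/string treated as a +1 ion composition.
#' @param n_labels Number of isotopologue bins, 1 to 4 (default 4, M+0..M+3).
#' @param constants Constants list from [npsid_constants()].
#' @return An \code{isotope_pattern}: data.frame with columns \code{label}
#'   ("M+0".."M+3"), \code{mz} and \code{abundance} (M+0 = 1).
#' @export
#' @examples
#' isotope_pattern(mh_ion("C18H27NO"))
isotope_pattern <- function(ion, n_labels = 4L,
                            constants = default_constants()) {
  if (is.character(ion) || inherits(ion, "chem_formula")) ion <- ion_species(ion)
  stopifnot(inherits(ion, "ion_species"))
  n_labels <- as.integer(n_labels)
  if (is.na(n_labels) || n_labels < 1L || n_labels > 4L) {
    stop("n_labels must be between 1 and 4", call. = FALSE)
  }
  f <- ion$formula
  if (length(f) == 0L) stop("formula is empty", call. = FALSE)
  miss <- setdiff(names(f), names(constants$isotopes))
  if (length(miss)) {
    stop(sprintf("no isotope data for element(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  shift_max <- n_labels - 1L
  acc <- data.frame(shift = 0, dmass = 0, ab = 1)
  for (el in names(f)) {
    terms <- element_terms(constants$isotopes[[el]], formula_count(f, el),
                           shift_max)
    acc <- merge_terms(acc, terms, shift_max)
  }
  m0 <- exact_mass(ion, constants = constants)
  z <- abs(ion$charge)
  if (z == 0L) z <- 1L
  labels <- paste0("M+", 0:shift_max)
  mz <- ab <- numeric(n_labels)
  for (s in 0:shift_max) {
    bin <- acc[acc$shift == s, , drop = FALSE]
    if (nrow(bin) == 0L) { mz[s + 1L] <- NA_real_; ab[s + 1L] <- 0; next }
    ab[s + 1L] <- sum(bin$ab)
    mz[s + 1L] <- m0 + bin$dmass[which.max(bin$ab)] / z
  }
  new_isotope_pattern(labels, mz, ab / ab[1L])
}

# cross-element convolution of (shift, dmass, ab) term tables
merge_terms <- function(a, b, shift_max) {
  idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  shift <- a$shift[idx$i] + b$shift[idx$j]
  keep <- shift <= shift_max
  data.frame(shift = shift[keep],
             dmass = a$dmass[idx$i][keep] + b$dmass[idx$j][keep],
             ab = a$ab[idx$i][keep] * b$ab[idx$j][keep])
}

#' Construct an isotope pattern from observed peaks
#'
#' Normalises raw intensities so M+0 = 1; the pattern is therefore
#' scale-invariant in the raw intensities.
#'
#' @param labels Character labels ("M+0".."M+3"), ordered.
#' @param mz Numeric m/z per label (strictly increasing where present).
#' @param intensity Non-negative intensities (raw or relative).
#' @return An \code{isotope_pattern}.
#' @export
new_isotope_pattern <- function(labels, mz, intensity) {
  stopifnot(length(labels) == length(mz), length(mz) == length(intensity))
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (labels[1L] != "M+0") stop("pattern must start at M+0", call. = FALSE)
  ok <- !is.na(mz)
  if (any(diff(mz[ok]) <= 0)) {
    stop("m/z must be strictly increasing across labels", call. = FALSE)
  }
  if (is.na(intensity[1L]) || intensity[1L] <= 0) {
    stop("M+0 intensity must be positive", call. = FALSE)
  }
  structure(data.frame(label = labels, mz = mz,
                       abundance = intensity / intensity[1L],
                       stringsAsFactors = FALSE),
            class = c("isotope_pattern", "data.frame"))
}

#' Relative isotopic abundance (RIA)
#'
#' The M+1/M+0 ion-abundance ratio of a pattern.
#'
#' @param pattern An \code{isotope_pattern} containing M+0 and M+1.
#' @return Dimensionless ratio.
#' @export
ria <- function(pattern) {
  i0 <- match("M+0", pattern$label)
  i1 <- match("M+1", pattern$label)
  if (is.na(i1) || is.na(pattern$abundance[i1])) {
    stop("pattern has no M+1 abundance", call. = FALSE)
  }
  pattern$abundance[i1] / pattern$abundance[i0]
}

#' RIA error in percent
#'
#' (experimental RIA - calculated RIA) / calculated RIA x 100, the standard
#' relative-isotopic-abundance agreement measure.
#'
#' @param experimental_ria,calculated_ria RIA ratios; calculated must be
#'   positive.
#' @param digits Display rounding (default 2 decimals); \code{NULL} for
#'   full precision.
#' @return Signed percent.
#' @export
#' @examples
#' ria_error(0.19, 0.20)  # -5
ria_error <- function(experimental_ria, calculated_ria, digits = 2) {
  if (any(calculated_ria <= 0)) {
    stop("calculated RIA must be positive", call. = FALSE)
  }
  e <- (experimental_ria - calculated_ria) / calculated_ria * 100
  if (!is.null(digits)) round(e, digits) else e
}

#' Compare experimental and calculated isotope patterns
#'
#' Per-label mass accuracy (ppm) and M+1/M+0 RIA error, with pass flags at
#' the configured tolerances. Labels absent from the experimental pattern
#' (truncated envelopes of low-abundance species) are recorded as absent,
#' not failed.
#'
#' @param experimental,calculated \code{isotope_pattern} objects sharing
#'   M+0.
#' @param ppm_tol Per-label ppm tolerances, recycled to the calculated
#'   pattern length. Defaults 5/5/5/7.5 ppm for M+0..M+3, enveloping mass
#'   accuracies observed on Orbitrap instruments at these masses.
#' @param ria_tol_pct Relative RIA tolerance in percent (default 20).
#' @return A \code{pattern_agreement} list: \code{per_label} data.frame
#'   (label, dm_ppm, pass, present), \code{ria_error_pct},
#'   \code{ria_pass}, \code{pass} (all present labels and RIA pass).
#' @export
compare_patterns <- function(experimental, calculated,
                             ppm_tol = c(5, 5, 5, 7.5), ria_tol_pct = 20) {
  stopifnot(inherits(experimental, "data.frame"),
            inherits(calculated, "data.frame"))
  ppm_tol <- rep_len(ppm_tol, nrow(calculated))
  per <- lapply(seq_len(nrow(calculated)), function(i) {
    lab <- calculated$label[i]
    j <- match(lab, experimental$label)
    present <- !is.na(j) && !is.na(experimental$mz[j])
    if (!present) {
      return(data.frame(label = lab, dm_ppm = NA_real_, pass = NA,
                        present = FALSE))
    }
    dm <- ppm_error(experimental$mz[j], calculated$mz[i], digits = NULL)
    data.frame(label = lab, dm_ppm = dm, pass = abs(dm) <= ppm_tol[i],
               present = TRUE)
  })
  per <- do.call(rbind, per)
  re <- NA_real_; rp <- NA
  if ("M+1" %in% experimental$label &&
      !is.na(experimental$abundance[match("M+1", experimental$label)])) {
    re <- ria_error(ria(experimental), ria(calculated), digits = NULL)
    rp <- abs(re) <= ria_tol_pct
  }
  structure(list(per_label = per, ria_error_pct = re, ria_pass = rp,
                 pass = all(per$pass[per$present]) && isTRUE(rp | is.na(rp))),
            class = "pattern_agreement")
}

#' @export
print.pattern_agreement <- function(x, ...) {
  cat("<pattern agreement>\n")
  print(x$per_label, row.names = FALSE)
  cat(sprintf("RIA error: %s%%  overall pass: %s\n",
              if (is.na(x$ria_error_pct)) "NA" else
                formatC(x$ria_error_pct, digits = 2, format = "f"), x$pass))
  invisible(x)
}
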