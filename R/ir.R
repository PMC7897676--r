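#' @title Infrared spectral library search
#' @description Solid-deposition GC-FTIR spectra are compared by a quality
#'   match factor (QMF): the Pearson correlation of Savitzky-Golay first
#'   derivatives of the two spectra, clamped at zero and expressed in
#'   percent. Differentiation suppresses baseline offsets and slow drift
#'   and weights the sharp, structure-specific bands of the fingerprint
#'   region (below ~1500 cm-1), which is what makes the score discriminate
#'   positional isomers that share most of their absorption bands.
#' @name ir_match
NULL

#' Default wavenumber grid
#'
#' 650-4000 cm-1 at 4 cm-1 resolution, the standard mid-IR acquisition
#' range of solid-deposition GC-FTIR detectors.
#' @return Numeric vector of wavenumbers (ascending).
#' @export
default_ir_grid <- function() seq(650, 4000, by = 4)

#' Construct an IR spectrum
#'
#' @param wavenumber Ascending wavenumber grid (cm-1).
#' @param absorbance Absorbance vector of the same length.
#' @param name Spectrum name.
#' @param resolution Nominal resolution in cm-1 (default inferred from the
#'   grid spacing).
#' @param n_depositions Number of co-added analyte depositions this
#'   spectrum represents (default 1).
#' @return An \code{ir_spectrum}.
#' @export
ir_spectrum <- function(wavenumber, absorbance, name = "spectrum",
                        resolution = NULL, n_depositions = 1L) {
  if (length(wavenumber) != length(absorbance)) {
    stop("wavenumber and absorbance lengths differ", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  }
  if (is.null(resolution)) resolution <- stats::median(diff(wavenumber))
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance),
                 name = name, resolution = resolution,
                 n_depositions = as.integer(n_depositions)),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %s: %d points, %.0f-%.0f cm-1, %d deposition(s)\n",
              x$name, length(x$wavenumber), min(x$wavenumber),
              max(x$wavenumber), x$n_depositions))
  invisible(x)
}

#' Resample and normalise a spectrum onto a target grid
#'
#' Linear interpolation onto \code{target_grid} (points outside the
#' recorded range are truncated) followed by min-max normalisation to
#' [0, 1]. The spectrum must overlap the target grid by at least 90%.
#' A constant spectrum normalises to all zeros and is flagged degenerate.
#'
#' @param spectrum An \code{ir_spectrum}.
#' @param target_grid Ascending wavenumber grid (default
#'   [default_ir_grid()]).
#' @return An \code{ir_spectrum} on the target grid, with attribute
#'   \code{degenerate} if constant.
#' @export
preprocess_ir <- function(spectrum, target_grid = default_ir_grid()) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  inside <- target_grid >= min(spectrum$wavenumber) &
    target_grid <= max(spectrum$wavenumber)
  if (mean(inside) < 0.9) {
    stop("spectrum overlaps less than 90% of the target grid", call. = FALSE)
  }
  y <- stats::approx(spectrum$wavenumber, spectrum$absorbance,
                     xout = target_grid[inside], rule = 1)$y
  rng <- range(y)
  degenerate <- diff(rng) == 0
  y <- if (degenerate) rep(0, length(y)) else (y - rng[1]) / diff(rng)
  out <- ir_spectrum(target_grid[inside], y, name = spectrum$name,
                     resolution = stats::median(diff(target_grid)),
                     n_depositions = spectrum$n_depositions)
  attr(out, "degenerate") <- degenerate
  out
}

# Savitzky-Golay derivative filter coefficients: least-squares fit of a
# degree-p polynomial in a (2m+1)-point window, evaluated at the centre.
sg_coefficients <- function(window = 9L, order = 2L, derivative = 1L) {
  stopifnot(window %% 2L == 1L, order < window, derivative <= order)
  m <- (window - 1L) %/% 2L
  A <- outer(-m:m, 0:order, `^`)
  C <- solve(t(A) %*% A, t(A))
  C[derivative + 1L, ] * factorial(derivative)
}

# first derivative of y on a uniform grid; edges (m points each end) are
# dropped so both spectra lose the same samples before correlation
sg_derivative <- function(y, window = 9L, order = 2L, spacing = 1) {
  co <- sg_coefficients(window, order, 1L)
  n <- length(y)
  m <- (window - 1L) %/% 2L
  if (n < window) stop("spectrum shorter than the filter window", call. = FALSE)
  d <- vapply(seq.int(m + 1L, n - m), function(i) {
    sum(co * y[(i - m):(i + m)])
  }, 0)
  d / spacing
}

#' Quality match factor between two spectra
#'
#' First-derivative correlation score: both spectra are differentiated
#' with a Savitzky-Golay filter (default 9-point window, order-2
#' polynomial) and the Pearson correlation r of the derivative vectors is
#' reported as QMF = 100 * max(r, 0). The score is symmetric and invariant
#' to positive affine rescaling of either spectrum; zero-variance
#' derivatives give QMF 0 with a degenerate flag.
#'
#' @param query,reference \code{ir_spectrum} objects on the same grid,
#'   at least 16 points.
#' @param window,order Savitzky-Golay window (odd) and polynomial order.
#' @return QMF in percent (attribute \code{degenerate} flags zero-variance
#'   input).
#' @export
#' @examples
#' g <- default_ir_grid()
#' s <- ir_spectrum(g, dnorm(g, 1200, 20) + dnorm(g, 2900, 40))
#' qmf(s, s)  # 100
qmf <- function(query, reference, window = 9L, order = 2L) {
  stopifnot(inherits(query, "ir_spectrum"), inherits(reference, "ir_spectrum"))
  if (length(query$wavenumber) != length(reference$wavenumber) ||
      any(abs(query$wavenumber - reference$wavenumber) > 1e-9)) {
    stop("spectra must share one wavenumber grid", call. = FALSE)
  }
  if (length(query$wavenumber) < 16L) {
    stop("spectra must have at least 16 points", call. = FALSE)
  }
  dq <- sg_derivative(query$absorbance, window, order)
  dr <- sg_derivative(reference$absorbance, window, order)
  if (stats::sd(dq) == 0 || stats::sd(dr) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  r <- stats::cor(dq, dr)
  structure(100 * max(r, 0), degenerate = FALSE)
}

#' Search a spectral library
#'
#' Scores the query against every library entry and returns the hit list
#' ranked by descending QMF; ties are broken alphabetically by entry name
#' so ranks are reproducible.
#'
#' @param query An \code{ir_spectrum}.
#' @param library Named list of \code{ir_spectrum} objects (an IR
#'   library); names must be unique.
#' @param preprocess Preprocess query and entries onto the common default
#'   grid first? Default TRUE.
#' @return Data.frame (rank, name, qmf).
#' @export
rank_library <- function(query, library, preprocess = TRUE) {
  if (!length(library)) stop("library is empty", call. = FALSE)
  if (anyDuplicated(names(library))) {
    stop("library entry names must be unique", call. = FALSE)
  }
  if (preprocess) {
    query <- preprocess_ir(query)
    library <- lapply(library, preprocess_ir)
  }
  scores <- vapply(library, function(refsp) as.numeric(qmf(query, refsp)), 0)
  ord <- order(-scores, names(library))
  data.frame(rank = seq_along(ord), name = names(library)[ord],
             qmf = as.numeric(scores[ord]), stringsAsFactors = FALSE)
}

#' Co-add multiple depositions
#'
#' Pointwise sum of spectra recorded over repeated depositions of the
#' GC-eluted analyte on the same disc spot. Deposition physically
#' accumulates analyte, so coherent signal grows linearly with the number
#' of runs while independent noise grows only as its square root --
#' co-addition therefore raises the signal-to-noise ratio and with it the
#' attainable QMF.
#'
#' @param depositions List of \code{ir_spectrum} objects on one grid
#'   (length >= 1).
#' @return An \code{ir_spectrum} with summed absorbance and accumulated
#'   \code{n_depositions}.
#' @export
coadd <- function(depositions) {
  if (!length(depositions)) stop("need at least one deposition", call. = FALSE)
  g <- depositions[[1]]$wavenumber
  for (s in depositions[-1]) {
    if (length(s$wavenumber) != length(g) ||
        any(abs(s$wavenumber - g) > 1e-9)) {
      stop("all depositions must share one wavenumber grid", call. = FALSE)
    }
  }
  ir_spectrum(g, Reduce(`+`, lapply(depositions, `[[`, "absorbance")),
              name = depositions[[1]]$name,
              resolution = depositions[[1]]$resolution,
              n_depositions = sum(vapply(depositions, `[[`, 0L,
                                         "n_depositions")))
}

#' Estimate the limit of identification (LOI)
#'
#' The LOI is the smallest number of co-added depositions whose median QMF
#' against the true reference reaches a library-search threshold. Each
#' replicate simulates \code{n} depositions of a low-amplitude analyte
#' signal plus per-deposition noise, a single readout noise for the
#' co-added measurement, and baseline drift; the median QMF over
#' replicates is compared to the threshold on an increasing deposition
#' ladder.
#'
#' @param reference Clean reference \code{ir_spectrum} (normalised scale).
#' @param qmf_threshold Threshold in (0, 100); 80 is a practical
#'   library-search criterion.
#' @param amplitude Analyte signal amplitude per deposition, as a fraction
#'   of the normalised reference (default 0.018, emulating the weak
#'   absorbances of trace analytes in extracted biofluids relative to the
#'   detector noise floor: a single deposition is barely above noise and
#'   not library-searchable).
#' @param deposition_noise_sd Independent noise added per deposition
#'   (default 0.0005).
#' @param readout_noise_sd Detector noise of the single co-added readout
#'   (default 0.02).
#' @param drift_amplitude Slow sinusoidal baseline drift amplitude per
#'   readout (default 0.005).
#' @param max_depositions Ladder maximum (default 14).
#' @param n_replicates Replicates per ladder step (>= 30 recommended).
#' @param seed Integer seed; replicate r at step n uses a deterministic
#'   sub-seed so the ladder is reproducible.
#' @return List with \code{loi} (smallest n meeting the threshold, or NA
#'   if "not reached") and \code{ladder} (data.frame n, median_qmf).
#' @export
limit_of_identification <- function(reference, qmf_threshold = 80,
                                    amplitude = 0.018,
                                    deposition_noise_sd = 5e-4,
                                    readout_noise_sd = 0.02,
                                    drift_amplitude = 0.005,
                                    max_depositions = 14L,
                                    n_replicates = 30L, seed = 1L) {
  if (qmf_threshold <= 0 || qmf_threshold >= 100) {
    stop("qmf_threshold must be in (0, 100)", call. = FALSE)
  }
  ref <- preprocess_ir(reference)
  g <- ref$wavenumber
  med <- numeric(max_depositions)
  for (n in seq_len(max_depositions)) {
    qs <- vapply(seq_len(n_replicates), function(r) {
      set.seed(seed * 10000L + n * 100L + r)
      y <- n * amplitude * ref$absorbance +
        stats::rnorm(length(g), sd = deposition_noise_sd * sqrt(n)) +
        stats::rnorm(length(g), sd = readout_noise_sd) +
        drift_amplitude * sin(2 * pi * (g - min(g)) / diff(range(g)) *
                                stats::runif(1, 0.5, 2) +
                                stats::runif(1, 0, 2 * pi))
      as.numeric(qmf(ir_spectrum(g, y), ref))
    }, 0)
    med[n] <- stats::median(qs)
  }
  ladder <- data.frame(n = seq_len(max_depositions), median_qmf = med)
  reached <- which(med >= qmf_threshold)
  list(loi = if (length(reached)) min(reached) else NA_integer_,
       ladder = ladder)
}
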