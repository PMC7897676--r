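#' @title Seeded synthetic-data generators
#' @description Raw casework data behind forensic identifications are
#'   rarely released, so every pipeline stage here is exercised against
#'   ground-truth-tagged synthetic inputs: MS1 peak tables emulating the
#'   statistical structure of a metabolite screen (ppm-scale mass jitter,
#'   earlier-eluting metabolites, log-normal abundances, decoy features)
#'   and IR libraries containing positional-isomer families that share
#'   most absorption bands but differ in the fingerprint region. All
#'   generators are deterministic given their seed.
#' @name synthetic_data
NULL

#' MS simulation configuration
#'
#' @param parent_formula Neutral parent formula string.
#' @param parent_rt Parent retention time in minutes.
#' @param rules Transformation rules (default [default_rule_set()]).
#' @param depth Phase I enumeration depth.
#' @param include Character vector of planted analytes: acronyms from the
#'   bundled reference (default: all reference analytes).
#' @param abundances Named numeric vector of mean abundances per planted
#'   acronym; unnamed analytes draw from the log-normal below.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model for
#'   analytes without an explicit abundance (defaults log(1e6) and 1.5,
#'   giving the 2-3 orders of magnitude dynamic range typical of urinary
#'   metabolite profiles).
#' @param mass_jitter_ppm Gaussian m/z jitter sigma in ppm (default 0.5,
#'   consistent with sub-1.4 ppm accuracies of externally calibrated
#'   Orbitrap data).
#' @param mass_bias_ppm Systematic mass bias in ppm (default 0).
#' @param rt_model "uniform" draws metabolite tR uniformly in
#'   (0.4, 0.98) x parent_rt (metabolites are more polar and elute
#'   earlier); "reference" uses the reference tR values.
#' @param envelope_noise Relative noise on isotopologue abundances
#'   (default 0.02).
#' @param n_decoys Number of decoy peaks uniform in m/z (default 50).
#' @param decoy_mz_range m/z range for decoys.
#' @param seed Integer seed recorded in the output.
#' @return A list of class \code{ms_sim_config}.
#' @export
ms_sim_config <- function(parent_formula = "C18H27NO", parent_rt = 7.74,
                          rules = default_rule_set(), depth = 3L,
                          include = NULL, abundances = NULL,
                          abundance_meanlog = log(1e6),
                          abundance_sdlog = 1.5,
                          mass_jitter_ppm = 0.5, mass_bias_ppm = 0,
                          rt_model = c("uniform", "reference"),
                          envelope_noise = 0.02, n_decoys = 50L,
                          decoy_mz_range = c(100, 520), seed = 1L) {
  if (mass_jitter_ppm < 0 || envelope_noise < 0) {
    stop("noise parameters must be non-negative", call. = FALSE)
  }
  structure(list(parent_formula = parent_formula, parent_rt = parent_rt,
                 rules = rules, depth = as.integer(depth),
                 include = include, abundances = abundances,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 mass_jitter_ppm = mass_jitter_ppm,
                 mass_bias_ppm = mass_bias_ppm,
                 rt_model = match.arg(rt_model),
                 envelope_noise = envelope_noise,
                 n_decoys = as.integer(n_decoys),
                 decoy_mz_range = decoy_mz_range,
                 seed = as.integer(seed)),
            class = "ms_sim_config")
}

#' Simulate a metabolite-screen peak table
#'
#' Plants the reference analytes (parent plus metabolites) as M+0..M+3
#' isotopologue peaks with configured mass bias and jitter, envelope
#' noise, retention-time model and abundances, adds decoy peaks, and
#' returns the peak table together with a truth table mapping planted
#' analytes to their M+0 feature ids. Fully reproducible from the seed.
#'
#' @param config An [ms_sim_config()].
#' @param constants Constants list.
#' @return List with \code{peaks} (peak table data.frame), \code{truth}
#'   (acronym, mh_composition, mh_mz, rt_min, abundance, feature_id) and
#'   \code{config}.
#' @export
simulate_peak_table <- function(config = ms_sim_config(),
                                constants = default_constants()) {
  stopifnot(inherits(config, "ms_sim_config"))
  set.seed(config$seed)
  ref <- meo_pcp_reference()
  include <- config$include
  if (is.null(include)) include <- ref$acronym
  ref <- ref[match(include, ref$acronym), , drop = FALSE]
  if (anyNA(ref$acronym)) stop("unknown analyte acronym(s)", call. = FALSE)

  n <- nrow(ref)
  abund <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  names(abund) <- ref$acronym
  if (!is.null(config$abundances)) {
    common <- intersect(names(config$abundances), names(abund))
    abund[common] <- config$abundances[common]
  }
  parent_acr <- ref$acronym[ref$phase == "parent"]
  rt <- if (config$rt_model == "reference") ref$rt_min else
    stats::runif(n, 0.4 * config$parent_rt, 0.98 * config$parent_rt)
  rt[ref$phase == "parent"] <- config$parent_rt
  if (config$rt_model == "uniform") {
    # planted isomer features sharing one composition must be
    # chromatographically resolved, or they would not be distinct ground
    # truth: enforce a minimum separation well above the grouping window
    for (comp in unique(ref$mh_composition)) {
      idx <- which(ref$mh_composition == comp & ref$phase != "parent")
      while (length(idx) > 1 && min(diff(sort(rt[idx]))) < 0.15) {
        rt[idx] <- stats::runif(length(idx), 0.4 * config$parent_rt,
                                0.98 * config$parent_rt)
      }
    }
  }

  rows <- list()
  truth <- list()
  fid <- 0L
  for (i in seq_len(n)) {
    pat <- isotope_pattern(ion_species(parse_formula(ref$mh_composition[i])),
                           constants = constants)
    jit <- config$mass_bias_ppm +
      stats::rnorm(4, sd = config$mass_jitter_ppm)
    mz <- pat$mz * (1 + jit * 1e-6)
    inten <- abund[i] * pat$abundance *
      pmax(0, 1 + stats::rnorm(4, sd = config$envelope_noise))
    ids <- sprintf("F%04d", fid + 1:4)
    fid <- fid + 4L
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = ids, mz = mz, intensity = inten, rt_min = rt[i],
      product_ions_10ev = c(ref$product_ions[i], "", "", ""),
      product_ions_25ev = c(ref$product_ions[i], "", "", ""),
      product_ions_50ev = c(ref$product_ions[i], "", "", ""),
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      acronym = ref$acronym[i], mh_composition = ref$mh_composition[i],
      mh_mz = pat$mz[1], rt_min = rt[i], abundance = abund[i],
      feature_id = ids[1], stringsAsFactors = FALSE)
  }
  if (config$n_decoys > 0L) {
    dmz <- stats::runif(config$n_decoys, config$decoy_mz_range[1],
                        config$decoy_mz_range[2])
    dint <- stats::rlnorm(config$n_decoys, config$abundance_meanlog - 2,
                          config$abundance_sdlog)
    drt <- stats::runif(config$n_decoys, 0.2, 1.05 * config$parent_rt)
    ids <- sprintf("D%04d", seq_len(config$n_decoys))
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = ids, mz = dmz, intensity = dint, rt_min = drt,
      product_ions_10ev = "", product_ions_25ev = "", product_ions_50ev = "",
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, truth = do.call(rbind, truth), config = config)
}

#' Urine screening abundance profile
#'
#' Relative mean abundances emulating the urinary profile reported for a
#' 3-MeO-PCP intoxication: the parent and six metabolites (O-demethyl-,
#' O-demethyl-piperidine-OH-, O-demethyl-piperidine-di-HO-,
#' piperidine-di-HO-, and the O-demethyl- and O-demethyl-piperidine-OH-
#' glucuronides) dominate, with elevated metabolite-to-parent ratios for
#' M1g, M1h and M2a; all other analytes have minor abundances.
#'
#' @return Named numeric vector of mean abundances.
#' @export
urine_screening_abundances <- function() {
  major <- c("M1h" = 1.00e7, "M2a" = 8.0e6, "M1a" = 6.0e6,
             "3-MeO-PCP" = 5.0e6, "M1g" = 4.0e6, "M2c" = 3.0e6,
             "M1b" = 2.5e6)
  ref <- meo_pcp_reference()
  minor <- stats::setNames(rep(2.0e5, sum(!ref$acronym %in% names(major))),
                           setdiff(ref$acronym, names(major)))
  c(major, minor)
}

#' IR simulation configuration
#'
#' @param n_decoys Number of unrelated library compounds.
#' @param n_isomers Members per positional-isomer family (default 3, e.g.
#'   the 2-/3-/4-substituted series).
#' @param n_bands Bands per compound (default 12).
#' @param shared_fraction Fraction of bands shared within an isomer family
#'   (default 0.8); the differing bands are placed in the fingerprint
#'   region below 1500 cm-1, where they are sharper and more intense than
#'   the shared skeleton bands (widths 6-14 vs 15-45 cm-1), mirroring the
#'   structure-specific fingerprint bands of solid-phase spectra.
#' @param band_center_range,band_width_range,band_amplitude_range Shared
#'   band parameter ranges (cm-1, cm-1, a.u.).
#' @param fingerprint_width_range,fingerprint_amplitude_range Ranges for
#'   the isomer-distinguishing fingerprint bands.
#' @param noise_sd Additive white noise sigma on query spectra.
#' @param drift_amplitude Baseline drift amplitude on query spectra.
#' @param seed Integer seed.
#' @return A list of class \code{ir_sim_config}.
#' @export
ir_sim_config <- function(n_decoys = 20L, n_isomers = 3L, n_bands = 12L,
                          shared_fraction = 0.8,
                          band_center_range = c(700, 3900),
                          band_width_range = c(15, 45),
                          band_amplitude_range = c(0.2, 0.8),
                          fingerprint_width_range = c(6, 14),
                          fingerprint_amplitude_range = c(0.6, 1.0),
                          noise_sd = 0.01, drift_amplitude = 0.02,
                          seed = 1L) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_decoys = as.integer(n_decoys),
                 n_isomers = as.integer(n_isomers),
                 n_bands = as.integer(n_bands),
                 shared_fraction = shared_fraction,
                 band_center_range = band_center_range,
                 band_width_range = band_width_range,
                 band_amplitude_range = band_amplitude_range,
                 fingerprint_width_range = fingerprint_width_range,
                 fingerprint_amplitude_range = fingerprint_amplitude_range,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 seed = as.integer(seed)),
            class = "ir_sim_config")
}

gaussian_bands <- function(grid, centers, widths, amplitudes) {
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    y <- y + amplitudes[i] * exp(-0.5 * ((grid - centers[i]) / widths[i])^2)
  }
  y
}

#' Simulate an IR library with a positional-isomer family
#'
#' Builds a library of band-sum spectra: one family of \code{n_isomers}
#' positional isomers sharing \code{shared_fraction} of their bands (the
#' rest placed in the fingerprint region) plus \code{n_decoys} unrelated
#' compounds, together with noisy query spectra (one per isomer) carrying
#' truth labels. Reproducible from the seed.
#'
#' @param config An [ir_sim_config()].
#' @return List with \code{library} (named list of \code{ir_spectrum}),
#'   \code{queries} (named list, names = true library entry), and
#'   \code{config}.
#' @export
simulate_ir_library <- function(config = ir_sim_config()) {
  stopifnot(inherits(config, "ir_sim_config"))
  set.seed(config$seed)
  grid <- default_ir_grid()
  n_shared <- round(config$shared_fraction * config$n_bands)
  n_own <- config$n_bands - n_shared
  ru <- function(n, r) stats::runif(n, r[1], r[2])

  shared <- list(centers = ru(n_shared, config$band_center_range),
                 widths = ru(n_shared, config$band_width_range),
                 amplitudes = ru(n_shared, config$band_amplitude_range))
  lib <- list()
  for (i in seq_len(config$n_isomers)) {
    own <- list(centers = ru(n_own, c(660, 1500)),
                widths = ru(n_own, config$fingerprint_width_range),
                amplitudes = ru(n_own, config$fingerprint_amplitude_range))
    y <- gaussian_bands(grid, c(shared$centers, own$centers),
                        c(shared$widths, own$widths),
                        c(shared$amplitudes, own$amplitudes))
    nm <- sprintf("isomer_%d", i)
    lib[[nm]] <- ir_spectrum(grid, y, name = nm)
  }
  for (i in seq_len(config$n_decoys)) {
    y <- gaussian_bands(grid, ru(config$n_bands, config$band_center_range),
                        ru(config$n_bands, config$band_width_range),
                        ru(config$n_bands, config$band_amplitude_range))
    nm <- sprintf("decoy_%02d", i)
    lib[[nm]] <- ir_spectrum(grid, y, name = nm)
  }
  queries <- list()
  for (i in seq_len(config$n_isomers)) {
    nm <- sprintf("isomer_%d", i)
    y <- lib[[nm]]$absorbance +
      stats::rnorm(length(grid), sd = config$noise_sd) +
      config$drift_amplitude *
        sin(2 * pi * (grid - min(grid)) / diff(range(grid)) *
              stats::runif(1, 0.5, 2) + stats::runif(1, 0, 2 * pi))
    queries[[nm]] <- ir_spectrum(grid, y, name = paste0("query_", nm))
  }
  list(library = lib, queries = queries, config = config)
}
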