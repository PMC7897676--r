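#' @title Metabolite annotation against observed peak tables
#' @description Matches candidate metabolite formulas to centroided MS1
#'   features and scores each match against five identification criteria:
#'   (1) chromatographic behaviour relative to the parent (metabolites,
#'   being more hydrophilic, elute earlier), (2) accurate mass of the MH+
#'   ion, (3) agreement of the MH+ isotopic pattern, (4) accurate masses of
#'   collision-induced product ions, and (5) concordance with published
#'   analytical results. A candidate is "identified" when criteria 2 and 3
#'   pass together with at least one of 1, 4 or 5.
#' @name metabolite_annotation
NULL

#' Annotation configuration
#'
#' @param ppm_tol MH+ (M+0) match tolerance in ppm; default 5 (envelopes
#'   the sub-1.4 ppm accuracies typical of Orbitrap full-scan data, with
#'   margin for jitter).
#' @param label_ppm_tol Per-label tolerances for M+0..M+3 pattern
#'   comparison; default c(5, 5, 5, 7.5).
#' @param ria_tol_pct Relative RIA tolerance in percent; default 20.
#' @param rt_guard Guard band in minutes for the retention-time criterion:
#'   a metabolite passes criterion 1 iff its tR < parent tR - rt_guard.
#' @param rt_window Retention-time window (min) used to group isotopologue
#'   peaks of one feature and to separate isomeric features.
#' @param frag_ppm_tol Product-ion match tolerance in ppm; default 10.
#' @param min_product_ions Minimum matched product ions for criterion 4.
#' @return A list of class \code{annotation_config}.
#' @export
annotation_config <- function(ppm_tol = 5, label_ppm_tol = c(5, 5, 5, 7.5),
                              ria_tol_pct = 20, rt_guard = 0.1,
                              rt_window = 0.05, frag_ppm_tol = 10,
                              min_product_ions = 1L) {
  if (ppm_tol <= 0 || any(label_ppm_tol <= 0) || ria_tol_pct <= 0 ||
      frag_ppm_tol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  structure(list(ppm_tol = ppm_tol, label_ppm_tol = label_ppm_tol,
                 ria_tol_pct = ria_tol_pct, rt_guard = rt_guard,
                 rt_window = rt_window, frag_ppm_tol = frag_ppm_tol,
                 min_product_ions = as.integer(min_product_ions)),
            class = "annotation_config")
}

#' Published reference data for 3-MeO-PCP and its metabolites
#'
#' The bundled table of MH+ elemental compositions, retention times,
#' per-isotopologue exact and accurate masses and product ions reported
#' for 3-MeO-PCP and its phase I/II metabolites in human biofluids.
#' Used as the default literature evidence (criterion 5), as the default
#' product-ion reference (criterion 4), and by the synthetic-data
#' generator to plant realistic ground truth.
#'
#' @return Data.frame, one row per reported analyte (acronym, name,
#'   mh_composition, phase, artifact, rt_min, rt_all, exact/accurate/dm per
#'   isotopologue, product_ions).
#' @export
meo_pcp_reference <- function() {
  path <- system.file("extdata", "meo_pcp_reference.csv", package = "npsid")
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  ref$artifact <- as.logical(ref$artifact)
  ref
}

split_mz_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Annotate a peak table with metabolite candidates
#'
#' For every candidate formula, features whose m/z lies within
#' \code{ppm_tol} of the predicted MH+ m/z are matched; distinct features
#' (separated in retention time) are treated as isomeric features sharing
#' one composition, each scored separately, with the most abundant flagged
#' as primary. The isotope envelope of a matched feature is reconstructed
#' from peaks co-eluting within \code{rt_window} at the predicted M+1..M+3
#' m/z values.
#'
#' @param peaks Peak table data.frame (feature_id, mz, intensity, rt_min,
#'   optional product_ions_10ev/25ev/50ev columns of semicolon-separated
#'   m/z).
#' @param candidates Candidate table from [enumerate_candidates()].
#' @param parent_rt Parent compound retention time in minutes (> 0).
#' @param config An [annotation_config()].
#' @param fragment_ref Named list mapping MH+ composition to a numeric
#'   vector of reference product-ion m/z (criterion 4). Defaults to the
#'   bundled 3-MeO-PCP reference.
#' @param literature Character vector of MH+ compositions reported in the
#'   literature (criterion 5). Defaults to the bundled reference.
#' @param constants Constants list.
#' @return Data.frame with one row per (candidate, matched feature) plus
#'   one row per unmatched candidate: candidate fields, \code{feature_id},
#'   \code{rt_min}, \code{intensity}, \code{dm_ppm}, \code{ambiguous},
#'   \code{is_primary}, criterion columns (\code{c1_rt}, \code{c2_mass},
#'   \code{c3_pattern}, \code{c4_product_ions}, \code{c5_literature},
#'   with \code{c4_n_matched}, \code{ria_error_pct}) and \code{status}
#'   ("identified", "tentative" or "rejected").
#' @export
annotate <- function(peaks, candidates, parent_rt,
                     config = annotation_config(),
                     fragment_ref = NULL, literature = NULL,
                     constants = default_constants()) {
  if (parent_rt <= 0) stop("parent_rt must be positive", call. = FALSE)
  stopifnot(all(c("feature_id", "mz", "intensity", "rt_min") %in%
                  names(peaks)))
  if (is.null(fragment_ref) || is.null(literature)) {
    ref <- meo_pcp_reference()
    if (is.null(literature)) literature <- unique(ref$mh_composition)
    if (is.null(fragment_ref)) {
      fragment_ref <- lapply(split(ref$product_ions, ref$mh_composition),
                             function(x) unique(unlist(lapply(x, split_mz_list))))
    }
  }
  prod_cols <- grep("^product_ions", names(peaks), value = TRUE)

  rows <- lapply(seq_len(nrow(candidates)), function(ci) {
    cand <- candidates[ci, , drop = FALSE]
    pred <- isotope_pattern(ion_species(parse_formula(cand$mh_formula)),
                            constants = constants)
    dm_all <- (peaks$mz - cand$mh_mz) / cand$mh_mz * 1e6
    hit <- which(abs(dm_all) <= config$ppm_tol)
    if (!length(hit)) {
      return(cbind(cand[c("formula", "mh_formula", "mh_mz", "phase",
                          "n_steps", "artifact")],
                   data.frame(feature_id = NA_character_, rt_min = NA_real_,
                              intensity = NA_real_, dm_ppm = NA_real_,
                              ambiguous = FALSE, is_primary = FALSE,
                              c1_rt = NA, c2_mass = FALSE, c3_pattern = NA,
                              c4_product_ions = NA, c4_n_matched = NA_integer_,
                              c5_literature = cand$mh_formula %in% literature,
                              ria_error_pct = NA_real_,
                              status = "rejected",
                              stringsAsFactors = FALSE)))
    }
    # cluster hits into isomeric features by retention time; within one
    # cluster keep the deterministic best peak (min |dm|, tie -> intensity)
    ord <- order(peaks$rt_min[hit])
    hit <- hit[ord]
    cl <- cumsum(c(1, diff(peaks$rt_min[hit]) > config$rt_window))
    picked <- vapply(split(hit, cl), function(ix) {
      best <- order(abs(dm_all[ix]), -peaks$intensity[ix])
      ix[best[1L]]
    }, 0L)
    ambiguous <- length(hit) > length(picked) || length(picked) > 1L
    primary <- picked[which.max(peaks$intensity[picked])]

    sub <- lapply(picked, function(pk) {
      rt <- peaks$rt_min[pk]
      coel <- abs(peaks$rt_min - rt) <= config$rt_window
      # reconstruct the experimental envelope at the predicted ladder
      env_mz <- rep(NA_real_, 4); env_int <- rep(NA_real_, 4)
      env_mz[1] <- peaks$mz[pk]; env_int[1] <- peaks$intensity[pk]
      for (k in 2:4) {
        tol <- config$label_ppm_tol[k]
        cand_pk <- which(coel &
          abs(peaks$mz - pred$mz[k]) / pred$mz[k] * 1e6 <= tol)
        cand_pk <- setdiff(cand_pk, pk)
        if (length(cand_pk)) {
          j <- cand_pk[which.min(abs(peaks$mz[cand_pk] - pred$mz[k]))]
          env_mz[k] <- peaks$mz[j]; env_int[k] <- peaks$intensity[j]
        }
      }
      expat <- new_isotope_pattern(paste0("M+", 0:3), env_mz, env_int)
      agr <- compare_patterns(expat, pred,
                              ppm_tol = config$label_ppm_tol,
                              ria_tol_pct = config$ria_tol_pct)
      c3 <- isTRUE(agr$pass) && agr$per_label$present[2L]
      # criterion 4: observed product ions vs the reference fragment list
      frags_ref <- fragment_ref[[cand$mh_formula]]
      obs_frags <- unique(unlist(lapply(prod_cols, function(cn)
        split_mz_list(peaks[[cn]][pk]))))
      n4 <- if (length(frags_ref) && length(obs_frags)) {
        sum(vapply(obs_frags, function(fm)
          any(abs(fm - frags_ref) / frags_ref * 1e6 <=
                config$frag_ppm_tol), TRUE))
      } else 0L
      c4 <- if (length(frags_ref)) n4 >= config$min_product_ions else NA
      c1 <- rt < parent_rt - config$rt_guard
      c2 <- TRUE  # matched within tolerance by construction
      c5 <- cand$mh_formula %in% literature
      status <- if (c2 && c3 && (isTRUE(c1) || isTRUE(c4) || isTRUE(c5)))
        "identified" else "tentative"
      cbind(cand[c("formula", "mh_formula", "mh_mz", "phase", "n_steps",
                   "artifact")],
            data.frame(feature_id = peaks$feature_id[pk], rt_min = rt,
                       intensity = peaks$intensity[pk],
                       dm_ppm = dm_all[pk], ambiguous = ambiguous,
                       is_primary = pk == primary,
                       c1_rt = c1, c2_mass = c2, c3_pattern = c3,
                       c4_product_ions = c4, c4_n_matched = n4,
                       c5_literature = c5,
                       ria_error_pct = agr$ria_error_pct,
                       status = status, stringsAsFactors = FALSE))
    })
    do.call(rbind, sub)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select a screening panel of the most abundant analytes
#'
#' The parent compound is always included; the remaining \code{k - 1} slots
#' are filled by identified, non-artifact metabolite features in descending
#' matched intensity (ties broken alphabetically by formula, then by
#' retention time). If fewer than \code{k} analytes qualify, a shorter
#' panel is returned with a warning.
#'
#' @param annotated Annotation table from [annotate()].
#' @param k Panel size (>= 1).
#' @param parent_formula Neutral parent formula string used to pin the
#'   parent row (default "C18H27NO").
#' @return The selected annotation rows, parent first, then by descending
#'   intensity.
#' @export
select_panel <- function(annotated, k, parent_formula = "C18H27NO") {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  parent_formula <- format(parse_formula(parent_formula))
  is_parent <- annotated$formula == parent_formula &
    !is.na(annotated$feature_id)
  parent <- annotated[is_parent, , drop = FALSE]
  if (nrow(parent) > 1L) {
    parent <- parent[which.max(parent$intensity), , drop = FALSE]
  }
  pool <- annotated[!is.na(annotated$feature_id) &
                      annotated$status == "identified" &
                      !annotated$artifact &
                      annotated$formula != parent_formula, , drop = FALSE]
  # one entry per feature: a feature can match several candidate paths
  pool <- pool[!duplicated(pool$feature_id), , drop = FALSE]
  pool <- pool[order(-pool$intensity, pool$formula, pool$rt_min), ,
               drop = FALSE]
  take <- utils::head(pool, max(0L, k - nrow(parent)))
  panel <- rbind(parent, take)
  if (nrow(panel) < k) {
    warning(sprintf("only %d of %d panel slots could be filled",
                    nrow(panel), k), call. = FALSE)
  }
  rownames(panel) <- NULL
  panel
}

#' Build a reference-style annotation report
#'
#' One row per identified candidate feature, with per-isotopologue exact
#' m/z, accurate (observed) m/z and recomputed mass accuracy, plus the
#' observed product ions. Absent measurements are kept as NA and rendered
#' as "-" by [write_report()].
#'
#' @param annotated Annotation table from [annotate()].
#' @param peaks The peak table the annotation was computed from (used to
#'   recover envelope and product-ion observations).
#' @param config The [annotation_config()] used.
#' @param constants Constants list.
#' @return Data.frame of class \code{annotation_report}.
#' @export
build_report <- function(annotated, peaks, config = annotation_config(),
                         constants = default_constants()) {
  idd <- annotated[!is.na(annotated$feature_id) &
                     annotated$status == "identified", , drop = FALSE]
  if (!nrow(idd)) stop("no identified candidates to report", call. = FALSE)
  prod_cols <- grep("^product_ions", names(peaks), value = TRUE)
  rows <- lapply(seq_len(nrow(idd)), function(i) {
    r <- idd[i, , drop = FALSE]
    pred <- isotope_pattern(ion_species(parse_formula(r$mh_formula)),
                            constants = constants)
    pk <- match(r$feature_id, peaks$feature_id)
    coel <- abs(peaks$rt_min - peaks$rt_min[pk]) <= config$rt_window
    acc <- rep(NA_real_, 4)
    acc[1] <- peaks$mz[pk]
    for (k in 2:4) {
      tol <- config$label_ppm_tol[k]
      cand_pk <- which(coel &
        abs(peaks$mz - pred$mz[k]) / pred$mz[k] * 1e6 <= tol)
      cand_pk <- setdiff(cand_pk, pk)
      if (length(cand_pk)) {
        acc[k] <- peaks$mz[cand_pk[which.min(abs(peaks$mz[cand_pk] -
                                                   pred$mz[k]))]]
      }
    }
    # store display-rounded masses and recompute dm from the stored values,
    # so the report's triplets are internally consistent
    acc <- round(acc, 4)
    ex4 <- round(pred$mz, 4)
    dm <- ifelse(is.na(acc), NA_real_, round((acc - ex4) / ex4 * 1e6, 2))
    obs_frags <- sort(unique(unlist(lapply(prod_cols, function(cn)
      split_mz_list(peaks[[cn]][pk])))), decreasing = TRUE)
    data.frame(formula = r$formula, mh_composition = r$mh_formula,
               rt_min = r$rt_min,
               exact_m0 = round(pred$mz[1], 4), accurate_m0 = acc[1],
               dm_m0 = dm[1],
               exact_m1 = round(pred$mz[2], 4), accurate_m1 = acc[2],
               dm_m1 = dm[2],
               exact_m2 = round(pred$mz[3], 4), accurate_m2 = acc[3],
               dm_m2 = dm[3],
               exact_m3 = round(pred$mz[4], 4), accurate_m3 = acc[4],
               dm_m3 = dm[4],
               product_ions = paste(formatC(obs_frags, format = "f",
                                            digits = 4),
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("annotation_report", "data.frame")
  out
}
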