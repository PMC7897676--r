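#' @title Readers and writers
#' @description Delimited peak tables, IR spectra in a two-column dialect
#'   or minimal JCAMP-DX (XYDATA), annotation reports and run
#'   configuration. All readers validate structure and report malformed
#'   rows with line numbers; nothing is silently coerced.
#' @name io
NULL

PEAK_COLS <- c("feature_id", "mz", "intensity", "rt_min")

#' Read / write a peak table
#'
#' CSV with header columns \code{feature_id, mz, intensity, rt_min} and
#' optional \code{product_ions_10ev/25ev/50ev} columns holding
#' semicolon-separated product-ion m/z. Write then read is the identity on
#' canonical tables.
#'
#' @param path File path.
#' @return Peak table data.frame.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(PEAK_COLS, names(tab))
  if (length(miss)) {
    stop("peak table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("mz", "intensity", "rt_min")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & nzchar(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at line(s): %s", col,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    }
    tab[[col]] <- v
  }
  if (any(tab$mz <= 0, na.rm = TRUE)) {
    stop("m/z values must be positive", call. = FALSE)
  }
  if (any(tab$rt_min < 0, na.rm = TRUE) ||
      any(tab$intensity < 0, na.rm = TRUE)) {
    stop("retention times and intensities must be non-negative",
         call. = FALSE)
  }
  tab
}

#' @rdname read_peak_table
#' @param peaks Peak table data.frame.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IR spectrum
#'
#' Understands a minimal JCAMP-DX dialect (\code{##XYDATA=(X++(Y..Y))}
#' with \code{##FIRSTX}, \code{##LASTX}, \code{##NPOINTS},
#' \code{##YFACTOR}) and a plain two-column delimited dialect
#' (wavenumber, absorbance). Descending wavenumber order is re-sorted
#' ascending with a message.
#'
#' @param path File path (.jdx/.dx treated as JCAMP, anything else as
#'   two-column).
#' @param name Spectrum name (defaults to JCAMP TITLE or file name).
#' @return An \code{ir_spectrum}.
#' @export
read_ir <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^##XYDATA", lines))) {
    return(read_jcamp(lines, name %||% basename(path)))
  }
  fields <- strsplit(trimws(lines[nzchar(trimws(lines))]), "[,\t ]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop("expected two columns at line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 2,
                               byrow = TRUE))
  if (anyNA(m)) stop("non-numeric spectral data in ", path, call. = FALSE)
  x <- m[, 1]; y <- m[, 2]
  if (all(diff(x) < 0)) {
    message("wavenumbers were descending; re-sorted ascending")
    y <- rev(y); x <- rev(x)
  }
  ir_spectrum(x, y, name = name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_jcamp <- function(lines, default_name) {
  get_field <- function(key) {
    i <- grep(paste0("^##", key, "="), lines)
    if (!length(i)) return(NULL)
    sub(paste0("^##", key, "="), "", lines[i[1]])
  }
  title <- get_field("TITLE") %||% default_name
  firstx <- as.numeric(get_field("FIRSTX"))
  lastx <- as.numeric(get_field("LASTX"))
  npoints <- as.integer(get_field("NPOINTS"))
  yfactor <- as.numeric(get_field("YFACTOR") %||% "1")
  i0 <- grep("^##XYDATA", lines)[1]
  iend <- grep("^##END", lines)
  iend <- if (length(iend)) min(iend[iend > i0]) else length(lines) + 1L
  body <- lines[seq.int(i0 + 1L, iend - 1L)]
  ys <- lapply(strsplit(trimws(body), "[ \t]+"), function(tok) {
    as.numeric(tok[-1]) # first token per line is the X start value
  })
  y <- unlist(ys) * yfactor
  if (anyNA(c(firstx, lastx, npoints)) || length(y) != npoints) {
    stop(sprintf("malformed JCAMP-DX: NPOINTS=%s but %d Y values read",
                 npoints, length(y)), call. = FALSE)
  }
  x <- seq(firstx, lastx, length.out = npoints)
  if (firstx > lastx) { x <- rev(x); y <- rev(y)
    message("wavenumbers were descending; re-sorted ascending") }
  ir_spectrum(x, y, name = title)
}

#' Write an IR spectrum
#'
#' @param spectrum An \code{ir_spectrum}.
#' @param path Output path; \code{format} defaults to "jcamp" for
#'   .jdx/.dx files and "table" otherwise.
#' @param format "jcamp" or "table".
#' @export
write_ir <- function(spectrum, path, format = NULL) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (is.null(format)) {
    format <- if (grepl("\\.(jdx|dx)$", path, ignore.case = TRUE))
      "jcamp" else "table"
  }
  if (format == "table") {
    utils::write.table(
      data.frame(wavenumber = spectrum$wavenumber,
                 absorbance = spectrum$absorbance),
      path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  n <- length(spectrum$wavenumber)
  hdr <- c(paste0("##TITLE=", spectrum$name),
           "##JCAMP-DX=4.24", "##DATA TYPE=INFRARED SPECTRUM",
           "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
           paste0("##FIRSTX=", spectrum$wavenumber[1]),
           paste0("##LASTX=", spectrum$wavenumber[n]),
           paste0("##NPOINTS=", n), "##YFACTOR=1",
           "##XYDATA=(X++(Y..Y))")
  idx <- split(seq_len(n), (seq_len(n) - 1L) %/% 6L)
  body <- vapply(idx, function(ix) {
    paste(c(format(spectrum$wavenumber[ix[1]], digits = 12),
            format(spectrum$absorbance[ix], digits = 10)),
          collapse = " ")
  }, "")
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}

#' Write an annotation report
#'
#' Renders a [build_report()] table to CSV with absent measurements shown
#' as the conventional "-" marker.
#'
#' @param report An \code{annotation_report}.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- report
  for (col in names(out)) {
    v <- out[[col]]
    if (is.numeric(v)) v <- ifelse(is.na(v), "-", format(v, trim = TRUE))
    v[!nzchar(v)] <- "-"
    out[[col]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' JSON configuration with keys \code{ppm_tol}, \code{label_ppm_tol},
#' \code{ria_tol_pct}, \code{rt_guard}, \code{rt_window},
#' \code{frag_ppm_tol}, \code{min_product_ions}, \code{qmf_threshold},
#' \code{seed}. Unknown keys are rejected; tolerances must be positive.
#'
#' @param path JSON file path.
#' @return List with an [annotation_config()] under \code{annotation},
#'   plus \code{qmf_threshold} and \code{seed}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path)
  known <- c("ppm_tol", "label_ppm_tol", "ria_tol_pct", "rt_guard",
             "rt_window", "frag_ppm_tol", "min_product_ions",
             "qmf_threshold", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ann_keys <- intersect(names(raw), known[1:7])
  ann <- do.call(annotation_config, raw[ann_keys])
  qt <- raw$qmf_threshold %||% 80
  if (qt <= 0 || qt >= 100) {
    stop("qmf_threshold must lie in (0, 100)", call. = FALSE)
  }
  list(annotation = ann, qmf_threshold = qt,
       seed = as.integer(raw$seed %||% 1L))
}
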