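#' Construct an MS/MS spectrum
#'
#' The central container of the package: one fragment spectrum tied to a
#' precursor ion. Peaks are stored as a two-column matrix (`mz`, `intensity`)
#' and are kept sorted by ascending m/z.
#'
#' @param spectrum_id Character identifier, unique within a collection.
#' @param precursor_mz Precursor m/z in Da (> 0).
#' @param rt Retention time of the precursor apex, in seconds.
#' @param peaks Two-column numeric matrix or data frame with columns
#'   `mz` (Da, > 0) and `intensity` (>= 0).
#' @param ion_mode `"positive"` or `"negative"`.
#' @param compound_id Optional compound identifier (several spectra may share
#'   one compound).
#' @param inchikey Optional InChIKey.
#' @param ontology_terms Optional character vector of chemical-ontology term
#'   ids annotating the compound class.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, rt, peaks,
                     ion_mode = c("positive", "negative"),
                     compound_id = NULL, inchikey = NULL,
                     ontology_terms = NULL) {
  ion_mode <- match.arg(ion_mode)
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("`peaks` must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0L) {
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
    if (any(peaks[, "mz"] <= 0)) stop("peak m/z values must be > 0")
    if (any(peaks[, "intensity"] < 0)) stop("peak intensities must be >= 0")
    if (any(diff(peaks[, "mz"]) <= 0))
      stop("peak m/z values must be strictly increasing (duplicate m/z?)")
  }
  if (!isTRUE(is.finite(as.numeric(precursor_mz)) && as.numeric(precursor_mz) > 0))
    stop("`precursor_mz` must be a finite value > 0")
  structure(
    list(spectrum_id = as.character(spectrum_id),
         precursor_mz = as.numeric(precursor_mz),
         rt = as.numeric(rt),
         peaks = peaks,
         ion_mode = ion_mode,
         compound_id = if (is.null(compound_id)) NULL else as.character(compound_id),
         inchikey = if (is.null(inchikey)) NULL else as.character(inchikey),
         ontology_terms = if (is.null(ontology_terms)) NULL else as.character(ontology_terms)),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> precursor m/z %.4f @ %.1f s (%s), %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$rt, x$ion_mode,
              nrow(x$peaks)))
  if (!is.null(x$compound_id)) cat("  compound:", x$compound_id, "\n")
  if (!is.null(x$ontology_terms))
    cat("  ontology:", paste(x$ontology_terms, collapse = "; "), "\n")
  invisible(x)
}

base_peak_intensity <- function(s) {
  if (nrow(s$peaks) == 0L) 0 else max(s$peaks[, "intensity"])
}

#' Parse spectra from MSP text
#'
#' Reads a NIST-style MSP library. Recognised header keys (case-insensitive):
#' `Name`, `PrecursorMZ`/`Precursor_mz`, `RetentionTime`/`RT` (seconds unless
#' suffixed `min`), `Ion_mode` (`P`/`N`/`positive`/`negative`), `InChIKey`,
#' `Comments`, `Num Peaks`. Compound class terms travel in the `Comments`
#' field under a reserved `ontology=` key with `;`-separated term ids, and
#' the compound id under `compound=` (MSP has no standard slot for either;
#' this keeps files readable by other MSP consumers).
#'
#' @param text MSP content as a single string or character vector of lines;
#'   alternatively `file` may name a file to read.
#' @param file Optional path to an MSP file.
#' @return List of [spectrum] objects (empty list for empty input).
#' @export
parse_msp <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `text` or `file`")
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- sub("\r$", "", text)
  blank <- grepl("^\\s*$", text)
  if (all(blank)) return(list())
  # split into records on blank lines
  rec_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1L]))
  rec_id[blank] <- NA
  recs <- split(text[!blank], rec_id[!blank])
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    out[[i]] <- parse_msp_record(recs[[i]], i)
  }
  out
}

parse_msp_record <- function(lines, index) {
  is_kv <- grepl("^[A-Za-z][A-Za-z0-9_ /-]*:", lines)
  np_line <- grep("^num peaks *:", tolower(lines))
  if (length(np_line) != 1L)
    stop(sprintf("MSP record %d: missing 'Num Peaks' line", index))
  header <- lines[seq_len(np_line)]
  header <- header[is_kv[seq_len(np_line)]]
  keys <- tolower(sub(":.*$", "", header))
  vals <- trimws(sub("^[^:]*:", "", header))
  names(vals) <- trimws(keys)
  n_declared <- suppressWarnings(as.integer(vals[["num peaks"]]))
  if (is.na(n_declared))
    stop(sprintf("MSP record %d: unparseable 'Num Peaks'", index))
  peak_lines <- lines[-seq_len(np_line)]
  peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
  toks <- strsplit(trimws(peak_lines), "[ \t;]+")
  if (length(toks) != n_declared)
    stop(sprintf("MSP record %d ('%s'): declares %d peaks but lists %d",
                 index, vals["name"] %||% "?", n_declared, length(toks)))
  pk <- matrix(0, nrow = n_declared, ncol = 2,
               dimnames = list(NULL, c("mz", "intensity")))
  for (j in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[[j]][1:2]))
    if (any(is.na(v)))
      stop(sprintf("MSP record %d: malformed peak line '%s'",
                   index, peak_lines[j]))
    pk[j, ] <- v
  }
  getv <- function(...) {
    for (k in c(...)) if (!is.na(vals[k]) && !is.null(vals[[k]])) return(vals[[k]])
    NULL
  }
  rt <- getv("retentiontime", "rt", "retention_time")
  rt_val <- if (is.null(rt)) NA_real_ else {
    num <- suppressWarnings(as.numeric(sub("[^0-9.eE+-].*$", "", rt)))
    if (grepl("min", rt, ignore.case = TRUE)) num * 60 else num
  }
  mode_raw <- tolower(getv("ion_mode", "ionmode", "mode") %||% "positive")
  ion_mode <- if (startsWith(mode_raw, "n")) "negative" else "positive"
  comments <- getv("comments") %||% ""
  onto <- comment_field(comments, "ontology")
  cmpd <- comment_field(comments, "compound")
  spectrum(
    spectrum_id = getv("name") %||% sprintf("spectrum_%d", index),
    precursor_mz = as.numeric(getv("precursormz", "precursor_mz") %||% NA),
    rt = rt_val,
    peaks = pk,
    ion_mode = ion_mode,
    compound_id = cmpd,
    inchikey = getv("inchikey"),
    ontology_terms = if (is.null(onto)) NULL
                     else strsplit(onto, ";", fixed = TRUE)[[1L]])
}

comment_field <- function(comments, key) {
  m <- regmatches(comments,
                  regexpr(sprintf('%s="[^"]*"', key), comments))
  if (length(m) == 0L) return(NULL)
  sub('"$', "", sub(sprintf('^%s="', key), "", m))
}

#' Serialise spectra to MSP text
#'
#' Inverse of [parse_msp]: `parse_msp(serialize_msp(x))` reproduces every
#' field, including compound ids and ontology terms carried in `Comments`.
#'
#' @param spectra List of [spectrum] objects.
#' @param file Optional path; when given the text is also written there.
#' @return MSP text as a single string (invisibly when `file` is given).
#' @export
serialize_msp <- function(spectra, file = NULL) {
  recs <- vapply(spectra, function(s) {
    com <- character(0)
    if (!is.null(s$compound_id))
      com <- c(com, sprintf('compound="%s"', s$compound_id))
    if (!is.null(s$ontology_terms))
      com <- c(com, sprintf('ontology="%s"',
                            paste(s$ontology_terms, collapse = ";")))
    hdr <- c(
      sprintf("Name: %s", s$spectrum_id),
      sprintf("PrecursorMZ: %.6f", s$precursor_mz),
      if (!is.na(s$rt)) sprintf("RetentionTime: %.3f", s$rt),
      sprintf("Ion_mode: %s", ifelse(s$ion_mode == "negative", "N", "P")),
      if (!is.null(s$inchikey)) sprintf("InChIKey: %s", s$inchikey),
      if (length(com)) sprintf("Comments: %s", paste(com, collapse = " ")),
      sprintf("Num Peaks: %d", nrow(s$peaks)))
    pk <- sprintf("%.6f %.6g", s$peaks[, "mz"], s$peaks[, "intensity"])
    paste(c(hdr, pk), collapse = "\n")
  }, character(1))
  txt <- if (length(recs)) paste0(paste(recs, collapse = "\n\n"), "\n") else ""
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}
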