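#' Chromatographic trace
#'
#' One extracted-ion chromatogram: intensity over retention time at a fixed
#' m/z, either at MS1 level or inside a DIA isolation window (MS2).
#'
#' @param rt Strictly increasing retention times (seconds).
#' @param intensity Non-negative intensities, same length as `rt`.
#' @param mz Trace m/z center (Da).
#' @param level `"MS1"` or `"MS2"`.
#' @param window_id Isolation-window index for MS2 traces.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(rt, intensity, mz, level = c("MS1", "MS2"),
                         window_id = NULL) {
  level <- match.arg(level)
  if (length(rt) != length(intensity))
    stop("rt and intensity lengths differ")
  if (length(rt) > 1L && any(diff(rt) <= 0))
    stop("rt must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(rt = as.numeric(rt), intensity = as.numeric(intensity),
                 mz = as.numeric(mz), level = level,
                 window_id = window_id),
            class = "chromatogram")
}

#' DIA run container
#'
#' MS1 traces plus per-isolation-window MS2 traces. Windows are stepped
#' m/z ranges that jointly cover the scan range; every precursor within a
#' window is co-fragmented, so precursor-fragment links must be
#' reconstructed computationally (see [reconstruct_spectra]).
#'
#' @param ms1_traces List of MS1 [chromatogram]s.
#' @param isolation_windows Two-column matrix/data frame (`low_mz`,
#'   `high_mz`), contiguous and non-overlapping.
#' @param ms2_traces List of MS2 [chromatogram]s with valid `window_id`.
#' @param ion_mode `"positive"` or `"negative"`.
#' @return An object of class `dia_run`.
#' @export
dia_run <- function(ms1_traces, isolation_windows, ms2_traces,
                    ion_mode = c("positive", "negative")) {
  ion_mode <- match.arg(ion_mode)
  w <- as.matrix(isolation_windows)
  colnames(w) <- c("low_mz", "high_mz")
  if (any(w[, 2] <= w[, 1])) stop("isolation windows must have low < high")
  w <- w[order(w[, 1]), , drop = FALSE]
  if (nrow(w) > 1L && any(w[-1L, 1] > w[-nrow(w), 2] + 1e-9))
    stop("isolation windows leave gaps in the scan range")
  wid <- vapply(ms2_traces, function(tr) tr$window_id %||% NA_integer_,
                numeric(1))
  if (any(is.na(wid)) || any(wid < 1 | wid > nrow(w)))
    stop("every MS2 trace needs a valid window_id")
  structure(list(ms1_traces = ms1_traces, isolation_windows = w,
                 ms2_traces = ms2_traces, ion_mode = ion_mode),
            class = "dia_run")
}

#' @export
print.dia_run <- function(x, ...) {
  cat(sprintf("<dia_run> %d MS1 traces, %d MS2 traces in %d windows (%s)\n",
              length(x$ms1_traces), length(x$ms2_traces),
              nrow(x$isolation_windows), x$ion_mode))
  invisible(x)
}

#' Serialise a DIA run to JSON
#' @param run A [dia_run].
#' @param file Output path.
#' @export
write_dia_run <- function(run, file) {
  payload <- list(
    format = "specfam_dia_run", version = 1L, ion_mode = run$ion_mode,
    isolation_windows = unname(apply(run$isolation_windows, 1L, as.list)),
    ms1_traces = lapply(run$ms1_traces, unclass),
    ms2_traces = lapply(run$ms2_traces, unclass))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' Read a DIA run serialised by [write_dia_run]
#' @param file Path to the JSON file.
#' @return A [dia_run].
#' @export
read_dia_run <- function(file) {
  p <- jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
  if (!identical(p$format, "specfam_dia_run")) stop("not a DIA-run file")
  mk <- function(tr) chromatogram(unlist(tr$rt), unlist(tr$intensity),
                                  tr$mz, tr$level, tr$window_id)
  dia_run(lapply(p$ms1_traces, mk),
          do.call(rbind, lapply(p$isolation_windows, function(w)
            c(w$low_mz, w$high_mz))),
          lapply(p$ms2_traces, mk),
          p$ion_mode)
}

window_of <- function(run, mz) {
  w <- run$isolation_windows
  hit <- which(mz >= w[, 1] & mz <= w[, 2])
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Detect chromatographic peaks in a single trace
#'
#' A deliberately simple detector for reconstructed/simulated traces: local
#' maxima are accepted as peaks when their apex rises `snthresh`-fold above
#' the noise level (median absolute deviation of the off-peak trace) and
#' the peak base width falls within `peakwidth`. Peak bounds extend from
#' the apex to the first point below 2 percent of apex height (or a local
#' minimum); the area is trapezoidal over the bounds.
#'
#' @param trace A [chromatogram].
#' @param peakwidth Numeric length-2, admissible base widths in seconds.
#' @param snthresh Minimum apex/noise ratio.
#' @return Data frame with columns `mz`, `rt_apex`, `rt_lo`, `rt_hi`,
#'   `area`, `height`, `level`, `window_id` (zero rows when nothing found).
#' @export
detect_peaks <- function(trace, peakwidth = c(10, 20), snthresh = 5) {
  empty <- data.frame(mz = numeric(0), rt_apex = numeric(0),
                      rt_lo = numeric(0), rt_hi = numeric(0),
                      area = numeric(0), height = numeric(0),
                      level = character(0), window_id = integer(0))
  n <- length(trace$rt)
  if (n < 5L) return(empty)
  y <- trace$intensity
  rt <- trace$rt
  # candidate apexes: strict local maxima (plateaus take the first point)
  left <- c(-Inf, y[-n])
  right <- c(y[-1L], -Inf)
  apex <- which(y > left & y >= right & y > 0)
  if (length(apex) == 0L) return(empty)
  bounds <- lapply(apex, function(i) {
    floor_i <- 0.02 * y[i]
    slack <- 0.05 * y[i]  # tolerate noise upticks during descent
    lo <- i
    while (lo > 1L && y[lo - 1L] > floor_i && y[lo - 1L] <= y[lo] + slack)
      lo <- lo - 1L
    hi <- i
    while (hi < n && y[hi + 1L] > floor_i && y[hi + 1L] <= y[hi] + slack)
      hi <- hi + 1L
    c(lo, hi)
  })
  in_peak <- rep(FALSE, n)
  for (b in bounds) in_peak[b[1]:b[2]] <- TRUE
  # off-peak MAD; fall back to the whole trace when candidate regions cover
  # most of it (otherwise the estimate is biased low on noise-only traces)
  noise <- stats::mad(y[!in_peak])
  if (!is.finite(noise) || noise == 0 || sum(!in_peak) < n / 2)
    noise <- stats::mad(y)
  if (!is.finite(noise) || noise == 0) noise <- .Machine$double.eps
  keep <- logical(length(apex))
  for (k in seq_along(apex)) {
    b <- bounds[[k]]
    width <- rt[b[2]] - rt[b[1]]
    # half-max width guards against narrow noise spikes whose base bounds
    # wander wide by chance
    half <- which(y[b[1]:b[2]] >= 0.5 * y[apex[k]]) + b[1] - 1L
    half_w <- rt[max(half)] - rt[min(half)]
    keep[k] <- (y[apex[k]] / noise >= snthresh) &&
      width >= peakwidth[1] && width <= peakwidth[2] &&
      half_w >= 0.3 * peakwidth[1]
  }
  apex <- apex[keep]
  bounds <- bounds[keep]
  if (length(apex) == 0L) return(empty)
  # drop duplicate apexes sharing identical bounds (keep highest)
  key <- vapply(bounds, paste, character(1), collapse = ":")
  ord <- order(-y[apex])
  first <- !duplicated(key[ord])
  sel <- ord[first]
  apex <- apex[sel]; bounds <- bounds[sel]
  area <- vapply(seq_along(apex), function(k) {
    b <- bounds[[k]]
    idx <- b[1]:b[2]
    sum(diff(rt[idx]) * (y[idx][-1L] + y[idx][-length(idx)]) / 2)
  }, numeric(1))
  out <- data.frame(
    mz = trace$mz,
    rt_apex = rt[apex],
    rt_lo = vapply(bounds, function(b) rt[b[1]], numeric(1)),
    rt_hi = vapply(bounds, function(b) rt[b[2]], numeric(1)),
    area = area,
    height = y[apex],
    level = trace$level,
    window_id = trace$window_id %||% NA_integer_)
  out[order(out$rt_apex), , drop = FALSE]
}

#' Detect peaks in every trace of a DIA run
#'
#' @param run A [dia_run].
#' @param peakwidth,snthresh Passed to [detect_peaks].
#' @return List with data frames `ms1` and `ms2`; each row carries a
#'   `trace_idx` pointing back into the run's trace lists.
#' @export
detect_peaks_run <- function(run, peakwidth = c(10, 20), snthresh = 5) {
  scan <- function(traces) {
    res <- lapply(seq_along(traces), function(i) {
      p <- detect_peaks(traces[[i]], peakwidth, snthresh)
      if (nrow(p)) p$trace_idx <- i
      p
    })
    res <- res[vapply(res, nrow, integer(1)) > 0L]
    if (length(res) == 0L) {
      e <- detect_peaks(chromatogram(1:5, rep(0, 5), 0), peakwidth, snthresh)
      e$trace_idx <- integer(0)
      return(e)
    }
    do.call(rbind, res)
  }
  list(ms1 = scan(run$ms1_traces), ms2 = scan(run$ms2_traces))
}

#' Reconstruct precursor-linked MS/MS spectra from a DIA run
#'
#' For each detected MS1 peak, candidate fragments are the MS2 peaks of the
#' isolation window covering the precursor m/z whose retention-time bounds
#' overlap the precursor's. A fragment is retained when the Pearson
#' correlation of its trace with the precursor trace, evaluated on their
#' intersected RT support (the fragment trace linearly interpolated onto
#' the MS1 grid), reaches `min_cor`. Fragments with fewer than three shared
#' RT points are skipped. Precursors retaining no fragment yield no
#' spectrum.
#'
#' @param run A [dia_run].
#' @param ms1_peaks,ms2_peaks Peak tables from [detect_peaks_run] (defaults
#'   computed when `NULL`).
#' @param min_cor Minimum trace correlation (default 0.5).
#' @param peakwidth,snthresh Detection settings used when peaks are not
#'   supplied.
#' @return List of [spectrum] objects; each carries the retained fragments'
#'   trace correlations in attribute `"correlations"`.
#' @export
reconstruct_spectra <- function(run, ms1_peaks = NULL, ms2_peaks = NULL,
                                min_cor = 0.5, peakwidth = c(10, 20),
                                snthresh = 5) {
  if (is.null(ms1_peaks) || is.null(ms2_peaks)) {
    pk <- detect_peaks_run(run, peakwidth, snthresh)
    ms1_peaks <- ms1_peaks %||% pk$ms1
    ms2_peaks <- ms2_peaks %||% pk$ms2
  }
  out <- list()
  for (i in seq_len(nrow(ms1_peaks))) {
    p <- ms1_peaks[i, ]
    win <- window_of(run, p$mz)
    if (is.na(win)) next
    cand <- ms2_peaks[ms2_peaks$window_id == win &
                        ms2_peaks$rt_lo <= p$rt_hi &
                        ms2_peaks$rt_hi >= p$rt_lo, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ptr <- run$ms1_traces[[p$trace_idx]]
    frag_mz <- frag_int <- frag_cor <- numeric(0)
    for (j in seq_len(nrow(cand))) {
      q <- cand[j, ]
      ftr <- run$ms2_traces[[q$trace_idx]]
      lo <- max(p$rt_lo, q$rt_lo)
      hi <- min(p$rt_hi, q$rt_hi)
      grid <- ptr$rt[ptr$rt >= lo & ptr$rt <= hi]
      if (length(grid) < 3L) next
      a <- ptr$intensity[match(grid, ptr$rt)]
      b <- stats::approx(ftr$rt, ftr$intensity, xout = grid, rule = 2)$y
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- stats::cor(a, b)
      if (is.finite(r) && r >= min_cor) {
        frag_mz <- c(frag_mz, q$mz)
        frag_int <- c(frag_int, q$area)
        frag_cor <- c(frag_cor, r)
      }
    }
    if (length(frag_mz) == 0L) next
    # collapse duplicate fragment m/z (same trace can yield split peaks)
    ord <- order(frag_mz)
    frag_mz <- frag_mz[ord]; frag_int <- frag_int[ord]; frag_cor <- frag_cor[ord]
    dup <- c(FALSE, diff(frag_mz) <= 1e-9)
    if (any(dup)) {
      keepi <- !dup
      frag_int <- vapply(split(frag_int, cumsum(keepi)), max, numeric(1))
      frag_cor <- vapply(split(frag_cor, cumsum(keepi)), max, numeric(1))
      frag_mz <- frag_mz[keepi]
    }
    s <- spectrum(
      spectrum_id = sprintf("P%.4fT%.1f", p$mz, p$rt_apex),
      precursor_mz = p$mz, rt = p$rt_apex,
      peaks = cbind(mz = frag_mz, intensity = frag_int),
      ion_mode = run$ion_mode)
    attr(s, "correlations") <- stats::setNames(frag_cor, sprintf("%.4f", frag_mz))
    out[[length(out) + 1L]] <- s
  }
  out
}

#' Retain spectra whose precursor elutes inside an RT window
#'
#' Early RT regions are dominated by unretained salts and very late ones by
#' broad lipid signals; both ends are trimmed. Boundaries are inclusive.
#'
#' @param spectra List of [spectrum] objects.
#' @param low,high Window bounds in seconds (defaults 60 and 1200).
#' @return Filtered list.
#' @export
filter_rt_window <- function(spectra, low = 60, high = 1200) {
  keep <- vapply(spectra, function(s) !is.na(s$rt) && s$rt >= low && s$rt <= high,
                 logical(1))
  spectra[keep]
}

#' Merge overlapping spectra of shared precursors
#'
#' Spectra whose precursor m/z values agree within the merging tolerance are
#' combined into one spectrum: peaks closer than
#' `max(mzd, ppm * mz / 1e6)` are unified at their intensity-weighted mean
#' m/z with intensity equal to the maximum over members. The operation is
#' idempotent.
#'
#' @param spectra List of [spectrum] objects (one ion mode).
#' @param mzd Absolute merge tolerance in Da (default 0.05).
#' @param ppm Relative merge tolerance in ppm (default 50).
#' @return List of merged [spectrum] objects.
#' @export
merge_overlapping_spectra <- function(spectra, mzd = 0.05, ppm = 50) {
  if (length(spectra) <= 1L) return(spectra)
  prec <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  grp <- group_values_1d(prec, mzd, ppm)
  out <- lapply(split(seq_along(spectra), grp), function(idx) {
    members <- spectra[idx]
    if (length(members) == 1L) return(members[[1L]])
    all_mz <- unlist(lapply(members, function(s) s$peaks[, "mz"]))
    all_int <- unlist(lapply(members, function(s) s$peaks[, "intensity"]))
    g <- group_values_1d(all_mz, mzd, ppm)
    mz_new <- vapply(split(seq_along(all_mz), g), function(k) {
      w <- all_int[k]
      if (sum(w) == 0) mean(all_mz[k]) else sum(all_mz[k] * w) / sum(w)
    }, numeric(1))
    int_new <- vapply(split(all_int, g), max, numeric(1))
    ref <- members[[which.max(vapply(members, base_peak_intensity, numeric(1)))]]
    spectrum(
      spectrum_id = ref$spectrum_id,
      precursor_mz = mean(prec[idx]),
      rt = stats::median(vapply(members, `[[`, numeric(1), "rt")),
      peaks = cbind(mz = mz_new, intensity = int_new),
      ion_mode = ref$ion_mode,
      compound_id = ref$compound_id, inchikey = ref$inchikey,
      ontology_terms = ref$ontology_terms)
  })
  names(out) <- NULL
  out
}

C13_DELTA <- 1.003355

#' Clean a single MS/MS spectrum
#'
#' Applies, in order: the absolute intensity floor
#' (`msms_intensity_threshold`); rejection when the spectrum's base peak is
#' below `min_intensity_of_max_ms2_peak` relative to the strongest MS2
#' signal of the run; rejection when fewer than
#' `min_proportion_ms2_peaks` of the original peaks survive the floor; and
#' C13 deisotoping, removing peaks sitting +1.003355 or +2.006710 Da above
#' a stronger peak within the deisotoping tolerance.
#'
#' @param s A [spectrum] with at least one peak.
#' @param config A [pipeline_config].
#' @param run_base_intensity The strongest MS2 intensity observed in the
#'   run; when `NULL` the relative base-peak check is skipped.
#' @param deisotope Apply fragment deisotoping (default `TRUE`).
#' @return The cleaned [spectrum], or `NULL` when the spectrum is rejected.
#'   An empty input spectrum is an error (distinct from rejection).
#' @export
clean_spectrum <- function(s, config = pipeline_config(),
                           run_base_intensity = NULL, deisotope = TRUE) {
  if (nrow(s$peaks) == 0L) stop("cannot clean an empty spectrum")
  n0 <- nrow(s$peaks)
  keep <- s$peaks[, "intensity"] >= config$msms_intensity_threshold
  pk <- s$peaks[keep, , drop = FALSE]
  if (nrow(pk) == 0L) return(NULL)
  if (!is.null(run_base_intensity) &&
      max(pk[, "intensity"]) <
        config$min_intensity_of_max_ms2_peak * run_base_intensity)
    return(NULL)
  if (nrow(pk) / n0 < config$min_proportion_ms2_peaks) return(NULL)
  if (deisotope && nrow(pk) > 1L) {
    drop <- rep(FALSE, nrow(pk))
    ord <- order(-pk[, "intensity"])
    for (i in ord) {
      if (drop[i]) next
      for (mult in 1:2) {
        target <- pk[i, "mz"] + mult * C13_DELTA
        tol <- mz_tolerance(target, config$deisotope_mz_abs, config$deisotope_ppm)
        hit <- which(!drop & abs(pk[, "mz"] - target) <= tol &
                       pk[, "intensity"] < pk[i, "intensity"])
        drop[hit] <- TRUE
      }
    }
    pk <- pk[!drop, , drop = FALSE]
  }
  s$peaks <- pk
  s
}

#' Remove isotopologue precursor spectra
#'
#' Across a set of reconstructed spectra, a spectrum whose precursor sits
#' +1.003355 or +2.006710 Da above a stronger, co-eluting precursor (RT
#' within `max_rt_difference` minutes) is treated as a C13 isotopologue and
#' dropped.
#'
#' @param spectra List of [spectrum] objects.
#' @param config A [pipeline_config].
#' @return Filtered list.
#' @export
deisotope_precursors <- function(spectra, config = pipeline_config()) {
  if (length(spectra) <= 1L) return(spectra)
  prec <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  rt <- vapply(spectra, `[[`, numeric(1), "rt")
  bp <- vapply(spectra, base_peak_intensity, numeric(1))
  rt_tol <- config$max_rt_difference * 60
  drop <- rep(FALSE, length(spectra))
  ord <- order(-bp)
  for (i in ord) {
    if (drop[i]) next
    for (mult in 1:2) {
      target <- prec[i] + mult * C13_DELTA
      tol <- mz_tolerance(target, config$deisotope_mz_abs, config$deisotope_ppm)
      hit <- which(!drop & abs(prec - target) <= tol &
                     abs(rt - rt[i]) <= rt_tol & bp < bp[i])
      drop[hit] <- TRUE
    }
  }
  spectra[!drop]
}
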