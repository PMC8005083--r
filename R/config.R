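#' Pipeline configuration
#'
#' Bundles every tunable of the reconstruction/classification pipeline with
#' defaults matching the published workflow. Retention times are seconds
#' throughout, except `max_rt_difference` which is given in minutes (the
#' convention of the originating tool) and converted on use.
#'
#' @param min_cor Minimum Pearson correlation between fragment and precursor
#'   chromatographic traces for a fragment to be retained (default 0.5).
#' @param rt_window Precursor retention-time window in seconds, spectra
#'   outside are discarded (default `c(60, 1200)`, boundaries inclusive).
#' @param merge_mzd,merge_ppm Peak-merging tolerances when combining
#'   overlapping spectra (defaults 0.05 Da, 50 ppm).
#' @param grouping_mz_abs,grouping_ppm Fragment-matrix m/z grouping
#'   tolerances (defaults 0.01 Da, 20 ppm).
#' @param mapping_mz_abs Absolute m/z tolerance when mapping spectra onto
#'   MS1 features (default 0.01 Da).
#' @param max_rt_difference Maximum RT difference, in minutes, for
#'   spectrum-to-feature mapping and precursor deisotoping (default 0.02).
#' @param msms_intensity_threshold Absolute intensity floor for MS2 peaks
#'   (default 10).
#' @param min_intensity_of_max_ms2_peak Minimum base-peak intensity of a
#'   spectrum relative to the strongest MS2 signal of the run
#'   (default 1e-4, i.e. 0.01 percent).
#' @param min_proportion_ms2_peaks Minimum fraction of a spectrum's peaks
#'   surviving the intensity floor (default 0.05).
#' @param deisotope_mz_abs,deisotope_ppm Isotopologue matching tolerances
#'   (defaults 0.01 Da, 10 ppm).
#' @param presence_threshold Relative abundance above which a compound is
#'   called present in a sample (default 0.001, i.e. 0.1 percent of the
#'   sample's largest peak).
#' @param peakwidth Expected chromatographic peak width bounds in seconds
#'   (default `c(10, 20)`).
#' @param snthresh Signal-to-noise threshold for peak detection (default 5).
#' @param random_seed Integer seed for all stochastic steps.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_cor = 0.5,
                            rt_window = c(60, 1200),
                            merge_mzd = 0.05, merge_ppm = 50,
                            grouping_mz_abs = 0.01, grouping_ppm = 20,
                            mapping_mz_abs = 0.01,
                            max_rt_difference = 0.02,
                            msms_intensity_threshold = 10,
                            min_intensity_of_max_ms2_peak = 1e-4,
                            min_proportion_ms2_peaks = 0.05,
                            deisotope_mz_abs = 0.01, deisotope_ppm = 10,
                            presence_threshold = 0.001,
                            peakwidth = c(10, 20), snthresh = 5,
                            random_seed = 1L) {
  stopifnot(min_cor >= 0, min_cor <= 1,
            length(rt_window) == 2L, rt_window[1] < rt_window[2],
            merge_mzd > 0, merge_ppm > 0,
            grouping_mz_abs > 0, grouping_ppm > 0,
            mapping_mz_abs > 0, max_rt_difference > 0,
            min_proportion_ms2_peaks >= 0,
            deisotope_mz_abs > 0, deisotope_ppm > 0,
            presence_threshold > 0, presence_threshold < 1,
            length(peakwidth) == 2L, peakwidth[1] < peakwidth[2],
            snthresh > 0)
  structure(as.list(environment()), class = "pipeline_config")
}
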