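# Small fixtures shared across test files.

make_spectrum <- function(id, precursor, mz, intensity = NULL,
                          mode = "negative", ...) {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  spectrum(id, precursor, rt = 300,
           peaks = cbind(mz = mz, intensity = intensity),
           ion_mode = mode, ...)
}

# a tiny manually assembled family with known consensus weights
make_family <- function(freqs, mzs, kinds = NULL) {
  if (is.null(kinds)) kinds <- rep("fragment", length(freqs))
  structure(list(
    term = "FAM1", term_name = "Test family",
    member_ids = sprintf("m%d", seq_len(12)),
    compound_ids = sprintf("c%d", seq_len(6)),
    consensus = data.frame(
      feature = sprintf("f%d", seq_along(freqs)),
      kind = kinds, mz = mzs, freq = freqs,
      median_intensity = rep(0.5, length(freqs)),
      stringsAsFactors = FALSE)),
    class = "metabolite_family")
}

gaussian_trace <- function(apex, height, sd = 3, noise = 0,
                           grid = seq(0, 600, by = 1), mz = 200,
                           level = "MS1", window_id = NULL, seed = NULL) {
  y <- height * exp(-(grid - apex)^2 / (2 * sd^2))
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(0, y + rnorm(length(grid), 0, noise))
  }
  chromatogram(grid, y, mz, level, window_id)
}
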