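# Small configurations and recordings shared across test files.

# short-duration config: full model, 20 s instead of 213 s
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, duration_s = 20, ...)
}

# a plain white-noise recording
noise_recording <- function(seed = 1, n_s = 20, fs = 2048, sd = 1,
                            side = "left") {
  set.seed(seed)
  lfp_recording(matrix(rnorm(4 * n_s * fs, sd = sd), 4), fs, "P01", side)
}

# a flat normalized spectrum (equal power in every 1-Hz bin)
flat_spectrum <- function(value = 1, f_max = 100, channels = 1) {
  normalize_spectrum(psd_from_bins(1:f_max,
                                   matrix(value, channels, f_max)))
}

# one full synthetic side with its truth, cached per (seed, duration)
.side_cache <- new.env(parent = emptyenv())
cached_side <- function(seed = 1, duration_s = 20) {
  key <- paste0("s", seed, "_d", duration_s)
  if (is.null(.side_cache[[key]]))
    .side_cache[[key]] <- generate_lfp_side(
      sim_config(seed = seed, duration_s = duration_s), 1, "left")
  .side_cache[[key]]
}
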