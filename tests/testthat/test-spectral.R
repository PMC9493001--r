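test_that("Welch PSD concentrates a sinusoid's analytic power", {
  fs <- 2048; n_s <- 20
  t <- (0:(n_s * fs - 1)) / fs
  rec <- lfp_recording(matrix(rep(sin(2 * pi * 24 * t), 4), 4,
                              byrow = TRUE), fs)
  psd <- compute_psd(rec)
  # A^2/2 = 0.5 for a unit sinusoid, summed over bins around the peak
  around <- psd$freq >= 21 & psd$freq <= 27
  expect_equal(sum(psd$power[1, around]), 0.5, tolerance = 0.02)
})

test_that("Welch PSD integrates to the signal variance (Parseval)", {
  rec <- noise_recording(seed = 5, n_s = 30, sd = 2)
  psd <- compute_psd(rec)
  tot <- rowSums(psd$power)   # df = 1 Hz
  expect_equal(unname(tot), rep(4, 4), tolerance = 0.05 * 4)
})

test_that("PSD scales quadratically with amplitude", {
  rec <- noise_recording(seed = 6, n_s = 4)
  psd1 <- compute_psd(rec)
  rec$samples <- 2 * rec$samples
  psd2 <- compute_psd(rec)
  expect_equal(psd2$power, 4 * psd1$power, tolerance = 1e-12)
})

test_that("PSD averages only over accepted window spans", {
  rec <- noise_recording(seed = 7, n_s = 10)
  all_w <- compute_psd(rec)
  some <- compute_psd(rec, accepted = c(1:4, 7:10))
  # two runs of 4 windows: 7 half-overlapping segments each
  expect_equal(some$n_segments, 14)
  expect_gt(all_w$n_segments, some$n_segments)
  expect_error(compute_psd(rec, accepted = integer(0)), "no accepted")
})

test_that("normalization makes reference-band power sum to one", {
  g <- cached_side(seed = 2)
  pp <- preprocess_recording(g$recording)
  spec <- normalize_spectrum(compute_psd(pp$recording, pp$accepted))
  ref <- stnbeta:::reference_mask(spec$freq)
  expect_equal(unname(rowSums(spec$rel_power[, ref])), rep(1, 4),
               tolerance = 1e-9)
})

test_that("flat spectra give band powers proportional to bandwidth", {
  spec <- flat_spectrum()
  bp <- band_powers(spec)
  expect_equal(bp$power[bp$band == "high_beta"], 15 / 80)
  expect_equal(bp$power[bp$band == "theta"], 3 / 80)
  expect_equal(bp$power[bp$band == "alpha"], 6 / 80)
  expect_equal(bp$power[bp$band == "low_beta"], 7 / 80)
  expect_equal(bp$power[bp$band == "low_gamma"], 15 / 80)
})

test_that("normalized spectra are invariant to positive gain", {
  psd <- psd_from_bins(1:100, matrix(runif(400, 0.5, 2), 4, 100))
  s1 <- normalize_spectrum(psd)
  psd$power <- 17.3 * psd$power
  s2 <- normalize_spectrum(psd)
  expect_equal(s1$rel_power, s2$rel_power, tolerance = 1e-12)
})

test_that("low-beta and high-beta partition broad-beta exactly", {
  g <- cached_side(seed = 3)
  pp <- preprocess_recording(g$recording)
  bp <- band_powers(normalize_spectrum(compute_psd(pp$recording, pp$accepted)))
  for (ct in 0:3) {
    rows <- bp[bp$contact == ct, ]
    expect_equal(rows$power[rows$band == "broad_beta"],
                 rows$power[rows$band == "low_beta"] +
                   rows$power[rows$band == "high_beta"],
                 tolerance = 1e-12)
  }
})

test_that("argmax across contacts honors the lower-index tie rule", {
  mk <- function(p) {
    data.frame(contact = 0:3, label = paste0("C", 0:3),
               band = "high_beta", power = p)
  }
  r <- max_across_contacts(mk(c(0.1, 0.3, 0.2, 0.05)), "high_beta")
  expect_equal(r$contact_index, 1L)
  expect_equal(r$power, 0.3)
  expect_false(r$tie)
  r2 <- max_across_contacts(mk(rep(0.2, 4)), "high_beta")
  expect_equal(r2$contact_index, 0L)
  expect_true(r2$tie)
  expect_error(max_across_contacts(mk(1:4 / 10), "delta"), "not present")
})

test_that("peak frequency finds the largest strict local maximum", {
  f <- 1:100
  bump <- function(mu, a) a * dnorm(f, mu, 2)
  one <- normalize_spectrum(psd_from_bins(f, rbind(1 / f + bump(24, 3))))
  expect_equal(peak_frequency(one)$peak_hz, 24)

  mono <- normalize_spectrum(psd_from_bins(f, rbind(1 / f^1.5)))
  expect_true(is.na(peak_frequency(mono)$peak_hz))

  # two bumps: the larger one wins, both are reported
  two <- normalize_spectrum(psd_from_bins(
    f, rbind(1 / f + bump(13, 1.5) + bump(24, 3))))
  pk <- peak_frequency(two)
  expect_equal(pk$peak_hz, 24)
  expect_setequal(pk$local_maxima$freq, c(13, 24))
})

test_that("end-to-end normalized features are gain-invariant", {
  g <- cached_side(seed = 4)
  f1 <- extract_side_features(g$recording)
  rec2 <- g$recording
  rec2$samples <- 3.7 * rec2$samples
  f2 <- extract_side_features(rec2)
  pow_cols <- grep("^power_", names(f1), value = TRUE)
  expect_equal(as.numeric(f1[pow_cols]), as.numeric(f2[pow_cols]),
               tolerance = 1e-9)
  expect_identical(f1$contact_high_beta, f2$contact_high_beta)
})
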