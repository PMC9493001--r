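#' Canonical frequency-band definitions
#'
#' The band set used throughout the analysis, with half-open
#' \code{[f_lo, f_hi)} membership of 1-Hz bins labeled by center frequency:
#' theta 4--7, alpha 7--13, low-beta 13--20, high-beta 20--35, low-gamma
#' 40--55, and the composite broad-beta 13--35 Hz. Under the half-open rule
#' the 13-Hz bin belongs to low-beta and the 20-Hz bin to high-beta, and
#' low-beta + high-beta = broad-beta exactly.
#'
#' @return data.frame with columns \code{band}, \code{f_lo}, \code{f_hi}.
#' @export
band_definitions <- function() {
  data.frame(
    band = c("theta", "alpha", "low_beta", "high_beta", "low_gamma",
             "broad_beta"),
    f_lo = c(4, 7, 13, 20, 40, 13),
    f_hi = c(7, 13, 20, 35, 55, 35),
    stringsAsFactors = FALSE
  )
}

#' Reference bands for relative-power normalization
#'
#' Power is normalized to the total over 5--55 and 65--95 Hz, excluding the
#' movement-artifact range below 5 Hz and the 60-Hz mains line (55--65 Hz).
#' Half-open bins: 80 one-Hz bins in total.
#'
#' @return two-column matrix of \code{(f_lo, f_hi)} rows.
#' @export
reference_bands <- function() {
  matrix(c(5, 55, 65, 95), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("f_lo", "f_hi")))
}

bins_in_band <- function(freq, f_lo, f_hi) freq >= f_lo & freq < f_hi

reference_mask <- function(freq) {
  rb <- reference_bands()
  Reduce(`|`, lapply(seq_len(nrow(rb)),
                     function(i) bins_in_band(freq, rb[i, 1], rb[i, 2])))
}

#' Welch power spectral density of a recording
#'
#' Averaged periodogram over 1-s Hann-windowed segments with 50% overlap,
#' giving a 1-Hz frequency resolution. Segments are placed only inside
#' maximal runs of consecutive accepted 1-s windows, so that spans flagged
#' by the artifact screen never contribute.
#'
#' @param rec an \code{lfp_recording} (typically already referenced and
#'   detrended).
#' @param accepted integer indices of accepted 1-s windows, as returned by
#'   \code{\link{reject_artifact_segments}}; \code{NULL} accepts all.
#' @param seg_len_s segment length in seconds (1 s gives 1-Hz bins).
#' @param overlap fractional overlap between segments.
#' @return an object of class \code{lfp_psd}: \code{freq} (Hz, bin centers),
#'   \code{power} (channels x bins, one-sided density in units^2/Hz),
#'   \code{fs}, \code{n_segments}, \code{contact_labels}.
#' @export
compute_psd <- function(rec, accepted = NULL, seg_len_s = 1, overlap = 0.5) {
  fs <- rec$fs
  nseg <- as.integer(round(seg_len_s * fs))
  n <- ncol(rec$samples)
  n_win <- n %/% nseg
  if (is.null(accepted)) accepted <- seq_len(n_win)
  if (length(accepted) < 1) stopf("no accepted windows to average")

  # segment start indices: 50% overlap inside runs of consecutive windows
  step <- as.integer(round(nseg * (1 - overlap)))
  starts <- integer(0)
  acc <- sort(unique(accepted))
  run_brk <- c(0, which(diff(acc) > 1), length(acc))
  for (r in seq_len(length(run_brk) - 1)) {
    w <- acc[(run_brk[r] + 1):run_brk[r + 1]]
    lo <- (w[1] - 1) * nseg + 1
    hi <- w[length(w)] * nseg
    starts <- c(starts, seq(lo, hi - nseg + 1, by = step))
  }

  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / nseg)  # periodic Hann
  u <- sum(w^2)
  nf <- nseg %/% 2 + 1
  acc_pow <- matrix(0, nrow(rec$samples), nf)
  for (s0 in starts) {
    seg <- rec$samples[, s0:(s0 + nseg - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)              # per-segment demean
    seg <- sweep(seg, 2, w, `*`)
    sp <- t(apply(seg, 1, function(x) abs(stats::fft(x))[seq_len(nf)]^2))
    acc_pow <- acc_pow + sp
  }
  pxx <- acc_pow / (length(starts) * fs * u)
  pxx[, 2:(nf - 1)] <- 2 * pxx[, 2:(nf - 1)]  # one-sided doubling
  structure(list(freq = (0:(nf - 1)) / seg_len_s, power = pxx, fs = fs,
                 n_segments = length(starts),
                 contact_labels = rec$contact_labels),
            class = "lfp_psd")
}

#' Construct a PSD object directly from bin powers
#'
#' Used for analytic (expected) spectra and in tests; shares the bin
#' conventions of \code{\link{compute_psd}}.
#'
#' @param freq bin center frequencies (Hz, 1-Hz spacing).
#' @param power channels x bins matrix of one-sided power density.
#' @param contact_labels optional channel labels.
#' @return an \code{lfp_psd}.
#' @export
psd_from_bins <- function(freq, power, contact_labels = NULL) {
  power <- rbind(power)
  if (is.null(contact_labels)) contact_labels <- paste0("ch", seq_len(nrow(power)))
  structure(list(freq = freq, power = power, fs = NA_real_,
                 n_segments = NA_integer_, contact_labels = contact_labels),
            class = "lfp_psd")
}

#' Normalize a PSD to relative power per 1-Hz bin
#'
#' Divides each contact's spectrum by its total power over the reference
#' bands (5--55 and 65--95 Hz), so that the relative power summed over the
#' reference bins equals 1 for every contact. Normalized features are
#' invariant under any positive gain applied to the recording.
#'
#' @param psd an \code{lfp_psd}.
#' @return an object of class \code{normalized_spectrum}: \code{freq},
#'   \code{rel_power} (channels x bins), \code{contact_labels}.
#' @export
normalize_spectrum <- function(psd) {
  mask <- reference_mask(psd$freq)
  if (!any(mask)) stopf("spectrum does not cover the reference bands")
  ref <- rowSums(psd$power[, mask, drop = FALSE])
  if (any(ref <= 0)) stopf("zero reference-band power; cannot normalize")
  structure(list(freq = psd$freq, rel_power = psd$power / ref,
                 contact_labels = psd$contact_labels),
            class = "normalized_spectrum")
}

#' Normalized band powers per contact
#'
#' Sums relative power over the 1-Hz bins whose center lies in each band's
#' half-open \code{[f_lo, f_hi)} interval.
#'
#' @param spec a \code{normalized_spectrum}.
#' @param bands band table as from \code{\link{band_definitions}}.
#' @return a \code{band_power_table}: data.frame with \code{contact}
#'   (0-based index), \code{label}, \code{band}, \code{power}.
#' @export
band_powers <- function(spec, bands = band_definitions()) {
  if (any(bands$f_hi > max(spec$freq) + 0.5))
    stopf("band extends beyond the computed spectrum")
  out <- do.call(rbind, lapply(seq_len(nrow(bands)), function(i) {
    m <- bins_in_band(spec$freq, bands$f_lo[i], bands$f_hi[i])
    data.frame(contact = seq_len(nrow(spec$rel_power)) - 1L,
               label = spec$contact_labels,
               band = bands$band[i],
               power = rowSums(spec$rel_power[, m, drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Maximum band power across the four contacts
#'
#' Selects, for one band, the contact carrying the largest normalized power.
#' Ties are broken toward the lower (deeper) contact index and flagged.
#'
#' @param table a \code{band_power_table}.
#' @param band band name present in the table.
#' @return list with \code{band}, \code{contact_index}, \code{label},
#'   \code{power}, \code{tie} (logical).
#' @export
max_across_contacts <- function(table, band) {
  rows <- table[table$band == band, , drop = FALSE]
  if (nrow(rows) == 0) stopf("band '%s' not present in table", band)
  rows <- rows[order(rows$contact), , drop = FALSE]
  i <- which.max(rows$power)  # first max = lowest contact index
  list(band = band,
       contact_index = rows$contact[i],
       label = rows$label[i],
       power = rows$power[i],
       tie = sum(rows$power == rows$power[i]) > 1)
}

#' Spectral peak frequency within a range
#'
#' Frequency of the largest strict local maximum of the relative power
#' within \code{range} (default 10--35 Hz). Returns \code{NA} when the
#' spectrum is monotone over the range (no interior local maximum).
#'
#' @param spec a \code{normalized_spectrum}.
#' @param range two-element numeric, inclusive frequency range in Hz.
#' @param contact 0-based contact index to inspect.
#' @return list with \code{peak_hz} (NA if absent) and \code{local_maxima}
#'   (all strict local maxima in the range, decreasing power order).
#' @export
peak_frequency <- function(spec, range = c(10, 35), contact = 0L) {
  f <- spec$freq
  if (range[1] < min(f) || range[2] > max(f))
    stopf("requested range outside the computed spectrum")
  p <- spec$rel_power[contact + 1L, ]
  idx <- which(f >= range[1] & f <= range[2])
  interior <- idx[idx > 1 & idx < length(f)]
  is_max <- vapply(interior, function(i) p[i] > p[i - 1] && p[i] > p[i + 1],
                   logical(1))
  peaks <- interior[is_max]
  peaks <- peaks[order(p[peaks], decreasing = TRUE)]
  list(peak_hz = if (length(peaks)) f[peaks[1]] else NA_real_,
       local_maxima = data.frame(freq = f[peaks], rel_power = p[peaks]))
}
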