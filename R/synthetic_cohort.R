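#' Configuration of the synthetic LFP cohort
#'
#' Defines the study conditions emulated by the generator: 26 patients with
#' two STN sides, ~213 s of 4-contact resting LFP at 2048 Hz per side, a
#' 1/f^chi aperiodic background, narrowband low-beta and high-beta
#' oscillations whose amplitude decays as a Gaussian of distance between
#' the contact and the band's source depth along the lead, a 60-Hz mains
#' line, and clinical outcomes drawn from the published two-predictor linear
#' model (bradykinesia-rigidity improvement = b0 + b1 * max high-beta power
#' + b2 * contact distance + noise, with b1 = 0.425, b2 = -0.026 and the
#' noise calibrated so the fitted model explains 37.4% of the variance).
#'
#' @param seed root integer seed; every random draw flows from it through a
#'   documented per-(patient, side, stream) substream map.
#' @param n_patients number of patients.
#' @param sides_per_patient STN sides per patient.
#' @param fs sampling rate, Hz.
#' @param duration_s recording length, seconds (default the recorded mean).
#' @param band_peaks list with elements \code{low_beta} and \code{high_beta};
#'   each either a length-2 range the per-side peak is drawn from uniformly,
#'   or a single fixed frequency in Hz.
#' @param spatial_sigma_mm Gaussian amplitude-decay scale of the oscillation
#'   sources along the lead, mm.
#' @param aperiodic_exponent chi of the 1/f^chi background.
#' @param mains_hz mains frequency (60 Hz).
#' @param outcome_coeffs named numeric (intercept, power, distance); the
#'   response is an improvement fraction in [0, 1] scale.
#' @param target_r2 variance fraction the refitted outcome model should
#'   explain; sets the outcome noise SD by variance matching.
#' @param n_poor_quality sides marked poor recording quality and excluded.
#' @param n_zero_tremor analyzable sides with zero baseline tremor
#'   (excluded from the tremor analysis set).
#' @param tremor_ceiling_prob probability a tremor side is completely
#'   suppressed (efficacy 1), mimicking the reported ceiling (20 of 39).
#' @param background_scale 1/f background power scale (uV^2 Hz^(chi-1)).
#' @param noise_floor flat sensor-noise PSD, uV^2/Hz.
#' @param osc_power_scale named numeric, median total oscillation power
#'   (uV^2) of each band's source at zero distance.
#' @param osc_power_sdlog log-SD of the per-side lognormal power draw.
#' @param osc_bandwidth_hz FWHM of the narrowband (Gaussian-shaped) peaks.
#' @param source_depth_range_mm range the per-band source depth is drawn
#'   from, mm along the lead (contacts sit at 0, 2, 4, 6 mm).
#' @param mains_amplitude mains sinusoid amplitude, uV.
#' @param mains_jitter_sd relative SD of the per-contact mains amplitude
#'   (a small spread keeps a residual line after common-average
#'   referencing, as in real recordings).
#' @param contact_selection named numeric \code{(gamma0, gamma1)} of the
#'   programming model: the chronic stimulation contact is drawn with
#'   weights \code{exp(-(gamma0 + gamma1 * power) * |offset|)} around the
#'   contact with the maximum high-beta normalized power, emulating
#'   empirical contact selection that co-localizes with the beta source
#'   more reliably when the oscillation is strong. This induces the
#'   negative rank correlation between maximum high-beta power and the
#'   stimulation-contact distance observed clinically.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 26L,
                       sides_per_patient = 2L,
                       fs = 2048,
                       duration_s = 213,
                       band_peaks = list(low_beta = c(13, 20),
                                         high_beta = c(20, 35)),
                       spatial_sigma_mm = 1.5,
                       aperiodic_exponent = 1.5,
                       mains_hz = 60,
                       outcome_coeffs = c(intercept = 0.25, power = 0.425,
                                          distance = -0.026),
                       target_r2 = 0.374,
                       n_poor_quality = 2L,
                       n_zero_tremor = 11L,
                       tremor_ceiling_prob = 20 / 39,
                       background_scale = 1,
                       noise_floor = 0.001,
                       osc_power_scale = c(low_beta = 0.35, high_beta = 0.35),
                       osc_power_sdlog = 0.6,
                       osc_bandwidth_hz = 3,
                       source_depth_range_mm = c(-1, 7),
                       mains_amplitude = 1,
                       mains_jitter_sd = 0.1,
                       contact_selection = c(gamma0 = -1.6, gamma1 = 8)) {
  stopifnot(n_patients >= 1, sides_per_patient %in% 1:2, fs > 0,
            duration_s > 0, spatial_sigma_mm > 0, aperiodic_exponent > 0,
            target_r2 > 0, target_r2 < 1, osc_bandwidth_hz > 0,
            length(outcome_coeffs) == 3)
  f_hi <- max(mains_hz,
              vapply(band_peaks, max, numeric(1)),
              max(reference_bands()))
  if (fs <= 2 * f_hi)
    stopf("fs (%g) must exceed twice the highest generated frequency (%g)",
          fs, f_hi)
  if (abs(duration_s * fs - round(duration_s * fs)) > 1e-9)
    stopf("duration_s * fs must be an integer sample count")
  names(outcome_coeffs) <- c("intercept", "power", "distance")
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              sides_per_patient = as.integer(sides_per_patient), fs = fs,
              duration_s = duration_s, band_peaks = band_peaks,
              spatial_sigma_mm = spatial_sigma_mm,
              aperiodic_exponent = aperiodic_exponent, mains_hz = mains_hz,
              outcome_coeffs = outcome_coeffs, target_r2 = target_r2,
              n_poor_quality = as.integer(n_poor_quality),
              n_zero_tremor = as.integer(n_zero_tremor),
              tremor_ceiling_prob = tremor_ceiling_prob,
              background_scale = background_scale, noise_floor = noise_floor,
              osc_power_scale = osc_power_scale,
              osc_power_sdlog = osc_power_sdlog,
              osc_bandwidth_hz = osc_bandwidth_hz,
              source_depth_range_mm = source_depth_range_mm,
              mains_amplitude = mains_amplitude,
              mains_jitter_sd = mains_jitter_sd,
              contact_selection = contact_selection)
  class(cfg) <- "sim_config"
  cfg
}

# stream tags of the substream map (one per independent random purpose)
.streams <- c(spectral = 1L, active = 2L, covariates = 3L, poor = 4L,
              zero_tremor = 5L, brady_noise = 6L, tremor = 7L, axial = 8L,
              signal = 9L, updrs = 10L)

side_code <- function(side) match(side, c("left", "right"))

#' Per-side latent spectral parameters (deterministic in the seed)
#' @keywords internal
side_params <- function(cfg, patient_index, side) {
  side <- match.arg(side, c("left", "right"))
  sc <- side_code(side)
  lead <- lead_model()
  depths <- contact_depths(lead)
  draw_peak <- function(rng) if (length(rng) == 1) rng else
    stats::runif(1, rng[1], rng[2])
  with_seed(substream_seed(cfg$seed, .streams["spectral"], patient_index, sc), {
    lb_peak <- draw_peak(cfg$band_peaks$low_beta)
    hb_peak <- draw_peak(cfg$band_peaks$high_beta)
    lb_depth <- stats::runif(1, cfg$source_depth_range_mm[1],
                             cfg$source_depth_range_mm[2])
    hb_depth <- stats::runif(1, cfg$source_depth_range_mm[1],
                             cfg$source_depth_range_mm[2])
    lb_a2 <- cfg$osc_power_scale[["low_beta"]] *
      stats::rlnorm(1, 0, cfg$osc_power_sdlog)
    hb_a2 <- cfg$osc_power_scale[["high_beta"]] *
      stats::rlnorm(1, 0, cfg$osc_power_sdlog)
    mains_amp <- cfg$mains_amplitude *
      (1 + stats::rnorm(lead$n_contacts, 0, cfg$mains_jitter_sd))
    mains_phase <- stats::runif(1, 0, 2 * pi)
    kern <- function(d0) exp(-(depths - d0)^2 / (2 * cfg$spatial_sigma_mm^2))
    list(patient_index = patient_index, side = side,
         lb_peak = lb_peak, hb_peak = hb_peak,
         lb_depth = lb_depth, hb_depth = hb_depth,
         lb_amp = sqrt(lb_a2) * kern(lb_depth),   # per-contact amplitudes
         hb_amp = sqrt(hb_a2) * kern(hb_depth),
         mains_amp = mains_amp, mains_phase = mains_phase,
         depths = depths)
  })
}

# integral of background + white PSD over [a, b]
.bg_integral <- function(a, b, p0, chi, floor) {
  anti <- function(f) {
    f <- pmax(f, 0)
    below <- pmin(f, 1)                 # flat below 1 Hz at p0
    above <- pmax(f, 1)
    p0 * below + p0 * (above^(1 - chi) - 1) / (1 - chi)
  }
  p0_part <- anti(b) - anti(a)
  p0_part + floor * (b - a)
}

#' Expected (analytic) post-reference spectrum of one synthetic side
#'
#' Bin-integrated expected PSD on the 1-Hz grid, after common-average
#' referencing: incoherent components (background, sensor noise, per-contact
#' narrowband oscillations) mix as (1 - 1/C)^2 own + 1/C^2 others; the
#' coherent mains line keeps amplitude (m_c - mean(m)). This analytic
#' spectrum defines the ground-truth normalized band powers the estimation
#' pipeline is asked to recover.
#'
#' @param cfg a \code{sim_config}.
#' @param sp side parameters from \code{side_params}.
#' @param f_max top bin center, Hz.
#' @return an \code{lfp_psd} of expected bin powers.
#' @keywords internal
expected_psd <- function(cfg, sp, f_max = 100) {
  centers <- 1:f_max
  a <- centers - 0.5
  b <- centers + 0.5
  nc <- length(sp$depths)
  sigf <- cfg$osc_bandwidth_hz / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  osc_bin <- function(total_pow, mu)
    total_pow * (stats::pnorm(b, mu, sigf) - stats::pnorm(a, mu, sigf))
  bg <- .bg_integral(a, b, cfg$background_scale, cfg$aperiodic_exponent,
                     cfg$noise_floor)
  incoh <- matrix(0, nc, length(centers))
  for (c_i in seq_len(nc)) {
    incoh[c_i, ] <- bg +
      osc_bin(sp$lb_amp[c_i]^2, sp$lb_peak) +
      osc_bin(sp$hb_amp[c_i]^2, sp$hb_peak)
  }
  own <- (1 - 1 / nc)^2
  oth <- 1 / nc^2
  post <- own * incoh + oth * (matrix(colSums(incoh), nc, length(centers),
                                      byrow = TRUE) - incoh)
  m_ref <- sp$mains_amp - mean(sp$mains_amp)
  mains_bin <- which(centers == round(cfg$mains_hz))
  if (length(mains_bin)) post[, mains_bin] <- post[, mains_bin] + m_ref^2 / 2
  psd_from_bins(centers, post,
                contact_label(seq_len(nc) - 1, sp$side))
}

#' Ground-truth spectral features of one synthetic side
#'
#' Normalized band powers, per-band argmax contacts and center-to-center
#' distances to the active contact, all derived from the analytic expected
#' spectrum (not from a realized noisy recording).
#'
#' @param cfg a \code{sim_config}.
#' @param patient_index patient number (1-based).
#' @param side \code{"left"} or \code{"right"}.
#' @return one-row data.frame of true features.
#' @export
true_side_features <- function(cfg, patient_index, side) {
  sp <- side_params(cfg, patient_index, side)
  spec <- normalize_spectrum(expected_psd(cfg, sp))
  bp <- band_powers(spec)
  sc <- side_code(side)
  hb_max <- max_across_contacts(bp, "high_beta")
  # programming model: selection concentrates on the high-beta argmax,
  # more tightly the stronger the oscillation
  gam <- max(0, cfg$contact_selection[["gamma0"]] +
               cfg$contact_selection[["gamma1"]] * hb_max$power)
  w <- exp(-gam * abs(0:3 - hb_max$contact_index))
  active <- with_seed(
    substream_seed(cfg$seed, .streams["active"], patient_index, sc),
    sample(0:3, 1, prob = w))
  lead <- lead_model()
  out <- data.frame(patient_index = patient_index, side = side,
                    active_contact = active, stringsAsFactors = FALSE)
  for (bn in band_definitions()$band) {
    mx <- max_across_contacts(bp, bn)
    out[[paste0("power_", bn)]] <- mx$power
    out[[paste0("contact_", bn)]] <- mx$contact_index
  }
  out$dist_low_beta_mm <- contact_distance(active, out$contact_low_beta, lead)
  out$dist_high_beta_mm <- contact_distance(active, out$contact_high_beta, lead)
  out$lb_source_depth <- sp$lb_depth
  out$hb_source_depth <- sp$hb_depth
  out$hb_source_contact <- which.max(sp$hb_amp) - 1L
  out$lb_source_contact <- which.max(sp$lb_amp) - 1L
  out
}

# synthesize Gaussian noise with a target one-sided PSD via FFT shaping
spectral_noise <- function(n, fs, psd_fun) {
  w <- stats::rnorm(n)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)           # fold to |f|
  h <- sqrt(psd_fun(f) * fs / 2)
  h[1] <- 0                      # no DC
  Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
}

#' Synthesize one side's 4-contact LFP recording
#'
#' Each contact is the sum of an independent 1/f^chi background, independent
#' narrowband low-beta and high-beta oscillations (Gaussian spectral shape,
#' ~3 Hz FWHM) scaled by the band's Gaussian depth kernel, a coherent 60-Hz
#' mains sinusoid with slight per-contact amplitude spread, and white sensor
#' noise. Deterministic given (seed, patient_index, side).
#'
#' @param cfg a \code{sim_config}.
#' @param patient_index patient number (1-based).
#' @param side \code{"left"} or \code{"right"}.
#' @return list with \code{recording} (an \code{lfp_recording}) and
#'   \code{truth} (the \code{\link{true_side_features}} row).
#' @export
generate_lfp_side <- function(cfg, patient_index, side) {
  side <- match.arg(side, c("left", "right"))
  if (cfg$duration_s <= 0) stopf("non-positive duration")
  sp <- side_params(cfg, patient_index, side)
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  sigf <- cfg$osc_bandwidth_hz / (2 * sqrt(2 * log(2)))
  bg_psd <- function(f) cfg$background_scale * pmax(f, 1)^(-cfg$aperiodic_exponent)
  t <- (0:(n - 1)) / cfg$fs
  mains_common <- sin(2 * pi * cfg$mains_hz * t + sp$mains_phase)
  samples <- with_seed(
    substream_seed(cfg$seed, .streams["signal"], patient_index,
                   side_code(side)), {
    m <- matrix(0, 4, n)
    for (c_i in 1:4) {
      x <- spectral_noise(n, cfg$fs, bg_psd) +
        spectral_noise(n, cfg$fs, function(f) rep(cfg$noise_floor, length(f)))
      if (sp$lb_amp[c_i] > 0)
        x <- x + sp$lb_amp[c_i] *
          spectral_noise(n, cfg$fs, function(f) stats::dnorm(f, sp$lb_peak, sigf))
      if (sp$hb_amp[c_i] > 0)
        x <- x + sp$hb_amp[c_i] *
          spectral_noise(n, cfg$fs, function(f) stats::dnorm(f, sp$hb_peak, sigf))
      m[c_i, ] <- x + sp$mains_amp[c_i] * mains_common
    }
    m
  })
  rec <- lfp_recording(samples, cfg$fs, sprintf("P%02d", patient_index), side)
  list(recording = rec,
       truth = true_side_features(cfg, patient_index, side))
}

#' Generate efficacy outcomes from the published linear model
#'
#' Draws bradykinesia-rigidity improvement fractions
#' \code{b0 + b1 * power + b2 * distance + e}, with i.i.d. Gaussian noise
#' whose SD is chosen by variance matching so that the expected R^2 of a
#' two-predictor OLS refit on the realized predictors equals
#' \code{target_r2}: with signal sum of squares SS and n observations,
#' sigma^2 = (1 - R2) * SS / ((n - 3) - (1 - R2) * (n - 1)).
#'
#' @param cfg a \code{sim_config}.
#' @param features data.frame with columns \code{power} (normalized
#'   high-beta fraction) and \code{distance} (mm).
#' @param seed integer seed; defaults to a fixed substream of the config
#'   seed.
#' @param sigma optional noise SD override; \code{NULL} calibrates it from
#'   \code{target_r2} (0 gives the noiseless limit).
#' @return list with \code{efficacy} (noisy fractions), \code{noiseless},
#'   \code{sigma} (calibrated noise SD) and \code{coeffs}.
#' @export
generate_outcomes <- function(cfg, features,
                              seed = substream_seed(cfg$seed,
                                                    .streams["brady_noise"]),
                              sigma = NULL) {
  if (NROW(features) == 0) stopf("empty feature list")
  p <- features$power
  d <- features$distance
  if (any(!is.finite(p)) || any(!is.finite(d))) stopf("non-finite features")
  b <- cfg$outcome_coeffs
  mu <- b[["intercept"]] + b[["power"]] * p + b[["distance"]] * d
  ss <- sum((mu - mean(mu))^2)
  n <- length(mu)
  denom <- (n - 3) - (1 - cfg$target_r2) * (n - 1)
  if (is.null(sigma)) {
    if (b[["power"]] == 0 && b[["distance"]] == 0) {
      sigma <- 0.1                     # pure-noise outcome scale
    } else {
      if (ss <= 0)
        stopf("degenerate predictor variance; cannot calibrate outcome noise")
      if (denom > 0) {
        sigma <- sqrt((1 - cfg$target_r2) * ss / denom)
      } else {
        # below n ~ 7 the fitted R^2 exceeds the target for any noise level
        # (k/(n-1) chance inflation); fall back to the population ratio
        sigma <- sqrt((1 - cfg$target_r2) / cfg$target_r2 * ss / (n - 1))
      }
    }
  }
  eff <- with_seed(seed, mu + stats::rnorm(n, 0, sigma))
  list(efficacy = eff, noiseless = unname(mu), sigma = sigma,
       coeffs = b)
}

#' Build the full synthetic cohort plan
#'
#' One row per STN side: ground-truth spectral features (from the analytic
#' expected spectra), active contact, poor-quality and zero-baseline-tremor
#' flags, patient covariates, and outcome fractions for the three symptom
#' domains. Bradykinesia-rigidity outcomes follow the published linear
#' model with calibrated noise; tremor outcomes are drawn independently of
#' all band powers with a point mass at complete suppression; axial
#' outcomes are one independent draw per patient.
#'
#' @param cfg a \code{sim_config}.
#' @return data.frame of class \code{cohort_plan}.
#' @export
cohort_plan <- function(cfg) {
  sides <- if (cfg$sides_per_patient == 2) c("left", "right") else "left"
  rows <- list()
  for (pi in seq_len(cfg$n_patients))
    for (s in sides) rows[[length(rows) + 1]] <- true_side_features(cfg, pi, s)
  plan <- do.call(rbind, rows)
  plan$patient_id <- sprintf("P%02d", plan$patient_index)
  plan$side_id <- paste0(plan$patient_id, "_", plan$side)
  n_sides <- nrow(plan)

  # poor-quality exclusions
  poor <- with_seed(substream_seed(cfg$seed, .streams["poor"]),
                    sample(n_sides, min(cfg$n_poor_quality, n_sides)))
  plan$poor_quality <- seq_len(n_sides) %in% poor
  analyzable <- which(!plan$poor_quality)

  # zero-baseline-tremor sides among the analyzable ones
  zt <- with_seed(substream_seed(cfg$seed, .streams["zero_tremor"]),
                  sample(analyzable, min(cfg$n_zero_tremor, length(analyzable))))
  plan$zero_tremor <- seq_len(n_sides) %in% zt

  # patient covariates (independent of all spectral features)
  cov <- with_seed(substream_seed(cfg$seed, .streams["covariates"]), {
    np <- cfg$n_patients
    off <- round(pmax(15, stats::rnorm(np, 43.2, 15)) * 2) / 2
    resp <- pmin(0.8, pmax(0.1, stats::rnorm(np, 0.42, 0.12)))
    data.frame(
      patient_id = sprintf("P%02d", seq_len(np)),
      sex = ifelse(stats::runif(np) < 9 / 26, "F", "M"),
      age = round(pmin(80, pmax(35, stats::rnorm(np, 61.0, 7.6)))),
      duration = round(pmax(2, stats::rnorm(np, 14.4, 5.8))),
      updrs3_off_med = off,
      updrs3_on_med = round(off * (1 - resp) * 2) / 2,
      ledd = round(stats::rlnorm(np, log(1250), 0.35)),
      dyskinesia = stats::runif(np) < 18 / 26,
      subtype = ifelse(stats::runif(np) < 7 / 26, "T", "AR"),
      stringsAsFactors = FALSE)
  })
  cov$levodopa_response <- cov$updrs3_off_med - cov$updrs3_on_med
  plan <- merge(plan, cov, by = "patient_id", sort = FALSE)
  plan <- plan[order(plan$patient_index, plan$side), ]

  # bradykinesia-rigidity outcome: published model, noise calibrated on the
  # analyzable (quality-passing) sides, the set the regression is fit on
  feat <- data.frame(power = plan$power_high_beta,
                     distance = plan$dist_high_beta_mm)
  cal <- generate_outcomes(cfg, feat[!plan$poor_quality, , drop = FALSE])
  all_mu <- cfg$outcome_coeffs[["intercept"]] +
    cfg$outcome_coeffs[["power"]] * feat$power +
    cfg$outcome_coeffs[["distance"]] * feat$distance
  plan$eff_brady_frac <- with_seed(
    substream_seed(cfg$seed, .streams["brady_noise"]),
    all_mu + stats::rnorm(n_sides, 0, cal$sigma))
  plan$eff_brady_noiseless <- all_mu
  attr(plan, "outcome_sigma") <- cal$sigma

  # tremor: independent of band powers, ceiling at complete suppression
  plan$eff_tremor_frac <- with_seed(
    substream_seed(cfg$seed, .streams["tremor"]), {
      ceilinged <- stats::runif(n_sides) < cfg$tremor_ceiling_prob
      ifelse(ceilinged, 1, stats::rbeta(n_sides, 2, 1.5))
    })
  plan$eff_tremor_frac[plan$zero_tremor] <- NA_real_

  # axial: one draw per patient, independent of features
  ax <- with_seed(substream_seed(cfg$seed, .streams["axial"]),
                  pmin(0.95, pmax(-0.2, stats::rnorm(cfg$n_patients, 0.3, 0.15))))
  plan$eff_axial_frac <- ax[plan$patient_index]

  rownames(plan) <- NULL
  class(plan) <- c("cohort_plan", "data.frame")
  plan
}

# split a subscore across k items with a per-item cap of 4
split_items <- function(total, k) {
  total <- max(0L, min(as.integer(round(total)), 4L * k))
  base <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  over <- base > 4L
  if (any(over)) {                      # push overflow onto other items
    spill <- sum(base[over] - 4L)
    base[over] <- 4L
    i <- 1L
    while (spill > 0 && i <= k) {
      room <- 4L - base[i]
      add <- min(room, spill)
      base[i] <- base[i] + add
      spill <- spill - add
      i <- i + 1L
    }
  }
  base
}

#' Build the UPDRS-III item table for a cohort plan
#'
#' Long-format med-OFF item scores (items 20--31) under stim-OFF and
#' stim-ON, with lateralized items 20--26 carried per hemibody and axial
#' items 27--31 once per patient. Baseline subscores are drawn per
#' hemibody; stim-ON subscores realize each side's target efficacy fraction
#' (rounded to integer item scores), with each STN mapped to its
#' contralateral hemibody.
#'
#' @param cfg a \code{sim_config}.
#' @param plan a \code{cohort_plan}.
#' @return data.frame with columns patient, med_state, stim_state, item,
#'   side, score.
#' @export
updrs_table <- function(cfg, plan) {
  rows <- list()
  add <- function(pid, stim, items, side, scores) {
    rows[[length(rows) + 1]] <<- data.frame(
      patient = pid, med_state = "OFF", stim_state = stim, item = items,
      side = side, score = scores, stringsAsFactors = FALSE)
  }
  base <- with_seed(substream_seed(cfg$seed, .streams["updrs"]), {
    np <- cfg$n_patients
    list(brady = matrix(sample(6:18, np * 2, TRUE), np, 2,
                        dimnames = list(NULL, c("left", "right"))),
         tremor = matrix(sample(2:8, np * 2, TRUE), np, 2,
                         dimnames = list(NULL, c("left", "right"))),
         axial = sample(4:15, np, TRUE))
  })
  for (pi in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", pi)
    prows <- plan[plan$patient_index == pi, , drop = FALSE]
    for (hemi in c("left", "right")) {
      stn <- if (hemi == "left") "right" else "left"  # contralateral STN
      srow <- prows[prows$side == stn, , drop = FALSE]
      b_off <- base$brady[pi, hemi]
      t_off <- base$tremor[pi, hemi]
      eff_b <- if (nrow(srow)) srow$eff_brady_frac else 0
      eff_t <- if (nrow(srow)) srow$eff_tremor_frac else 0
      if (nrow(srow) && srow$zero_tremor) t_off <- 0L
      b_on <- max(0L, as.integer(round(b_off * (1 - max(min(eff_b, 1), -1)))))
      t_on <- if (is.na(eff_t)) 0L else
        max(0L, as.integer(round(t_off * (1 - eff_t))))
      add(pid, "OFF", 20:21, hemi, split_items(t_off, 2))
      add(pid, "ON", 20:21, hemi, split_items(t_on, 2))
      add(pid, "OFF", 22:26, hemi, split_items(b_off, 5))
      add(pid, "ON", 22:26, hemi, split_items(b_on, 5))
    }
    a_off <- base$axial[pi]
    eff_a <- prows$eff_axial_frac[1]
    a_on <- max(0L, as.integer(round(a_off * (1 - eff_a))))
    add(pid, "OFF", 27:31, "axial", split_items(a_off, 5))
    add(pid, "ON", 27:31, "axial", split_items(a_on, 5))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic cohort bundle to disk
#'
#' Emits delimited-text recordings (one CSV per side, one column per
#' contact, labels C0--C3 / C8--C11), the UPDRS item table, side- and
#' patient-level metadata, the ground-truth plan, and the configuration as
#' YAML. Identical seeds produce byte-identical bundles.
#'
#' @param cfg a \code{sim_config}.
#' @param dir output directory (created if needed).
#' @param write_recordings set \code{FALSE} to skip the (large) time-series
#'   files and emit only tables.
#' @return invisibly, the \code{cohort_plan}.
#' @export
generate_cohort <- function(cfg, dir, write_recordings = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stopf("cannot create output directory '%s'", dir)
  plan <- cohort_plan(cfg)
  upd <- updrs_table(cfg, plan)
  num <- vapply(plan, is.numeric, logical(1))
  plan_out <- plan
  plan_out[num] <- lapply(plan_out[num], function(x) signif(x, 10))
  utils::write.csv(plan_out, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(upd, file.path(dir, "updrs.csv"), row.names = FALSE)
  meta_cols <- c("patient_id", "sex", "age", "duration", "updrs3_on_med",
                 "updrs3_off_med", "ledd", "dyskinesia", "subtype",
                 "levodopa_response")
  meta <- unique(plan[, meta_cols])
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  sides <- plan[, c("patient_id", "side", "side_id", "active_contact",
                    "poor_quality")]
  sides$active_label <- contact_label(sides$active_contact, sides$side)
  utils::write.csv(sides, file.path(dir, "sides.csv"), row.names = FALSE)
  cfg_out <- cfg
  class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  if (write_recordings) {
    rec_dir <- file.path(dir, "recordings")
    if (!dir.exists(rec_dir)) dir.create(rec_dir)
    for (i in seq_len(nrow(plan))) {
      g <- generate_lfp_side(cfg, plan$patient_index[i], plan$side[i])
      m <- t(g$recording$samples)
      colnames(m) <- g$recording$contact_labels
      utils::write.csv(data.frame(round(m, 4), check.names = FALSE),
                       file.path(rec_dir, paste0(plan$side_id[i], ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(plan)
}

#' Refit the outcome model on a cohort plan
#'
#' Two-predictor OLS of the bradykinesia-rigidity improvement fraction on
#' maximum high-beta power and contact distance over the analyzable
#' (quality-passing) sides, i.e. the estimation counterpart of the
#' generator's outcome model.
#'
#' @param plan a \code{cohort_plan}.
#' @return a \code{regression_result}.
#' @export
fit_outcome_model <- function(plan) {
  ok <- !plan$poor_quality
  ols_fit(plan$eff_brady_frac[ok],
          data.frame(power = plan$power_high_beta[ok],
                     distance = plan$dist_high_beta_mm[ok]))
}

#' Read a delimited-text recording written by \code{generate_cohort}
#'
#' @param path CSV path (one column per contact, labeled header).
#' @param fs sampling rate in Hz.
#' @param patient_id patient identifier.
#' @param side \code{"left"} or \code{"right"}.
#' @return an \code{lfp_recording}.
#' @export
read_lfp_csv <- function(path, fs, patient_id = "P", side = "left") {
  if (!file.exists(path)) stopf("recording file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  lfp_recording(t(as.matrix(df)), fs, patient_id, side,
                contact_labels = colnames(df))
}
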