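SCATTER_CHANNELS <- c("SSC", "FSCL", "FSCM", "FSCU")

#' Optical response profile of one cell in one scatter channel
#'
#' Phenomenological model of the angle-resolved scattering response as a
#' function of axial position: forward-scatter channels (FSCL/FSCM/FSCU)
#' produce a two-lobe profile — two Gaussian peaks separated by the drawn
#' peak distance (converted to length via the flow speed), with amplitudes
#' in the drawn ratio and a bridge between them whose depth below the
#' smaller peak is `dip_depth`. S-phase events may replace the dip by a
#' plateau carrying a sinusoidal ripple. SSC is single-lobed with width
#' proportional to the cell diameter.
#'
#' @param draw list of per-event morphology parameters: `peak_distance`
#'   (us), `amplitude_ratio` (second/first peak), `lobe_fwhm` (us),
#'   `dip_depth`, `plateau` (logical), `osc_amp`, `osc_phase`, `diameter`
#'   (um), `amp` (peak amplitude, ADC counts).
#' @param channel one of `SSC`, `FSCL`, `FSCM`, `FSCU`.
#' @param beam a [beam_model()] (provides the flow speed for the time-to-
#'   length conversion).
#' @return A function of axial position x (um).
#' @export
make_profile <- function(draw, channel, beam = beam_model()) {
  if (!channel %in% SCATTER_CHANNELS)
    stop("make_profile is defined for scatter channels only, got: ", channel)
  v <- beam$flow_speed                      # um/us
  amp <- draw$amp %||% 1
  if (channel == "SSC") {
    sigma <- draw$diameter / (2 * sqrt(2 * log(2)))
    return(function(x) amp * exp(-x^2 / (2 * sigma^2)))
  }
  d <- draw$peak_distance * v               # lobe separation, um
  sigma <- draw$lobe_fwhm * v / (2 * sqrt(2 * log(2)))
  ratio <- draw$amplitude_ratio
  a1 <- amp / max(1, ratio)
  a2 <- a1 * ratio
  plateau <- isTRUE(draw$plateau)
  dip <- if (plateau) 0.08 else draw$dip_depth
  bridge_amp <- (1 - dip) * min(a1, a2)
  osc_amp <- if (plateau) (draw$osc_amp %||% 0) else 0
  osc_phase <- draw$osc_phase %||% 0
  lambda <- 1.0 * v                          # ripple wavelength, um (1 us)
  function(x) {
    lobes <- a1 * exp(-(x + d / 2)^2 / (2 * sigma^2)) +
             a2 * exp(-(x - d / 2)^2 / (2 * sigma^2))
    bridge <- bridge_amp * exp(-(x / (0.8 * d / 2))^8)
    if (osc_amp > 0)
      bridge <- bridge * (1 + osc_amp * sin(2 * pi * x / lambda + osc_phase))
    lobes + pmax(bridge, 0)
  }
}

#' Convolve an optical response profile with the excitation beam
#'
#' The recorded pulse is the spatial overlap integral of the cell's
#' response profile with the Gaussian beam as the cell moves at the flow
#' speed: `pulse(t) = integral profile(x) beam(x - v t) dx`. A delta-like
#' profile therefore reproduces the beam itself in time (FWHM 1.15 us at
#' the defaults), and the operation is linear in the profile.
#'
#' @param profile function of axial position (um), compact support.
#' @param beam a [beam_model()].
#' @param support numeric length-2: x-range (um) containing the profile's
#'   support.
#' @param resolution integration step in um (default: fine enough to
#'   oversample the beam > 50x).
#' @return A function of time (us) returning the pulse, vectorized in t.
#' @export
beam_convolve <- function(profile, beam, support = c(-40, 40),
                          resolution = beam$fwhm_short_axis / 50) {
  x <- seq(support[1], support[2], by = resolution)
  px <- profile(x)
  bf <- beam_profile_fn(beam)
  v <- beam$flow_speed
  function(t) {
    vapply(t, function(ti) sum(px * bf(x - v * ti)) * resolution, numeric(1))
  }
}

# zero-phase low-pass: raised-cosine frequency response, unit passband
.lowpass_response <- function(freqs, cutoff) {
  f <- abs(freqs)
  lo <- 0.85 * cutoff; hi <- 1.15 * cutoff
  ifelse(f <= lo, 1,
         ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - lo) / (hi - lo)))))
}

#' Filter, sample and digitize a continuous pulse
#'
#' Evaluates the pulse on an oversampled grid, applies a zero-phase
#' low-pass at the configured cutoff (7 MHz at defaults, applied before
#' decimation so no aliasing is introduced), decimates to the acquisition
#' rate, adds Gaussian baseline noise and quantizes to unsigned integers
#' with clipping at the ADC range.
#'
#' @param pulse function of time (us) over `[0, window)`.
#' @param noise a [noise_model()].
#' @param config an [acquisition_config()].
#' @param oversample oversampling factor of the analog grid.
#' @param seed optional integer; if given the RNG state is set (and
#'   restored afterwards) so the draw is reproducible in isolation.
#' @return Integer vector of `n_samples` ADC counts.
#' @export
sample_and_digitize <- function(pulse, noise = noise_model(),
                                config = acquisition_config(),
                                oversample = 10, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  dt <- sample_period_us(config) / oversample
  n_fine <- config$n_samples * oversample
  tt <- (seq_len(n_fine) - 1) * dt
  y <- pulse(tt)
  stopifnot(length(y) == n_fine, all(is.finite(y)))
  y <- .fft_lowpass(matrix(y, ncol = 1), dt, noise$lowpass_cutoff)[, 1]
  y <- y[seq(1, n_fine, by = oversample)]
  y <- y + noise$baseline_level +
    stats::rnorm(length(y), 0, noise$baseline_sd)
  .quantize(y, config$adc_bits)
}

.quantize <- function(y, adc_bits) {
  as.integer(pmin(pmax(round(y), 0), 2^adc_bits - 1))
}

# zero-phase low-pass of each column of y sampled at step dt (us);
# cutoff in Hz
.fft_lowpass <- function(y, dt, cutoff) {
  n <- nrow(y)
  freqs <- c(0, seq_len(n - 1)) / (n * dt) * 1e6     # Hz
  freqs <- ifelse(freqs > 1 / (2 * dt) * 1e6, freqs - 1 / dt * 1e6, freqs)
  H <- .lowpass_response(freqs, cutoff)
  Re(stats::mvfft(stats::mvfft(y) * H, inverse = TRUE)) / n
}

#' Align an event to the acquisition trigger
#'
#' The SSC channel arms the trigger: all channels are shifted so the first
#' upward crossing of the threshold in SSC lands at the configured trigger
#' point (sample index 20, i.e. 2 us, at defaults), then cropped to the
#' acquisition window. Samples shifted in from outside the recorded range
#' are filled with baseline draws. Events whose SSC never crosses the
#' threshold are rejected (`NULL`), mirroring a no-trigger on the
#' instrument.
#'
#' @param channels numeric matrix `n_channels x n_raw_samples` (raw
#'   recording, possibly longer than the acquisition window); rows ordered
#'   as `config$channel_names`.
#' @param config an [acquisition_config()].
#' @param threshold trigger level in ADC counts.
#' @param noise a [noise_model()] supplying the baseline fill.
#' @return `n_channels x n_samples` matrix, or `NULL` if the trigger never
#'   fired.
#' @export
trigger_align <- function(channels, config = acquisition_config(),
                          threshold, noise = noise_model()) {
  stopifnot(is.matrix(channels), nrow(channels) == config$n_channels)
  ssc <- channels[match("SSC", config$channel_names), ]
  above <- ssc >= threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  if (length(rising) == 0) return(NULL)
  cross <- rising[1]
  target <- trigger_index(config) + 1L       # R index of the trigger sample
  shift <- cross - target
  src <- seq_len(config$n_samples) + shift
  valid <- src >= 1 & src <= ncol(channels)
  out <- matrix(0, nrow(channels), config$n_samples)
  for (r in seq_len(nrow(channels))) {
    fill <- .quantize(noise$baseline_level +
                        stats::rnorm(sum(!valid), 0, noise$baseline_sd),
                      config$adc_bits)
    out[r, valid] <- channels[r, src[valid]]
    out[r, !valid] <- fill
  }
  out
}

# ---- cohort simulation ----------------------------------------------------

# per-event parameter draws for one class
.draw_class_params <- function(spec, n) {
  pd_fscl <- stats::rnorm(n, spec$peak_distance_mean$FSCL, spec$peak_distance_sd)
  pd_fscu <- stats::rnorm(n, spec$peak_distance_mean$FSCU, spec$peak_distance_sd)
  ar <- function(ch) pmax(0.2, stats::rnorm(
    n, spec$amplitude_ratio_mean[[ch]] %||% 1, spec$amplitude_ratio_sd))
  pi_true <- if (length(spec$pi_mean) == 2)
    stats::runif(n, spec$pi_mean[1], spec$pi_mean[2])
  else rep(spec$pi_mean, n)
  data.frame(
    phase = rep(spec$phase, n),
    diameter = stats::rnorm(n, spec$diameter_mean,
                            spec$diameter_mean * spec$diameter_cv),
    pd_FSCL = pd_fscl, pd_FSCU = pd_fscu,
    ratio_FSCL = ar("FSCL"), ratio_FSCU = ar("FSCU"),
    lobe_fwhm = pmax(0.3, stats::rnorm(n, spec$lobe_fwhm_mean,
                                       spec$lobe_fwhm_sd)),
    dip_depth = rep(spec$dip_depth, n),
    plateau = spec$phase == "S" & stats::runif(n) < spec$s_phase_plateau_prob,
    osc_amp = rep(spec$s_phase_oscillation_amp, n),
    osc_phase = stats::runif(n, 0, 2 * pi),
    pi_true = pi_true * (1 + stats::rnorm(n, 0, spec$pi_cv)),
    brdu = rep(spec$brdu_positive, n),
    stringsAsFactors = FALSE)
}

# nominal peak scatter amplitudes (ADC counts) for a 12 um cell
.CHANNEL_GAIN <- c(SSC = 8000, FSCL = 12000, FSCU = 9000)

.draw_amplitudes <- function(params, noise) {
  n <- nrow(params)
  size_scale <- (params$diameter / 12)^2
  out <- list()
  for (ch in names(.CHANNEL_GAIN)) {
    out[[ch]] <- .CHANNEL_GAIN[[ch]] * size_scale *
      exp(stats::rnorm(n, 0, noise$amplitude_cv))
  }
  as.data.frame(out)
}

# shared per-event shape parameters of a two-lobe channel, unit taller peak.
# The drawn peak distance, lobe FWHM and dip depth are observables of the
# *recorded* pulse (the Fig.-1c-style shape vocabulary), so the lobes are
# laid out directly in time at those scales.
.shape_params <- function(params, channel) {
  sig <- params$lobe_fwhm / (2 * sqrt(2 * log(2)))
  ratio <- params[[paste0("ratio_", channel)]]
  a1 <- 1 / pmax(1, ratio)
  a2 <- a1 * ratio
  dip <- ifelse(params$plateau, 0.08, params$dip_depth)
  list(pd = params[[paste0("pd_", channel)]],
       sig = sig,
       a1 = a1, a2 = a2,
       bridge_amp = (1 - dip) * pmin(a1, a2),
       osc_amp = ifelse(params$plateau, params$osc_amp, 0),
       osc_phase = params$osc_phase)
}

# bridge (inter-peak fill / plateau) relative to the pulse center, same
# definition everywhere; x may be a matrix with per-column events
.bridge_values <- function(x, sp, cols = NULL) {
  pick <- function(v) if (is.null(cols)) v else v[cols]
  half <- 0.8 * pick(sp$pd) / 2
  amp <- pick(sp$bridge_amp)
  osc <- pick(sp$osc_amp); ph <- pick(sp$osc_phase)
  b <- sweep(exp(-sweep(x, 2, half, "/")^8), 2, amp, "*")
  has_osc <- osc > 0
  if (any(has_osc)) {
    mod <- 1 + sweep(sin(2 * pi * x + rep(ph, each = nrow(x))), 2, osc, "*")
    b[, has_osc] <- b[, has_osc, drop = FALSE] * mod[, has_osc, drop = FALSE]
  }
  pmax(b, 0)
}

# evaluate per-event pulse waveforms for a block of events on a fine time
# grid. SSC is the cell-diameter Gaussian pre-compensated for beam-transit
# smearing (applied later); FSCL/FSCU two-lobe shapes are laid out directly
# at the drawn recorded-pulse scales. tt: fine grid (us); center: per-event
# pulse center times (us). Returns length(tt) x n matrix.
.profile_block <- function(tt, params, amps, center, channel, beam) {
  n <- nrow(params)
  m <- matrix(0, length(tt), n)
  if (channel == "SSC") {
    sig_b <- beam$fwhm_short_axis / beam$flow_speed / (2 * sqrt(2 * log(2)))
    sig <- params$diameter / beam$flow_speed / (2 * sqrt(2 * log(2)))
    comp <- sqrt(sig^2 + sig_b^2) / sig     # pre-compensate beam smearing
    for (i in seq_len(n))
      m[, i] <- amps$SSC[i] * comp[i] *
        exp(-(tt - center[i])^2 / (2 * sig[i]^2))
    return(m)
  }
  sp <- .shape_params(params, channel)
  amp <- amps[[channel]]
  for (i in seq_len(n)) {
    x <- tt - center[i]
    lobes <- sp$a1[i] * exp(-(x + sp$pd[i] / 2)^2 / (2 * sp$sig[i]^2)) +
             sp$a2[i] * exp(-(x - sp$pd[i] / 2)^2 / (2 * sp$sig[i]^2))
    bridge <- .bridge_values(matrix(x, ncol = 1), sp, cols = i)[, 1]
    m[, i] <- amp[i] * (lobes + bridge)
  }
  m
}

# convolve columns with the beam-transit kernel (time domain,
# density-normalized; skipped when beam is NULL) and low-pass, in one FFT
# pass
.beam_lowpass_fft <- function(m, dt, beam, cutoff) {
  n <- nrow(m)
  freqs <- c(0, seq_len(n - 1)) / (n * dt) * 1e6
  freqs <- ifelse(freqs > 1 / (2 * dt) * 1e6, freqs - 1 / dt * 1e6, freqs)
  H <- .lowpass_response(freqs, cutoff)
  if (!is.null(beam)) {
    sig_t <- beam$fwhm_short_axis / beam$flow_speed / (2 * sqrt(2 * log(2)))
    tk <- c(seq(0, (n - 1) %/% 2), seq(-(n - (n - 1) %/% 2 - 1), -1)) * dt
    kernel <- exp(-tk^2 / (2 * sig_t^2))
    kernel <- kernel / sum(kernel)           # unit DC gain
    H <- H * stats::fft(kernel)
  }
  Re(stats::mvfft(stats::mvfft(m) * H, inverse = TRUE)) / n
}

#' Simulate a synthetic multi-angle pulse-shape cohort
#'
#' Draws events i.i.d. from the cell-cycle class mixture, synthesizes
#' two-peak scatter pulses through the full signal chain (optical response
#' profile, Gaussian-beam transit, 7 MHz low-pass on an oversampled grid,
#' 10 MHz digitization, baseline noise, SSC-triggered alignment), adds
#' matched PI / BrdU-FITC fluorescence scalars, and optionally mixes in
#' doublets (two time-offset cells with summed PI area and stretched PI
#' width). Fully reproducible from `seed`.
#'
#' @param classes list of [cell_class_spec()]; mixture weights must sum
#'   to 1.
#' @param n_events number of events.
#' @param noise a [noise_model()].
#' @param beam a [beam_model()].
#' @param config an [acquisition_config()].
#' @param seed integer seed.
#' @param raw_window length (us) of the pre-trigger raw recording from
#'   which the acquisition window is cut (at most the 16 us maximum
#'   trigger window).
#' @return List with `pulses` (a [pulse_dataset()]), `events` (per-event
#'   scalar table: H/A/W per scatter channel, PI-H/A/W, FITC-H) and
#'   `truth` (per-event generating parameters incl. `phase` and `doublet`).
#' @export
simulate_cohort <- function(classes = default_cell_classes(),
                            n_events = 1000,
                            noise = noise_model(),
                            beam = beam_model(),
                            config = acquisition_config(),
                            seed = 1,
                            raw_window = 16) {
  if (n_events <= 0) stop("n_events must be positive")
  w <- vapply(classes, function(s) s$mixture_weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-6) stop("class mixture weights must sum to 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  cls <- sample.int(length(classes), n_events, replace = TRUE, prob = w)
  params <- do.call(rbind, lapply(seq_along(classes), function(k) {
    nk <- sum(cls == k)
    if (nk == 0) return(NULL)
    cbind(idx = which(cls == k), .draw_class_params(classes[[k]], nk))
  }))
  params <- params[order(params$idx), , drop = FALSE]
  amps <- .draw_amplitudes(params, noise)
  center <- raw_window / 2 + stats::runif(n_events, -0.3, 0.3)

  is_dbl <- stats::runif(n_events) < noise$doublet_fraction
  n_dbl <- sum(is_dbl)
  partner <- NULL
  if (n_dbl > 0) {
    pcls <- sample.int(length(classes), n_dbl, replace = TRUE, prob = w)
    partner <- do.call(rbind, lapply(seq_along(classes), function(k) {
      nk <- sum(pcls == k)
      if (nk == 0) return(NULL)
      cbind(idx = which(pcls == k), .draw_class_params(classes[[k]], nk))
    }))
    partner <- partner[order(partner$idx), , drop = FALSE]
    partner$offset <- stats::runif(n_dbl, noise$doublet_offset_range[1],
                                   noise$doublet_offset_range[2])
    partner_amps <- .draw_amplitudes(partner, noise)
  }

  os <- 10L
  dt_f <- sample_period_us(config) / os
  n_raw <- as.integer(round(raw_window / sample_period_us(config)))
  tt <- (seq_len(n_raw * os) - 1) * dt_f
  keep_idx <- seq(1, n_raw * os, by = os)

  digitize_channel <- function(channel) {
    # only the incoherent ~90-degree channel is transit-limited; coherent
    # forward-scatter interference structure is drawn at recorded scales
    smear_beam <- if (channel == "SSC") beam else NULL
    out <- matrix(0L, n_events, n_raw)
    chunk <- 1000L
    for (start in seq(1, n_events, by = chunk)) {
      rows <- start:min(start + chunk - 1, n_events)
      m <- .profile_block(tt, params[rows, ], amps[rows, , drop = FALSE],
                          center[rows], channel, beam)
      dbl_rows <- which(is_dbl[rows])
      if (length(dbl_rows) > 0) {
        drel <- match(rows[dbl_rows], which(is_dbl))
        m[, dbl_rows] <- m[, dbl_rows, drop = FALSE] +
          .profile_block(tt, partner[drel, , drop = FALSE],
                         partner_amps[drel, , drop = FALSE],
                         center[rows[dbl_rows]] + partner$offset[drel],
                         channel, beam)
      }
      m <- .beam_lowpass_fft(m, dt_f, smear_beam, noise$lowpass_cutoff)
      dec <- t(m[keep_idx, , drop = FALSE])
      dec <- dec + noise$baseline_level +
        matrix(stats::rnorm(length(dec), 0, noise$baseline_sd), nrow(dec))
      out[rows, ] <- matrix(.quantize(dec, config$adc_bits), nrow(dec))
    }
    out
  }

  raw <- list(SSC = digitize_channel("SSC"),
              FSCL = digitize_channel("FSCL"),
              FSCU = digitize_channel("FSCU"))
  # FSCM is redundant to FSCU: a noisy copy
  raw$FSCM <- matrix(
    .quantize(raw$FSCU + stats::rnorm(length(raw$FSCU), 0, noise$baseline_sd),
              config$adc_bits), n_events, n_raw)

  # trigger alignment on SSC (vectorized over events)
  thr <- noise$trigger_threshold
  above <- raw$SSC >= thr
  rising <- above & !cbind(FALSE, above[, -n_raw, drop = FALSE])
  cross <- apply(rising, 1, function(r) {
    i <- which(r); if (length(i)) i[1] else NA_integer_ })
  triggered <- !is.na(cross)
  n_rej <- sum(!triggered)
  if (n_rej > 0)
    message(n_rej, " event(s) never crossed the SSC trigger threshold; rejected")

  idx_keep <- which(triggered)
  n_out <- length(idx_keep)
  if (n_out == 0) stop("no event fired the trigger; check amplitudes/threshold")
  shift <- cross[idx_keep] - (trigger_index(config) + 1L)
  ns <- config$n_samples
  src_col <- outer(shift, seq_len(ns), "+")
  valid <- src_col >= 1 & src_col <= n_raw
  align <- function(mat) {
    sub <- mat[idx_keep, , drop = FALSE]
    out <- matrix(.quantize(
      noise$baseline_level + stats::rnorm(n_out * ns, 0, noise$baseline_sd),
      config$adc_bits), n_out, ns)
    lin <- cbind(as.vector(row(src_col)[valid]), as.vector(src_col[valid]))
    out[cbind(as.vector(row(src_col)[valid]),
              as.vector(col(src_col)[valid]))] <- sub[lin]
    out
  }
  aligned <- lapply(raw, align)

  data <- array(0, dim = c(n_out, config$n_channels, ns))
  for (ch in names(aligned))
    data[, match(ch, config$channel_names), ] <- aligned[[ch]]
  for (ch in setdiff(config$channel_names, names(aligned))) {
    ci <- match(ch, config$channel_names)
    data[, ci, ] <- matrix(.quantize(
      noise$baseline_level + stats::rnorm(n_out * ns, 0, noise$baseline_sd),
      config$adc_bits), n_out, ns)
  }
  pulses <- pulse_dataset(data, config, event_ids = idx_keep)

  # fluorescence scalars (matched ground truth); PI area tracks DNA content
  p <- params[idx_keep, , drop = FALSE]
  transit_w <- sqrt((p$diameter / beam$flow_speed)^2 +
                    (beam$fwhm_short_axis / beam$flow_speed)^2)
  pi_a <- p$pi_true
  pi_w <- transit_w + stats::rnorm(n_out, 0, 0.05)
  fitc <- ifelse(p$brdu,
                 stats::rlnorm(n_out, log(5000), 0.25),
                 stats::rlnorm(n_out, log(250), 0.35))
  pi_a2 <- rep(NA_real_, n_out)
  dbl_out <- is_dbl[idx_keep]
  if (any(dbl_out)) {
    drel <- match(idx_keep[dbl_out], which(is_dbl))
    pi_a2[dbl_out] <- partner$pi_true[drel]
    pi_a[dbl_out] <- pi_a[dbl_out] + partner$pi_true[drel]
    pi_w[dbl_out] <- pi_w[dbl_out] + partner$offset[drel]
    fitc[dbl_out] <- pmax(fitc[dbl_out], ifelse(
      partner$brdu[drel], stats::rlnorm(sum(dbl_out), log(5000), 0.25),
      stats::rlnorm(sum(dbl_out), log(250), 0.35)))
  }
  pi_h <- pi_a / pi_w

  events <- event_table(pulses, channels = SCATTER_CHANNELS)
  events[["PI-H"]] <- pi_h
  events[["PI-A"]] <- pi_a
  events[["PI-W"]] <- pi_w
  events[["FITC-H"]] <- fitc

  truth <- data.frame(event_id = idx_keep,
                      phase = p$phase,
                      doublet = dbl_out,
                      diameter = p$diameter,
                      pd_FSCL = p$pd_FSCL, pd_FSCU = p$pd_FSCU,
                      ratio_FSCL = p$ratio_FSCL, ratio_FSCU = p$ratio_FSCU,
                      lobe_fwhm = p$lobe_fwhm,
                      plateau = p$plateau,
                      pi_component1 = p$pi_true,
                      pi_component2 = pi_a2,
                      stringsAsFactors = FALSE)
  list(pulses = pulses, events = events, truth = truth,
       n_rejected = n_rej, seed = seed)
}

#' Estimate the distance between the two pulse peaks
#'
#' Baseline-subtracts the pulse, finds local maxima above a fraction of the
#' pulse height, takes the first and the last such maximum as the two
#' peaks, and refines each location by quadratic interpolation through the
#' three samples around it.
#'
#' @param pulse numeric sample vector.
#' @param config an [acquisition_config()].
#' @param rel_threshold minimal peak height relative to the pulse maximum.
#' @return Peak distance in us, or `NA` if fewer than two peaks are found.
#' @export
estimate_peak_distance <- function(pulse, config = acquisition_config(),
                                   rel_threshold = 0.4) {
  y <- pulse - pulse_baseline(pulse)
  n <- length(y)
  i <- 2:(n - 1)
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] >= rel_threshold * max(y)
  peaks <- i[is_max]
  if (length(peaks) < 2) return(NA_real_)
  refine <- function(k) {
    denom <- y[k - 1] - 2 * y[k] + y[k + 1]
    delta <- if (denom < 0) 0.5 * (y[k - 1] - y[k + 1]) / denom else 0
    k + delta
  }
  (refine(peaks[length(peaks)]) - refine(peaks[1])) * sample_period_us(config)
}
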