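#' Acquisition configuration
#'
#' Describes the digitizer settings of the pulse-shape recorder: sampling
#' rate, acquisition window, trigger point and channel layout. At the
#' defaults (10 MHz, 8 us window) every pulse holds 80 samples with the
#' trigger sitting at sample index 20 (0-based), i.e. 2 us into the window.
#'
#' @param sampling_rate sampling frequency in Hz (default 1e7).
#' @param window acquisition window in microseconds (default 8, at most 16).
#' @param trigger_time trigger position within the window in microseconds.
#' @param n_channels number of detection channels.
#' @param adc_bits ADC resolution in bits; samples live in
#'   `[0, 2^adc_bits - 1]`.
#' @param lowpass_cutoff analog low-pass cutoff in Hz applied before
#'   digitization.
#' @param channel_names ordered channel labels; position matters because the
#'   binary pulse file stores channels in this order.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate = 1e7,
                               window = 8,
                               trigger_time = 2,
                               n_channels = 8,
                               adc_bits = 16,
                               lowpass_cutoff = 7e6,
                               channel_names = c("SSC", "FSCL", "FSCM", "FSCU",
                                                 "FL-PI", "FL-FITC",
                                                 "AUX1", "AUX2")) {
  stopifnot(sampling_rate > 0, window > 0, trigger_time >= 0)
  if (window > 16)
    stop("acquisition window must not exceed 16 us")
  if (trigger_time >= window)
    stop("trigger_time must lie inside the acquisition window")
  n_samples <- window * sampling_rate * 1e-6
  if (abs(n_samples - round(n_samples)) > 1e-9 || n_samples < 1)
    stop("window x sampling_rate must be a positive integer number of samples")
  if (length(channel_names) != n_channels)
    stop("channel_names must have length n_channels")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  structure(list(
    sampling_rate = sampling_rate,
    window = window,
    trigger_time = trigger_time,
    n_channels = as.integer(n_channels),
    adc_bits = as.integer(adc_bits),
    lowpass_cutoff = lowpass_cutoff,
    channel_names = as.character(channel_names),
    n_samples = as.integer(round(n_samples))
  ), class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %g MHz, %g us window (trigger %g us), %d ch x %d samples, %d-bit\n",
    x$sampling_rate / 1e6, x$window, x$trigger_time,
    x$n_channels, x$n_samples, x$adc_bits))
  invisible(x)
}

# sample period in microseconds
sample_period_us <- function(config) 1e6 / config$sampling_rate

# 0-based sample index of the trigger point
trigger_index <- function(config) {
  as.integer(round(config$trigger_time * config$sampling_rate * 1e-6))
}

#' Gaussian excitation beam model
#'
#' The laser spot is elliptical with a Gaussian intensity profile along the
#' flow axis; its short-axis FWHM divided by the flow speed sets the minimal
#' transit-time FWHM of any pulse (1.15 us at the defaults).
#'
#' @param fwhm_short_axis FWHM of the beam along the flow direction, in um.
#' @param flow_speed flow speed in m/s (numerically um/us).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(fwhm_short_axis = 5.75, flow_speed = 5.0) {
  stopifnot(fwhm_short_axis > 0, flow_speed > 0)
  structure(list(fwhm_short_axis = fwhm_short_axis,
                 flow_speed = flow_speed),
            class = "beam_model")
}

# beam irradiance vs axial position, unit peak
beam_profile_fn <- function(beam) {
  sigma <- beam$fwhm_short_axis / (2 * sqrt(2 * log(2)))
  function(x) exp(-x^2 / (2 * sigma^2))
}

#' Noise and artefact model for the synthetic cytometer
#'
#' @param baseline_level detector baseline in ADC counts.
#' @param baseline_sd Gaussian baseline noise SD in ADC counts.
#' @param lowpass_cutoff low-pass cutoff in Hz applied on the oversampled
#'   analog grid before decimation.
#' @param doublet_fraction probability that an event is a doublet (two cells
#'   traversing the beam in close succession).
#' @param doublet_offset_range range (us) of the uniform time offset between
#'   the two cells of a doublet.
#' @param amplitude_cv multiplicative log-normal spread of per-event scatter
#'   amplitudes.
#' @param trigger_threshold absolute SSC level (ADC counts) that arms the
#'   acquisition trigger.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline_level = 400,
                        baseline_sd = 8,
                        lowpass_cutoff = 7e6,
                        doublet_fraction = 0.02,
                        doublet_offset_range = c(1.5, 3.5),
                        amplitude_cv = 0.10,
                        trigger_threshold = 1500) {
  stopifnot(doublet_fraction >= 0, doublet_fraction <= 1,
            baseline_sd >= 0, length(doublet_offset_range) == 2,
            all(doublet_offset_range > 0))
  structure(list(baseline_level = baseline_level,
                 baseline_sd = baseline_sd,
                 lowpass_cutoff = lowpass_cutoff,
                 doublet_fraction = doublet_fraction,
                 doublet_offset_range = doublet_offset_range,
                 amplitude_cv = amplitude_cv,
                 trigger_threshold = trigger_threshold),
            class = "noise_model")
}

#' Cell-cycle class specification for the synthetic cytometer
#'
#' Each class draws per-event morphology parameters of the *recorded*
#' forward-scatter pulse: the distance between the two pulse peaks, the
#' peak amplitude ratio (second/first), the peak width, the cell diameter
#' (drives the SSC pulse width and overall scatter amplitude), the
#' inter-peak dip structure and the matched fluorescence ground truth (PI
#' DNA content, BrdU positivity).
#'
#' @param phase one of "G1", "S", "G2M".
#' @param mixture_weight class prior in the cohort mixture.
#' @param diameter_mean,diameter_cv cell diameter distribution (um).
#' @param peak_distance_mean named list (per scatter channel, us) of mean
#'   peak distances.
#' @param peak_distance_sd SD of the per-event peak distance (us).
#' @param amplitude_ratio_mean named list (per channel) of mean second/first
#'   peak amplitude ratios.
#' @param amplitude_ratio_sd SD of the ratio.
#' @param lobe_fwhm_mean,lobe_fwhm_sd FWHM of each recorded pulse peak (us).
#' @param dip_depth depth of the inter-peak dip relative to the smaller peak
#'   (1 = dip to baseline, 0 = flat bridge).
#' @param s_phase_plateau_prob probability that the dip is replaced by an
#'   oscillating plateau (S-phase morphology).
#' @param s_phase_oscillation_amp relative amplitude of the plateau ripple.
#' @param pi_mean mean PI signal (area counts); a length-2 vector means the
#'   DNA content is drawn uniformly between the two values (S phase).
#' @param pi_cv coefficient of variation of the PI signal.
#' @param brdu_positive logical; TRUE only for S phase.
#' @return An object of class `cell_class_spec`.
#' @export
cell_class_spec <- function(phase,
                            mixture_weight,
                            diameter_mean, diameter_cv = 0.08,
                            peak_distance_mean, peak_distance_sd = 0.08,
                            amplitude_ratio_mean, amplitude_ratio_sd = 0.08,
                            lobe_fwhm_mean = 0.8, lobe_fwhm_sd = 0.08,
                            dip_depth = 0.65,
                            s_phase_plateau_prob = 0,
                            s_phase_oscillation_amp = 0,
                            pi_mean, pi_cv = 0.04,
                            brdu_positive = FALSE) {
  phase <- match.arg(phase, c("G1", "S", "G2M"))
  stopifnot(mixture_weight >= 0, diameter_mean > 0,
            dip_depth >= 0, dip_depth <= 1,
            s_phase_plateau_prob >= 0, s_phase_plateau_prob <= 1)
  structure(list(phase = phase,
                 mixture_weight = mixture_weight,
                 diameter_mean = diameter_mean, diameter_cv = diameter_cv,
                 peak_distance_mean = peak_distance_mean,
                 peak_distance_sd = peak_distance_sd,
                 amplitude_ratio_mean = amplitude_ratio_mean,
                 amplitude_ratio_sd = amplitude_ratio_sd,
                 lobe_fwhm_mean = lobe_fwhm_mean, lobe_fwhm_sd = lobe_fwhm_sd,
                 dip_depth = dip_depth,
                 s_phase_plateau_prob = s_phase_plateau_prob,
                 s_phase_oscillation_amp = s_phase_oscillation_amp,
                 pi_mean = pi_mean, pi_cv = pi_cv,
                 brdu_positive = isTRUE(brdu_positive)),
            class = "cell_class_spec")
}

#' Default cell-cycle class mixture
#'
#' Three classes calibrated to the published pulse morphology of dividing
#' HEK293 cells: peak distance grows by 0.5 us from G1 to G2/M, the FSCU
#' amplitude ratio increases with cell-cycle progression, some S-phase
#' events show an oscillating inter-peak plateau, cell size grows
#' G1 < S < G2/M, and PI scales from 2N to 4N DNA content with BrdU
#' positivity marking S phase. Mixture weights follow the phase abundances
#' of an asynchronously dividing culture.
#'
#' @param pi_2n mean PI signal of the 2N (G1) population, arbitrary counts.
#' @return List of three `cell_class_spec` objects (G1, S, G2M).
#' @export
default_cell_classes <- function(pi_2n = 20000) {
  list(
    cell_class_spec("G1", mixture_weight = 0.55,
                    diameter_mean = 12.0,
                    peak_distance_mean = list(FSCL = 2.6, FSCU = 2.6),
                    amplitude_ratio_mean = list(SSC = 1, FSCL = 1.00, FSCU = 1.30),
                    lobe_fwhm_mean = 0.70,
                    pi_mean = pi_2n),
    cell_class_spec("S", mixture_weight = 0.35,
                    diameter_mean = 13.0,
                    peak_distance_mean = list(FSCL = 2.85, FSCU = 2.85),
                    amplitude_ratio_mean = list(SSC = 1, FSCL = 1.05, FSCU = 1.60),
                    lobe_fwhm_mean = 0.80,
                    s_phase_plateau_prob = 0.3,
                    s_phase_oscillation_amp = 0.15,
                    pi_mean = c(pi_2n, 2 * pi_2n),
                    brdu_positive = TRUE),
    cell_class_spec("G2M", mixture_weight = 0.10,
                    diameter_mean = 14.5,
                    peak_distance_mean = list(FSCL = 3.1, FSCU = 3.1),
                    amplitude_ratio_mean = list(SSC = 1, FSCL = 1.10, FSCU = 1.90),
                    lobe_fwhm_mean = 0.90,
                    pi_mean = 2 * pi_2n)
  )
}

#' Wavelet transform configuration
#'
#' @param mother_wavelet "haar" or "d4".
#' @param max_level deepest decomposition level J; `2^J` must not exceed the
#'   pulse length (J = 6 for 80-sample pulses).
#' @param boundary "circular" (classical MODWT; exactly shift-equivariant) or
#'   "reflection".
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(mother_wavelet = c("haar", "d4"),
                           max_level = 6,
                           boundary = c("circular", "reflection")) {
  mother_wavelet <- match.arg(mother_wavelet)
  boundary <- match.arg(boundary)
  stopifnot(max_level >= 1)
  structure(list(mother_wavelet = mother_wavelet,
                 max_level = as.integer(max_level),
                 boundary = boundary),
            class = "wavelet_config")
}

#' Reference-label gating configuration
#'
#' @param singlet_band_nsd half-width, in robust SDs, of the accepted band
#'   around the fitted PI width-vs-height trend; events outside are flagged
#'   as aggregates.
#' @param pi_window_nsd half-width, in SDs of the fitted 2N peak, of the 2N
#'   and 4N PI windows (the 4N SD is scaled by 2, i.e. constant CV).
#' @param pi_2n_window,pi_4n_window optional manual PI intervals overriding
#'   the automatic histogram fit.
#' @param brdu_threshold optional manual FITC-H cut separating BrdU+/-;
#'   `NULL` means locate the valley between the two FITC modes.
#' @param min_ssc_height optional debris cut: minimal SSC pulse height.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(singlet_band_nsd = 3,
                        pi_window_nsd = 2,
                        pi_2n_window = NULL,
                        pi_4n_window = NULL,
                        brdu_threshold = NULL,
                        min_ssc_height = 0) {
  stopifnot(singlet_band_nsd > 0, pi_window_nsd > 0)
  structure(list(singlet_band_nsd = singlet_band_nsd,
                 pi_window_nsd = pi_window_nsd,
                 pi_2n_window = pi_2n_window,
                 pi_4n_window = pi_4n_window,
                 brdu_threshold = brdu_threshold,
                 min_ssc_height = min_ssc_height),
            class = "gate_config")
}
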