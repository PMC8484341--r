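#' Variance-based selection of the informative wavelet level
#'
#' For each decomposition level the pulses are reconstructed from that
#' level's coefficients alone (MRA detail); the standard deviation across
#' events is computed at every time sampling point and summarized by its sum
#' over the window. The level with the largest summary carries the
#' across-event variation — the morphology differences the clustering should
#' see — and is selected (ties break toward the smaller level). Pulses are
#' baseline-subtracted (median of the pre-trigger samples) first so the
#' smooth level does not encode detector offsets.
#'
#' @param pulses a [pulse_dataset()] with at least 2 events.
#' @param channel channel label to analyze.
#' @param config a [wavelet_config()].
#' @return Object of class `level_diagnostics`: `sd_curves`
#'   (`max_level x n_samples` matrix of per-timepoint SDs), `summary`
#'   (per-level sums), `selected_level` (NA if all summaries are zero,
#'   i.e. identical pulses), `channel`, `config`.
#' @export
select_feature_level <- function(pulses, channel, config = wavelet_config()) {
  stopifnot(inherits(pulses, "pulse_dataset"))
  if (n_events(pulses) < 2)
    stop("level selection needs at least 2 events to measure across-event variation")
  m <- channel_matrix(pulses, channel)
  x <- t(m - pulse_baseline(m))            # n_samples x n_events
  filt <- wavelet_filters(config$mother_wavelet)
  J <- config$max_level
  if (2^J > nrow(x))
    stop(sprintf("2^max_level = %d exceeds pulse length %d", 2^J, nrow(x)))
  mra <- .modwt_mra_mat(x, filt, J, config$boundary)
  sd_curves <- t(vapply(mra$details,
                        function(d) apply(d, 1, stats::sd),
                        numeric(nrow(x))))
  summaries <- rowSums(sd_curves)
  if (max(summaries) <= 0) {
    warning("all pulses identical: per-timepoint SD is zero at every level, ",
            "no informative level exists")
    sel <- NA_integer_
  } else {
    sel <- which.max(summaries)            # which.max takes the first maximum
    if (sel == J)
      message("selected level is the deepest level (", J,
              "); variation may extend beyond the analyzed scales")
  }
  structure(list(sd_curves = sd_curves,
                 summary = summaries,
                 selected_level = sel,
                 channel = channel,
                 config = config),
            class = "level_diagnostics")
}

#' @export
print.level_diagnostics <- function(x, ...) {
  cat(sprintf("<level_diagnostics> channel %s: selected level %s\n",
              x$channel, x$selected_level))
  s <- sprintf("%.3g", x$summary)
  cat("  per-level SD sums:", paste(s, collapse = " "), "\n")
  invisible(x)
}

#' Extract per-event wavelet coefficient vectors at one level
#'
#' Returns, for every event, the detail coefficients of the chosen level for
#' the chosen channel — the undecimated transform keeps one coefficient per
#' sample, so each vector has the pulse length (80 at defaults). No
#' normalization is applied: coefficient magnitude carries the pulse
#' amplitude, which is itself informative.
#'
#' @param pulses a [pulse_dataset()].
#' @param channel channel label.
#' @param level decomposition level in `1..max_level`.
#' @param config a [wavelet_config()].
#' @return Object of class `wavelet_features`: `x` (`n_events x n_samples`
#'   coefficient matrix), `event_id`, `channel`, `level`, `config`.
#' @export
extract_features <- function(pulses, channel, level,
                             config = wavelet_config()) {
  stopifnot(inherits(pulses, "pulse_dataset"))
  if (!(level %in% seq_len(config$max_level)))
    stop("level must be in 1..", config$max_level)
  m <- channel_matrix(pulses, channel)
  x <- t(m - pulse_baseline(m))            # n_samples x n_events
  filt <- wavelet_filters(config$mother_wavelet)
  xw <- if (config$boundary == "reflection") .reflect(x) else x
  dec <- .modwt_mat(xw, filt, level)       # only need levels up to `level`
  structure(list(x = t(dec$W[[level]][seq_len(nrow(x)), , drop = FALSE]),
                 event_id = pulses$event_ids,
                 channel = channel,
                 level = as.integer(level),
                 config = config),
            class = "wavelet_features")
}

#' @export
print.wavelet_features <- function(x, ...) {
  cat(sprintf("<wavelet_features> channel %s, level %d: %d events x %d coefficients\n",
              x$channel, x$level, nrow(x$x), ncol(x$x)))
  invisible(x)
}
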