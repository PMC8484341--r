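#' Per-event multichannel pulse-shape dataset
#'
#' Container for raw pulse shapes: an `n_events x n_channels x n_samples`
#' array of unsigned integer ADC counts plus the acquisition configuration.
#'
#' @param data numeric array of dimension `c(n_events, n_channels,
#'   n_samples)`; values must be integers in `[0, 2^adc_bits - 1]`.
#' @param config an [acquisition_config()].
#' @param event_ids strictly increasing integer event identifiers; default
#'   `1:n_events`.
#' @return An object of class `pulse_dataset`.
#' @export
pulse_dataset <- function(data, config = acquisition_config(),
                          event_ids = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != config$n_channels)
    stop("data has ", dim(data)[2], " channels but config declares ",
         config$n_channels)
  if (dim(data)[3] != config$n_samples)
    stop("data has ", dim(data)[3], " samples/pulse but config implies ",
         config$n_samples)
  if (is.null(event_ids)) event_ids <- seq_len(dim(data)[1])
  event_ids <- as.integer(event_ids)
  if (length(event_ids) != dim(data)[1])
    stop("event_ids length must equal the number of events")
  if (length(event_ids) > 1 && any(diff(event_ids) <= 0))
    stop("event_ids must be strictly increasing")
  adc_max <- 2^config$adc_bits - 1
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > adc_max)
    stop(sprintf("sample values out of ADC range [0, %d]", adc_max))
  if (max(abs(data - round(data))) > 0)
    stop("sample values must be integers (ADC counts)")
  storage.mode(data) <- "integer"    # canonical storage: bit-exact round trips
  structure(list(config = config,
                 data = data,
                 event_ids = event_ids),
            class = "pulse_dataset")
}

#' @export
print.pulse_dataset <- function(x, ...) {
  cat(sprintf("<pulse_dataset> %d events, %d channels x %d samples (%s)\n",
              length(x$event_ids), x$config$n_channels, x$config$n_samples,
              paste(x$config$channel_names, collapse = ", ")))
  invisible(x)
}

n_events <- function(pulses) length(pulses$event_ids)

# n_events x n_samples matrix of one channel's pulses
channel_matrix <- function(pulses, channel) {
  ci <- match(channel, pulses$config$channel_names)
  if (is.na(ci)) stop("unknown channel: ", channel)
  m <- pulses$data[, ci, , drop = FALSE]
  dim(m) <- dim(m)[c(1, 3)]
  m
}

PSB_MAGIC <- charToRaw("PSBF")
PSB_VERSION <- 1L
CHNAME_BYTES <- 16L

psb_header_size <- function(n_channels) {
  # magic(4) version(2) rates/durations(4 x float64) nch(2) bits(2)
  # nsamp(4) nevents(4) names(16 x nch)
  4L + 2L + 8L * 4L + 2L + 2L + 4L + 4L + CHNAME_BYTES * n_channels
}

#' Write a pulse-shape dataset to the .psb binary format
#'
#' Versioned little-endian layout: a fixed header (magic `"PSBF"`, format
#' version, acquisition settings, channel names) followed by a fixed-stride
#' payload of one record per event: the `uint32` event id then
#' `n_channels x n_samples` `uint16` samples, channel-major. The fixed
#' stride makes seeking to event *i* O(1).
#'
#' @param dataset a [pulse_dataset()].
#' @param destination output file path.
#' @return `destination`, invisibly.
#' @export
write_psb <- function(dataset, destination) {
  stopifnot(inherits(dataset, "pulse_dataset"))
  cfg <- dataset$config
  if (cfg$adc_bits > 16)
    stop("psb stores uint16 samples; adc_bits must be <= 16")
  con <- file(destination, "wb")
  on.exit(close(con))
  writeBin(PSB_MAGIC, con)
  writeBin(PSB_VERSION, con, size = 2, endian = "little")
  writeBin(c(cfg$sampling_rate, cfg$window, cfg$trigger_time,
             cfg$lowpass_cutoff), con, size = 8, endian = "little")
  writeBin(cfg$n_channels, con, size = 2, endian = "little")
  writeBin(cfg$adc_bits, con, size = 2, endian = "little")
  writeBin(cfg$n_samples, con, size = 4, endian = "little")
  writeBin(length(dataset$event_ids), con, size = 4, endian = "little")
  for (nm in cfg$channel_names) {
    raw_nm <- charToRaw(nm)
    if (length(raw_nm) > CHNAME_BYTES)
      stop("channel name longer than ", CHNAME_BYTES, " bytes: ", nm)
    writeBin(c(raw_nm, raw(CHNAME_BYTES - length(raw_nm))), con)
  }
  nev <- length(dataset$event_ids)
  for (i in seq_len(nev)) {
    writeBin(dataset$event_ids[i], con, size = 4, endian = "little")
    # channel-major: channel 1 samples, channel 2 samples, ...
    # writeBin(size = 2) keeps the low 16 bits, which is exactly uint16
    # for values in [0, 65535] (validated by pulse_dataset)
    writeBin(as.integer(t(dataset$data[i, , ])), con, size = 2,
             endian = "little")
  }
  invisible(destination)
}

#' Read a .psb pulse-shape file
#'
#' Inverse of [write_psb()]; validates the magic string, format version and
#' payload length, and refuses truncated files with the offending byte
#' offset.
#'
#' @param source path to a `.psb` file.
#' @return A [pulse_dataset()].
#' @export
read_psb <- function(source) {
  sz <- file.size(source)
  con <- file(source, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4 || !identical(magic, PSB_MAGIC))
    stop("not a psb file (bad magic)")
  version <- readBin(con, "integer", 1, size = 2, endian = "little")
  if (!identical(version, PSB_VERSION))
    stop("unsupported psb format version: ", version)
  hdr <- readBin(con, "numeric", 4, size = 8, endian = "little")
  n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
  adc_bits <- readBin(con, "integer", 1, size = 2, endian = "little")
  n_samples <- readBin(con, "integer", 1, size = 4, endian = "little")
  nev <- readBin(con, "integer", 1, size = 4, endian = "little")
  ch_names <- vapply(seq_len(n_channels), function(i) {
    b <- readBin(con, "raw", CHNAME_BYTES)
    rawToChar(b[b != as.raw(0)])
  }, character(1))
  cfg <- acquisition_config(sampling_rate = hdr[1], window = hdr[2],
                            trigger_time = hdr[3], lowpass_cutoff = hdr[4],
                            n_channels = n_channels, adc_bits = adc_bits,
                            channel_names = ch_names)
  if (cfg$n_samples != n_samples)
    stop(sprintf(
      "header inconsistency: window %g us at %g Hz implies %d samples, header says %d",
      hdr[2], hdr[1], cfg$n_samples, n_samples))
  stride <- 4L + 2L * n_channels * n_samples
  expected <- psb_header_size(n_channels) + as.numeric(stride) * nev
  if (sz != expected)
    stop(sprintf(
      "corrupt psb payload: expected %d bytes, file has %d (truncation at byte offset %d?)",
      expected, sz, sz))
  data <- array(0L, dim = c(nev, n_channels, n_samples))
  event_ids <- integer(nev)
  for (i in seq_len(nev)) {
    event_ids[i] <- readBin(con, "integer", 1, size = 4, endian = "little")
    v <- readBin(con, "integer", n_channels * n_samples, size = 2,
                 signed = FALSE, endian = "little")
    data[i, , ] <- matrix(v, nrow = n_channels, byrow = TRUE)
  }
  pulse_dataset(data, cfg, event_ids)
}

#' Baseline estimate of a pulse
#'
#' Median of the first `n_pre` samples; the trigger convention (2 us into
#' the window) guarantees pre-pulse samples at the start of every record.
#'
#' @param pulse numeric sample vector, or an `n_events x n_samples` matrix
#'   (one baseline per row).
#' @param n_pre number of leading samples used.
#' @return Baseline estimate(s) in ADC counts.
#' @export
pulse_baseline <- function(pulse, n_pre = 5) {
  if (is.matrix(pulse))
    apply(pulse[, seq_len(n_pre), drop = FALSE], 1, stats::median)
  else
    stats::median(pulse[seq_len(n_pre)])
}

#' Derive conventional height / area / width parameters from one pulse
#'
#' The three scalars a conventional cytometer stores per channel:
#' `height = max - baseline`, `area` the baseline-subtracted sum (clipped at
#' zero) times the sample period, and `width` the time between the first and
#' last crossing of `baseline + width_fraction * height`, linearly
#' interpolated between samples (FWHM at the default `width_fraction` 0.5).
#' Sample index 0 corresponds to time 0 of the window.
#'
#' @param pulse numeric vector of `n_samples` ADC counts.
#' @param config an [acquisition_config()].
#' @param baseline baseline level; default [pulse_baseline()] of the pulse.
#' @param width_fraction threshold fraction of the height, in (0, 1).
#' @return A list with `height` (counts), `area` (counts * us),
#'   `width` (us).
#' @export
derive_haw <- function(pulse, config = acquisition_config(),
                       baseline = NULL, width_fraction = 0.5) {
  stopifnot(length(pulse) == config$n_samples,
            width_fraction > 0, width_fraction < 1)
  if (is.null(baseline)) baseline <- pulse_baseline(pulse)
  dt <- sample_period_us(config)
  height <- max(pulse) - baseline
  if (height <= 0)
    return(list(height = 0, area = 0, width = 0))
  area <- sum(pmax(pulse - baseline, 0)) * dt
  level <- baseline + width_fraction * height
  above <- pulse >= level
  idx <- which(above)
  first <- idx[1]; last <- idx[length(idx)]
  # linear interpolation at the rising and falling crossings (0-based time)
  t_first <- if (first == 1) 0 else
    (first - 2) + (level - pulse[first - 1]) / (pulse[first] - pulse[first - 1])
  t_last <- if (last == length(pulse)) length(pulse) - 1 else
    (last - 1) + (pulse[last] - level) / (pulse[last] - pulse[last + 1])
  list(height = height, area = area, width = (t_last - t_first) * dt)
}

#' Build a per-event scalar table from a pulse dataset
#'
#' Derives H/A/W for every channel of every event, producing the list-mode
#' view of the data. Columns are named `"<CHANNEL>-H"`, `"<CHANNEL>-A"`,
#' `"<CHANNEL>-W"`.
#'
#' @param pulses a [pulse_dataset()].
#' @param channels channels to derive; default all.
#' @param width_fraction passed to [derive_haw()].
#' @return A `data.frame` with one row per event (`event_id` first).
#' @export
event_table <- function(pulses, channels = pulses$config$channel_names,
                        width_fraction = 0.5) {
  out <- data.frame(event_id = pulses$event_ids)
  for (ch in channels) {
    m <- channel_matrix(pulses, ch)
    haw <- t(apply(m, 1, function(p) {
      r <- derive_haw(p, pulses$config, width_fraction = width_fraction)
      c(r$height, r$area, r$width)
    }))
    out[[paste0(ch, "-H")]] <- haw[, 1]
    out[[paste0(ch, "-A")]] <- haw[, 2]
    out[[paste0(ch, "-W")]] <- haw[, 3]
  }
  out
}

#' Link an FCS-derived event table with a pulse dataset
#'
#' Inner join on `event_id`: events present in only one of the two views
#' are reported via a warning and dropped (routine practice when list-mode
#' and pulse files disagree, e.g. after an aborted write). Output rows
#' follow the pulse-file order.
#'
#' @param fcs_table `data.frame` with an `event_id` column.
#' @param pulses a [pulse_dataset()].
#' @return List with `events` (the joined table) and `pulses` (subset
#'   dataset restricted to the common events, in file order).
#' @export
link_events <- function(fcs_table, pulses) {
  stopifnot(is.data.frame(fcs_table), "event_id" %in% names(fcs_table),
            inherits(pulses, "pulse_dataset"))
  common <- intersect(pulses$event_ids, fcs_table$event_id)
  if (length(common) == 0)
    stop("linkage error: no event_id shared between FCS table and pulse file")
  only_fcs <- setdiff(fcs_table$event_id, common)
  only_psb <- setdiff(pulses$event_ids, common)
  if (length(only_fcs) || length(only_psb))
    warning(sprintf(
      "dropping unmatched events: %d only in FCS (%s), %d only in pulse file (%s)",
      length(only_fcs), paste(utils::head(only_fcs, 5), collapse = ","),
      length(only_psb), paste(utils::head(only_psb, 5), collapse = ",")))
  keep <- pulses$event_ids %in% common
  sub <- pulse_dataset(pulses$data[keep, , , drop = FALSE], pulses$config,
                       pulses$event_ids[keep])
  rows <- match(sub$event_ids, fcs_table$event_id)
  list(events = fcs_table[rows, , drop = FALSE], pulses = sub)
}
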