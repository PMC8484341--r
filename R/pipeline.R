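#' Default simulation scenario
#'
#' A declarative description of one synthetic acquisition (classes, noise,
#' beam, acquisition settings, event count, seed) that can be round-tripped
#' through YAML for provenance.
#'
#' @param n_events cohort size.
#' @param seed RNG seed.
#' @param doublet_fraction doublet probability.
#' @return A list understood by [run_simulate()].
#' @export
default_scenario <- function(n_events = 10000, seed = 1,
                             doublet_fraction = 0.02) {
  list(schema_version = 1L,
       n_events = n_events,
       seed = seed,
       classes = default_cell_classes(),
       noise = noise_model(doublet_fraction = doublet_fraction),
       beam = beam_model(),
       acquisition = acquisition_config())
}

#' Simulate a cohort and write its artifacts
#'
#' Runs [simulate_cohort()] and writes the pulse file (`cohort.psb`), the
#' linked FCS 3.0 list-mode file (`cohort.fcs`), the ground-truth CSV and a
#' JSON manifest recording the scenario (seed included) for provenance.
#'
#' @param scenario a [default_scenario()]-shaped list.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the [simulate_cohort()] result with `paths` attached.
#' @export
run_simulate <- function(scenario = default_scenario(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(classes = scenario$classes,
                         n_events = scenario$n_events,
                         noise = scenario$noise,
                         beam = scenario$beam,
                         config = scenario$acquisition,
                         seed = scenario$seed)
  paths <- list(psb = file.path(out_dir, "cohort.psb"),
                fcs = file.path(out_dir, "cohort.fcs"),
                truth = file.path(out_dir, "ground_truth.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_psb(sim$pulses, paths$psb)
  export_fcs(sim$events, paths$fcs)
  utils::write.csv(sim$truth, paths$truth, row.names = FALSE)
  manifest <- list(schema_version = 1L,
                   seed = scenario$seed,
                   n_events = scenario$n_events,
                   n_written = length(sim$pulses$event_ids),
                   n_rejected = sim$n_rejected,
                   classes = lapply(scenario$classes, unclass),
                   noise = unclass(scenario$noise),
                   beam = unclass(scenario$beam))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  sim$paths <- paths
  invisible(sim)
}

#' Fit the full wavelet-cluster pipeline on one acquisition
#'
#' The reference analysis chain: singlet and phase gating from the
#' fluorescence labels, per-channel MODWT with variance-based level
#' selection, k-means vector quantization of the selected-level
#' coefficients on the two forward-scatter channels, combination into the
#' k x k contingency of combined clusters, phase-enrichment computation and
#' six-group assignment.
#'
#' @param pulses a [pulse_dataset()] (or path to a `.psb` file).
#' @param events event table aligned with `pulses` (or path to an FCS
#'   file); must carry PI/FITC scalars for reference gating.
#' @param channels the two channels to cluster and combine.
#' @param k clusters per channel.
#' @param seed RNG seed for the clustering.
#' @param wavelet a [wavelet_config()].
#' @param gates a [gate_config()].
#' @param level optional fixed decomposition level (per-channel selection
#'   when `NULL`).
#' @param size_cutoff_fraction,t_specific,t_mixed see [enrichment_table()]
#'   and [assign_groups()].
#' @param out_dir optional directory; when given, writes cluster models
#'   (JSON), enrichment/group table (CSV), level diagnostics (CSV), the
#'   gated event table (FCS with cluster and group parameters) and a
#'   base-graphics PDF with the level-diagnostic curves and the group map.
#' @return Object of class `mapsfc_fit`: gated `events`, per-channel
#'   `models` and `levels`, `combined`, grouped `enrichment`, and
#'   `fingerprints`.
#' @export
run_fit <- function(pulses, events,
                    channels = c("FSCL", "FSCU"),
                    k = 8, seed = 1,
                    wavelet = wavelet_config(),
                    gates = gate_config(),
                    level = NULL,
                    size_cutoff_fraction = 0.005,
                    t_specific = 1.5, t_mixed = 1.1,
                    out_dir = NULL) {
  if (is.character(pulses)) pulses <- read_psb(pulses)
  if (is.character(events)) events <- read_fcs(events)$data
  stopifnot(length(channels) == 2)
  if (!"event_id" %in% names(events))
    events$event_id <- pulses$event_ids
  linked <- link_events(events, pulses)
  events <- linked$events; pulses <- linked$pulses

  events <- gate_singlets(events, gates)
  events <- gate_phases(events, gates)

  diags <- list(); models <- list(); labels <- list()
  for (ch in channels) {
    dg <- select_feature_level(pulses, ch, wavelet)
    lv <- if (is.null(level)) dg$selected_level else level
    if (is.na(lv))
      stop("degenerate data on channel ", ch,
           ": no informative wavelet level (identical pulses?)")
    feats <- extract_features(pulses, ch, lv, wavelet)
    mod <- fit_channel_clusters(feats, k = k, seed = seed)
    diags[[ch]] <- dg
    models[[ch]] <- mod
    labels[[ch]] <- mod$labels
  }
  combined <- combine_clusters(labels[[channels[1]]], labels[[channels[2]]],
                               k, k)
  enr <- enrichment_table(combined, events, size_cutoff_fraction)
  enr <- assign_groups(enr, t_specific, t_mixed)

  events$cluster_combined <- combined$combined_id
  events$cluster_group <- as.integer(enr$group[match(combined$combined_id,
                                                     enr$cluster)])
  fit <- structure(list(events = events,
                        models = models,
                        diagnostics = diags,
                        combined = combined,
                        enrichment = enr,
                        channels = channels,
                        fingerprints = vapply(models, `[[`, "",
                                              "fingerprint"),
                        wavelet = wavelet,
                        seed = seed),
                   class = "mapsfc_fit")
  if (!is.null(out_dir)) .write_fit_reports(fit, out_dir)
  fit
}

#' @export
print.mapsfc_fit <- function(x, ...) {
  cat(sprintf("<mapsfc_fit> %d events, channels %s (levels %s), %d combined clusters\n",
              nrow(x$events), paste(x$channels, collapse = "+"),
              paste(vapply(x$models, `[[`, 0L, "level"), collapse = ","),
              x$combined$k_A * x$combined$k_B))
  print(table(group = x$enrichment$group))
  invisible(x)
}

.write_fit_reports <- function(fit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in fit$channels)
    write_cluster_model(fit$models[[ch]],
                        file.path(out_dir, paste0("model_", ch, ".json")))
  utils::write.csv(as.data.frame(fit$enrichment),
                   file.path(out_dir, "enrichment_groups.csv"),
                   row.names = FALSE)
  dcurves <- do.call(rbind, lapply(fit$channels, function(ch) {
    d <- fit$diagnostics[[ch]]
    data.frame(channel = ch, level = seq_along(d$summary),
               sd_sum = d$summary, selected = seq_along(d$summary) ==
                 d$selected_level)
  }))
  utils::write.csv(dcurves, file.path(out_dir, "level_diagnostics.csv"),
                   row.names = FALSE)
  export_fcs(fit$events, file.path(out_dir, "events_with_clusters.fcs"))
  grDevices::pdf(file.path(out_dir, "fit_report.pdf"), width = 8, height = 5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  for (ch in fit$channels) {
    d <- fit$diagnostics[[ch]]
    graphics::matplot(t(d$sd_curves), type = "l", lty = 1,
                      xlab = "sample", ylab = "SD across events",
                      main = paste0(ch, ": per-level SD (level ",
                                    d$selected_level, " selected)"))
  }
  grp <- matrix(as.integer(fit$enrichment$group),
                fit$combined$k_A, fit$combined$k_B, byrow = TRUE)
  graphics::par(mfrow = c(1, 1))
  graphics::image(seq_len(nrow(grp)), seq_len(ncol(grp)), grp,
                  xlab = fit$channels[1], ylab = fit$channels[2],
                  main = "combined-cluster group map",
                  col = grDevices::hcl.colors(7, "Spectral"))
  invisible(out_dir)
}

#' Assign a probe acquisition to a frozen fit and compare compositions
#'
#' Wraps the centroid-transfer analyses: in `"sorted"` mode the probe (a
#' fluorescence-sorted aliquot) is assigned with the reference centroids
#' and per-group fractions / per-cluster fold changes are reported; in
#' `"arrest"` mode the probe is the t = 0 h post-arrest sample and
#' clusters are mapped to G2M / G1&S by their size response.
#'
#' @param fit a [run_fit()] result (the frozen reference).
#' @param probe_pulses probe [pulse_dataset()] (or `.psb` path).
#' @param mode `"sorted"` or `"arrest"`.
#' @param out_dir optional directory for CSV reports.
#' @param ratio_threshold for `"arrest"` mode, see [assign_by_arrest()].
#' @return A `composition_report` (`"sorted"`) or the [assign_by_arrest()]
#'   map (`"arrest"`).
#' @export
run_transfer <- function(fit, probe_pulses, mode = c("sorted", "arrest"),
                         out_dir = NULL, ratio_threshold = 1.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "mapsfc_fit"))
  if (is.character(probe_pulses)) probe_pulses <- read_psb(probe_pulses)
  labels <- lapply(fit$channels, function(ch) {
    feats <- extract_features(probe_pulses, ch, fit$models[[ch]]$level,
                              fit$wavelet)
    assign_clusters(feats, fit$models[[ch]])
  })
  probe_combined <- combine_clusters(labels[[1]], labels[[2]],
                                     fit$models[[1]]$k, fit$models[[2]]$k)
  result <- if (mode == "sorted") {
    compare_samples(
      reference = list(combined = fit$combined, enrichment = fit$enrichment,
                       fingerprints = fit$fingerprints),
      probe = list(combined = probe_combined,
                   fingerprints = fit$fingerprints))
  } else {
    ids <- fit$enrichment$cluster
    f <- function(cmb) {
      n <- as.integer(table(factor(cmb$combined_id, levels = ids)))
      n / sum(n)
    }
    assign_by_arrest(f(fit$combined), f(probe_combined), ratio_threshold)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (mode == "sorted") {
      utils::write.csv(result$groups,
                       file.path(out_dir, "group_composition.csv"),
                       row.names = FALSE)
      utils::write.csv(result$clusters,
                       file.path(out_dir, "cluster_fold_changes.csv"),
                       row.names = FALSE)
    } else {
      utils::write.csv(result, file.path(out_dir, "arrest_assignment.csv"),
                       row.names = FALSE)
    }
  }
  result
}

#' Read / write a simulation scenario as YAML
#'
#' @param scenario a [default_scenario()]-shaped list.
#' @param path YAML file path.
#' @return `read_scenario` returns the scenario list with typed
#'   configuration objects restored.
#' @export
write_scenario <- function(scenario, path) {
  plain <- scenario
  plain$classes <- lapply(scenario$classes, unclass)
  plain$noise <- unclass(scenario$noise)
  plain$beam <- unclass(scenario$beam)
  plain$acquisition <- unclass(scenario$acquisition)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  s <- yaml::read_yaml(path)
  if (is.null(s$schema_version) || s$schema_version != 1)
    stop("unsupported scenario schema version")
  s$n_events <- as.integer(s$n_events)
  s$seed <- as.integer(s$seed)
  # rebuild typed objects through the constructors so validation reruns
  s$classes <- lapply(s$classes, function(cl) {
    cl$pi_mean <- unlist(cl$pi_mean)
    do.call(cell_class_spec, cl)
  })
  s$noise$doublet_offset_range <- unlist(s$noise$doublet_offset_range)
  s$noise <- do.call(noise_model, s$noise)
  s$beam <- do.call(beam_model, s$beam)
  s$acquisition$n_samples <- NULL
  s$acquisition$channel_names <- unlist(s$acquisition$channel_names)
  s$acquisition <- do.call(acquisition_config, s$acquisition)
  s
}
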