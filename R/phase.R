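PHASES <- c("G1", "S", "G2M")
CLUSTER_GROUPS <- c("G1", "G1&S", "S&G1", "S&G2M", "G2M",
                    "undefined", "below_cutoff")

#' Flag singlet events from the PI width-vs-height relation
#'
#' Cell aggregates carry roughly additive DNA signal area but a transit
#' width stretched by the second cell, so they sit above the width-vs-height
#' trend of single cells. A robust linear fit of `PI-W` on `PI-H` is
#' computed and events within `singlet_band_nsd` robust SDs of the trend
#' (and above any `min_ssc_height` debris cut) are flagged as singlets.
#'
#' @param events `data.frame` with `PI-H` and `PI-W` columns.
#' @param config a [gate_config()].
#' @return `events` with a logical `singlet` column.
#' @export
gate_singlets <- function(events, config = gate_config()) {
  if (!all(c("PI-H", "PI-W") %in% names(events)))
    stop("gate_singlets requires PI-H and PI-W columns")
  h <- events[["PI-H"]]; w <- events[["PI-W"]]
  fit <- suppressWarnings(MASS::rlm(w ~ h, maxit = 50))
  resid <- w - stats::predict(fit)
  s <- stats::mad(resid)
  if (s == 0) s <- stats::sd(resid)        # degenerate noiseless input
  singlet <- abs(resid) <= config$singlet_band_nsd * s
  if (config$min_ssc_height > 0 && "SSC-H" %in% names(events))
    singlet <- singlet & events[["SSC-H"]] >= config$min_ssc_height
  if (mean(singlet) < 0.5)
    warning(sprintf("only %.1f%% of events pass the singlet gate",
                    100 * mean(singlet)))
  events$singlet <- singlet
  events
}

# locate the 2N peak of the PI histogram: the largest density mode
.pi_2n_peak <- function(pi_vals) {
  d <- stats::density(pi_vals, n = 512)
  mu <- d$x[which.max(d$y)]
  near <- pi_vals[abs(pi_vals - mu) < 0.2 * mu]
  list(mu = mu, sigma = stats::mad(near, center = mu))
}

# valley between the two modes of log(FITC)
.brdu_valley <- function(fitc) {
  lx <- log(pmax(fitc, 1))
  d <- stats::density(lx, n = 512)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  if (length(peaks) >= 2) {
    peaks <- peaks[order(d$y[peaks], decreasing = TRUE)][1:2]
    lo <- min(peaks); hi <- max(peaks)
    valley <- d$x[lo + which.min(d$y[lo:hi]) - 1]
  } else {
    km <- stats::kmeans(lx, centers = 2, nstart = 5)
    valley <- mean(km$centers)
  }
  exp(valley)
}

#' Assign reference cell-cycle phases from PI and BrdU fluorescence
#'
#' BrdU incorporation marks replicating cells, so `S` is called first:
#' any singlet with `FITC-H` above the BrdU threshold. Remaining singlets
#' are `G1` if their PI signal falls in the fitted 2N window, `G2M` if in
#' the 4N window (centered at twice the 2N peak), otherwise `unlabeled`.
#' Windows default to `mu +/- 2 sigma` around the fitted 2N peak and
#' `2 mu +/- 2 (2 sigma)` for 4N (the SD scales with the mean).
#'
#' @param events `data.frame` after [gate_singlets()], with `PI-A` and
#'   `FITC-H` columns.
#' @param config a [gate_config()]; manual windows/thresholds override the
#'   automatic fits.
#' @return `events` with a `reference_phase` column
#'   (`G1`/`S`/`G2M`/`unlabeled`) and the fitted gates stored in
#'   `attr(, "gates")`.
#' @export
gate_phases <- function(events, config = gate_config()) {
  if (!"singlet" %in% names(events))
    stop("run gate_singlets before gate_phases")
  if (!all(c("PI-A", "FITC-H") %in% names(events)))
    stop("gate_phases requires PI-A and FITC-H columns")
  sing <- events$singlet
  pi_vals <- events[["PI-A"]][sing]

  if (is.null(config$pi_2n_window) || is.null(config$pi_4n_window)) {
    pk <- .pi_2n_peak(pi_vals)
    if (!is.finite(pk$sigma) || pk$sigma <= 0)
      stop("PI histogram fit failed (no spread around the 2N peak); ",
           "supply pi_2n_window/pi_4n_window manually")
    w2 <- config$pi_2n_window %||%
      (pk$mu + c(-1, 1) * config$pi_window_nsd * pk$sigma)
    w4 <- config$pi_4n_window %||%
      (2 * pk$mu + c(-1, 1) * config$pi_window_nsd * 2 * pk$sigma)
  } else {
    w2 <- config$pi_2n_window; w4 <- config$pi_4n_window
  }
  if (w4[1] <= w2[2])
    stop("fitted 2N and 4N PI windows overlap; supply windows manually")
  thr <- config$brdu_threshold %||% .brdu_valley(events[["FITC-H"]][sing])

  phase <- rep("unlabeled", nrow(events))
  pi_a <- events[["PI-A"]]; fitc <- events[["FITC-H"]]
  is_s <- sing & fitc > thr
  is_g1 <- sing & !is_s & pi_a >= w2[1] & pi_a <= w2[2]
  is_g2 <- sing & !is_s & pi_a >= w4[1] & pi_a <= w4[2]
  phase[is_s] <- "S"; phase[is_g1] <- "G1"; phase[is_g2] <- "G2M"
  events$reference_phase <- phase
  attr(events, "gates") <- list(pi_2n_window = w2, pi_4n_window = w4,
                                brdu_threshold = thr)
  events
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cluster phase enrichment over the combined clustering
#'
#' For each combined cluster the fraction of its labeled singlets in each
#' phase is divided by the phase's fraction among all labeled singlets:
#' `e(c, p) = f_c(p) / f_all(p)`, the observed-over-expected enrichment
#' factor. Clusters holding fewer than `size_cutoff_fraction` of all events
#' are flagged and excluded from group assignment. The conservation
#' identity `sum_p f_all(p) e(c, p) = 1` holds for every cluster with
#' labeled events.
#'
#' @param combined a [combine_clusters()] result.
#' @param events event table with `reference_phase` (after
#'   [gate_phases()]), row-aligned with `combined`.
#' @param size_cutoff_fraction minimal cluster size as a fraction of all
#'   events.
#' @return `data.frame` of class `enrichment_table`, one row per combined
#'   cluster: `cluster` (0-based id), `label_A`, `label_B`, `n`,
#'   `n_labeled`, `f_G1`, `f_S`, `f_G2M`, `e_G1`, `e_S`, `e_G2M`,
#'   `below_cutoff`. Global phase fractions are in `attr(, "f_all")`.
#' @export
enrichment_table <- function(combined, events, size_cutoff_fraction = 0.005) {
  stopifnot(inherits(combined, "combined_clustering"),
            nrow(events) == length(combined$combined_id))
  if (!"reference_phase" %in% names(events))
    stop("events need reference_phase; run gate_phases first")
  labeled <- events$reference_phase %in% PHASES
  if (!any(labeled))
    stop("no labeled events to compute enrichment from")
  f_all <- prop.table(table(factor(events$reference_phase[labeled],
                                   levels = PHASES)))
  n_total <- nrow(events)
  ids <- seq_len(combined$k_A * combined$k_B) - 1L
  cl <- factor(combined$combined_id, levels = ids)
  n_c <- as.integer(table(cl))
  tab <- table(cl[labeled], factor(events$reference_phase[labeled],
                                   levels = PHASES))
  n_lab <- rowSums(tab)
  f_c <- sweep(tab, 1, pmax(n_lab, 1), "/")
  e <- sweep(f_c, 2, as.numeric(f_all), "/")
  e[, as.numeric(f_all) == 0] <- NA        # undefined, not infinite
  e[n_lab == 0, ] <- NA
  out <- data.frame(
    cluster = ids,
    label_A = ids %/% combined$k_B + 1L,
    label_B = ids %% combined$k_B + 1L,
    n = n_c,
    n_labeled = as.integer(n_lab),
    f_G1 = as.numeric(f_c[, "G1"]), f_S = as.numeric(f_c[, "S"]),
    f_G2M = as.numeric(f_c[, "G2M"]),
    e_G1 = as.numeric(e[, "G1"]), e_S = as.numeric(e[, "S"]),
    e_G2M = as.numeric(e[, "G2M"]),
    below_cutoff = n_c < size_cutoff_fraction * n_total
  )
  attr(out, "f_all") <- as.numeric(f_all)
  attr(out, "n_events") <- n_total
  attr(out, "size_cutoff_fraction") <- size_cutoff_fraction
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Assign combined clusters to the six cell-cycle groups
#'
#' Rules, applied per cluster on the phase enrichments: a cluster is a
#' *pure* `G1` or `G2M` group if that phase tops the ranking with
#' `e >= t_specific` while every other phase stays below `t_mixed`; it is a
#' *mixed* group when the top two phases are cell-cycle-adjacent (G1-S or
#' S-G2M) and both reach `t_mixed`, named top-first (`G1&S` vs `S&G1`; the
#' S-G2/M pair is always reported as `S&G2M`, the only such group in the
#' scheme). Everything else is `undefined`; clusters under the size cutoff
#' stay `below_cutoff`. G1-G2/M is not adjacent: no mixed group exists for
#' that pair.
#'
#' @param table an [enrichment_table()].
#' @param t_specific enrichment needed for a pure G1/G2M call.
#' @param t_mixed enrichment needed from both phases of a mixed call.
#' @return The table with a `group` factor column added.
#' @export
assign_groups <- function(table, t_specific = 1.5, t_mixed = 1.1) {
  stopifnot(inherits(table, "enrichment_table"))
  e_mat <- as.matrix(table[, c("e_G1", "e_S", "e_G2M")])
  colnames(e_mat) <- PHASES
  group <- rep("undefined", nrow(table))
  for (i in seq_len(nrow(table))) {
    e <- e_mat[i, ]
    if (table$below_cutoff[i]) { group[i] <- "below_cutoff"; next }
    if (all(is.na(e))) next
    e[is.na(e)] <- 0
    ord <- order(e, decreasing = TRUE)
    top <- PHASES[ord[1]]; second <- PHASES[ord[2]]
    if (top %in% c("G1", "G2M") && e[ord[1]] >= t_specific &&
        all(e[ord[-1]] < t_mixed)) {
      group[i] <- top
    } else if (e[ord[1]] >= t_mixed && e[ord[2]] >= t_mixed) {
      pair <- sort(c(top, second))
      if (identical(pair, c("G1", "S")))
        group[i] <- if (top == "G1") "G1&S" else "S&G1"
      else if (identical(pair, c("G2M", "S")))
        group[i] <- "S&G2M"
      # G1-G2M is not adjacent in the cycle: stays undefined
    }
  }
  table$group <- factor(group, levels = CLUSTER_GROUPS)
  table
}

#' Compare a probe acquisition against a reference clustering
#'
#' The probe (e.g. a fluorescence-sorted aliquot) must have been assigned
#' with the *frozen* centroids of the reference sample; the stored model
#' fingerprints are checked to forbid silent refitting. Reports per-group
#' composition of both samples, per-cluster fold changes of the
#' size-normalized cluster occupancies, and the three clusters most
#' enriched in the probe.
#'
#' @param reference list with `combined` ([combine_clusters()]),
#'   `enrichment` (grouped [enrichment_table()]) and `fingerprints`
#'   (character vector of the channel models' fingerprints).
#' @param probe list with `combined` and `fingerprints` from assigning the
#'   probe events via [assign_clusters()] with the same models.
#' @param n_top how many top-enriched clusters to report.
#' @return Object of class `composition_report`: `groups` (data.frame of
#'   per-group fractions in reference and probe), `clusters` (per-cluster
#'   normalized sizes and fold change), `top_enriched` (cluster ids).
#' @export
compare_samples <- function(reference, probe, n_top = 3) {
  if (!identical(reference$fingerprints, probe$fingerprints))
    stop("model fingerprint mismatch: probe was not assigned with the ",
         "reference centroids")
  enr <- reference$enrichment
  stopifnot(inherits(enr, "enrichment_table"), "group" %in% names(enr))
  ids <- enr$cluster
  frac <- function(cmb) {
    n <- as.integer(table(factor(cmb$combined_id, levels = ids)))
    n / sum(n)
  }
  f_ref <- frac(reference$combined)
  f_probe <- frac(probe$combined)
  fold <- ifelse(f_ref > 0, f_probe / f_ref, NA)
  clusters <- data.frame(cluster = ids, group = enr$group,
                         f_reference = f_ref, f_probe = f_probe,
                         fold_change = fold)
  groups <- data.frame(
    group = levels(enr$group),
    f_reference = as.numeric(tapply(f_ref, enr$group, sum, default = 0)),
    f_probe = as.numeric(tapply(f_probe, enr$group, sum, default = 0)))
  eligible <- !enr$below_cutoff & !is.na(fold)
  top <- ids[eligible][order(fold[eligible], decreasing = TRUE)][
    seq_len(min(n_top, sum(eligible)))]
  structure(list(groups = groups, clusters = clusters, top_enriched = top),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("<composition_report>\n")
  print(x$groups, row.names = FALSE)
  cat("top enriched clusters:", paste(x$top_enriched, collapse = ", "), "\n")
  invisible(x)
}

#' Label-free cluster assignment from a cell-cycle-arrest time course
#'
#' With no staining available, clusters are mapped by their response to a
#' G2 arrest: clusters that grow in the sample taken right after release
#' (t = 0 h) relative to the untreated control are specific for `G2M`;
#' clusters that shrink are `G1&S`. Both samples must be assigned with the
#' same frozen centroids.
#'
#' @param control_sizes named per-cluster fractions in the control sample.
#' @param arrested_sizes named per-cluster fractions at t = 0 h after
#'   release.
#' @param ratio_threshold minimal fold change to call a cluster
#'   (`>= ratio_threshold` grows, `<= 1/ratio_threshold` shrinks).
#' @return `data.frame` with `cluster`, `ratio` and `assignment`
#'   (`G2M` / `G1&S` / `unassigned`).
#' @export
assign_by_arrest <- function(control_sizes, arrested_sizes,
                             ratio_threshold = 1.2) {
  stopifnot(length(control_sizes) == length(arrested_sizes),
            ratio_threshold > 1)
  ratio <- ifelse(control_sizes > 0, arrested_sizes / control_sizes, NA)
  assignment <- rep("unassigned", length(ratio))
  assignment[!is.na(ratio) & ratio >= ratio_threshold] <- "G2M"
  assignment[!is.na(ratio) & ratio <= 1 / ratio_threshold] <- "G1&S"
  n_zero <- sum(control_sizes == 0 & arrested_sizes > 0)
  if (n_zero > 0)
    message(n_zero, " cluster(s) absent from the control left unassigned")
  data.frame(cluster = seq_along(ratio) - 1L,
             ratio = as.numeric(ratio),
             assignment = assignment)
}

#' Per-time-point composition under an arrest-derived cluster map
#'
#' @param assignment result of [assign_by_arrest()].
#' @param sizes_by_time matrix of per-cluster fractions (clusters x time
#'   points).
#' @return `data.frame` with one row per time point: summed fractions of
#'   `G2M`- and `G1&S`-mapped clusters.
#' @export
arrest_composition <- function(assignment, sizes_by_time) {
  stopifnot(nrow(sizes_by_time) == nrow(assignment))
  data.frame(
    time = colnames(sizes_by_time) %||% as.character(seq_len(ncol(sizes_by_time))),
    f_G2M = colSums(sizes_by_time[assignment$assignment == "G2M", ,
                                  drop = FALSE]),
    f_G1S = colSums(sizes_by_time[assignment$assignment == "G1&S", ,
                                  drop = FALSE]),
    row.names = NULL)
}
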