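gated_cohort <- function() {
  fixture("gated_cohort", function() {
    sim <- simulate_cohort(n_events = 2000,
                           noise = noise_model(doublet_fraction = 0.10),
                           seed = 21)
    sim$events <- gate_phases(gate_singlets(sim$events))
    sim
  })
}

test_that("singlet gating removes doublets and keeps single cells", {
  sim <- gated_cohort()
  tr <- sim$truth
  ev <- sim$events
  # >= 90% of true doublets flagged out
  expect_gte(mean(!ev$singlet[tr$doublet]), 0.90)
  # >= 99% of true singlets retained
  expect_gte(mean(ev$singlet[!tr$doublet]), 0.99)

  nodbl <- small_cohort()   # doublet_fraction 0.02, but check the 0 case too
  ev0 <- gate_singlets(
    simulate_cohort(n_events = 400,
                    noise = noise_model(doublet_fraction = 0),
                    seed = 33)$events)
  expect_gte(mean(ev0$singlet), 0.99)

  expect_error(gate_singlets(data.frame(x = 1)), "PI-H")
})

test_that("phase gates reproduce ground-truth labels on singlets", {
  sim <- gated_cohort()
  keep <- sim$events$singlet & !sim$truth$doublet
  called <- sim$events$reference_phase[keep]
  truth <- sim$truth$phase[keep]
  expect_gte(mean(called == truth), 0.95)
  # wrong calls essentially absent; the remainder is 'unlabeled'
  expect_lte(mean(called != truth & called != "unlabeled"), 0.005)

  gates <- attr(sim$events, "gates")
  expect_lt(gates$pi_2n_window[2], gates$pi_4n_window[1]) # disjoint windows

  # BrdU precedence: a BrdU+ event with 4N DNA content is S
  ev <- sim$events
  fake <- ev[1, ]
  fake[["PI-A"]] <- mean(gates$pi_4n_window)
  fake[["FITC-H"]] <- gates$brdu_threshold * 10
  merged <- rbind(fake, ev[-1, ])
  merged$singlet <- TRUE
  relab <- gate_phases(merged, gate_config(
    pi_2n_window = gates$pi_2n_window, pi_4n_window = gates$pi_4n_window,
    brdu_threshold = gates$brdu_threshold))
  expect_identical(relab$reference_phase[1], "S")

  # between windows and BrdU-negative -> unlabeled
  fake[["PI-A"]] <- mean(c(gates$pi_2n_window[2], gates$pi_4n_window[1]))
  fake[["FITC-H"]] <- 1
  merged <- rbind(fake, ev[-1, ]); merged$singlet <- TRUE
  relab <- gate_phases(merged, gate_config(
    pi_2n_window = gates$pi_2n_window, pi_4n_window = gates$pi_4n_window,
    brdu_threshold = gates$brdu_threshold))
  expect_identical(relab$reference_phase[1], "unlabeled")

  expect_error(gate_phases(sim$events[, c("event_id", "PI-A", "FITC-H")]),
               "gate_singlets")
})

test_that("enrichment follows its definition and conservation identity", {
  # hand-built case: global mix (0.5, 0.3, 0.2)
  phases <- c(rep("G1", 500), rep("S", 300), rep("G2M", 200))
  ev <- data.frame(event_id = 1:1000, reference_phase = phases,
                   stringsAsFactors = FALSE)
  # cluster 0 = pure G1, cluster 1 = exactly the global mix, cluster 2 = rest
  cl <- rep(2L, 1000)
  cl[1:100] <- 0L
  cl[c(101:150, 501:530, 801:820)] <- 1L
  cmb <- combine_clusters(cl %/% 8L + 1L, cl %% 8L + 1L, 8, 8)
  enr <- enrichment_table(cmb, ev, size_cutoff_fraction = 0.005)

  r0 <- enr[enr$cluster == 0, ]
  expect_equal(c(r0$e_G1, r0$e_S, r0$e_G2M), c(2, 0, 0))
  r1 <- enr[enr$cluster == 1, ]
  expect_equal(c(r1$e_G1, r1$e_S, r1$e_G2M), c(1, 1, 1))

  # conservation: sum_p f_all(p) e(c, p) = 1 for every populated cluster
  f_all <- attr(enr, "f_all")
  pop <- enr[enr$n_labeled > 0, ]
  lhs <- as.matrix(pop[, c("e_G1", "e_S", "e_G2M")]) %*% f_all
  expect_equal(as.numeric(lhs), rep(1, nrow(pop)), tolerance = 1e-12)

  # cutoff: clusters under 0.5% of events are flagged
  expect_true(all(enr$below_cutoff[!(enr$cluster %in% c(0, 1, 2))]))
  expect_false(any(enr$below_cutoff[enr$cluster %in% c(0, 1, 2)]))
  expect_identical(sum(enr$n), 1000L)
})

test_that("six-group assignment follows the enrichment ranking rules", {
  mk <- function(e) {
    tab <- data.frame(cluster = 0L, label_A = 1L, label_B = 1L,
                      n = 100L, n_labeled = 100L,
                      f_G1 = 0, f_S = 0, f_G2M = 0,
                      e_G1 = e[1], e_S = e[2], e_G2M = e[3],
                      below_cutoff = FALSE)
    attr(tab, "f_all") <- c(1, 1, 1) / 3
    class(tab) <- c("enrichment_table", "data.frame")
    as.character(assign_groups(tab)$group[1])
  }
  expect_identical(mk(c(2.1, 0.4, 0.1)), "G1")
  expect_identical(mk(c(0.1, 0.4, 2.1)), "G2M")
  expect_identical(mk(c(1.3, 1.2, 0.2)), "G1&S")
  expect_identical(mk(c(1.2, 1.3, 0.2)), "S&G1")
  expect_identical(mk(c(0.2, 1.3, 1.2)), "S&G2M")
  expect_identical(mk(c(0.2, 1.2, 1.3)), "S&G2M")  # only S-G2M mixed group
  expect_identical(mk(c(1.0, 1.0, 1.0)), "undefined")
  # G1-G2M is not cell-cycle-adjacent: no mixed group
  expect_identical(mk(c(1.4, 0.1, 1.3)), "undefined")
  # specific call blocked when another phase is also enriched
  expect_identical(mk(c(1.8, 1.15, 0.1)), "G1&S")
})

test_that("label permutation destroys specific assignments", {
  sim <- gated_cohort()
  fit <- fixture("perm_fit", function() {
    s <- gated_cohort()
    run_fit(s$pulses, s$events, seed = 2)
  })
  n_specific <- sum(fit$enrichment$group %in% c("G1", "G2M"))
  expect_gt(n_specific, 0)

  # at least one real specific cluster is significantly enriched
  f_all <- attr(fit$enrichment, "f_all")
  signif_enrichment <- function(enr) {
    spec_rows <- which(enr$group %in% c("G1", "G2M"))
    vapply(spec_rows, function(i) {
      phase <- as.character(enr$group[i])
      k <- round(enr[[paste0("f_", phase)]][i] * enr$n_labeled[i])
      p0 <- f_all[match(phase, c("G1", "S", "G2M"))]
      stats::binom.test(k, enr$n_labeled[i], p0,
                        alternative = "greater")$p.value * 64
    }, numeric(1))
  }
  expect_true(any(signif_enrichment(fit$enrichment) < 0.05))

  # permuting the labels leaves no significant specific cluster
  set.seed(41)
  ev <- fit$events
  lab <- ev$reference_phase %in% c("G1", "S", "G2M")
  ev$reference_phase[lab] <- sample(ev$reference_phase[lab])
  enr_perm <- assign_groups(enrichment_table(fit$combined, ev))
  p_perm <- signif_enrichment(enr_perm)
  expect_true(length(p_perm) == 0 || all(p_perm > 0.05))
})

test_that("sorted-aliquot comparison: identity probes and fingerprints", {
  fit <- fixture("perm_fit", function() {
    s <- gated_cohort()
    run_fit(s$pulses, s$events, seed = 2)
  })
  ref <- list(combined = fit$combined, enrichment = fit$enrichment,
              fingerprints = fit$fingerprints)
  # probe = reference -> all defined fold changes are 1
  rep_id <- compare_samples(ref, list(combined = fit$combined,
                                      fingerprints = fit$fingerprints))
  fc <- rep_id$clusters$fold_change
  expect_equal(fc[!is.na(fc)], rep(1, sum(!is.na(fc))))
  expect_equal(sum(rep_id$groups$f_probe), 1)
  expect_equal(sum(rep_id$groups$f_reference), 1)

  # wrong model is refused
  expect_error(compare_samples(ref, list(combined = fit$combined,
                                         fingerprints = c("bogus", "x"))),
               "fingerprint")
})

test_that("arrest-response mapping classifies clusters by size fold change", {
  ctrl <- c(0.25, 0.25, 0.40, 0.10, 0)
  arr0 <- c(0.50, 0.23, 0.165, 0.10, 0.005)
  map <- assign_by_arrest(ctrl, arr0, ratio_threshold = 1.2)
  expect_identical(map$assignment,
                   c("G2M", "unassigned", "G1&S", "unassigned", "unassigned"))

  # identical samples -> nothing assigned
  same <- assign_by_arrest(ctrl, ctrl)
  expect_true(all(same$assignment == "unassigned"))

  # composition curves sum the mapped fractions
  sizes <- cbind(t0 = arr0, t1 = (arr0 + ctrl) / 2, t2 = ctrl)
  comp <- arrest_composition(map, sizes)
  expect_equal(comp$f_G2M, as.numeric(sizes[1, ]))
  expect_true(all(diff(comp$f_G2M) < 0))    # decays back toward control
})

test_that("arrest time course recovers the generator phase schedule", {
  # control fit; probes drawn with increasing G2M fraction reversed in time
  fit <- fixture("perm_fit", function() {
    s <- gated_cohort()
    run_fit(s$pulses, s$events, seed = 2)
  })
  mix <- function(w_g2m, seed) {
    cls <- default_cell_classes()
    w0 <- c(0.55, 0.35, 0.10)
    w <- w0 * (1 - w_g2m) / (1 - 0.10)
    w[3] <- w_g2m
    for (i in 1:3) cls[[i]]$mixture_weight <- w[i] / sum(w)
    simulate_cohort(cls, 800, seed = seed)$pulses
  }
  probes <- list(t0 = mix(0.85, 61), t2 = mix(0.45, 62), t5 = mix(0.15, 63))
  map <- run_transfer(fit, probes$t0, mode = "arrest")
  expect_gt(sum(map$assignment == "G2M"), 0)
  expect_gt(sum(map$assignment == "G1&S"), 0)
  sizes <- vapply(probes, function(p) {
    lab <- lapply(fit$channels, function(ch)
      assign_clusters(extract_features(p, ch, fit$models[[ch]]$level),
                      fit$models[[ch]]))
    cmb <- combine_clusters(lab[[1]], lab[[2]], 8, 8)
    n <- as.integer(table(factor(cmb$combined_id, levels = 0:63)))
    n / sum(n)
  }, numeric(64))
  comp <- arrest_composition(map, sizes)
  # G2M-mapped composition decays after release from arrest
  expect_true(all(diff(comp$f_G2M) < 0))
  expect_true(all(diff(comp$f_G1S) > 0))
})
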