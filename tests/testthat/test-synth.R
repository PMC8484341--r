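test_that("optical response profiles have the drawn geometry", {
  bm <- beam_model()
  # peak distance 2.5 us at 5 m/s -> lobe centers 12.5 um apart
  draw <- list(peak_distance = 2.5, amplitude_ratio = 1, lobe_fwhm = 0.7,
               dip_depth = 1, plateau = FALSE, diameter = 12, amp = 1)
  prof <- make_profile(draw, "FSCL", bm)
  x <- seq(-15, 15, by = 0.01)
  y <- prof(x)
  pk <- x[order(y, decreasing = TRUE)[1:2]]
  expect_equal(abs(diff(sort(pk))), 12.5, tolerance = 0.2)
  expect_equal(prof(x), prof(-x), tolerance = 1e-12)  # ratio 1: symmetric

  # dip 0: the bridge fills the gap to the lobe level, single envelope;
  # the two-lobe integral is preserved in the lobe component
  draw0 <- draw; draw0$dip_depth <- 0
  y0 <- make_profile(draw0, "FSCL", bm)(x)
  expect_gte(min(y0[abs(x) <= 4]), 0.8 * max(y0))  # no deep central dip left
  # while dip 1 retains a true two-peak structure
  expect_lt(min(y[abs(x) <= 4]) / max(y), 0.2)

  expect_error(make_profile(draw, "FL-PI", bm), "scatter channels")
})

test_that("beam convolution reproduces the transit response and is linear", {
  bm <- beam_model()   # 5.75 um / 5 m/s -> 1.15 us FWHM
  delta <- function(x) dnorm(x, 0, 0.01)
  pulse <- beam_convolve(delta, bm, support = c(-1, 1), resolution = 0.002)
  tt <- seq(-3, 3, by = 0.001)
  y <- pulse(tt)
  expect_equal(diff(range(tt[y >= max(y) / 2])), 1.15, tolerance = 0.01)

  # linearity in the profile
  twice <- beam_convolve(function(x) 2 * delta(x), bm,
                         support = c(-1, 1), resolution = 0.002)
  expect_equal(twice(tt), 2 * y, tolerance = 1e-10)

  # two deltas 3 us apart stay resolved at 3 us spacing
  pair <- function(x) dnorm(x, -7.5, 0.01) + dnorm(x, 7.5, 0.01)
  yp <- beam_convolve(pair, bm, support = c(-12, 12), resolution = 0.002)(tt)
  pk <- sort(tt[order(yp, decreasing = TRUE)[1:2]])
  # closed form: sum of two Gaussians 1.15 us FWHM at +/-1.5 us
  sig <- 1.15 / (2 * sqrt(2 * log(2)))
  expect_equal(yp / max(yp),
               {g <- exp(-(tt - 1.5)^2 / (2 * sig^2)) +
                     exp(-(tt + 1.5)^2 / (2 * sig^2)); g / max(g)},
               tolerance = 1e-3)
})

test_that("digitization clips, is deterministic, and keeps the baseline", {
  cfg <- acquisition_config()
  nz <- noise_model(baseline_level = 400, baseline_sd = 0)
  flat <- sample_and_digitize(function(t) rep(0, length(t)), nz, cfg)
  expect_identical(flat, rep(400L, 80))

  big <- sample_and_digitize(function(t) rep(1e6, length(t)), nz, cfg)
  expect_true(all(big == 65535L))

  noisy <- noise_model(baseline_sd = 5)
  a <- sample_and_digitize(function(t) 3000 * dnorm(t, 4, 0.5), noisy, cfg,
                           seed = 21)
  b <- sample_and_digitize(function(t) 3000 * dnorm(t, 4, 0.5), noisy, cfg,
                           seed = 21)
  expect_identical(a, b)
})

test_that("trigger alignment puts the SSC crossing at the trigger sample", {
  cfg <- acquisition_config()
  nz <- noise_model(baseline_sd = 0)
  ch <- matrix(400, 8, 160)
  ch[1, 36:70] <- 5000                      # crossing at raw index 36
  al <- trigger_align(ch, cfg, threshold = 1500, noise = nz)
  expect_identical(dim(al), c(8L, 80L))
  expect_identical(which(al[1, ] >= 1500)[1], 21L)  # 2 us at 10 MHz, 1-based

  # crossing already at the trigger point: window is copied unshifted
  ch2 <- matrix(400, 8, 160)
  ch2[1, 21:50] <- 5000
  al2 <- trigger_align(ch2, cfg, threshold = 1500, noise = nz)
  expect_identical(al2, ch2[, 1:80])

  # sub-threshold event is rejected
  expect_null(trigger_align(matrix(400, 8, 160), cfg, threshold = 1500,
                            noise = nz))
})

test_that("cohorts follow the class mixture and are seed-reproducible", {
  sim <- fixture("mix_cohort", function()
    simulate_cohort(n_events = 1000, seed = 3))
  counts <- table(factor(sim$truth$phase, c("G1", "S", "G2M")))
  # binomial 99% bounds around (550, 350, 100)
  expect_true(abs(counts[["G1"]] - 550) < 2.58 * sqrt(1000 * .55 * .45))
  expect_true(abs(counts[["S"]] - 350) < 2.58 * sqrt(1000 * .35 * .65))
  expect_true(abs(counts[["G2M"]] - 100) < 2.58 * sqrt(1000 * .10 * .90))

  again <- simulate_cohort(n_events = 1000, seed = 3)
  expect_identical(again$pulses$data, sim$pulses$data)
  expect_identical(again$events, sim$events)
  expect_identical(again$truth, sim$truth)

  expect_error(simulate_cohort(n_events = 0), "positive")
})

test_that("doublets carry summed PI area and stretched PI width", {
  sim <- fixture("dbl_cohort", function()
    simulate_cohort(n_events = 800,
                    noise = noise_model(doublet_fraction = 0.15), seed = 9))
  tr <- sim$truth
  expect_gt(sum(tr$doublet), 0)
  # additivity of the constituent PI areas, exact before measurement noise
  dbl <- tr[tr$doublet, ]
  got <- sim$events[["PI-A"]][tr$doublet]
  expect_equal(got, dbl$pi_component1 + dbl$pi_component2, tolerance = 1e-12)
  # doublet PI-W systematically larger than singlet PI-W
  expect_gt(min(sim$events[["PI-W"]][tr$doublet]),
            stats::quantile(sim$events[["PI-W"]][!tr$doublet], 0.9))

  none <- fixture("nodbl_cohort", function()
    simulate_cohort(n_events = 300,
                    noise = noise_model(doublet_fraction = 0), seed = 9))
  expect_false(any(none$truth$doublet))
})

test_that("noiseless peak detection recovers per-event peak distances", {
  s1 <- pure_cohort(1)
  m <- mapsfc:::channel_matrix(s1$pulses, "FSCL")
  pd <- apply(m, 1, estimate_peak_distance)
  err <- abs(pd - s1$truth$pd_FSCL)
  expect_lt(stats::quantile(err, 0.99, na.rm = TRUE), 0.1) # one sample period
  expect_lt(stats::median(err, na.rm = TRUE), 0.03)
})

test_that("mean G2M - G1 peak-distance offset matches the configured 0.5 us", {
  s1 <- pure_cohort(1)
  s3 <- pure_cohort(3, seed = 6)
  pd1 <- apply(mapsfc:::channel_matrix(s1$pulses, "FSCL"), 1,
               estimate_peak_distance)
  pd3 <- apply(mapsfc:::channel_matrix(s3$pulses, "FSCL"), 1,
               estimate_peak_distance)
  expect_equal(mean(pd3, na.rm = TRUE) - mean(pd1, na.rm = TRUE), 0.5,
               tolerance = 0.05)
})

test_that("generated cohorts are valid pulse datasets that survive psb I/O", {
  sim <- small_cohort()
  f <- withr::local_tempfile(fileext = ".psb")
  write_psb(sim$pulses, f)
  back <- read_psb(f)
  expect_identical(back$data, sim$pulses$data)
  expect_identical(back$event_ids, sim$pulses$event_ids)
})
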