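# Shared synthetic fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env))
    assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# small mixed cohort at the default study conditions
small_cohort <- function() {
  fixture("small_cohort", function()
    simulate_cohort(n_events = 500, seed = 7))
}

# single-class cohorts with low noise for parameter-recovery checks
pure_cohort <- function(class_index, n = 300, seed = 5, noise = NULL) {
  key <- paste0("pure_", class_index, "_", n, "_", seed)
  fixture(key, function() {
    cls <- default_cell_classes()[[class_index]]
    cls$mixture_weight <- 1
    if (is.null(noise))
      noise <- noise_model(baseline_sd = 2, doublet_fraction = 0)
    simulate_cohort(list(cls), n, noise = noise, seed = seed)
  })
}

random_pulse_dataset <- function(n_events = 4, seed = 99) {
  set.seed(seed)
  cfg <- acquisition_config()
  pulse_dataset(array(sample(0:65535, n_events * 8 * 80, replace = TRUE),
                      c(n_events, 8, 80)), cfg)
}
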