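# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 60 s noise-free, drift-free record (exact landmark work)
clean_record <- function() fixture("clean_record", function()
  synth_record(group_params(noise_sd = 0, drift_amp = 0), 60, 100, 0, 7))

# 60 s record at default (noisy) conditions
noisy_record <- function() fixture("noisy_record", function()
  synth_record(group_params(), 60, 100, 1, 11))

# small strongly-separated cohort for classifier tests
strong_cohort_small <- function() fixture("strong_cohort_small", function()
  synth_cohort(preset_cohort("strong", n_patients = 24,
                             event_prevalence = 0.5, duration = 30,
                             seed = 3)))

expect_segmentation_valid <- function(seg) {
  expect_true(all(seg$onsets < seg$peaks))
  expect_true(all(seg$peaks < seg$offsets))
  if (length(seg$onsets) > 1) {
    expect_true(all(diff(seg$onsets) > 0))
    expect_true(all(seg$offsets[-length(seg$offsets)] <=
                      seg$onsets[-1]))
  }
}
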