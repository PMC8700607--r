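# Shared fixtures. The full-scale default dataset and its derived objects
# are expensive, so they are memoised for the whole test run; smaller
# coarse-grid configurations are used where full chromatographic resolution
# adds nothing to the property under test.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_dataset <- function() {
  memoise_fixture("dataset", generate_dataset(run_config(), seed = 1))
}

default_features <- function(channel) {
  memoise_fixture(paste0("features_", channel),
                  dataset_features(default_dataset(), channel))
}

default_adulteration_report <- function() {
  memoise_fixture("adult", run_all_adulteration_studies(default_dataset(),
                                                        seed = 1))
}

# Coarse grid (0.05 min step, 501 points) for property tests where run time
# matters more than chromatographic resolution.
coarse_config <- function(...) {
  run_config(grid = default_grid(step = 0.05), ...)
}

# Noise-free single-peak template for analytic checks.
toy_template <- function(amp_cv = 0, rt_jitter_sd = 0) {
  class_template("black",
                 data.frame(rt_min = c(5, 11), width_min = c(0.3, 0.4),
                            amp_uv = c(2, 5), amp_fld = c(1, 3)),
                 amp_cv = amp_cv, rt_jitter_sd = rt_jitter_sd)
}

gauss_oracle <- function(grid, rt, width, amp) {
  out <- numeric(length(grid))
  for (k in seq_along(rt)) {
    out <- out + amp[k] * exp(-(grid - rt[k])^2 / (2 * width[k]^2))
  }
  out
}
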