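# Shared fixtures for the test suite. All randomness is seeded locally.

# a small configuration that runs the whole pipeline quickly
small_config <- function(seed = 1, n_rcs = 150, ...) {
  trial_config(n_rcs = n_rcs, seed = seed, ...)
}

# one complete vitals row (all components in their zero-point bands)
normal_vitals <- function(n = 1) {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    respiratory_rate = 16, spo2 = 98, on_oxygen = FALSE,
    systolic_bp = 120, pulse = 75, consciousness = "Alert",
    temperature = 37.0, stringsAsFactors = FALSE)
}

# independent transcription of the NEWS 2 chart, written as nested
# conditionals (deliberately a different representation from the banded
# lookup table shipped with the package)
oracle_news2 <- function(component, value) {
  switch(component,
    respiratory_rate =
      if (value <= 8) 3 else if (value <= 11) 1 else if (value <= 20) 0
      else if (value <= 24) 2 else 3,
    spo2 =
      if (value <= 91) 3 else if (value <= 93) 2 else if (value <= 95) 1 else 0,
    systolic_bp =
      if (value <= 90) 3 else if (value <= 100) 2 else if (value <= 110) 1
      else if (value <= 219) 0 else 3,
    pulse =
      if (value <= 40) 3 else if (value <= 50) 1 else if (value <= 90) 0
      else if (value <= 110) 1 else if (value <= 130) 2 else 3,
    temperature = {
      v <- round(value, 1)
      if (v <= 35.0) 3 else if (v <= 36.0) 1 else if (v <= 38.0) 0
      else if (v <= 39.0) 1 else 2
    },
    on_oxygen = if (isTRUE(value)) 2 else 0,
    consciousness = if (identical(value, "Alert")) 0 else 3,
    stop("unknown component"))
}

# simulate a trial and run a light analysis; used by several test files
quick_analysis <- function(seed = 1, m = 3, ...) {
  sim <- simulate_trial(small_config(seed = seed, ...))
  analyze_trial(sim, m = m, maxit = 3, engine = "pmm")
}
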