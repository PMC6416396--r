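# Shared fixtures, built in code. Heavier shared objects are memoized per
# test session.

.fixture_env <- new.env()

# The reference study conditions (576 segments, 7 modes, calibrated noise).
study_world <- function(seed = 1) {
  key <- paste0("world", seed)
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- default_world(seed = seed)
  .fixture_env[[key]]
}

study_template <- function(seed = 1) {
  key <- paste0("tmpl", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- initial_template(study_world(seed), wavelet_config(),
                                            seed = derive_seed(seed, "tmpl"))
  }
  .fixture_env[[key]]
}

# A small, fast world for structural tests.
tiny_world <- function(seed = 5, n_segments = 12, m_modes = 1, sigma = 0,
                       clutter_rate = 0) {
  tm <- sample_transmission_matrix(m_modes, n_segments, seed = seed)
  w <- pa_world(tm, absorber_spec(), transducer_spec(),
                noise_spec(sigma = sigma, clutter_rate = clutter_rate,
                           clutter_amp = if (clutter_rate > 0) 5 else 0))
  w
}

default_gate <- function(world) {
  ta <- world$absorbers[[1]]$arrival_time
  c(ta - 0.5e-6, ta + 0.5e-6)
}

# Noise-free total-intensity objective: the independent brute-force yardstick
# for GA oracle tests (no signal chain involved).
intensity_sum <- function(tm, mask) sum(speckle_intensities(tm, mask))
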