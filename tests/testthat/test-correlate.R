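# Normalized correlation, template gating and fitness.

test_that("ncc matches a brute-force evaluation and is affine invariant", {
  x <- with_seed(1, stats::rnorm(64))
  y <- with_seed(2, stats::rnorm(64))
  # independent brute force of the defining sum
  brute <- function(x, y) {
    num <- 0; dx <- 0; dy <- 0
    for (n in seq_along(x)) {
      num <- num + (x[n] - mean(x)) * (y[n] - mean(y))
      dx <- dx + (x[n] - mean(x))^2
      dy <- dy + (y[n] - mean(y))^2
    }
    num / sqrt(dx * dy)
  }
  expect_equal(ncc(x, y), brute(x, y), tolerance = 1e-12)
  expect_equal(ncc(x, y), stats::cor(x, y), tolerance = 1e-12)

  expect_equal(ncc(x, x), 1)
  expect_equal(ncc(x, -x + 3), -1)
  expect_equal(ncc(3 * x + 5, x), 1)
  expect_error(ncc(rep(1, 10), x[1:10]), "zero variance")
  expect_error(ncc(x, y[1:10]), "equal length")
})

test_that("detect accepts the template's own reference with gamma = 1", {
  w <- tiny_world(sigma = 0)
  cfg <- wavelet_config()
  tmpl <- initial_template(w, cfg, seed = 3)
  det <- detect(acquire(rep(1L, 12), w, seed = 1), tmpl, cfg)
  expect_equal(det$gamma, 1, tolerance = 1e-6)
  expect_true(det$accepted)
})

test_that("template replacement keeps threshold and window, discards the old reference", {
  w <- tiny_world(sigma = 0)
  cfg <- wavelet_config()
  tmpl <- initial_template(w, cfg, seed = 3)
  mask <- c(rep(1L, 6), rep(0L, 6))
  det <- detect(acquire(mask, w, seed = 2), tmpl, cfg)
  expect_true(det$accepted)
  up <- update_template(tmpl, det)
  expect_identical(up$threshold, tmpl$threshold)
  expect_identical(up$window, tmpl$window)
  expect_identical(up$reference$samples, det$denoised$samples)
  # replace-then-detect the same trace: gamma = 1
  det2 <- detect(acquire(mask, w, seed = 2), up, cfg)
  expect_equal(det2$gamma, 1, tolerance = 1e-9)

  fake <- det; fake$accepted <- FALSE
  expect_error(update_template(tmpl, fake), "rejected")
})

test_that("acceptance is monotone in the threshold", {
  w <- study_world()
  cfg <- wavelet_config()
  tmpl <- study_template()
  mask <- with_seed(77, as.integer(stats::runif(576) < 0.5))
  det <- detect(acquire(mask, w, seed = 8), tmpl, cfg)
  for (thr in c(0.2, 0.5, 0.7, 0.9, 0.99)) {
    t2 <- tmpl; t2$threshold <- thr
    d2 <- pafocus:::gate_denoised(det$denoised, t2)
    expect_identical(d2$accepted, d2$gamma >= thr)
  }
})

test_that("noise-free fitness equals the windowed peak-to-peak exactly", {
  w <- tiny_world(sigma = 0)
  cfg <- wavelet_config()
  tmpl <- initial_template(w, cfg, seed = 3)
  mask <- rep(1L, 12)
  ev <- fitness_single(mask, w, tmpl, cfg, n_acq = 5, seed = 1)
  tr <- acquire(mask, w, seed = 0)
  idx <- trace_time(tr) >= tmpl$window[1] & trace_time(tr) <= tmpl$window[2]
  direct <- max(tr$samples[idx]) - min(tr$samples[idx])
  expect_equal(ev$fitness, direct, tolerance = 1e-6)
  expect_equal(ev$n_accepted, 5L)
})

test_that("an all-zero mask yields zero fitness, not an error", {
  w <- tiny_world(sigma = 0)
  cfg <- wavelet_config()
  tmpl <- initial_template(w, cfg, seed = 3)
  ev <- fitness_single(rep(0L, 12), w, tmpl, cfg, n_acq = 5, seed = 1)
  expect_equal(ev$fitness, 0)
  expect_true(ev$none_accepted)
})

test_that("peak-to-peak is measured inside the gate", {
  # samples spanning [-1, 2] inside the gate -> peak-to-peak 3
  w <- tiny_world()
  tr <- pa_trace(numeric(2048), dt = w$dt, t0 = w$t0)
  gate <- default_gate(w)
  idx <- which(trace_time(tr) >= gate[1] & trace_time(tr) <= gate[2])
  tr$samples[idx[10]] <- 2
  tr$samples[idx[20]] <- -1
  tr$samples[1] <- 50  # clutter far outside the gate must not count
  ref <- synthesize_waveform(1, w$absorbers[[1]], w$transducer)
  tmpl <- pa_template(ref, threshold = 0.7, window = gate)
  det <- pafocus:::gate_denoised(tr, tmpl)
  expect_equal(det$peak_to_peak, 3)
})

test_that("two-point fitness is the geometric mean and demands disjoint gates", {
  sep_t <- 500e-6 / 1500
  ab1 <- absorber_spec(arrival_time = 21e-6, mu_a = 1)
  ab2 <- absorber_spec(arrival_time = 21e-6 + sep_t, mu_a = 1)
  tm <- sample_transmission_matrix(2, 16, seed = 4)
  w <- pa_world(tm, list(ab1, ab2), transducer_spec(), noise_spec())
  cfg <- wavelet_config()
  hw <- 0.16e-6
  g1 <- c(21e-6 - hw, 21e-6 + hw)
  g2 <- c(21e-6 + sep_t - hw, 21e-6 + sep_t + hw)
  ref <- denoise(acquire(rep(1L, 16), w, seed = 0), cfg)
  tm1 <- pa_template(ref, window = g1)
  tm2 <- pa_template(ref, window = g2)
  ev <- fitness_two_point(rep(1L, 16), w, list(tm1, tm2), cfg, n_acq = 2, seed = 1)
  expect_equal(ev$fitness, sqrt(ev$p[1] * ev$p[2]))
  expect_gt(ev$fitness, 0)

  bad <- pa_template(ref, window = c(21e-6 - hw, 21e-6 + sep_t))
  expect_error(fitness_two_point(rep(1L, 16), w, list(bad, tm2), cfg, seed = 1),
               "overlap")

  # gate separation: each gate responds to its own absorber's mu_a; the only
  # coupling is the few-percent spectral tail of the band-limited pulses
  w_boost1 <- w
  w_boost1$absorbers[[1]] <- absorber_spec(arrival_time = 21e-6, mu_a = 2)
  ev_b <- fitness_two_point(rep(1L, 16), w_boost1, list(tm1, tm2), cfg,
                            n_acq = 2, seed = 1)
  expect_equal(ev_b$p[1] / ev$p[1], 2, tolerance = 0.05)
  expect_equal(ev_b$p[2], ev$p[2], tolerance = 0.05)
})
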