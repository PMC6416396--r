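# Forward model: transmission-matrix statistics, speckle intensities,
# photoacoustic amplitude, pulse synthesis, noise and clutter.

test_that("transmission matrix sampling is seeded, shaped and circular-Gaussian", {
  a <- sample_transmission_matrix(1, 1, seed = 7)
  b <- sample_transmission_matrix(1, 1, seed = 7)
  expect_identical(a$entries, b$entries)

  m <- sample_transmission_matrix(3, 5, seed = 2)
  expect_equal(dim(m$entries), c(3L, 5L))

  # zero-mean circular Gaussian: component means within 3 sd of the estimator
  big <- sample_transmission_matrix(500, 1, seed = 11)
  tol <- 3 / sqrt(500) * sqrt(0.5)
  expect_lt(abs(mean(Re(big$entries))), tol)
  expect_lt(abs(mean(Im(big$entries))), tol)
  expect_equal(mean(Mod(big$entries)^2), 1, tolerance = 0.15)

  expect_error(sample_transmission_matrix(0, 5, seed = 1), "geometry")
})

test_that("speckle intensities are coherent sums of open segments", {
  tm <- sample_transmission_matrix(4, 6, seed = 3)
  expect_equal(speckle_intensities(tm, rep(0, 6)), rep(0, 4))

  one <- rep(0, 6); one[3] <- 1
  expect_equal(speckle_intensities(tm, one), Mod(tm$entries[, 3])^2)

  # two segments with identical entries add constructively to 4|t|^2
  tm2 <- tm
  tm2$entries[, 4] <- tm2$entries[, 3]
  two <- rep(0, 6); two[c(3, 4)] <- 1
  expect_equal(speckle_intensities(tm2, two), 4 * Mod(tm2$entries[, 3])^2)

  expect_error(speckle_intensities(tm, rep(1, 5)), "mask length")
  expect_error(speckle_intensities(tm, c(rep(1, 5), 2)), "binary")
})

test_that("per-mode intensity across matrix realizations is exponential with mean k", {
  # fixed mask with k open segments, across matrix realizations: intensity
  # of a mode is exponential with mean k (unit-variance entries)
  k <- 8
  mask <- c(rep(1, k), rep(0, 8))
  draws <- vapply(1:2000, function(i) {
    speckle_intensities(sample_transmission_matrix(1, 16, seed = i), mask)
  }, 0)
  expect_equal(mean(draws), k, tolerance = 0.1)
  ks <- suppressWarnings(stats::ks.test(draws, "pexp", rate = 1 / k))
  expect_gt(ks$p.value, 0.01)
})

test_that("all-on mask carries twice the expected intensity of random masks", {
  tm <- sample_transmission_matrix(40, 64, seed = 9)
  all_on <- mean(speckle_intensities(tm, rep(1, 64)))
  rnd <- with_seed(21, {
    mean(vapply(1:500, function(i) {
      mean(speckle_intensities(tm, as.integer(stats::runif(64) < 0.5)))
    }, 0))
  })
  expect_equal(all_on / rnd, 2, tolerance = 0.2)
})

test_that("pa_amplitude is the product of sensitivity, Grueneisen, mu_a and total fluence", {
  ab <- absorber_spec(grueneisen = 1, mu_a = 1)
  expect_equal(pa_amplitude(c(1, 1), ab, sensitivity = 1), 2)
  ab2 <- absorber_spec(grueneisen = 1, mu_a = 2)
  expect_equal(pa_amplitude(c(1, 1), ab2), 2 * pa_amplitude(c(1, 1), ab))
  ab3 <- absorber_spec(grueneisen = 0.2, mu_a = 0.5)
  expect_equal(pa_amplitude(c(4, 6), ab3), 1)
  expect_error(pa_amplitude(c(-1, 2), ab), "non-negative")
})

test_that("synthesized pulse peaks at 0.66 c_s / D_a and scales linearly", {
  ab <- absorber_spec(diameter = 150e-6)
  td <- transducer_spec()
  tr <- synthesize_waveform(1, ab, td, c_s = 1500, dt = 5e-9, n_samples = 2048)
  spec <- Mod(stats::fft(tr$samples))[1:1025]
  f <- (0:1024) / (2048 * 5e-9)
  f_peak <- f[which.max(spec)]
  expect_equal(f_peak, 6.6e6, tolerance = 0.1)

  expect_equal(synthesize_waveform(0, ab, td)$samples, numeric(2048))

  t1 <- synthesize_waveform(1, ab, td)
  t2 <- synthesize_waveform(2, ab, td)
  p2p <- function(x) max(x$samples) - min(x$samples)
  expect_equal(p2p(t2) / p2p(t1), 2, tolerance = 1e-9)

  # bipolar and (near) zero-mean
  expect_lt(abs(mean(t1$samples)) / max(abs(t1$samples)), 1e-6)
  expect_error(synthesize_waveform(1, ab, td, dt = 1e-7), "undersampled")
})

test_that("white noise honors sigma, the seed and the sigma = 0 identity", {
  tr <- pa_trace(numeric(10000), dt = 5e-9)
  expect_identical(add_noise(tr, noise_spec(sigma = 0), seed = 1), tr)
  n1 <- add_noise(tr, noise_spec(sigma = 1), seed = 4)
  n2 <- add_noise(tr, noise_spec(sigma = 1), seed = 4)
  expect_identical(n1$samples, n2$samples)
  expect_gt(stats::sd(n1$samples), 0.97)
  expect_lt(stats::sd(n1$samples), 1.03)
})

test_that("clutter bursts are in-band, move between acquisitions, and vanish at rate 0", {
  tr <- pa_trace(numeric(2048), dt = 5e-9, t0 = 16e-6)
  ns <- noise_spec(sigma = 0, clutter_rate = 0, clutter_amp = 1)
  expect_identical(add_clutter(tr, ns, seed = 1), tr)

  ns3 <- noise_spec(sigma = 0, clutter_rate = 3, clutter_amp = 1)
  c1 <- add_clutter(tr, ns3, seed = 100)
  c2 <- add_clutter(tr, ns3, seed = 101)
  expect_gt(max(abs(c1$samples)), 0)
  # burst positions differ across consecutive seeds
  expect_false(which.max(abs(c1$samples)) == which.max(abs(c2$samples)))

  # spectral peak of the clutter falls inside the transducer passband
  spec <- Mod(stats::fft(c1$samples))[1:1025]
  f <- (0:1024) / (2048 * 5e-9)
  fp <- f[which.max(spec)]
  expect_gt(fp, 2.5e6)
  expect_lt(fp, 7.5e6)
})

test_that("acquire composes pulses, noise and clutter deterministically", {
  w <- tiny_world(sigma = 0, clutter_rate = 0)
  mask <- rep(1L, 12)
  ints <- speckle_intensities(w$tm, mask)
  amp <- pa_amplitude(ints, w$absorbers[[1]])
  direct <- synthesize_waveform(amp, w$absorbers[[1]], w$transducer,
                                c_s = w$c_s, dt = w$dt, n_samples = w$n_samples,
                                t0 = w$t0)
  expect_equal(acquire(mask, w, seed = 1)$samples, direct$samples)

  expect_equal(acquire(rep(0L, 12), w, seed = 1)$samples, numeric(2048))

  # determinism, and clutter-seed independence of the signal+noise part
  wn <- tiny_world(sigma = 0.5, clutter_rate = 2)
  a1 <- acquire(mask, wn, seed = 42)
  a2 <- acquire(mask, wn, seed = 42)
  expect_identical(a1$samples, a2$samples)
})

test_that("two absorbers 500 um apart give pulses separated by 500 um / c_s", {
  sep_t <- 500e-6 / 1500
  ab1 <- absorber_spec(arrival_time = 21e-6)
  ab2 <- absorber_spec(arrival_time = 21e-6 + sep_t)
  tm <- sample_transmission_matrix(1, 8, seed = 2)
  w <- pa_world(tm, list(ab1, ab2), transducer_spec(), noise_spec())
  tr <- acquire(rep(1L, 8), w, seed = 1)
  tt <- trace_time(tr)
  # locate the two (positive) pulse peaks
  half <- tt < 21e-6 + sep_t / 2
  p1 <- tt[half][which.max(abs(tr$samples[half]))]
  p2 <- tt[!half][which.max(abs(tr$samples[!half]))]
  expect_equal(p2 - p1, sep_t, tolerance = 0.05)
})

test_that("calibrated default world puts the mean signal peak at 3.86 sigma", {
  # signal amplitude over noise level, random-mask ensemble: the noise sigma
  # of default_world() is calibrated so this mean is the 3.86 operating point
  w <- study_world()
  gate <- default_gate(w)
  wnf <- w
  wnf$noise <- noise_spec(sigma = 0, clutter_rate = 0)
  snrs <- vapply(1:60, function(i) {
    mask <- with_seed(3000 + i, as.integer(stats::runif(576) < 0.5))
    tr <- acquire(mask, wnf, seed = 4000 + i)
    snr(tr, w$noise$sigma, window = gate)
  }, 0)
  expect_equal(mean(snrs), 3.86, tolerance = 0.15)
})
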