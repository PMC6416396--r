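# Forward model: binary segment mask -> speckle intensities on the absorber
# -> photoacoustic source amplitude -> band-limited bipolar pressure pulse
# -> white noise + transient clutter. Stands in for the DMD / scatterer /
# transducer / oscilloscope chain of the physical experiment.

#' Absorber specification
#'
#' Describes one optical absorber (in the experiment, a black nylon thread
#' embedded in agarose). The photoacoustic source term is
#' `s = Gamma * mu_a * phi` with `phi` the local fluence, and the emitted
#' pulse has center frequency `0.66 * c_s / diameter`.
#'
#' @param grueneisen Grueneisen parameter (dimensionless, > 0).
#' @param mu_a Optical absorption coefficient (1/m, > 0).
#' @param diameter Absorber diameter D_a in meters (> 0).
#' @param arrival_time Acoustic time of flight to the transducer in seconds.
#' @param sensitivity Relative transducer gain at this absorber's position in
#'   the focal zone (dimensionless, default 1).
#' @return An `absorber_spec` list.
#' @export
absorber_spec <- function(grueneisen = 1, mu_a = 1, diameter = 150e-6,
                          arrival_time = 21e-6, sensitivity = 1) {
  for (nm in c("grueneisen", "mu_a", "diameter", "arrival_time", "sensitivity")) {
    stop_if_not_scalar_pos(get(nm), nm)
  }
  structure(list(grueneisen = grueneisen, mu_a = mu_a, diameter = diameter,
                 arrival_time = arrival_time, sensitivity = sensitivity),
            class = "absorber_spec")
}

#' Ultrasound transducer specification
#'
#' The transducer is modeled as a flat-top band-pass: unit response between
#' `center_freq * (1 -/+ fractional_bandwidth / 2)` with Gaussian skirts
#' (standard deviation `0.15 * center_freq`). A 5 MHz transducer with
#' fractional bandwidth 0.7 therefore passes 3.25--6.75 MHz, covering the
#' 6.6 MHz photoacoustic pulse of a 150 um absorber.
#'
#' @param center_freq Nominal center frequency f in Hz.
#' @param fractional_bandwidth Passband width as a fraction of `center_freq`
#'   (in (0, 2)).
#' @param focal_length Focal length F in meters, or `NULL` if unknown.
#' @param crystal_diameter Crystal diameter D in meters, or `NULL` if unknown.
#' @param sensitivity Overall relative gain (default 1).
#' @return A `transducer_spec` list.
#' @export
transducer_spec <- function(center_freq = 5e6, fractional_bandwidth = 0.7,
                            focal_length = NULL, crystal_diameter = NULL,
                            sensitivity = 1) {
  stop_if_not_scalar_pos(center_freq, "center_freq")
  stop_if_not_scalar_pos(sensitivity, "sensitivity")
  if (!(fractional_bandwidth > 0 && fractional_bandwidth < 2)) {
    stop("'fractional_bandwidth' must lie in (0, 2)", call. = FALSE)
  }
  if (!is.null(focal_length)) stop_if_not_scalar_pos(focal_length, "focal_length")
  if (!is.null(crystal_diameter)) stop_if_not_scalar_pos(crystal_diameter, "crystal_diameter")
  structure(list(center_freq = center_freq,
                 fractional_bandwidth = fractional_bandwidth,
                 focal_length = focal_length, crystal_diameter = crystal_diameter,
                 sensitivity = sensitivity),
            class = "transducer_spec")
}

#' Noise specification
#'
#' White Gaussian oscilloscope noise of level `sigma` (the `sigma * omega`
#' term of the measurement model `h = s + sigma * omega`, `omega ~ N(0,1)`)
#' plus transient clutter: a Poisson number of short band-limited bursts per
#' acquisition, at uniformly random record positions, sharing the
#' photoacoustic frequency band (so simple band-pass filtering cannot remove
#' them).
#'
#' @param sigma White-noise standard deviation (pressure units, >= 0).
#' @param clutter_rate Expected number of clutter bursts per acquisition (>= 0).
#' @param clutter_amp Peak-amplitude scale of a clutter burst.
#' @param clutter_cycles Burst length in carrier cycles (default 8).
#' @param seed Optional integer recorded with the spec.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sigma = 0, clutter_rate = 0, clutter_amp = 0,
                       clutter_cycles = 8, seed = NULL) {
  stop_if_not_scalar_pos(sigma, "sigma", allow_zero = TRUE)
  stop_if_not_scalar_pos(clutter_rate, "clutter_rate", allow_zero = TRUE)
  stop_if_not_scalar_pos(clutter_amp, "clutter_amp", allow_zero = TRUE)
  stop_if_not_scalar_pos(clutter_cycles, "clutter_cycles")
  structure(list(sigma = sigma, clutter_rate = clutter_rate,
                 clutter_amp = clutter_amp, clutter_cycles = clutter_cycles,
                 seed = seed),
            class = "noise_spec")
}

#' Sample a speckle transmission matrix
#'
#' Draws the complex coupling from `n_segments` controllable input segments
#' (the DMD) to `m_modes` independent speckle modes on the absorber. Entries
#' are i.i.d. circular complex Gaussian with zero mean and unit variance --
#' the fully developed speckle regime, under which the binary-amplitude
#' enhancement theory `(1/2 + (N-1)/(2*pi)) / M` holds.
#'
#' @param m_modes Number of output modes (rows, >= 1).
#' @param n_segments Number of input segments (columns, >= 1).
#' @param seed Integer seed; the same seed reproduces identical entries.
#' @return A `pa_tmatrix` with fields `entries` (complex matrix), `m_modes`,
#'   `n_segments`, `seed`.
#' @examples
#' tm <- sample_transmission_matrix(7, 576, seed = 1)
#' dim(tm$entries)
#' @export
sample_transmission_matrix <- function(m_modes, n_segments, seed) {
  if (!(is.numeric(m_modes) && m_modes >= 1) ||
      !(is.numeric(n_segments) && n_segments >= 1)) {
    stop("invalid geometry: 'm_modes' and 'n_segments' must be >= 1", call. = FALSE)
  }
  m_modes <- as.integer(m_modes); n_segments <- as.integer(n_segments)
  entries <- with_seed(seed, {
    matrix(complex(real = rnorm(m_modes * n_segments, sd = sqrt(0.5)),
                   imaginary = rnorm(m_modes * n_segments, sd = sqrt(0.5))),
           nrow = m_modes, ncol = n_segments)
  })
  structure(list(entries = entries, m_modes = m_modes,
                 n_segments = n_segments, seed = as.integer(seed)),
            class = "pa_tmatrix")
}

#' @export
print.pa_tmatrix <- function(x, ...) {
  cat(sprintf("<pa_tmatrix> %d modes x %d segments, seed %d\n",
              x$m_modes, x$n_segments, x$seed))
  invisible(x)
}

as_mask <- function(mask, n_segments = NULL) {
  mask <- as.integer(mask)
  if (anyNA(mask) || !all(mask %in% c(0L, 1L))) {
    stop("a mask must be a binary 0/1 vector", call. = FALSE)
  }
  if (!is.null(n_segments) && length(mask) != n_segments) {
    stop(sprintf("mask length %d does not match the %d segments of the transmission matrix",
                 length(mask), n_segments), call. = FALSE)
  }
  mask
}

#' Speckle intensities on the absorber under a binary mask
#'
#' Mode `m` receives the coherent sum of the open segments:
#' `I_m = |sum_n t_mn * b_n|^2`. These intensities realize the fluence the
#' absorber integrates.
#'
#' @param tm A `pa_tmatrix`.
#' @param mask Binary 0/1 vector of length `n_segments`.
#' @return Numeric vector of `m_modes` non-negative intensities.
#' @export
speckle_intensities <- function(tm, mask) {
  stopifnot(inherits(tm, "pa_tmatrix"))
  mask <- as_mask(mask, tm$n_segments)
  field <- tm$entries %*% mask
  as.double(Mod(field)^2)
}

#' Photoacoustic source amplitude
#'
#' Evaluates `sensitivity * Gamma * mu_a * sum(I)`: the source pressure is
#' linear in the Grueneisen parameter, the absorption coefficient and the
#' total fluence the absorber intercepts.
#'
#' @param intensities Non-negative speckle intensities (from
#'   [speckle_intensities()]).
#' @param absorber An [absorber_spec()].
#' @param sensitivity Relative transducer gain; defaults to the absorber's
#'   own `sensitivity` field.
#' @return Scalar source amplitude (pressure units).
#' @export
pa_amplitude <- function(intensities, absorber, sensitivity = absorber$sensitivity) {
  stopifnot(inherits(absorber, "absorber_spec"))
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  sensitivity * absorber$grueneisen * absorber$mu_a * sum(intensities)
}

# Frequency response of the flat-top transducer passband on the FFT grid of
# an n-sample record with step dt.
transducer_response <- function(transducer, n, dt) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * dt)
  fa <- abs(f)
  fc <- transducer$center_freq
  f1 <- fc * (1 - transducer$fractional_bandwidth / 2)
  f2 <- fc * (1 + transducer$fractional_bandwidth / 2)
  skirt <- 0.15 * fc
  h <- numeric(n) + 1
  lo <- fa < f1; hi <- fa > f2
  h[lo] <- exp(-((fa[lo] - f1) / skirt)^2 / 2)
  h[hi] <- exp(-((fa[hi] - f2) / skirt)^2 / 2)
  h
}

# Cache of unit-amplitude pulse waveforms keyed by their defining parameters;
# synthesis inside the optimizer loop then reduces to a scale.
.pulse_cache <- new.env(parent = emptyenv())

unit_pulse <- function(absorber, transducer, c_s, dt, n_samples, t0) {
  args <- c(absorber$diameter, absorber$arrival_time,
            transducer$center_freq, transducer$fractional_bandwidth,
            c_s, dt, n_samples, t0)
  # fast path: the optimizer re-requests the same pulse tens of thousands
  # of times per run
  if (!is.null(.pulse_cache$last_args) && identical(args, .pulse_cache$last_args)) {
    return(.pulse_cache$last_pulse)
  }
  key <- paste(sprintf("%a", args), collapse = "|")
  hit <- .pulse_cache[[key]]
  if (!is.null(hit)) {
    .pulse_cache$last_args <- args
    .pulse_cache$last_pulse <- hit
    return(hit)
  }
  f0 <- 0.66 * c_s / absorber$diameter
  if (dt >= 1 / (4 * f0)) {
    stop(sprintf("undersampled: dt = %.3g s is too coarse for a %.3g Hz pulse (need dt < %.3g s)",
                 dt, f0, 1 / (4 * f0)), call. = FALSE)
  }
  t <- t0 + (0:(n_samples - 1)) * dt
  tau <- 1 / (2 * pi * f0)
  # N-shaped (bipolar, zero-mean) pulse: derivative of a Gaussian whose
  # magnitude spectrum peaks exactly at f0, then transducer band-limiting.
  p <- -(t - absorber$arrival_time) / tau * exp(-(t - absorber$arrival_time)^2 / (2 * tau^2))
  h <- transducer_response(transducer, n_samples, dt)
  p <- Re(stats::fft(stats::fft(p) * h, inverse = TRUE)) / n_samples
  pk <- max(abs(p))
  if (pk > 0) p <- p / pk  # unit peak: SNR = amplitude / sigma by construction
  .pulse_cache[[key]] <- p
  .pulse_cache$last_args <- args
  .pulse_cache$last_pulse <- p
  p
}

#' Synthesize the photoacoustic pressure pulse
#'
#' Generates a bipolar (N-shaped, zero-mean) pulse centered at the
#' absorber's acoustic arrival time. The pulse's magnitude spectrum peaks at
#' the size-determined center frequency `0.66 * c_s / D_a` and is
#' band-limited by the transducer passband. The trace is normalized so its
#' peak absolute value equals `amplitude` (peak-to-peak is proportional to
#' `amplitude`; zero amplitude gives the all-zero trace).
#'
#' @param amplitude Source amplitude (>= 0), e.g. from [pa_amplitude()].
#' @param absorber An [absorber_spec()].
#' @param transducer A [transducer_spec()].
#' @param c_s Speed of sound in the coupling medium (m/s; default 1500,
#'   water).
#' @param dt Sampling interval in seconds; must satisfy `dt < 1/(4 f0)`.
#' @param n_samples Record length.
#' @param t0 Time of the first sample (seconds).
#' @return A [pa_trace].
#' @examples
#' tr <- synthesize_waveform(1, absorber_spec(), transducer_spec(),
#'                           dt = 5e-9, n_samples = 2048, t0 = 16e-6)
#' @export
synthesize_waveform <- function(amplitude, absorber, transducer, c_s = 1500,
                                dt = 5e-9, n_samples = 2048, t0 = 16e-6) {
  stopifnot(inherits(absorber, "absorber_spec"), inherits(transducer, "transducer_spec"))
  stop_if_not_scalar_pos(amplitude, "amplitude", allow_zero = TRUE)
  p <- unit_pulse(absorber, transducer, c_s, dt, n_samples, t0)
  pa_trace(amplitude * p, dt = dt, t0 = t0)
}

#' Add white Gaussian noise to a trace
#'
#' Implements the `sigma * omega` term of the measurement model: adds i.i.d.
#' `N(0, sigma^2)` draws to every sample. `sigma = 0` returns the input
#' unchanged; the output is deterministic given `seed`.
#'
#' @param trace A [pa_trace].
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return A [pa_trace].
#' @export
add_noise <- function(trace, noise, seed = noise$seed) {
  stopifnot(inherits(trace, "pa_trace"), inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(trace)
  w <- with_seed(seed, stats::rnorm(length(trace$samples), sd = noise$sigma))
  pa_trace(trace$samples + w, dt = trace$dt, t0 = trace$t0)
}

#' Superimpose transient clutter bursts
#'
#' Adds a Poisson(`clutter_rate`) number of Gaussian-windowed tone bursts at
#' uniformly random positions within the record. Each burst's carrier
#' frequency is drawn uniformly inside the transducer passband, so the
#' clutter occupies the same frequency band as the photoacoustic signal and
#' appears at different positions on every acquisition -- the regime in
#' which frequency-domain filtering fails and correlation gating is needed.
#'
#' @param trace A [pa_trace].
#' @param noise A [noise_spec()]; `clutter_rate = 0` returns the input
#'   unchanged.
#' @param seed Integer seed.
#' @param transducer A [transducer_spec()] defining the clutter band.
#' @return A [pa_trace].
#' @export
add_clutter <- function(trace, noise, seed = noise$seed,
                        transducer = transducer_spec()) {
  stopifnot(inherits(trace, "pa_trace"), inherits(noise, "noise_spec"))
  if (noise$clutter_rate == 0 || noise$clutter_amp == 0) return(trace)
  tt <- trace_time(trace)
  y <- with_seed(seed, {
    k <- stats::rpois(1, noise$clutter_rate)
    out <- trace$samples
    if (k > 0) {
      fc <- transducer$center_freq
      bw <- transducer$fractional_bandwidth
      for (i in seq_len(k)) {
        f_b <- stats::runif(1, fc * (1 - bw / 2), fc * (1 + bw / 2))
        t_c <- stats::runif(1, min(tt), max(tt))
        amp <- noise$clutter_amp * stats::runif(1, 0.5, 1.5)
        dur <- noise$clutter_cycles / f_b       # burst length in seconds
        env <- exp(-((tt - t_c) / (dur / 2))^2 / 2)
        out <- out + amp * env * sin(2 * pi * f_b * (tt - t_c) + stats::runif(1, 0, 2 * pi))
      }
    }
    out
  })
  pa_trace(y, dt = trace$dt, t0 = trace$t0)
}

#' Assemble a simulated experiment ("world")
#'
#' Bundles the transmission matrix, absorbers, transducer, noise model and
#' the acquisition grid into one object consumed by [acquire()],
#' [fitness_single()] and [run_ga()].
#'
#' @param tm A `pa_tmatrix`.
#' @param absorbers A single [absorber_spec()] or a list of them.
#' @param transducer A [transducer_spec()].
#' @param noise A [noise_spec()].
#' @param c_s Speed of sound (m/s).
#' @param dt Sampling interval (s).
#' @param n_samples Record length.
#' @param t0 Time of the first sample (s).
#' @return A `pa_world` list.
#' @export
pa_world <- function(tm, absorbers, transducer = transducer_spec(),
                     noise = noise_spec(), c_s = 1500, dt = 5e-9,
                     n_samples = 2048, t0 = 16e-6) {
  stopifnot(inherits(tm, "pa_tmatrix"))
  if (inherits(absorbers, "absorber_spec")) absorbers <- list(absorbers)
  stopifnot(length(absorbers) >= 1L,
            all(vapply(absorbers, inherits, TRUE, "absorber_spec")),
            inherits(transducer, "transducer_spec"), inherits(noise, "noise_spec"))
  structure(list(tm = tm, absorbers = absorbers, transducer = transducer,
                 noise = noise, c_s = c_s, dt = dt,
                 n_samples = as.integer(n_samples), t0 = t0),
            class = "pa_world")
}

#' White-noise level that fixes the pre-denoising SNR of random masks
#'
#' Calibrates the noise to the *realized* medium, the way an experiment
#' measures its operating SNR. For the world's transmission matrix, the
#' mask-averaged total intensity under Bernoulli(1/2) masks is (exactly)
#' `sum_m ( |sum_n t_mn / 2|^2 + sum_n |t_mn|^2 / 4 )` -- the mean-field
#' power of each mode plus its incoherent half-variance -- whose ensemble
#' expectation is `M * N / 2` but which fluctuates appreciably between
#' media through the mean-field term. The returned sigma makes the realized
#' mean peak-amplitude-to-noise ratio equal `target_snr` (the synthesized
#' pulse has unit peak per unit amplitude).
#'
#' @param world A [pa_world()] (its first absorber is used).
#' @param target_snr Desired mean pre-denoising SNR (default 3.86).
#' @return The white-noise sigma.
#' @export
calibrate_sigma <- function(world, target_snr = 3.86) {
  stopifnot(inherits(world, "pa_world"))
  ab <- world$absorbers[[1]]
  ab$sensitivity * ab$grueneisen * ab$mu_a * mean_mask_intensity(world$tm) /
    target_snr
}

# Exact mask-average of the total intensity for a fixed transmission matrix.
mean_mask_intensity <- function(tm) {
  mu <- rowSums(tm$entries) / 2
  sum(Mod(mu)^2) + sum(Mod(tm$entries)^2) / 4
}

#' Default simulated experiment
#'
#' The reference study conditions: a 32 x 18 = 576-segment DMD, 7
#' independent speckle modes on a 150 um absorber, a 5 MHz transducer with
#' fractional bandwidth 1, water coupling (1500 m/s), 2048 samples at 5 ns
#' starting at 16 us with acoustic arrival at 21 us, white noise calibrated
#' so random masks yield a mean pre-denoising SNR of 3.86, and on average
#' one in-band clutter burst per acquisition with amplitude comparable to
#' the mean pulse peak.
#'
#' @param seed Master seed for the transmission matrix.
#' @param n_segments,m_modes Geometry (defaults 576 and 7).
#' @param snr_pre Pre-denoising SNR the white noise is calibrated to.
#' @param clutter_rate Expected clutter bursts per acquisition.
#' @return A [pa_world()].
#' @export
default_world <- function(seed = 1, n_segments = 576, m_modes = 7,
                          snr_pre = 3.86, clutter_rate = 1) {
  tm <- sample_transmission_matrix(m_modes, n_segments, seed = derive_seed(seed, "tmatrix"))
  ab <- absorber_spec()
  w <- pa_world(tm, ab, transducer_spec(), noise_spec())
  mean_peak <- ab$sensitivity * ab$grueneisen * ab$mu_a * mean_mask_intensity(tm)
  w$noise <- noise_spec(sigma = mean_peak / snr_pre,
                        clutter_rate = clutter_rate,
                        clutter_amp = mean_peak)
  w
}

#' Acquire one simulated oscilloscope shot
#'
#' Composes the full forward model for one binary mask: per-absorber speckle
#' intensities, source amplitudes, synthesized pulses at their respective
#' arrival times, then white noise and clutter. Deterministic given `seed`;
#' the noise and clutter streams are derived from it independently, so
#' changing only the clutter sub-seed changes only the clutter.
#'
#' @param mask Binary 0/1 vector over the segments.
#' @param world A [pa_world()].
#' @param seed Integer seed for this acquisition.
#' @return A [pa_trace].
#' @export
acquire <- function(mask, world, seed = 0L) {
  stopifnot(inherits(world, "pa_world"))
  mask <- as_mask(mask, world$tm$n_segments)
  ints <- speckle_intensities(world$tm, mask)
  y <- numeric(world$n_samples)
  for (ab in world$absorbers) {
    amp <- pa_amplitude(ints, ab)
    tr <- synthesize_waveform(amp, ab, world$transducer, c_s = world$c_s,
                              dt = world$dt, n_samples = world$n_samples,
                              t0 = world$t0)
    y <- y + tr$samples
  }
  out <- pa_trace(y, dt = world$dt, t0 = world$t0)
  out <- add_noise(out, world$noise, seed = derive_seed(seed, "noise"))
  add_clutter(out, world$noise, seed = derive_seed(seed, "clutter"),
              transducer = world$transducer)
}
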