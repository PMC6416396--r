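# Closed-form theory: binary-amplitude enhancement, transducer focal
# geometry, speckle mode counting, photoacoustic center frequency, SNR.

#' Theoretical binary-amplitude enhancement
#'
#' For N controllable segments and M independent optical modes within the
#' acoustic focal region, the expected enhancement of the optimized over the
#' random-mask photoacoustic amplitude is
#' `eta = (1/2 + (N - 1)/(2*pi)) / M`, commonly approximated as
#' `N / (2*pi*M)`.
#'
#' @param n_segments N, number of controllable segments (>= 1).
#' @param m_modes M, number of independent modes (> 0, may be fractional).
#' @return A list with `exact` and `approx` values of eta.
#' @examples
#' enhancement_theory(576, 7.47)$approx  # ~ 12.27
#' @export
enhancement_theory <- function(n_segments, m_modes) {
  stopifnot(n_segments >= 1)
  if (!(is.numeric(m_modes) && m_modes > 0)) {
    stop("'m_modes' must be > 0", call. = FALSE)
  }
  list(exact = (0.5 + (n_segments - 1) / (2 * pi)) / m_modes,
       approx = n_segments / (2 * pi * m_modes))
}

#' Transducer geometry
#'
#' Collects the geometric and acoustic parameters entering the focal-zone
#' formulas. The focal diameter `phi` can be given directly (when the focal
#' length and crystal diameter are not known) or derived via
#' [focal_diameter()].
#'
#' @param c_s Speed of sound (m/s, default 1500, water).
#' @param transducer_freq Transducer frequency f (Hz).
#' @param focal_length Focal length F (m), optional.
#' @param crystal_diameter Crystal diameter D (m), optional.
#' @param focal_diameter Focal diameter phi (m), direct entry (default 880e-6).
#' @param absorber_diameter Absorber diameter D_a (m, default 150e-6).
#' @param speckle_diameter Speckle grain diameter at the target (m, default
#'   150e-6).
#' @return A `geometry_spec` list.
#' @export
geometry_spec <- function(c_s = 1500, transducer_freq = 5e6,
                          focal_length = NULL, crystal_diameter = NULL,
                          focal_diameter = 880e-6, absorber_diameter = 150e-6,
                          speckle_diameter = 150e-6) {
  for (nm in c("c_s", "transducer_freq", "focal_diameter",
               "absorber_diameter", "speckle_diameter")) {
    stop_if_not_scalar_pos(get(nm), nm)
  }
  if (!is.null(focal_length)) stop_if_not_scalar_pos(focal_length, "focal_length")
  if (!is.null(crystal_diameter)) stop_if_not_scalar_pos(crystal_diameter, "crystal_diameter")
  structure(list(c_s = c_s, transducer_freq = transducer_freq,
                 focal_length = focal_length, crystal_diameter = crystal_diameter,
                 focal_diameter = focal_diameter,
                 absorber_diameter = absorber_diameter,
                 speckle_diameter = speckle_diameter),
            class = "geometry_spec")
}

#' Transducer focal diameter
#'
#' `phi = c_s * F / (f * D)`: the -6 dB focal-zone width of a focused
#' single-element transducer.
#'
#' @param g A [geometry_spec()] with `focal_length` and `crystal_diameter`
#'   present.
#' @return The focal diameter in meters.
#' @examples
#' g <- geometry_spec(focal_length = 30e-3, crystal_diameter = 10.227e-3)
#' focal_diameter(g) * 1e6  # ~ 880 um
#' @export
focal_diameter <- function(g) {
  stopifnot(inherits(g, "geometry_spec"))
  if (is.null(g$focal_length) || is.null(g$crystal_diameter)) {
    stop("focal_length and crystal_diameter are required; alternatively supply ",
         "'focal_diameter' directly in geometry_spec()", call. = FALSE)
  }
  g$c_s * g$focal_length / (g$transducer_freq * g$crystal_diameter)
}

#' Number of independent optical modes in the focal zone
#'
#' The absorbing area seen by the transducer is `D_a * phi` (absorber
#' diameter times focal diameter); dividing by the area of one speckle
#' grain, `pi * (d_sp / 2)^2`, gives the mode count
#' `M = D_a * phi / (pi * (d_sp/2)^2)`. M may be fractional.
#'
#' @param g A [geometry_spec()].
#' @return The mode count M.
#' @examples
#' mode_count(geometry_spec())  # ~ 7.47
#' @export
mode_count <- function(g) {
  stopifnot(inherits(g, "geometry_spec"))
  g$absorber_diameter * g$focal_diameter / (pi * (g$speckle_diameter / 2)^2)
}

#' Photoacoustic center frequency of a spherical-ish absorber
#'
#' `f = 0.66 * c_s / D_a`: a 150 um absorber in water emits around 6.6 MHz.
#'
#' @param c_s Speed of sound (m/s).
#' @param d_a Absorber diameter (m).
#' @return The center frequency in Hz.
#' @examples
#' center_frequency(1500, 150e-6) / 1e6  # 6.6 MHz
#' @export
center_frequency <- function(c_s, d_a) {
  stop_if_not_scalar_pos(c_s, "c_s")
  stop_if_not_scalar_pos(d_a, "d_a")
  0.66 * c_s / d_a
}

#' Signal-to-noise ratio of a trace
#'
#' The ratio of the peak absolute amplitude (inside an optional gate) to a
#' reference noise standard deviation, the latter measured from a
#' signal-free (laser-off) record. `statistic = "p2p_half"` uses half the
#' gated peak-to-peak instead of the peak.
#'
#' @param trace A [pa_trace].
#' @param noise_std Reference noise standard deviation (> 0).
#' @param window Optional `(start, end)` gate in seconds.
#' @param statistic `"peak"` (default) or `"p2p_half"`.
#' @return The SNR.
#' @export
snr <- function(trace, noise_std, window = NULL,
                statistic = c("peak", "p2p_half")) {
  stopifnot(inherits(trace, "pa_trace"))
  statistic <- match.arg(statistic)
  if (!(is.numeric(noise_std) && length(noise_std) == 1L && noise_std > 0)) {
    stop("'noise_std' must be > 0: SNR is undefined without a noise reference",
         call. = FALSE)
  }
  y <- if (is.null(window)) trace$samples else trace$samples[window_index(trace, window)]
  a <- if (statistic == "peak") max(abs(y)) else (max(y) - min(y)) / 2
  a / noise_std
}

#' Measured enhancement
#'
#' Ratio of the optimized fitness to a baseline fitness (the random-mask
#' ensemble mean; see [random_mask_baseline()]).
#'
#' @param best Optimized fitness.
#' @param baseline Baseline fitness (> 0).
#' @return `best / baseline`.
#' @export
enhancement_measured <- function(best, baseline) {
  if (!(is.numeric(baseline) && length(baseline) == 1L && baseline > 0)) {
    stop("'baseline' must be > 0", call. = FALSE)
  }
  best / baseline
}
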