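# Correlation gating: decide whether a denoised acquisition is a
# photoacoustic signal by its normalized correlation with an adaptive
# template, and turn accepted acquisitions into the optimizer's
# peak-to-peak fitness.

#' Detection template
#'
#' Holds the reference photoacoustic waveform (a denoised trace), the
#' acceptance threshold on the normalized correlation coefficient (default
#' 0.7: genuine photoacoustic signals correlate above 0.8 with each other,
#' clutter and noise below 0.4), the time gate around the expected acoustic
#' arrival, and the lag tolerance of the correlation search.
#'
#' @param reference A denoised [pa_trace].
#' @param threshold Acceptance threshold in `[-1, 1]` (default 0.7).
#' @param window Length-2 numeric `(start, end)` in seconds; must lie inside
#'   the reference's time span.
#' @param lag_tolerance Maximum absolute lag (seconds) scanned when
#'   correlating, absorbing residual sampling jitter; default 20 ns (four
#'   samples at the default grid). Acquisitions are laser-trigger
#'   time-locked, so a wide search is unnecessary and would let in-band
#'   clutter phase-align with the reference.
#' @return A `pa_template`.
#' @export
pa_template <- function(reference, threshold = 0.7, window,
                        lag_tolerance = 2e-8) {
  stopifnot(inherits(reference, "pa_trace"))
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold >= -1 && threshold <= 1)) {
    stop("'threshold' must lie in [-1, 1]", call. = FALSE)
  }
  tt <- trace_time(reference)
  if (!(length(window) == 2L && window[1] < window[2] &&
        window[1] >= tt[1] && window[2] <= tt[length(tt)])) {
    stop("'window' must be (start, end) inside the reference trace span", call. = FALSE)
  }
  stop_if_not_scalar_pos(lag_tolerance, "lag_tolerance", allow_zero = TRUE)
  structure(list(reference = reference, threshold = threshold,
                 window = as.double(window), lag_tolerance = lag_tolerance),
            class = "pa_template")
}

#' Normalized correlation coefficient
#'
#' The zero-mean, unit-variance inner product of two equal-length windows:
#' `sum((x - mean(x)) * (y - mean(y)))` divided by the square root of the
#' product of the two centered sums of squares. Always in `[-1, 1]`, equal
#' to 1 for an exact (positive affine) waveform match.
#'
#' @param x,y Equal-length numeric windows, neither constant.
#' @return The correlation coefficient.
#' @examples
#' ncc(sin(1:50), 3 * sin(1:50) + 5)
#' @export
ncc <- function(x, y) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y) || length(x) < 2L) {
    stop("'x' and 'y' must have equal length >= 2", call. = FALSE)
  }
  cx <- x - mean(x); cy <- y - mean(y)
  sx <- sum(cx^2); sy <- sum(cy^2)
  if (sx == 0 || sy == 0) {
    stop("zero variance: correlation is undefined for a constant window", call. = FALSE)
  }
  sum(cx * cy) / sqrt(sx * sy)
}

# Max ncc of y against x over integer lags -max_lag..max_lag (y shifted).
ncc_max_lag <- function(x, y, max_lag) {
  n <- length(y)
  best <- -Inf
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      g <- ncc(x[1:(n - lag)], y[(1 + lag):n])
    } else {
      g <- ncc(x[(1 - lag):n], y[1:(n + lag)])
    }
    if (g > best) best <- g
  }
  best
}

#' Gate a trace against a template
#'
#' Denoises the acquisition, extracts the template's time gate, and computes
#' the normalized correlation coefficient against the template reference,
#' maximized over lags within the template's lag tolerance. The acquisition
#' is accepted iff the correlation reaches the threshold. The peak-to-peak
#' value is measured inside the gate only, so clutter elsewhere in the
#' record cannot inflate the fitness.
#'
#' @param trace The raw acquired [pa_trace].
#' @param template A [pa_template()].
#' @param cfg A [wavelet_config()] used for denoising.
#' @return A `detection_result` list: `gamma`, `accepted`, `peak_to_peak`,
#'   and the `denoised` trace (for template replacement).
#' @export
detect <- function(trace, template, cfg = wavelet_config()) {
  stopifnot(inherits(trace, "pa_trace"), inherits(template, "pa_template"))
  gate_denoised(denoise(trace, cfg), template)
}

# Gating of an already-denoised trace (detect() minus the wavelet pass).
gate_denoised <- function(dn, template) {
  idx <- window_index(dn, template$window)
  ref_idx <- window_index(template$reference, template$window)
  x <- template$reference$samples[ref_idx]
  y <- dn$samples[idx]
  n <- min(length(x), length(y))
  x <- x[1:n]; y <- y[1:n]
  max_lag <- as.integer(floor(template$lag_tolerance / dn$dt))
  max_lag <- min(max_lag, n - 2L)
  gamma <- ncc_max_lag(x, y, max_lag)
  structure(list(gamma = gamma,
                 accepted = gamma >= template$threshold,
                 peak_to_peak = max(y) - min(y),
                 denoised = dn),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection> gamma = %.4f, %s, peak-to-peak = %.4g\n",
              x$gamma, if (x$accepted) "accepted" else "rejected", x$peak_to_peak))
  invisible(x)
}

#' Replace the template reference with an accepted signal
#'
#' As the optimization raises the signal amplitude, the waveform drifts
#' slightly; replacing the template with each accepted (denoised)
#' acquisition keeps the gate matched to the current signal. The threshold,
#' gate window and lag tolerance are unchanged; the previous reference is
#' discarded.
#'
#' @param template A [pa_template()].
#' @param accepted The accepted denoised [pa_trace] (e.g. `detect(...)$denoised`
#'   of an accepted acquisition).
#' @return The updated [pa_template()].
#' @export
update_template <- function(template, accepted) {
  stopifnot(inherits(template, "pa_template"))
  if (inherits(accepted, "detection_result")) {
    if (!accepted$accepted) stop("cannot update the template from a rejected acquisition",
                                 call. = FALSE)
    accepted <- accepted$denoised
  }
  stopifnot(inherits(accepted, "pa_trace"))
  pa_template(accepted, threshold = template$threshold, window = template$window,
              lag_tolerance = template$lag_tolerance)
}

#' Acquire the initial template with the all-on mask
#'
#' Mirrors the experimental start of the feedback loop: the reference
#' waveform is measured with every segment open (strong signal), at elevated
#' averaging, then denoised.
#'
#' @param world A [pa_world()].
#' @param cfg A [wavelet_config()].
#' @param window Time gate `(start, end)`; defaults to +/- 0.5 us around the
#'   first absorber's arrival time.
#' @param n_avg Number of averaged all-on acquisitions (default 16).
#' @param seed Integer seed.
#' @param threshold Acceptance threshold (default 0.7).
#' @param lag_tolerance Lag search tolerance in seconds.
#' @return A [pa_template()].
#' @export
initial_template <- function(world, cfg = wavelet_config(), window = NULL,
                             n_avg = 16, seed = 0L, threshold = 0.7,
                             lag_tolerance = 2e-8) {
  stopifnot(inherits(world, "pa_world"))
  if (is.null(window)) {
    ta <- world$absorbers[[1]]$arrival_time
    window <- c(ta - 0.5e-6, ta + 0.5e-6)
  }
  mask <- rep(1L, world$tm$n_segments)
  acc <- numeric(world$n_samples)
  for (i in seq_len(n_avg)) {
    acc <- acc + acquire(mask, world, seed = derive_seed(seed, "template", i))$samples
  }
  ref <- denoise(pa_trace(acc / n_avg, dt = world$dt, t0 = world$t0), cfg)
  pa_template(ref, threshold = threshold, window = window,
              lag_tolerance = lag_tolerance)
}

# One gated acquisition with degenerate windows treated as rejections
# (an all-zero noise-free trace carries no signal, not an error).
detect_or_reject <- function(trace, template, cfg) {
  dn <- denoise(trace, cfg)
  idx <- window_index(dn, template$window)
  y <- dn$samples[idx]
  if (max(y) == min(y) ||
      {
        ref <- template$reference$samples[window_index(template$reference, template$window)]
        max(ref) == min(ref)
      }) {
    return(structure(list(gamma = NA_real_, accepted = FALSE,
                          peak_to_peak = max(y) - min(y), denoised = dn),
                     class = "detection_result"))
  }
  gate_denoised(dn, template)
}

#' Fitness of a mask: accepted-average peak-to-peak
#'
#' Performs `n_acq` seeded acquisitions under the mask, gates each one, and
#' averages the gated peak-to-peak over the accepted acquisitions only
#' (rejected shots -- clutter hits, noise -- are ignored). If no acquisition
#' is accepted, the fitness is 0 and the result is flagged. The template is
#' replaced by the last accepted acquisition.
#'
#' @param mask Binary mask over the segments.
#' @param world A [pa_world()].
#' @param template A [pa_template()].
#' @param cfg A [wavelet_config()].
#' @param n_acq Acquisitions per mask (default 5).
#' @param seed Integer seed for this evaluation.
#' @return A list: `fitness` (average peak-to-peak, 0 if none accepted),
#'   `n_accepted`, `gammas`, `template` (possibly updated),
#'   `none_accepted` flag.
#' @export
fitness_single <- function(mask, world, template, cfg = wavelet_config(),
                           n_acq = 5, seed = 0L) {
  stopifnot(n_acq >= 1)
  gammas <- numeric(n_acq)
  p2ps <- numeric(n_acq)
  accepted <- logical(n_acq)
  for (i in seq_len(n_acq)) {
    tr <- acquire(mask, world, seed = derive_seed(seed, "acq", i))
    det <- detect_or_reject(tr, template, cfg)
    gammas[i] <- det$gamma
    p2ps[i] <- det$peak_to_peak
    accepted[i] <- det$accepted
    if (det$accepted) template <- update_template(template, det$denoised)
  }
  n_acc <- sum(accepted)
  list(fitness = if (n_acc > 0) mean(p2ps[accepted]) else 0,
       n_accepted = n_acc, gammas = gammas, p2ps = p2ps, accepted = accepted,
       template = template, none_accepted = n_acc == 0L)
}

#' Two-point fitness: geometric mean of per-gate peak-to-peak values
#'
#' For simultaneous two-point focusing the fitness is the square root of
#' the product of the two absorbers' accepted-average peak-to-peak values,
#' each measured in its own (disjoint) time gate with its own template.
#'
#' @param mask Binary mask.
#' @param world A [pa_world()] with two absorbers.
#' @param templates List of two [pa_template()]s with disjoint windows.
#' @param cfg A [wavelet_config()].
#' @param n_acq Acquisitions per mask.
#' @param seed Integer seed.
#' @return A list: `fitness` = `sqrt(P1 * P2)`, per-gate values `p`,
#'   updated `templates`.
#' @export
fitness_two_point <- function(mask, world, templates, cfg = wavelet_config(),
                              n_acq = 5, seed = 0L) {
  stopifnot(length(templates) == 2L,
            all(vapply(templates, inherits, TRUE, "pa_template")))
  w1 <- templates[[1]]$window; w2 <- templates[[2]]$window
  if (max(w1[1], w2[1]) < min(w1[2], w2[2])) {
    stop("the two gate windows overlap: peak-to-peak attribution is ambiguous",
         call. = FALSE)
  }
  p <- numeric(2)
  for (g in 1:2) {
    p2p <- numeric(0)
    for (i in seq_len(n_acq)) {
      tr <- acquire(mask, world, seed = derive_seed(seed, "acq", i))
      det <- detect_or_reject(tr, templates[[g]], cfg)
      if (det$accepted) {
        p2p <- c(p2p, det$peak_to_peak)
        templates[[g]] <- update_template(templates[[g]], det$denoised)
      }
    }
    p[g] <- if (length(p2p) > 0) mean(p2p) else 0
  }
  list(fitness = sqrt(p[1] * p[2]), p = p, templates = templates)
}
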