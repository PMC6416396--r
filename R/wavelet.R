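# Discrete wavelet transform and VisuShrink denoising. The transform is the
# periodized (circular) orthogonal DWT, so Parseval holds exactly and
# reconstruction is perfect to machine precision; orthogonality is what the
# universal-threshold theory assumes. Index tables per (length, filter
# length) are cached because the optimizer denoises tens of thousands of
# traces per run.

.dwt_cache <- new.env(parent = emptyenv())

dwt_indices <- function(n, L) {
  key <- paste(n, L, sep = "x")
  hit <- .dwt_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- 0:(n %/% 2L - 1L)
  # column j holds the circular indices (2k + L/2 - j) mod n, 1-based
  idx <- matrix(0L, nrow = n %/% 2L, ncol = L)
  for (j in 0:(L - 1L)) idx[, j + 1L] <- ((2L * k + L %/% 2L - j) %% n) + 1L
  .dwt_cache[[key]] <- idx
  idx
}

dwt_single <- function(x, filt) {
  n <- length(x)
  L <- length(filt$dec_lo)
  idx <- dwt_indices(n, L)
  a <- numeric(n %/% 2L)
  d <- numeric(n %/% 2L)
  for (j in seq_len(L)) {
    xi <- x[idx[, j]]
    a <- a + filt$dec_lo[j] * xi
    d <- d + filt$dec_hi[j] * xi
  }
  list(a = a, d = d)
}

idwt_single <- function(a, d, filt) {
  n <- 2L * length(a)
  L <- length(filt$dec_lo)
  idx <- dwt_indices(n, L)
  x <- numeric(n)
  for (j in seq_len(L)) {
    p <- idx[, j]
    x[p] <- x[p] + filt$dec_lo[j] * a + filt$dec_hi[j] * d
  }
  x
}

#' Wavelet denoising configuration
#'
#' Defaults follow the study recipe: fourth-order Daubechies mother wavelet,
#' eight decomposition levels, soft (VisuShrink) thresholding of the detail
#' coefficients at the universal threshold `K = sigma_hat * sqrt(2 log M)`,
#' with the noise level estimated by the median absolute deviation of the
#' finest-level detail coefficients.
#'
#' @param mother Mother wavelet name (see [wavelet_filter()]).
#' @param levels Decomposition depth (>= 1). Capped at the maximum depth the
#'   record length supports, with a warning.
#' @param threshold_mode `"soft"` (shrink toward zero by K) or `"hard"`
#'   (zero out coefficients below K).
#' @param log_base Base of the logarithm in the universal threshold
#'   (default natural log, Donoho-Johnstone's formulation).
#' @return A `wavelet_config` list.
#' @export
wavelet_config <- function(mother = "db4", levels = 8,
                           threshold_mode = c("soft", "hard"),
                           log_base = exp(1)) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(is.numeric(levels), length(levels) == 1L, levels >= 1)
  stop_if_not_scalar_pos(log_base, "log_base")
  wavelet_filter(mother)  # validate the name early
  structure(list(mother = mother, levels = as.integer(levels),
                 threshold_mode = threshold_mode, log_base = log_base),
            class = "wavelet_config")
}

# Deepest decomposition the length allows: each level halves an even length.
max_dwt_levels <- function(n) {
  lv <- 0L
  while (n %% 2L == 0L && n >= 4L) { n <- n %/% 2L; lv <- lv + 1L }
  lv
}

effective_levels <- function(n, levels, warn = TRUE) {
  mx <- max_dwt_levels(n)
  if (mx < 1L) stop(sprintf("record length %d cannot be decomposed (need an even length >= 4)", n),
                    call. = FALSE)
  if (levels > mx) {
    if (warn) warning(sprintf("requested %d levels exceeds the maximum %d for length %d; using %d",
                              levels, mx, n, mx), call. = FALSE)
    mx
  } else levels
}

#' Multilevel periodized DWT
#'
#' @param x Numeric vector (length divisible by `2^levels`).
#' @param cfg A [wavelet_config()].
#' @return A list with the level-`levels` approximation `a` and a list
#'   `det` of detail coefficient vectors, finest (level 1) first.
#' @export
dwt_forward <- function(x, cfg = wavelet_config()) {
  stopifnot(inherits(cfg, "wavelet_config"))
  filt <- wavelet_filter(cfg$mother)
  levels <- effective_levels(length(x), cfg$levels)
  det <- vector("list", levels)
  a <- as.double(x)
  for (l in seq_len(levels)) {
    w <- dwt_single(a, filt)
    a <- w$a
    det[[l]] <- w$d
  }
  list(a = a, det = det, mother = cfg$mother)
}

#' Inverse multilevel periodized DWT
#'
#' @param dec A decomposition from [dwt_forward()].
#' @return The reconstructed numeric vector.
#' @export
dwt_inverse <- function(dec) {
  filt <- wavelet_filter(dec$mother)
  a <- dec$a
  for (l in rev(seq_along(dec$det))) a <- idwt_single(a, dec$det[[l]], filt)
  a
}

#' Estimate the white-noise level of a trace
#'
#' Robust estimator used throughout VisuShrink practice: the median absolute
#' deviation of the finest-level detail coefficients divided by 0.6745. The
#' photoacoustic pulse is sparse and band-limited well below the finest
#' detail band, so it barely perturbs the estimate.
#'
#' @param trace A [pa_trace] or numeric vector.
#' @param cfg A [wavelet_config()] naming the mother wavelet.
#' @return The estimated noise standard deviation (>= 0).
#' @export
estimate_sigma <- function(trace, cfg = wavelet_config()) {
  x <- if (inherits(trace, "pa_trace")) trace$samples else as.double(trace)
  filt <- wavelet_filter(cfg$mother)
  if (length(x) < 2L * length(filt$dec_lo)) {
    stop(sprintf("trace too short for noise estimation: need at least %d samples",
                 2L * length(filt$dec_lo)), call. = FALSE)
  }
  d1 <- dwt_single(x, filt)$d
  stats::median(abs(d1)) / 0.6745
}

#' Universal (VisuShrink) threshold
#'
#' `K = sigma * sqrt(2 log M)` with `M` the signal length: for white
#' Gaussian noise, the largest of M i.i.d. coefficients is below K with
#' probability tending to one, so thresholding at K suppresses essentially
#' all noise coefficients.
#'
#' @param sigma Noise level (>= 0).
#' @param m_len Signal length (>= 1).
#' @param log_base Base of the logarithm (default natural).
#' @return The threshold K.
#' @examples
#' universal_threshold(2, 1024)
#' @export
universal_threshold <- function(sigma, m_len, log_base = exp(1)) {
  stop_if_not_scalar_pos(sigma, "sigma", allow_zero = TRUE)
  if (!(is.numeric(m_len) && length(m_len) == 1L && m_len >= 1)) {
    stop("'m_len' must be a single value >= 1", call. = FALSE)
  }
  sigma * sqrt(2 * log(m_len, base = log_base))
}

threshold_coeffs <- function(w, K, mode) {
  if (mode == "soft") sign(w) * pmax(abs(w) - K, 0) else w * (abs(w) > K)
}

#' Wavelet-denoise a trace
#'
#' Decomposes the trace to `cfg$levels` with the configured mother wavelet,
#' applies the universal threshold (computed from the trace's own estimated
#' noise level) to every detail level with the configured soft/hard rule,
#' leaves the approximation coefficients untouched, and reconstructs. The
#' output preserves length, `dt` and `t0`.
#'
#' @param trace A [pa_trace].
#' @param cfg A [wavelet_config()].
#' @return The denoised [pa_trace].
#' @examples
#' tr <- pa_trace(rnorm(512), dt = 5e-9)
#' dn <- denoise(tr, wavelet_config(levels = 6))
#' sd(dn$samples) < sd(tr$samples)
#' @export
denoise <- function(trace, cfg = wavelet_config()) {
  stopifnot(inherits(trace, "pa_trace"), inherits(cfg, "wavelet_config"))
  dec <- dwt_forward(trace$samples, cfg)
  sig <- stats::median(abs(dec$det[[1]])) / 0.6745
  K <- universal_threshold(sig, length(trace$samples), cfg$log_base)
  if (K > 0) dec$det <- lapply(dec$det, threshold_coeffs, K = K, mode = cfg$threshold_mode)
  pa_trace(dwt_inverse(dec), dt = trace$dt, t0 = trace$t0)
}
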