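# Synthetic speckle-plane image: the CCD analogue of the focus photographs.
# Purely a visualization artifact -- the optimizer's feedback is acoustic.

#' Render a synthetic speckle-plane intensity image
#'
#' Produces a fully developed speckle image for a given mask: a complex
#' background field (one independent white-noise field per segment, summed
#' over the open segments, then low-pass filtered to the grain size), plus,
#' inside a central target disc, grains driven by the actual transmission-
#' matrix mode amplitudes, so the optimized mask visibly brightens the
#' target region.
#'
#' @param tm A `pa_tmatrix` (its mode fields light the target disc).
#' @param mask Binary mask over the segments.
#' @param side Image side length in pixels (default 64).
#' @param grain_px Speckle grain diameter in pixels (default 5).
#' @param target_radius_px Radius of the target disc (default `2 * grain_px`).
#' @param seed Integer seed for the background fields; the same seed gives
#'   the same medium, so before/after images are comparable.
#' @return A `side x side` non-negative intensity matrix.
#' @export
speckle_image <- function(tm, mask, side = 64, grain_px = 5,
                          target_radius_px = 2 * grain_px, seed = 0L) {
  stopifnot(inherits(tm, "pa_tmatrix"))
  mask <- as_mask(mask, tm$n_segments)
  n_px <- side * side
  field <- with_seed(seed, {
    # background: sum of per-segment white complex fields over open segments;
    # drawing per segment keeps the image deterministic in (seed, mask)
    acc <- complex(real = numeric(n_px), imaginary = numeric(n_px))
    for (j in which(mask == 1L)) {
      blk <- with_seed(derive_seed(seed, "seg", j), {
        complex(real = stats::rnorm(n_px, sd = sqrt(0.5)),
                imaginary = stats::rnorm(n_px, sd = sqrt(0.5)))
      })
      acc <- acc + blk
    }
    acc
  })
  f2d <- matrix(field, side, side)
  # low-pass to the grain size: grain diameter ~ side / (2 * f_cut)
  fx <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  r2 <- outer(fx^2, fx^2, "+")
  f_cut <- 1 / (2 * grain_px)
  H <- exp(-r2 / (2 * (f_cut / 2)^2))
  sm <- stats::fft(stats::fft(f2d) * H, inverse = TRUE) / n_px
  img <- Mod(sm)^2
  # target disc: grains driven by the world's mode amplitudes
  amps <- tm$entries %*% mask
  ctr <- (side + 1) / 2
  ang <- 2 * pi * (seq_len(tm$m_modes) - 1) / max(tm$m_modes, 1)
  rad <- if (tm$m_modes > 1) target_radius_px * 0.6 else 0
  xg <- ctr + rad * cos(ang)
  yg <- ctr + rad * sin(ang)
  xs <- matrix(rep(seq_len(side), side), side)
  ys <- t(xs)
  scale <- mean(img) / max(mean(Mod(amps)^2), .Machine$double.eps) *
    max(tm$n_segments, 1) / max(sum(mask), 1)
  for (m in seq_len(tm$m_modes)) {
    blob <- exp(-((xs - xg[m])^2 + (ys - yg[m])^2) / (2 * (grain_px / 2.355)^2))
    img <- img + scale * Mod(amps[m])^2 * blob
  }
  img
}

#' Write an intensity image as a single-channel TIFF
#'
#' Intensities are scaled to `[0, 1]` by the image maximum before writing.
#'
#' @param img Non-negative intensity matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_speckle_tiff <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0))
  mx <- max(img)
  if (mx > 0) img <- img / mx
  tiff::writeTIFF(img, path)
  invisible(path)
}
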