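# Internal helpers: seeded RNG hygiene and deterministic seed derivation.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a child seed from a master seed
#'
#' Every random element of a run (transmission matrix, per-acquisition noise,
#' clutter positions, GA operators) draws its seed deterministically from one
#' master seed so that a whole experiment replays bit-identically. The
#' derivation mixes the master seed, a purpose label and an index through a
#' multiplicative hash and always returns a non-negative integer below 2^31.
#'
#' @param master Integer master seed.
#' @param purpose Character label naming the consumer (e.g. `"noise"`).
#' @param index Integer index for repeated consumers (default 0).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @examples
#' derive_seed(1, "noise", 3)
#' @export
derive_seed <- function(master, purpose = "", index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L)
  m <- 2147483647
  # every intermediate product stays below 2^53 so double arithmetic is exact
  h <- abs(as.double(master)) %% m
  for (c in utf8ToInt(as.character(purpose))) h <- (h * 31 + c) %% m
  h <- (h + (abs(as.double(index)) %% m) * 97 + 17) %% m
  h <- (h * 48271) %% m  # two Lehmer steps decorrelate nearby inputs
  h <- (h * 48271) %% m
  as.integer(h)
}

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0)
  if (!ok) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (allow_zero) "non-negative" else "positive"), call. = FALSE)
  }
  invisible(x)
}
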