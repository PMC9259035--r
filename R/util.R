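# Shared constants and small helpers.

# Kymograph distance calibration: one pixel in nanometres.
KYMO_PIXEL_NM <- 72.2

#' Derive a reproducible child seed from a master seed
#'
#' Stages of the pipeline (simulation, rendering, per-trajectory noise) each
#' receive their own seed derived deterministically from the master seed and a
#' stage label or index, so any stage can be rerun in isolation. The result
#' always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param key integer index or character label identifying the stage.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1, is.finite(master))
  h <- if (is.character(key)) sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) else as.numeric(key)
  s <- (abs(master) %% 2147483647) * 48271 + h * 69621 + 1
  as.integer(s %% 2147483629 + 1)
}

# Evaluate a piecewise-linear path (data.frame t0, x0, slope in um/s) at
# arbitrary times. Segments must be sorted by t0 with t0[1] <= min(times).
piecewise_eval <- function(segs, times) {
  i <- findInterval(times, segs$t0)
  i[i < 1L] <- 1L
  segs$x0[i] + segs$slope[i] * (times - segs$t0[i])
}

# Label (any vector column `col`) of the active piecewise segment at `times`.
piecewise_label <- function(segs, times, col) {
  i <- findInterval(times, segs$t0)
  i[i < 1L] <- 1L
  segs[[col]][i]
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) <= 1) return(0)
  stats::sd(x) / sqrt(length(x))
}
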