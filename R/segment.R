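#' Resolution-based pause threshold
#'
#' The minimum detectable movement rate given the kymograph geometry: one
#' distance pixel of displacement over a time window, converted to nm/min.
#' With 72.2 nm pixels and a 10-frame window at 5 s/frame this is
#' 72.2 nm / 50 s = 86.64 nm/min (conventionally quoted as 86.7 nm/min; the
#' unrounded value is used internally).
#' Slopes below the threshold are classified as paused; slopes at or above
#' it count as movement.
#'
#' @param pixel_nm distance pixel size (nm).
#' @param window_frames number of frames in the slope window.
#' @param frame_interval s per frame.
#' @return threshold in nm/min.
#' @examples
#' threshold_nm_per_min(72.2, 10, 5)   # 86.64
#' @export
threshold_nm_per_min <- function(pixel_nm, window_frames, frame_interval) {
  stopifnot(pixel_nm > 0, window_frames > 0, frame_interval > 0)
  pixel_nm / (window_frames * frame_interval) * 60
}

# least-squares slope of y over x (same length); returns 0 for < 2 points
ls_slope <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  mx <- mean(x); my <- mean(y)
  den <- sum((x - mx)^2)
  if (den <= 0) return(0)
  sum((x - mx) * (y - my)) / den
}

# segment velocity: least-squares slope over the segment interior (the first
# and last frame straddle the changepoints and carry partial displacement)
# Segment velocity: median of the rolling window slopes evaluated inside the
# segment (windows clipped to the segment). Robust against the partial
# displacement of the frames straddling the changepoints and against
# sub-resolution dwells buried inside a segment, mimicking how a slope is
# read off a kymograph along the steep stretch of a run. Falls back to the
# plain least-squares slope for segments not much longer than the window.
seg_velocity <- function(x, y, a, b, w = 10L) {
  n <- b - a + 1L
  if (n < w + 4L) {
    k <- if (n >= 6L) 1L else 0L
    return(ls_slope(x[(a + k):(b - k)], y[(a + k):(b - k)]))
  }
  stats::median(rolling_slope(x[a:b], y[a:b], w))
}

ls_sse <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  b <- ls_slope(x, y)
  r <- (y - mean(y)) - b * (x - mean(x))
  sum(r^2)
}

# centered rolling least-squares slope over `w` frames, truncated windows at
# the region ends; x in minutes, y in um -> slope um/min
rolling_slope <- function(x, y, w) {
  n <- length(x)
  h1 <- floor(w / 2); h2 <- w - h1 - 1L
  vapply(seq_len(n), function(i) {
    a <- max(1L, i - h1); b <- min(n, i + h2)
    ls_slope(x[a:b], y[a:b])
  }, numeric(1))
}

# collapse a per-frame label vector into a segment table (1-based, inclusive)
labels_to_segments <- function(labels) {
  r <- rle(labels)
  e <- cumsum(r$lengths)
  s <- c(1L, utils::head(e, -1) + 1L)
  data.frame(start = s, end = e, state = r$values, stringsAsFactors = FALSE)
}

merge_same <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  keep <- c(TRUE, seg$state[-1] != seg$state[-nrow(seg)])
  idx <- which(keep)
  data.frame(start = seg$start[idx],
             end = seg$end[c(idx[-1] - 1L, nrow(seg))],
             state = seg$state[idx], stringsAsFactors = FALSE,
             row.names = NULL)
}

# refine each junction between adjacent segments by a local least-squares
# changepoint search within +/- w frames of the initial boundary
refine_boundaries <- function(seg, x, y, w) {
  if (nrow(seg) <= 1) return(seg)
  for (j in seq_len(nrow(seg) - 1)) {
    a <- seg$start[j]; b <- seg$end[j + 1]
    lo <- max(a + 1L, seg$end[j] - w)
    hi <- min(b - 2L, seg$end[j] + w)
    if (lo > hi) next
    cand <- lo:hi
    cost <- vapply(cand, function(k) {
      ls_sse(x[a:k], y[a:k]) + ls_sse(x[(k + 1):b], y[(k + 1):b])
    }, numeric(1))
    k <- cand[which.min(cost)]
    seg$end[j] <- k
    seg$start[j + 1] <- k + 1L
  }
  seg
}

segment_region <- function(x, y, w, thr, moving_state, paused_state,
                           direction, refine = TRUE) {
  n <- length(x)
  if (n == 0) return(NULL)
  if (n <= 2) {
    return(data.frame(start = 1L, end = n, state = paused_state,
                      stringsAsFactors = FALSE))
  }
  thr <- thr * (1 - 1e-9)    # guard the at-threshold boundary case (counts
                             # as moving) against floating-point round-off
  sl <- rolling_slope(x, y, w) * direction
  labels <- ifelse(sl >= thr, moving_state, paused_state)
  seg <- labels_to_segments(labels)
  # a movement must span at least one full window to count
  short <- seg$state == moving_state & (seg$end - seg$start + 1L) < w
  seg$state[short] <- paused_state
  seg <- merge_same(seg)
  if (!refine) return(seg)
  seg <- refine_boundaries(seg, x, y, w)
  # re-validate against the threshold on refined segments (the minimum-span
  # rule applies to the smoothed labels above: a movement must be detectable
  # over a full window, but its refined extent may be shorter)
  vel <- vapply(seq_len(nrow(seg)), function(i)
    seg_velocity(x, y, seg$start[i], seg$end[i], w), numeric(1)) * direction
  bad <- seg$state == moving_state & vel < thr
  seg$state[bad] <- paused_state
  merge_same(seg)
}

#' Segment a track into runs, pauses and tip-tracking phases
#'
#' Implements the quantification rule set: a centred sliding-window
#' least-squares slope per frame; frames whose slope is below the threshold
#' (strictly less) are paused, frames at or above it are moving; movements
#' shorter than one full window are folded into the surrounding pause;
#' run/pause boundaries are then refined by a local least-squares
#' changepoint search. The lateral-to-end-on transition is the first frame
#' at which the track comes within one distance pixel of the plus end (and
#' stays there); frames before it can be `run_plus` (plus-end directed) or
#' `paused`, frames after it `tip_track` (minus-end directed, tracking
#' depolymerization) or `tip_paused`.
#'
#' @param track a `kt_track`.
#' @param mt_end plus-end position per frame (um): numeric vector, or the
#'   list returned by [extract_mt_end()], or `NULL` if the track can never
#'   convert (pure lateral analysis).
#' @param window_frames slope window (frames), default 10.
#' @param threshold pause threshold in nm/min; default derived from the
#'   pixel size and window via [threshold_nm_per_min()] (86.64 nm/min for
#'   72.2 nm pixels and a 10-frame window at 5 s).
#' @param pixel_nm distance pixel size (nm), used for the default threshold
#'   and the end-on capture distance.
#' @param refine refine segment boundaries by a local least-squares
#'   changepoint search (default). With `refine = FALSE` segments follow the
#'   smoothed threshold labels directly; that estimator is strictly monotone
#'   in the threshold but biased outward by up to half a window at each
#'   run/pause junction.
#' @param qc_crossed input-level quality flag: tracks from crossed or
#'   bundled microtubules are excluded from analysis; setting this `TRUE`
#'   makes segmentation fail with an exclusion error (the synthetic renderer
#'   never produces crossings, so this is a pass-through hook).
#' @return an object of class `kt_segmentation`: list with `segments`
#'   (data.frame `start_frame`, `end_frame` 0-based inclusive, `state`,
#'   `velocity` um/min signed, `displacement_um`), `end_on_frame` (0-based,
#'   or `NA`), `threshold_used` (nm/min), `window`.
#' @examples
#' pos <- c(seq(0, 1.2, length.out = 25), rep(1.2, 25))
#' tr <- new_track("demo", pos, frame_interval = 5)
#' seg <- segment_track(tr)
#' seg$segments
#' @export
segment_track <- function(track, mt_end = NULL, window_frames = 10,
                          threshold = NULL, pixel_nm = KYMO_PIXEL_NM,
                          refine = TRUE, qc_crossed = FALSE) {
  stopifnot(inherits(track, "kt_track"))
  if (qc_crossed)
    stop("track excluded: crossed or bundled microtubule (QC flag)")
  if (window_frames < 2) stop("window_frames must be at least 2")
  n <- length(track$positions)
  if (n <= window_frames)
    stop("track (", n, " frames) is shorter than the slope window")
  if (is.list(mt_end)) mt_end <- mt_end$position
  if (!is.null(mt_end) && length(mt_end) != n)
    stop("mt_end length does not match the track")
  if (is.null(threshold))
    threshold <- threshold_nm_per_min(pixel_nm, window_frames,
                                      track$frame_interval)
  thr_um <- threshold / 1000                     # um/min
  t_min <- (track$frames * track$frame_interval) / 60
  pos <- track$positions

  f_conv <- detect_end_on(pos, mt_end, tol = pixel_nm / 1000)

  lat_idx <- if (is.na(f_conv)) seq_len(n) else seq_len(f_conv - 1L)
  tip_idx <- if (is.na(f_conv)) integer(0) else f_conv:n

  seg_lat <- segment_region(t_min[lat_idx], pos[lat_idx], window_frames,
                            thr_um, "run_plus", "paused", direction = 1,
                            refine = refine)
  seg_tip <- segment_region(t_min[tip_idx], pos[tip_idx], window_frames,
                            thr_um, "tip_track", "tip_paused",
                            direction = -1, refine = refine)
  if (!is.null(seg_lat) && length(lat_idx)) {
    seg_lat$start <- seg_lat$start + lat_idx[1] - 1L
    seg_lat$end <- seg_lat$end + lat_idx[1] - 1L
  }
  if (!is.null(seg_tip)) {
    seg_tip$start <- seg_tip$start + tip_idx[1] - 1L
    seg_tip$end <- seg_tip$end + tip_idx[1] - 1L
  }
  seg <- rbind(seg_lat, seg_tip)
  vel <- vapply(seq_len(nrow(seg)), function(i)
    seg_velocity(t_min, pos, seg$start[i], seg$end[i], window_frames),
    numeric(1))
  disp <- pos[seg$end] - pos[seg$start]
  structure(list(
    segments = data.frame(start_frame = seg$start - 1L,
                          end_frame = seg$end - 1L,
                          state = seg$state, velocity = vel,
                          displacement_um = disp, stringsAsFactors = FALSE),
    end_on_frame = if (is.na(f_conv)) NA_integer_ else f_conv - 1L,
    threshold_used = threshold, window = window_frames,
    frame_interval = track$frame_interval,
    positions = pos, trajectory_id = track$trajectory_id
  ), class = "kt_segmentation")
}

# first frame (1-based) at which the track is within `tol` of the plus end
# and stays there (>= `sustain` frames or to the end); NA if never
detect_end_on <- function(pos, mt_end, tol, sustain = 5L) {
  if (is.null(mt_end)) return(NA_integer_)
  ok <- pos >= mt_end - tol
  if (!any(ok)) return(NA_integer_)
  r <- rle(ok)
  e <- cumsum(r$lengths)
  s <- c(1L, utils::head(e, -1) + 1L)
  n <- length(pos)
  hit <- which(r$values & (r$lengths >= sustain | e == n))
  if (!length(hit)) return(NA_integer_)
  s[hit[1]]
}

#' @export
print.kt_segmentation <- function(x, ...) {
  cat(sprintf("<kt_segmentation> %d segments, window %d frames, threshold %.2f nm/min, end-on %s\n",
              nrow(x$segments), x$window, x$threshold_used,
              if (is.na(x$end_on_frame)) "never"
              else sprintf("frame %d", x$end_on_frame)))
  print(x$segments, ...)
  invisible(x)
}
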