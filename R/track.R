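#' Track objects
#'
#' A `kt_track` is a per-frame position readout for one particle: 0-based
#' `frames`, `positions` along the microtubule axis (um, seed = 0) and a
#' per-frame `visible` flag (FALSE during blinking gaps, where the position
#' is linearly interpolated).
#'
#' @param trajectory_id label.
#' @param positions numeric positions (um).
#' @param visible logical vector (recycled), default all visible.
#' @param frame_interval s.
#' @param frames 0-based frame indices.
#' @return an object of class `kt_track`.
#' @export
new_track <- function(trajectory_id, positions, visible = TRUE,
                      frame_interval = 5,
                      frames = seq_along(positions) - 1L) {
  stopifnot(is.numeric(positions), length(positions) > 0,
            !is.unsorted(frames, strictly = TRUE))
  visible <- rep_len(as.logical(visible), length(positions))
  structure(list(trajectory_id = trajectory_id, frames = as.integer(frames),
                 positions = as.numeric(positions), visible = visible,
                 frame_interval = frame_interval),
            class = "kt_track")
}

#' Ground-truth track from a simulated trajectory
#'
#' Bypasses rendering: the simulator's kinetochore positions become the
#' track directly (all frames visible). Useful for testing the segmentation
#' against known state labels.
#'
#' @param traj a `kt_trajectory`.
#' @return a `kt_track`.
#' @export
track_from_trajectory <- function(traj) {
  id <- if (!is.null(traj$trajectory_id)) traj$trajectory_id else "truth"
  new_track(id, traj$kt_position, visible = TRUE,
            frame_interval = traj$frame_interval)
}

#' Extract a particle track from a kymograph channel
#'
#' Follows the intensity ridge frame by frame: within a search window
#' centred on the previous position, the background-subtracted
#' intensity-weighted centroid gives the new position. Frames whose peak
#' intensity does not clear the visibility threshold (blinking gaps) are
#' flagged not visible and their positions linearly interpolated across the
#' gap.
#'
#' @param kymo a `kymograph`.
#' @param channel channel name, default `"kinetochore"`.
#' @param start_hint starting distance pixel (0-based); default the
#'   brightest pixel of the first visible frame.
#' @param search_halfwidth search window half width (pixels).
#' @param vis_sigma visibility threshold in robust noise SDs above
#'   background.
#' @param max_gap longest tolerated invisible stretch (frames) before the
#'   track is declared lost.
#' @return a `kt_track` (positions in um).
#' @export
extract_track <- function(kymo, channel = "kinetochore", start_hint = NULL,
                          search_halfwidth = 6, vis_sigma = 5,
                          max_gap = 12) {
  stopifnot(inherits(kymo, "kymograph"))
  if (!channel %in% kymo$channels)
    stop("channel '", channel, "' not in kymograph (",
         paste(kymo$channels, collapse = ", "), ")")
  img <- kymo$data[match(channel, kymo$channels), , ]
  n_px <- nrow(img); n_frames <- ncol(img)
  px_um <- kymo$calibration$pixel_size / 1000
  if (!is.null(start_hint) && (start_hint < 0 || start_hint >= n_px))
    stop("start_hint outside the image")
  pos_px <- rep(NA_real_, n_frames)
  visible <- rep(FALSE, n_frames)
  prev <- if (is.null(start_hint)) NA_real_ else start_hint + 0.5
  gap <- 0L
  for (f in seq_len(n_frames)) {
    col <- img[, f]
    bg <- stats::median(col)
    noise <- stats::mad(col)
    if (noise <= 0) noise <- sqrt(max(bg, 1))
    if (is.na(prev)) {
      w <- seq_len(n_px)
    } else {
      w <- max(1, floor(prev - search_halfwidth)):
        min(n_px, ceiling(prev + search_halfwidth))
    }
    # a real emitter must clear both a peak and an integrated-mass test;
    # the mass test rejects lone bright background pixels
    mass <- sum(pmax(col[w] - bg, 0))
    mass_thr <- vis_sigma * sqrt(length(w) * max(bg, 1))
    if (max(col[w]) - bg >= vis_sigma * noise && mass >= mass_thr) {
      # centroid over a tight window centred on the in-window peak, so that
      # background pixels far from the spot carry no weight
      pk <- w[which.max(col[w])]
      cw <- max(1, pk - search_halfwidth):min(n_px, pk + search_halfwidth)
      v <- pmax(col[cw] - bg, 0)
      centroid <- sum((cw - 0.5) * v) / sum(v)
      pos_px[f] <- centroid
      visible[f] <- TRUE
      prev <- centroid
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > max_gap)
        stop("track lost at frame ", f - 1L,
             " (no signal for more than ", max_gap, " frames)")
    }
  }
  if (!any(visible)) stop("no visible signal in channel '", channel, "'")
  pos_px <- fill_gaps(pos_px)
  new_track(paste0(channel, "_track"), pos_px * px_um, visible,
            frame_interval = kymo$calibration$frame_interval)
}

# linear interpolation across NA gaps, nearest-value extension at the ends
fill_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- seq_along(x)
  ok <- !is.na(x)
  stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
}

#' Extract the microtubule plus-end position series from a kymograph
#'
#' Per frame, the plus end is located as the half-maximum falling edge of
#' the (lightly smoothed) microtubule line profile: the plateau intensity is
#' estimated near the seed, the background from the far rows, and the edge
#' position interpolated to sub-pixel precision. Frames where the channel is
#' blinked off (no plateau above background) are interpolated.
#'
#' @param kymo a `kymograph`.
#' @param channel channel name, default `"microtubule"`.
#' @return list with `position` (um, per frame) and `visible` (logical).
#' @export
extract_mt_end <- function(kymo, channel = "microtubule") {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$data[match(channel, kymo$channels), , ]
  n_px <- nrow(img); n_frames <- ncol(img)
  px_um <- kymo$calibration$pixel_size / 1000
  tip <- rep(NA_real_, n_frames)
  visible <- rep(FALSE, n_frames)
  for (f in seq_len(n_frames)) {
    col <- img[, f]
    sm <- stats::filter(col, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- col[is.na(sm)]
    bg <- stats::median(utils::tail(col, 3))
    plateau <- stats::median(sm[seq_len(min(5, n_px))])
    noise <- stats::mad(utils::tail(col, 6))   # background-row noise
    if (noise <= 0) noise <- sqrt(max(bg, 1))
    if (plateau - bg < 4 * noise) next    # channel off or fully depolymerized
    half <- (plateau + bg) / 2
    above <- which(sm >= half)
    j <- max(above)
    if (j >= n_px) {
      tip[f] <- n_px
    } else {
      # sub-pixel: crossing between centre of pixel j and j+1
      frac <- (sm[j] - half) / (sm[j] - sm[j + 1])
      tip[f] <- (j - 0.5) + frac
    }
    visible[f] <- TRUE
  }
  if (!any(visible)) stop("no microtubule signal found")
  list(position = fill_gaps(tip) * px_um, visible = visible)
}
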