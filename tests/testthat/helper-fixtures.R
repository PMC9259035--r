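# Fixtures are built in code: hand-constructed trajectories with known
# kinematics, used to exercise rendering and segmentation against exact
# expectations.

# a trajectory object with fully specified kinematics (um, seconds)
manual_trajectory <- function(kt, mt_end = NULL, state = NULL,
                              attachment = NULL, frame_interval = 5) {
  n <- length(kt)
  if (is.null(mt_end)) mt_end <- rep(max(kt) + 1, n)
  if (is.null(state)) state <- rep("lateral_pause", n)
  if (is.null(attachment)) attachment <- rep("lateral", n)
  structure(list(
    times = (seq_len(n) - 1) * frame_interval,
    kt_position = kt, mt_plus_end = mt_end, state = state,
    attachment = attachment, motile = TRUE, rng_seed = NA_integer_,
    frame_interval = frame_interval, duration = n * frame_interval,
    preset_name = "manual", trajectory_id = "manual"
  ), class = "kt_trajectory")
}

# piecewise-constant-velocity positions: segments given as (velocity um/min,
# duration s) pairs; sampled every frame_interval seconds
piecewise_positions <- function(vel_umin, dur_s, frame_interval = 5,
                                x0 = 0.5) {
  t_grid <- seq(0, sum(dur_s) - frame_interval, by = frame_interval)
  breaks <- cumsum(c(0, dur_s))
  pos <- numeric(length(t_grid))
  for (i in seq_along(t_grid)) {
    t <- t_grid[i]
    x <- x0
    for (k in seq_along(vel_umin)) {
      dt <- min(t, breaks[k + 1]) - breaks[k]
      if (dt > 0) x <- x + vel_umin[k] / 60 * dt
      if (t <= breaks[k + 1]) break
    }
    pos[i] <- x
  }
  pos
}

# per-frame segmentation labels expanded from a segment table
segment_labels <- function(seg, n) {
  lab <- rep(NA_character_, n)
  s <- seg$segments
  for (i in seq_len(nrow(s)))
    lab[(s$start_frame[i]:s$end_frame[i]) + 1L] <- s$state[i]
  lab
}

# map simulator states onto segmentation states
sim_state_as_segment_state <- function(state) {
  unname(c(lateral_run = "run_plus", lateral_pause = "paused",
           tip_move = "tip_track", tip_pause = "tip_paused")[state])
}

# TRUE for frames farther than `halfwidth` frames from any state transition
transition_mask <- function(state, halfwidth = 5) {
  n <- length(state)
  changes <- which(state[-1] != state[-n])
  keep <- rep(TRUE, n)
  for (c0 in changes) {
    lo <- max(1, c0 - halfwidth + 1)
    hi <- min(n, c0 + halfwidth)
    keep[lo:hi] <- FALSE
  }
  keep
}
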