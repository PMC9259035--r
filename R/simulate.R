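#' Stochastic simulation of kinetochore transport on dynamic microtubules
#'
#' The simulator implements a two-state (run/pause) lateral transport model
#' with irreversible lateral-to-end-on conversion and tip-coupled
#' depolymerization, on top of standard microtubule dynamic instability.
#' All events are sampled in continuous time (exponential dwells, exact
#' linear crossings) and only discretized onto the camera frame grid at the
#' end, so dwell statistics carry no frame-interval bias.
#'
#' @name simulate
NULL

# --- continuous-time engines ------------------------------------------------

# Microtubule plus-end path under dynamic instability with piecewise-constant
# rates. `epochs`: data.frame(t_start, v_growth, f_cat, f_res, v_depol),
# velocities um/min, frequencies events/min. Returns data.frame segments
# (t0, x0 um, slope um/s, phase) plus the catastrophe count as an attribute.
# The seed (length 0) is a stable template: a bare end that shrinks to 0
# re-enters growth. A rescue frequency of 0 makes shrinkage uninterruptible.
sim_mt_events <- function(epochs, duration, L0) {
  t <- 0; x <- L0; phase <- "growth"; ei <- 1L
  n_epochs <- nrow(epochs)
  n_cat <- 0L
  segs_t0 <- numeric(0); segs_x0 <- numeric(0)
  segs_sl <- numeric(0); segs_ph <- character(0)

  draw_end <- function(phase, ei, t) {
    rate <- if (phase == "growth") epochs$f_cat[ei] else epochs$f_res[ei]
    if (rate <= 0) Inf else t + stats::rexp(1, rate / 60)
  }
  t_event <- draw_end(phase, ei, t)
  guard <- 0L
  while (t < duration) {
    guard <- guard + 1L
    if (guard > 1e6) stop("microtubule simulation failed to advance")
    slope <- if (phase == "growth") epochs$v_growth[ei] / 60 else -epochs$v_depol[ei] / 60
    epoch_end <- if (ei < n_epochs) epochs$t_start[ei + 1L] else Inf
    hit0 <- if (slope < 0 && x > 0) t + x / (-slope) else Inf
    cand <- c(event = t_event, epoch = epoch_end, zero = hit0, end = duration)
    j <- which.min(cand)
    t_stop <- cand[[j]]
    segs_t0 <- c(segs_t0, t); segs_x0 <- c(segs_x0, x)
    segs_sl <- c(segs_sl, slope); segs_ph <- c(segs_ph, phase)
    x <- max(0, x + slope * (t_stop - t))
    t <- t_stop
    what <- names(cand)[j]
    if (what == "end") break
    if (what == "zero") {
      x <- 0; phase <- "growth"; t_event <- draw_end(phase, ei, t)
    } else if (what == "epoch") {
      ei <- ei + 1L
      t_event <- draw_end(phase, ei, t)   # memoryless redraw at rate change
    } else {
      if (phase == "growth") n_cat <- n_cat + 1L
      phase <- if (phase == "growth") "shrink" else "growth"
      t_event <- draw_end(phase, ei, t)
    }
  }
  segs <- data.frame(t0 = segs_t0, x0 = segs_x0, slope = segs_sl,
                     phase = segs_ph, stringsAsFactors = FALSE)
  attr(segs, "n_catastrophes") <- n_cat
  segs
}

mt_epochs_from_presets <- function(presets, t_starts) {
  data.frame(
    t_start = t_starts,
    v_growth = vapply(presets, `[[`, 0, "v_growth"),
    f_cat = vapply(presets, `[[`, 0, "f_cat"),
    f_res = vapply(presets, `[[`, 0, "f_res"),
    v_depol = vapply(presets, `[[`, 0, "v_depol_free")
  )
}

# Kinetochore path given a microtubule segment table. `epochs` is a
# data.frame(t_start, v_run, t_run_mean, t_pause_mean, v_tip, t_tipmove_mean,
# t_tippause_mean); `motile` a logical vector, one flag per epoch (a
# kinetochore may gain motility at an epoch boundary, never lose it).
# Conversion fires when the plus end comes within `conv_tol` um of the
# kinetochore; from then on the tip is slaved to the kinetochore
# (kinetochore-coupled depolymerization, no regrowth).
sim_kt_events <- function(mt_segs, epochs, motile, duration, x0, conv_tol) {
  t <- 0; x <- x0; ei <- 1L
  n_epochs <- nrow(epochs)
  attach <- "lateral"
  occ_lat <- function(ei) epochs$t_run_mean[ei] /
    (epochs$t_run_mean[ei] + epochs$t_pause_mean[ei])
  occ_tip <- function(ei) epochs$t_tipmove_mean[ei] /
    (epochs$t_tipmove_mean[ei] + epochs$t_tippause_mean[ei])
  draw_state <- function(attach, ei) {
    if (attach == "lateral") {
      if (!motile[ei]) return("lateral_pause")
      if (stats::runif(1) < occ_lat(ei)) "lateral_run" else "lateral_pause"
    } else {
      if (stats::runif(1) < occ_tip(ei)) "tip_move" else "tip_pause"
    }
  }
  dwell_mean <- function(state, ei) switch(state,
    lateral_run = epochs$t_run_mean[ei],
    lateral_pause = epochs$t_pause_mean[ei],
    tip_move = epochs$t_tipmove_mean[ei],
    tip_pause = epochs$t_tippause_mean[ei])
  draw_end <- function(state, ei, t) {
    if (state == "lateral_pause" && !motile[ei]) return(Inf)
    t + stats::rexp(1, 1 / dwell_mean(state, ei))
  }
  state_slope <- function(state, ei) switch(state,
    lateral_run = epochs$v_run[ei] / 60,
    tip_move = -epochs$v_tip[ei] / 60,
    0)

  kstate <- draw_state(attach, ei)
  t_kt <- draw_end(kstate, ei, t)
  mt_t0 <- mt_segs$t0
  rows <- vector("list", 256); nr <- 0L
  push <- function(t0, x0, slope, state, attach) {
    nr <<- nr + 1L
    if (nr > length(rows)) length(rows) <<- 2L * nr
    rows[[nr]] <<- list(t0 = t0, x0 = x0, slope = slope,
                        state = state, attach = attach)
  }
  guard <- 0L
  while (t < duration) {
    guard <- guard + 1L
    if (guard > 1e6) stop("kinetochore simulation failed to advance")
    epoch_end <- if (ei < n_epochs) epochs$t_start[ei + 1L] else Inf
    slope <- state_slope(kstate, ei)
    if (attach == "lateral") {
      mi <- findInterval(t, mt_t0)
      mt_next <- if (mi < nrow(mt_segs)) mt_t0[mi + 1L] else Inf
      tip <- mt_segs$x0[mi] + mt_segs$slope[mi] * (t - mt_segs$t0[mi])
      gap <- tip - x
      gap_slope <- mt_segs$slope[mi] - slope
      t_conv <- if (gap <= conv_tol) t
        else if (gap_slope < 0) t + (gap - conv_tol) / (-gap_slope)
        else Inf
      cand <- c(kt = t_kt, mt = mt_next, epoch = epoch_end,
                conv = t_conv, end = duration)
    } else {
      hit0 <- if (slope < 0 && x > 0) t + x / (-slope) else Inf
      cand <- c(kt = t_kt, epoch = epoch_end, zero = hit0, end = duration)
    }
    j <- which.min(cand)
    t_stop <- cand[[j]]
    if (t_stop > t) push(t, x, slope, kstate, attach)
    x <- x + slope * (t_stop - t)
    t <- t_stop
    what <- names(cand)[j]
    if (what == "end") break
    if (what == "conv") {
      # snap to the tip; attachment becomes end-on, irreversibly
      mi <- findInterval(t, mt_t0)
      x <- max(x, mt_segs$x0[mi] + mt_segs$slope[mi] * (t - mt_segs$t0[mi]))
      attach <- "end_on"
      kstate <- draw_state(attach, ei)
      t_kt <- draw_end(kstate, ei, t)
    } else if (what == "zero") {
      x <- 0
      kstate <- "tip_pause"
      t_kt <- Inf   # fully depolymerized: nothing left to track
    } else if (what == "kt") {
      kstate <- switch(kstate,
        lateral_run = "lateral_pause", lateral_pause = "lateral_run",
        tip_move = "tip_pause", tip_pause = "tip_move")
      t_kt <- draw_end(kstate, ei, t)
    } else if (what == "epoch") {
      prev_motile <- motile[ei]
      ei <- ei + 1L
      if (attach == "lateral" && !prev_motile && motile[ei]) {
        kstate <- draw_state(attach, ei)      # motility gained at switch
      }
      t_kt <- draw_end(kstate, ei, t)         # memoryless redraw
      if (attach == "end_on" && x <= 0) {     # fully depolymerized: stay put
        kstate <- "tip_pause"; t_kt <- Inf
      }
    }
    # "mt": microtubule segment boundary; conversion test refreshes next loop
  }
  if (nr == 0L) push(0, x0, 0, kstate, attach)
  rows <- rows[seq_len(nr)]
  data.frame(
    t0 = vapply(rows, `[[`, 0, "t0"),
    x0 = vapply(rows, `[[`, 0, "x0"),
    slope = vapply(rows, `[[`, 0, "slope"),
    state = vapply(rows, `[[`, "", "state"),
    attach = vapply(rows, `[[`, "", "attach"),
    stringsAsFactors = FALSE
  )
}

kt_epochs_from_presets <- function(presets, t_starts) {
  data.frame(
    t_start = t_starts,
    v_run = vapply(presets, `[[`, 0, "v_run"),
    t_run_mean = vapply(presets, `[[`, 0, "t_run_mean"),
    t_pause_mean = vapply(presets, `[[`, 0, "t_pause_mean"),
    v_tip = vapply(presets, `[[`, 0, "v_tip_track"),
    t_tipmove_mean = vapply(presets, `[[`, 0, "t_tipmove_mean"),
    t_tippause_mean = vapply(presets, `[[`, 0, "t_tippause_mean")
  )
}

# --- user-facing simulation functions ---------------------------------------

#' Simulate a free microtubule plus end
#'
#' The plus end grows at `v_growth`, undergoes catastrophe as a Poisson
#' process at frequency `f_cat`, shrinks at `v_depol_free` and is rescued at
#' frequency `f_res` (if positive). The length never drops below the seed at
#' position 0; a bare end reaching the seed resumes growth.
#'
#' @param preset a [make_preset()] object (or a list with the microtubule
#'   fields `v_growth`, `f_cat`, `f_res`, `v_depol_free`, `L0_range`).
#' @param duration total simulated time (s).
#' @param frame_interval sampling interval (s); frames are at
#'   `0, frame_interval, ..., duration - frame_interval`.
#' @param L0 initial length (um); default drawn uniformly from
#'   `preset$L0_range`.
#' @param seed optional integer seed.
#' @return an object of class `mt_trace`: list with `times` (s), `position`
#'   (plus-end position, um), `phase` (`"growth"`/`"shrink"` per frame),
#'   `segments` (exact piecewise-linear path), `n_catastrophes`.
#' @examples
#' mt <- simulate_microtubule(make_preset("WT"), duration = 300,
#'                            frame_interval = 5, L0 = 3, seed = 1)
#' range(mt$position)
#' @export
simulate_microtubule <- function(preset, duration, frame_interval,
                                 L0 = NULL, seed = NULL) {
  stopifnot(duration > 0, frame_interval > 0)
  if (preset$v_growth < 0 || preset$v_depol_free <= 0 ||
      preset$f_cat < 0 || preset$f_res < 0)
    stop("microtubule rates must be non-negative (depolymerization > 0)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(L0)) L0 <- stats::runif(1, preset$L0_range[1], preset$L0_range[2])
  epochs <- mt_epochs_from_presets(list(preset), 0)
  segs <- sim_mt_events(epochs, duration, L0)
  times <- seq(0, duration - frame_interval, by = frame_interval)
  structure(list(
    times = times,
    position = piecewise_eval(segs, times),
    phase = piecewise_label(segs, times, "phase"),
    segments = segs,
    n_catastrophes = attr(segs, "n_catastrophes"),
    duration = duration, frame_interval = frame_interval, L0 = L0
  ), class = "mt_trace")
}

#' Exact plus-end position of a simulated microtubule at arbitrary times
#'
#' @param mt an `mt_trace` from [simulate_microtubule()].
#' @param t times (s).
#' @return positions (um).
#' @export
mt_position_at <- function(mt, t) piecewise_eval(mt$segments, t)

#' Simulate a kinetochore on a microtubule
#'
#' The kinetochore starts laterally bound at a random position on the
#' microtubule. With probability `preset$p_motile` it is motile and
#' alternates exponentially distributed runs (advancing toward the plus end
#' at `v_run`) and pauses; otherwise it holds its position. When the plus
#' end comes within one kymograph pixel (72.2 nm) of the kinetochore -
#' either because the kinetochore runs into the tip or because a
#' depolymerizing tip reaches it - attachment converts irreversibly to
#' end-on: from then on the plus end is slaved to the kinetochore, which
#' alternates tip-tracking (at `v_tip_track`, minus-end directed) and tip
#' pauses, and the microtubule never regrows.
#'
#' @param preset a [make_preset()] object.
#' @param mt an `mt_trace` from [simulate_microtubule()].
#' @param seed optional integer seed.
#' @param conversion_tol capture distance for end-on conversion (um);
#'   default one kymograph pixel.
#' @return an object of class `kt_trajectory`: list with `times`,
#'   `kt_position` (um), `mt_plus_end` (um; equals `kt_position` after
#'   conversion), `state` (per frame, one of `lateral_run`, `lateral_pause`,
#'   `tip_move`, `tip_pause`), `attachment` (`lateral`/`end_on`), `motile`
#'   (whether the kinetochore was drawn motile), `rng_seed`.
#' @examples
#' p <- make_preset("WT")
#' mt <- simulate_microtubule(p, 1800, 5, seed = 2)
#' kt <- simulate_kinetochore(p, mt, seed = 3)
#' table(kt$state)
#' @export
simulate_kinetochore <- function(preset, mt, seed = NULL,
                                 conversion_tol = KYMO_PIXEL_NM / 1000) {
  stopifnot(inherits(mt, "mt_trace"))
  if (!is.null(seed)) set.seed(seed)
  duration <- mt$duration
  motile <- stats::runif(1) < preset$p_motile
  L0 <- mt$segments$x0[1]
  x0 <- stats::runif(1, preset$x0_fraction_range[1],
                     preset$x0_fraction_range[2]) * L0
  epochs <- kt_epochs_from_presets(list(preset), 0)
  segs <- sim_kt_events(mt$segments, epochs, motile, duration, x0,
                        conversion_tol)
  discretize_trajectory(segs, mt, preset, seed, motile)
}

discretize_trajectory <- function(segs, mt, preset, seed, motile) {
  times <- mt$times
  kt <- piecewise_eval(segs, times)
  state <- piecewise_label(segs, times, "state")
  attachment <- piecewise_label(segs, times, "attach")
  tip <- piecewise_eval(mt$segments, times)
  end_on <- attachment == "end_on"
  tip[end_on] <- kt[end_on]          # coupled depolymerization
  structure(list(
    times = times, kt_position = kt, mt_plus_end = tip,
    state = state, attachment = attachment,
    motile = motile, rng_seed = if (is.null(seed)) NA_integer_ else seed,
    frame_interval = mt$frame_interval, duration = mt$duration,
    preset_name = preset$name, kt_segments = segs
  ), class = "kt_trajectory")
}

#' @export
print.kt_trajectory <- function(x, ...) {
  conv <- which(x$attachment == "end_on")[1]
  cat(sprintf("<kt_trajectory> %d frames @ %gs, motile=%s, end-on %s\n",
              length(x$times), x$frame_interval, x$motile,
              if (is.na(conv)) "never" else sprintf("at frame %d", conv - 1L)))
  invisible(x)
}

#' Simulate a cohort of independent kinetochore trajectories
#'
#' @param preset a [make_preset()] object.
#' @param n number of trajectories.
#' @param duration movie length (s); default 30 min.
#' @param frame_interval frame interval (s); default 5 s.
#' @param seed optional integer master seed; per-trajectory seeds are derived
#'   with [derive_seed()] so the set is reproducible and trajectories are
#'   independent.
#' @return an object of class `trajectory_set`: list with `trajectories`
#'   (list of `kt_trajectory`), `preset`, `frame_interval`, `duration`.
#' @examples
#' ts <- simulate_cohort(make_preset("WT"), n = 4, duration = 600,
#'                       frame_interval = 5, seed = 1)
#' length(ts$trajectories)
#' @export
simulate_cohort <- function(preset, n, duration = 1800, frame_interval = 5,
                            seed = NULL) {
  if (!is.numeric(n) || n <= 0) stop("n must be a positive count")
  n <- as.integer(n)
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^30))
  trajectories <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    set.seed(si)
    mt <- simulate_microtubule(preset, duration, frame_interval)
    trajectories[[i]] <- simulate_kinetochore(preset, mt)
    trajectories[[i]]$rng_seed <- si
    trajectories[[i]]$trajectory_id <- paste0(preset$name, "_", i)
  }
  structure(list(trajectories = trajectories, preset = preset,
                 frame_interval = frame_interval, duration = duration,
                 seed = seed),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d trajectories, preset %s, %g s @ %g s/frame\n",
              length(x$trajectories), x$preset$name, x$duration,
              x$frame_interval))
  invisible(x)
}

#' Simulate a motor add-back (rescue) experiment
#'
#' Kinetochores evolve under `preset_before` until `t_switch`; at the switch
#' each kinetochore that was drawn non-motile independently becomes motile
#' with probability `p_rescue` and from then on every kinetochore (and the
#' microtubule dynamics) follows `preset_after`. This emulates adding
#' kinesin-8-containing lysate to immobile kinetochores assembled without the
#' motor; the packaged default rescue probability is 0.537, the measured
#' fraction of immobile kinetochores that started moving after add-back.
#'
#' @param preset_before,preset_after [make_preset()] objects.
#' @param t_switch add-back time (s), strictly inside `(0, duration)`.
#' @param p_rescue probability that a non-motile kinetochore becomes motile
#'   at the switch.
#' @param n number of trajectories.
#' @param duration,frame_interval as in [simulate_cohort()].
#' @param seed optional master seed.
#' @return a `trajectory_set`; each trajectory carries logical fields
#'   `motile` (initial draw) and `rescued`, and the set carries `t_switch`.
#' @examples
#' before <- make_preset("kip3_null"); before$p_motile <- 0
#' ts <- simulate_rescue(before, make_preset("WT"), t_switch = 300,
#'                       n = 5, duration = 900, seed = 1)
#' vapply(ts$trajectories, `[[`, TRUE, "rescued")
#' @export
simulate_rescue <- function(preset_before, preset_after, t_switch,
                            p_rescue = 0.537, n = 54, duration = 1800,
                            frame_interval = 5, seed = NULL) {
  if (!is.numeric(p_rescue) || p_rescue < 0 || p_rescue > 1)
    stop("p_rescue must be a probability in [0, 1]")
  if (t_switch <= 0 || t_switch >= duration)
    stop("t_switch must lie strictly inside (0, duration)")
  if (n <= 0) stop("n must be a positive count")
  n <- as.integer(n)
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^30))
  mt_epochs <- mt_epochs_from_presets(list(preset_before, preset_after),
                                      c(0, t_switch))
  kt_epochs <- kt_epochs_from_presets(list(preset_before, preset_after),
                                      c(0, t_switch))
  times <- seq(0, duration - frame_interval, by = frame_interval)
  trajectories <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    set.seed(si)
    L0 <- stats::runif(1, preset_before$L0_range[1], preset_before$L0_range[2])
    mt_segs <- sim_mt_events(mt_epochs, duration, L0)
    motile0 <- stats::runif(1) < preset_before$p_motile
    rescued <- if (motile0) FALSE else stats::runif(1) < p_rescue
    x0 <- stats::runif(1, preset_before$x0_fraction_range[1],
                       preset_before$x0_fraction_range[2]) * L0
    segs <- sim_kt_events(mt_segs, kt_epochs,
                          motile = c(motile0, motile0 || rescued),
                          duration, x0, KYMO_PIXEL_NM / 1000)
    mt <- structure(list(times = times, segments = mt_segs,
                         duration = duration,
                         frame_interval = frame_interval),
                    class = "mt_trace")
    tr <- discretize_trajectory(segs, mt, preset_after, si, motile0)
    tr$rescued <- rescued
    tr$trajectory_id <- paste0("rescue_", i)
    trajectories[[i]] <- tr
  }
  structure(list(trajectories = trajectories, preset = preset_after,
                 preset_before = preset_before, t_switch = t_switch,
                 p_rescue = p_rescue, frame_interval = frame_interval,
                 duration = duration, seed = seed),
            class = "trajectory_set")
}

# --- serialization ----------------------------------------------------------

#' Read and write trajectory sets as CSV
#'
#' One row per trajectory per frame with columns `trajectory_id`, `frame`
#' (0-based), `time_s`, `kt_um`, `mt_end_um`, `state`, `attachment`.
#'
#' @param ts a `trajectory_set`.
#' @param path file path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns a `trajectory_set` (without preset
#'   metadata beyond the name recorded per trajectory).
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  rows <- lapply(seq_along(ts$trajectories), function(i) {
    tr <- ts$trajectories[[i]]
    id <- if (!is.null(tr$trajectory_id)) tr$trajectory_id else as.character(i)
    data.frame(trajectory_id = id,
               frame = seq_along(tr$times) - 1L,
               time_s = tr$times, kt_um = tr$kt_position,
               mt_end_um = tr$mt_plus_end, state = tr$state,
               attachment = tr$attachment, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "frame", "time_s", "kt_um", "mt_end_um",
            "state", "attachment")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must contain columns: ", paste(need, collapse = ", "))
  ids <- unique(df$trajectory_id)
  dt <- if (nrow(df) > 1) diff(sort(unique(df$time_s)))[1] else NA_real_
  trajectories <- lapply(ids, function(id) {
    d <- df[df$trajectory_id == id, ]
    d <- d[order(d$frame), ]
    structure(list(times = d$time_s, kt_position = d$kt_um,
                   mt_plus_end = d$mt_end_um, state = d$state,
                   attachment = d$attachment,
                   motile = any(d$state == "lateral_run"),
                   rng_seed = NA_integer_, frame_interval = dt,
                   duration = max(d$time_s) + dt,
                   preset_name = NA_character_, trajectory_id = id),
              class = "kt_trajectory")
  })
  structure(list(trajectories = trajectories, preset = NULL,
                 frame_interval = dt,
                 duration = max(df$time_s) + dt),
            class = "trajectory_set")
}
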