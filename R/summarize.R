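#' Per-track motility summary
#'
#' Condenses a segmentation into the per-kinetochore statistics reported for
#' single tracks: the duration-weighted mean velocity over run segments
#' (pauses excluded; `NA` if the track never ran), the mean tip-tracking
#' speed, run lengths (net displacement of each run), run count, time
#' fractions spent moving versus paused (computed separately over the
#' lateral and tip-bound phases), and the `moved_at_all` /
#' `reached_plus_end` flags. Tip-phase frames after the microtubule has
#' fully depolymerized to the seed (track position within two pixels of 0)
#' are excluded - the physical track ends there. An alternative
#' gross-velocity definition (net displacement over total lateral time,
#' pauses included) is reported alongside as `gross_lateral_velocity`.
#'
#' @param seg a `kt_segmentation` from [segment_track()].
#' @param track the `kt_track` the segmentation came from (positions are
#'   taken from the segmentation if omitted).
#' @param pixel_nm distance pixel (nm) for the seed-exclusion distance.
#' @return an object of class `motility_summary` (a one-row list).
#' @export
summarize_track <- function(seg, track = NULL, pixel_nm = KYMO_PIXEL_NM) {
  stopifnot(inherits(seg, "kt_segmentation"))
  pos <- if (!is.null(track)) track$positions else seg$positions
  n <- length(pos)
  s <- seg$segments
  frames_of <- function(i) s$end_frame[i] - s$start_frame[i] + 1L

  runs <- which(s$state == "run_plus")
  tips <- which(s$state == "tip_track")
  run_lengths <- s$displacement_um[runs]
  run_frames <- if (length(runs)) frames_of(runs) else integer(0)
  mean_run_velocity <- if (length(runs))
    stats::weighted.mean(s$velocity[runs], run_frames) else NA_real_

  conv <- seg$end_on_frame                       # 0-based or NA
  lat_n <- if (is.na(conv)) n else conv
  # frame-state vector for fraction bookkeeping
  state <- rep(NA_character_, n)
  for (i in seq_len(nrow(s)))
    state[(s$start_frame[i]:s$end_frame[i]) + 1L] <- s$state[i]

  lat_idx <- if (lat_n > 0) seq_len(lat_n) else integer(0)
  tip_idx <- if (is.na(conv)) integer(0) else (conv + 1L):n
  # exclude fully-depolymerized tail (kinetochore at the seed)
  seed_tol <- 2 * pixel_nm / 1000
  tip_idx <- tip_idx[pos[tip_idx] > seed_tol]

  lat_moving <- sum(state[lat_idx] == "run_plus")
  tip_moving <- sum(state[tip_idx] == "tip_track")
  mean_tip_velocity <- if (length(tips))
    stats::weighted.mean(abs(s$velocity[tips]), frames_of(tips)) else NA_real_

  dt_min <- seg$frame_interval / 60
  gross <- if (length(lat_idx) > 1)
    (pos[max(lat_idx)] - pos[min(lat_idx)]) /
      ((length(lat_idx) - 1) * dt_min) else NA_real_

  structure(list(
    trajectory_id = seg$trajectory_id,
    mean_run_velocity = mean_run_velocity,
    gross_lateral_velocity = gross,
    mean_tip_velocity = mean_tip_velocity,
    run_lengths = run_lengths,
    n_runs = length(runs),
    lateral_frames = length(lat_idx),
    lateral_moving_fraction = if (length(lat_idx))
      lat_moving / length(lat_idx) else NA_real_,
    tip_frames = length(tip_idx),
    tip_moving_fraction = if (length(tip_idx))
      tip_moving / length(tip_idx) else NA_real_,
    lateral_moving_frames = lat_moving,
    tip_moving_frames = tip_moving,
    # lateral motility cannot be classified on less than one slope window of
    # lateral observation (e.g. near-immediate end-on conversion)
    moved_at_all = if (length(lat_idx) < seg$window) NA else length(runs) >= 1,
    reached_plus_end = !is.na(conv)
  ), class = "motility_summary")
}

#' Cohort-level summary statistics
#'
#' Aggregates per-track summaries the way the per-condition figures are
#' built: velocities as mean +/- SEM over tracks (each track contributing
#' its average; tracks with no runs are excluded from the velocity mean but
#' kept in the motile-fraction denominator), run lengths pooled over all
#' runs, time fractions pooled over all frames of the respective phase, the
#' fraction of kinetochores that moved at all and the fraction that reached
#' the plus end, plus 0.2-unit histograms of per-track velocities and
#' pooled run lengths.
#'
#' @param summaries a list of `motility_summary` objects.
#' @return an object of class `cohort_summary`.
#' @examples
#' tr <- new_track("a", seq(0, 1, length.out = 40), frame_interval = 5)
#' cs <- summarize_cohort(list(summarize_track(segment_track(tr))))
#' cs$fraction_moved
#' @export
summarize_cohort <- function(summaries) {
  if (length(summaries) == 0) stop("empty cohort")
  stopifnot(all(vapply(summaries, inherits, TRUE, "motility_summary")))
  g <- function(f) vapply(summaries, function(x) {
    v <- x[[f]]
    if (is.null(v) || length(v) != 1) NA_real_ else as.numeric(v)
  }, numeric(1))
  run_v <- g("mean_run_velocity")
  tip_v <- g("mean_tip_velocity")
  run_lengths <- unlist(lapply(summaries, `[[`, "run_lengths"))
  lat_frames <- g("lateral_frames"); lat_mov <- g("lateral_moving_frames")
  tip_frames <- g("tip_frames"); tip_mov <- g("tip_moving_frames")
  moved <- g("moved_at_all") > 0
  reached <- g("reached_plus_end") > 0

  structure(list(
    n_tracks = length(summaries),
    run_velocity_mean = mean(run_v, na.rm = TRUE),
    run_velocity_sem = sem(run_v),
    tip_velocity_mean = mean(tip_v, na.rm = TRUE),
    tip_velocity_sem = sem(tip_v),
    run_length_mean = if (length(run_lengths)) mean(run_lengths) else NA_real_,
    run_length_sem = sem(run_lengths),
    n_runs_total = length(run_lengths),
    mean_runs_per_track = mean(g("n_runs")),
    lateral_moving_fraction = if (sum(lat_frames) > 0)
      sum(lat_mov) / sum(lat_frames) else NA_real_,
    tip_moving_fraction = if (sum(tip_frames, na.rm = TRUE) > 0)
      sum(tip_mov, na.rm = TRUE) / sum(tip_frames, na.rm = TRUE) else NA_real_,
    fraction_moved = mean(moved, na.rm = TRUE),
    fraction_reached_end = mean(reached),
    velocity_histogram = make_histogram(run_v[!is.na(run_v)]),
    run_length_histogram = make_histogram(run_lengths)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d tracks\n", x$n_tracks))
  cat(sprintf("  run velocity  %.3f +/- %.3f um/min  (runs-only, per track)\n",
              x$run_velocity_mean, x$run_velocity_sem))
  cat(sprintf("  tip velocity  %.3f +/- %.3f um/min\n",
              x$tip_velocity_mean, x$tip_velocity_sem))
  cat(sprintf("  run length    %.3f +/- %.3f um  (%d runs pooled)\n",
              x$run_length_mean, x$run_length_sem, x$n_runs_total))
  cat(sprintf("  lateral time moving  %.1f%%   tip time moving  %.1f%%\n",
              100 * x$lateral_moving_fraction, 100 * x$tip_moving_fraction))
  cat(sprintf("  moved at all  %.1f%%   reached plus end  %.1f%%\n",
              100 * x$fraction_moved, 100 * x$fraction_reached_end))
  invisible(x)
}

#' Analyze a whole trajectory set end to end
#'
#' Convenience wrapper running, for every trajectory in the set, either the
#' full image route (render a noisy kymograph, extract the kinetochore track
#' and the plus-end series, segment) or the ground-truth route (segment the
#' simulator positions directly), then summarizing the cohort.
#'
#' @param ts a `trajectory_set`.
#' @param cfg an [imaging_config()] (image route only).
#' @param mode `"render"` (default) or `"truth"`.
#' @param seed master seed for rendering noise; per-trajectory seeds are
#'   derived from it.
#' @param window_frames,threshold passed to [segment_track()].
#' @return a list with `cohort` (a `cohort_summary`), `summaries`,
#'   `segmentations`.
#' @export
analyze_trajectory_set <- function(ts, cfg = NULL,
                                   mode = c("render", "truth"),
                                   seed = NULL, window_frames = 10,
                                   threshold = NULL) {
  stopifnot(inherits(ts, "trajectory_set"))
  mode <- match.arg(mode)
  if (mode == "render" && is.null(cfg))
    cfg <- imaging_config(frame_interval = ts$frame_interval,
                          duration = ts$duration)
  if (is.null(seed)) seed <- 1L
  segs <- vector("list", length(ts$trajectories))
  sums <- vector("list", length(ts$trajectories))
  for (i in seq_along(ts$trajectories)) {
    tr <- ts$trajectories[[i]]
    if (mode == "render") {
      ky <- render_kymograph(tr, cfg, seed = derive_seed(seed, i))
      track <- extract_track(ky)
      track$trajectory_id <- tr$trajectory_id
      mt_end <- extract_mt_end(ky)
    } else {
      track <- track_from_trajectory(tr)
      mt_end <- tr$mt_plus_end
    }
    sg <- segment_track(track, mt_end, window_frames = window_frames,
                        threshold = threshold)
    segs[[i]] <- sg
    sums[[i]] <- summarize_track(sg, track)
  }
  list(cohort = summarize_cohort(sums), summaries = sums,
       segmentations = segs)
}
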