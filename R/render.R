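#' Imaging configuration for synthetic kymographs
#'
#' Physical calibration and noise model for the renderer. Defaults mirror the
#' TIRF acquisition geometry the quantification assumes: 72.2 nm kymograph
#' pixels, one frame every 5 s, 30 min movies.
#'
#' @param pixel_size nm per distance pixel.
#' @param frame_interval s per time pixel.
#' @param duration movie length (s); must be a multiple of `frame_interval`.
#' @param psf_sigma Gaussian point-spread sigma (nm), applied along the
#'   distance axis.
#' @param photon_rate expected photons per point emitter per frame (a
#'   kinetochore particle carries many fluorophore copies); the
#'   microtubule line emits `photon_rate / 2` per covered pixel per frame.
#' @param background mean background counts per pixel per frame.
#' @param noise_model `"poisson"`, `"gaussian"` (matched mean/variance) or
#'   `"none"`.
#' @param blink_on_mean,blink_off_mean mean on/off dwell times (s) of the
#'   blinking telegraph process; `blink_off_mean = 0` disables blinking.
#' @param blink_channel channel the telegraph is applied to; by default the
#'   red (microtubule) channel, matching the red fluorescent protein tags
#'   that blink while GFP does not.
#' @return an object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size = 72.2, frame_interval = 5,
                           duration = 1800, psf_sigma = 150,
                           photon_rate = 300, background = 5,
                           noise_model = c("poisson", "gaussian", "none"),
                           blink_on_mean = 20, blink_off_mean = 10,
                           blink_channel = "microtubule") {
  noise_model <- match.arg(noise_model)
  stopifnot(pixel_size > 0, frame_interval > 0, psf_sigma >= 0,
            photon_rate > 0, background >= 0,
            blink_on_mean > 0, blink_off_mean >= 0)
  if (abs(duration / frame_interval - round(duration / frame_interval)) > 1e-9)
    stop("duration must be a multiple of frame_interval")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 duration = duration, psf_sigma = psf_sigma,
                 photon_rate = photon_rate, background = background,
                 noise_model = noise_model, blink_on_mean = blink_on_mean,
                 blink_off_mean = blink_off_mean,
                 blink_channel = blink_channel),
            class = "imaging_config")
}

# Exponential on/off telegraph sampled in continuous time, discretized to
# frame sample instants. Returns a logical visibility vector.
blink_telegraph <- function(n_frames, frame_interval, on_mean, off_mean) {
  if (off_mean <= 0) return(rep(TRUE, n_frames))
  duration <- n_frames * frame_interval
  t <- 0
  p_on <- on_mean / (on_mean + off_mean)
  state <- stats::runif(1) < p_on
  t0 <- numeric(0); s <- logical(0)
  while (t < duration) {
    t0 <- c(t0, t); s <- c(s, state)
    t <- t + stats::rexp(1, 1 / if (state) on_mean else off_mean)
    state <- !state
  }
  idx <- findInterval((seq_len(n_frames) - 1) * frame_interval, t0)
  s[idx]
}

apply_noise <- function(lambda, noise_model) {
  switch(noise_model,
    none = lambda,
    poisson = {
      x <- lambda
      x[] <- stats::rpois(length(lambda), lambda)
      x
    },
    gaussian = {
      x <- lambda + stats::rnorm(length(lambda), sd = sqrt(pmax(lambda, 0)))
      pmax(x, 0)
    })
}

#' Render a trajectory into a noisy two-channel kymograph
#'
#' Builds a distance-by-time intensity raster per channel: the microtubule
#' channel is a line of emitters from the seed (pixel 0) to the plus end,
#' the kinetochore channel a point emitter at the kinetochore position. Both
#' are convolved with a 1D Gaussian point-spread function (exact per-pixel
#' integration, so summed intensity per frame is conserved), blinking is
#' applied to the configured channel as an on/off telegraph, and shot noise
#' per `cfg$noise_model`.
#'
#' @param traj a `kt_trajectory` whose frame grid matches `cfg`.
#' @param cfg an [imaging_config()].
#' @param seed optional integer seed (blinking + noise).
#' @return an object of class `kymograph`: list with `data` (array
#'   `[channel, distance_pixel, time_pixel]`), `channels`
#'   (`c("microtubule", "kinetochore")`), `calibration`, `blink_visible`
#'   (per-channel logical matrix), `origin` (seed = distance pixel 0).
#'   Distance pixel `i` (0-based) covers `[i, i+1) * pixel_size`.
#' @examples
#' p <- make_preset("WT")
#' mt <- simulate_microtubule(p, 300, 5, L0 = 3, seed = 1)
#' kt <- simulate_kinetochore(p, mt, seed = 1)
#' ky <- render_kymograph(kt, imaging_config(duration = 300), seed = 1)
#' dim(ky$data)
#' @export
render_kymograph <- function(traj, cfg, seed = NULL) {
  stopifnot(inherits(traj, "kt_trajectory"), inherits(cfg, "imaging_config"))
  n_frames <- length(traj$times)
  if (n_frames != round(cfg$duration / cfg$frame_interval) ||
      abs(traj$frame_interval - cfg$frame_interval) > 1e-9)
    stop("trajectory frame grid does not match the imaging config")
  if (!is.null(seed)) set.seed(seed)
  px <- cfg$pixel_size / 1000                       # um per pixel
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  margin <- ceiling(3 * sigma_px) + 3
  n_px <- ceiling(max(traj$mt_plus_end, traj$kt_position) / px) + margin
  edges <- seq_len(n_px + 1) - 1                    # pixel edges, in pixels

  kt_px <- traj$kt_position / px
  mt_px <- traj$mt_plus_end / px

  # kinetochore: integrated Gaussian per pixel (energy-conserving)
  if (sigma_px > 0) {
    z <- stats::pnorm(outer(edges, kt_px, "-") / sigma_px)
    kt_img <- (z[-1, , drop = FALSE] - z[-nrow(z), , drop = FALSE]) *
      cfg$photon_rate
  } else {
    kt_img <- matrix(0, n_px, n_frames)
    j <- pmin(pmax(floor(kt_px), 0), n_px - 1) + 1
    kt_img[cbind(j, seq_len(n_frames))] <- cfg$photon_rate
  }

  # microtubule: uniform line density, fractional coverage at the tip,
  # then the same Gaussian blur (difference of integrated edge responses)
  mt_rate <- cfg$photon_rate / 2
  if (sigma_px > 0) {
    mt_cov <- blur_line_coverage(edges, mt_px, sigma_px)
  } else {
    mt_cov <- pmin(pmax(outer(-edges[-length(edges)], mt_px, "+"), 0), 1)
  }
  mt_img <- mt_cov * mt_rate

  vis <- matrix(TRUE, 2, n_frames,
                dimnames = list(c("microtubule", "kinetochore"), NULL))
  for (ch in intersect(cfg$blink_channel, rownames(vis))) {
    vis[ch, ] <- blink_telegraph(n_frames, cfg$frame_interval,
                                 cfg$blink_on_mean, cfg$blink_off_mean)
  }
  mt_img <- sweep(mt_img, 2, as.numeric(vis["microtubule", ]), `*`)
  kt_img <- sweep(kt_img, 2, as.numeric(vis["kinetochore", ]), `*`)

  data <- array(0, dim = c(2, n_px, n_frames),
                dimnames = list(channel = c("microtubule", "kinetochore"),
                                NULL, NULL))
  data[1, , ] <- apply_noise(mt_img + cfg$background, cfg$noise_model)
  data[2, , ] <- apply_noise(kt_img + cfg$background, cfg$noise_model)
  structure(list(data = data, channels = c("microtubule", "kinetochore"),
                 calibration = cfg, blink_visible = vis, origin = 0),
            class = "kymograph")
}

# Expected per-pixel coverage of a Gaussian-blurred line [0, tip]:
# integral over the pixel of (Phi((x-0)/s) - Phi((x-tip)/s)), evaluated
# analytically via the antiderivative s*(z*Phi(z) + phi(z)).
blur_line_coverage <- function(edges, tip_px, sigma_px) {
  G <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
  lo <- outer(edges, rep(0, length(tip_px)), "-") / sigma_px
  hi <- outer(edges, tip_px, "-") / sigma_px
  prim <- sigma_px * (G(lo) - G(hi))                # antiderivative at edges
  d <- prim[-1, , drop = FALSE] - prim[-nrow(prim), , drop = FALSE]
  pmin(pmax(d, 0), 1)
}

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kymograph> %d channel(s), %d distance px x %d frames (%.1f nm/px, %g s/frame)\n",
              d[1], d[2], d[3], x$calibration$pixel_size,
              x$calibration$frame_interval))
  invisible(x)
}

#' Render a synthetic spindle line-scan intensity profile
#'
#' Emulates a 1D line scan along the spindle axis of a metaphase cell.
#' `"bilobed"` places two Gaussian kinetochore clusters near the spindle
#' poles; `"declustered"` produces either three to five foci at random axial
#' positions or a single elongated plateau spanning the spindle (chosen at
#' random), the two failure modes counted as declustered.
#'
#' @param phenotype `"bilobed"` or `"declustered"`.
#' @param spindle_length um; must lie in the 2-3 um inclusion window
#'   (profiles outside it are rejected, mirroring the analysis exclusion).
#' @param cfg an [imaging_config()]; pixel size and noise model are used.
#' @param seed optional integer seed.
#' @param spot_sigma cluster sigma (um).
#' @return data.frame with columns `position_um`, `intensity`, plus
#'   attributes `phenotype` and `spindle_length`.
#' @export
render_spindle_profile <- function(phenotype = c("bilobed", "declustered"),
                                   spindle_length, cfg = imaging_config(),
                                   seed = NULL, spot_sigma = 0.15) {
  phenotype <- match.arg(phenotype)
  if (spindle_length < 2 || spindle_length > 3)
    stop("spindle_length outside the 2-3 um inclusion window")
  if (!is.null(seed)) set.seed(seed)
  px <- cfg$pixel_size / 1000
  pad <- 0.5
  pos <- seq(-pad, spindle_length + pad, by = px)
  amp <- cfg$photon_rate
  if (phenotype == "bilobed") {
    centers <- c(stats::runif(1, 0.15, 0.35),
                 spindle_length - stats::runif(1, 0.15, 0.35))
    weights <- stats::runif(2, 0.7, 1)
    lambda <- rowSums(vapply(seq_along(centers), function(i) {
      weights[i] * amp * exp(-(pos - centers[i])^2 / (2 * spot_sigma^2))
    }, numeric(length(pos))))
  } else if (stats::runif(1) < 0.5) {
    # 3+ resolvable foci: jittered even spacing keeps them >= ~0.55 um apart
    span <- spindle_length - 0.3
    k_max <- max(3, min(5, floor(span / 0.55) + 1))
    k <- if (k_max > 3) sample(3:k_max, 1) else 3L
    gap <- span / (k - 1)
    jit <- max(0, (gap - 0.56) / 2)
    centers <- 0.15 + gap * (0:(k - 1)) +
      stats::runif(k, -jit, jit)
    weights <- stats::runif(k, 0.6, 1)
    lambda <- rowSums(vapply(seq_along(centers), function(i) {
      weights[i] * amp * exp(-(pos - centers[i])^2 / (2 * spot_sigma^2))
    }, numeric(length(pos))))
  } else {
    # one long signal matching the spindle: smoothed top-hat
    lambda <- 0.8 * amp *
      (stats::pnorm((pos - 0.1) / spot_sigma) -
       stats::pnorm((pos - (spindle_length - 0.1)) / spot_sigma))
  }
  intensity <- as.numeric(apply_noise(lambda + cfg$background,
                                      cfg$noise_model))
  out <- data.frame(position_um = pos, intensity = intensity)
  attr(out, "phenotype") <- phenotype
  attr(out, "spindle_length") <- spindle_length
  out
}

# --- TIFF I/O ---------------------------------------------------------------

#' Write or read a kymograph as a multi-page TIFF
#'
#' Channels are written as separate pages (ImageJ-style channel-first
#' layout), distance along rows and time along columns, as 32-bit floats
#' scaled to `[0, 1]` by the recorded `intensity_scale`. The physical
#' calibration (pixel size, frame interval, duration, channel names,
#' intensity scale) is stored as a JSON sidecar at `<path>.json` and
#' restored on read.
#'
#' @param kymo a `kymograph`.
#' @param path file path.
#' @return `write_kymograph_tiff()` returns `path` invisibly;
#'   `read_kymograph_tiff()` returns a `kymograph`.
#' @export
write_kymograph_tiff <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  scale <- max(kymo$data, 1e-12)
  pages <- lapply(seq_along(kymo$channels),
                  function(ch) kymo$data[ch, , ] / scale)
  meta <- list(
    pixel_size_nm = kymo$calibration$pixel_size,
    frame_interval_s = kymo$calibration$frame_interval,
    duration_s = kymo$calibration$duration,
    channels = kymo$channels,
    intensity_scale = scale
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = TRUE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kymograph_tiff
#' @export
read_kymograph_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("kymograph calibration sidecar not found: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  cfg <- imaging_config(pixel_size = meta$pixel_size_nm,
                        frame_interval = meta$frame_interval_s,
                        duration = meta$duration_s)
  n_px <- nrow(pages[[1]]); n_frames <- ncol(pages[[1]])
  data <- array(0, dim = c(length(pages), n_px, n_frames),
                dimnames = list(channel = meta$channels, NULL, NULL))
  for (ch in seq_along(pages)) data[ch, , ] <- pages[[ch]] * meta$intensity_scale
  structure(list(data = data, channels = meta$channels, calibration = cfg,
                 blink_visible = NULL, origin = 0),
            class = "kymograph")
}

#' Generate a labeled pair of tracks for colocalization benchmarking
#'
#' Synthetic fixture generator for the colocalization classifier: a blinking
#' reference track and a query track constructed to be `"always"`,
#' `"partially"` (reference alone for an initial stretch, then the query
#' appears and stays) or `"never"` colocalized, with Gaussian localization
#' noise on both.
#'
#' @param category ground-truth category.
#' @param n_frames number of frames.
#' @param cfg an [imaging_config()]; blinking dwell means apply to the
#'   reference.
#' @param seed optional integer seed.
#' @param loc_sd localization noise (um).
#' @return list with `ref` and `query` (each a [new_track()]) and `category`.
#' @export
simulate_coloc_pair <- function(category = c("always", "partially", "never"),
                                n_frames = 200, cfg = imaging_config(),
                                seed = NULL, loc_sd = 0.02) {
  category <- match.arg(category)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n_frames)
  base <- 1 + cumsum(rep(0.3 / 60 * cfg$frame_interval, n_frames)) +
    stats::rnorm(n_frames, sd = loc_sd)
  ref_vis <- blink_telegraph(n_frames, cfg$frame_interval,
                             cfg$blink_on_mean, cfg$blink_off_mean)
  q <- base + stats::rnorm(n_frames, sd = loc_sd)
  q_vis <- rep(TRUE, n_frames)
  if (category == "never") {
    q <- base + 1.5 + stats::rnorm(n_frames, sd = loc_sd)
  } else if (category == "partially") {
    onset <- floor(n_frames * stats::runif(1, 0.2, 0.6))
    q_vis[seq_len(onset)] <- FALSE
  }
  list(ref = new_track("ref", positions = base, visible = ref_vis,
                       frame_interval = cfg$frame_interval),
       query = new_track("query", positions = q, visible = q_vis,
                         frame_interval = cfg$frame_interval),
       category = category)
}
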