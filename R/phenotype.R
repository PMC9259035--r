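#' Classify a spindle line scan as bilobed or declustered
#'
#' Metaphase kinetochore clustering is read off a 1D intensity profile along
#' the spindle axis: exactly two distinct peaks means the kinetochores are
#' clustered into the normal bilobed configuration; anything else (three or
#' more foci, or one long signal matching the spindle) is declustered.
#' "Distinct peak" is made operational as a local maximum with topographic
#' prominence of at least `prominence_frac` of the profile maximum (above
#' background) and at least `min_separation` from any higher accepted peak.
#' Only spindles 2-3 um long are analyzed; others are rejected, mirroring
#' the inclusion window of the assay.
#'
#' @param profile data.frame with `position_um` and `intensity` (as produced
#'   by [render_spindle_profile()]), or a numeric intensity vector with
#'   `positions` supplied separately.
#' @param spindle_length um; must lie in \[2, 3\].
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   background-subtracted profile maximum.
#' @param min_separation minimum separation between accepted peaks (um).
#' @param positions positions (um) if `profile` is a bare numeric vector.
#' @param smooth_window boxcar smoothing width (points) applied before peak
#'   finding.
#' @return an object of class `phenotype_call`: list with `value`
#'   (`"bilobed"`/`"declustered"`), `n_peaks`, `peak_positions_um`,
#'   `spindle_length`.
#' @examples
#' prof <- render_spindle_profile("bilobed", 2.5,
#'                                imaging_config(noise_model = "none"),
#'                                seed = 1)
#' classify_spindle(prof, 2.5)$value
#' @export
classify_spindle <- function(profile, spindle_length,
                             prominence_frac = 0.25, min_separation = 0.5,
                             positions = NULL, smooth_window = 3) {
  if (spindle_length < 2 || spindle_length > 3)
    stop("spindle excluded: length ", spindle_length,
         " um outside the 2-3 um analysis window")
  if (is.data.frame(profile)) {
    positions <- profile$position_um
    y <- profile$intensity
  } else {
    y <- as.numeric(profile)
    if (is.null(positions)) positions <- seq_along(y) * 0.0722
  }
  stopifnot(length(y) == length(positions), length(y) >= 5)
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    ys <- stats::filter(y, k, sides = 2)
    y <- ifelse(is.na(ys), y, as.numeric(ys))
  }
  bg <- min(y)
  peaks <- find_prominent_peaks(y - bg, positions,
                                min_prominence = prominence_frac *
                                  max(y - bg),
                                min_separation = min_separation)
  value <- if (nrow(peaks) == 2) "bilobed" else "declustered"
  structure(list(value = value, n_peaks = nrow(peaks),
                 peak_positions_um = peaks$position,
                 spindle_length = spindle_length),
            class = "phenotype_call")
}

# Local maxima with topographic prominence: for each candidate peak, walk
# left and right to the nearest higher point; the prominence is peak height
# minus the higher of the two interval minima. Peaks below min_prominence
# are dropped; of two accepted peaks closer than min_separation, the lower
# is dropped.
find_prominent_peaks <- function(y, positions, min_prominence,
                                 min_separation) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  # plateau maxima: rising then flat then falling
  if (!length(cand) && n >= 3) {
    m <- which(y == max(y))
    cand <- m[ceiling(length(m) / 2)]
  }
  if (!length(cand))
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- if (i > 1) y[seq_len(i - 1)] else numeric(0)
    higher_l <- which(left > h)
    min_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(i - 1)])
      else if (length(left)) min(left) else h
    right <- if (i < n) y[(i + 1):n] else numeric(0)
    higher_r <- which(right > h)
    min_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)])
      else if (length(right)) min(right) else h
    h - max(min_l, min_r)
  }, numeric(1))
  keep <- which(prom >= min_prominence)
  if (!length(keep))
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  df <- data.frame(position = positions[cand[keep]], height = y[cand[keep]],
                   prominence = prom[keep])
  df <- df[order(-df$height), ]
  sel <- logical(0)
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    if (!nrow(kept) || all(abs(kept$position - df$position[i]) >=
                           min_separation)) {
      kept <- rbind(kept, df[i, ])
    }
  }
  kept[order(kept$position), ]
}

#' Summarize spindle phenotype calls across replicates
#'
#' @param calls a list of `phenotype_call` objects (or a character vector of
#'   `"bilobed"`/`"declustered"` values).
#' @param replicate replicate label per call.
#' @return list with a per-replicate table (`replicate`, `n`,
#'   `bilobed_fraction`) and the cross-replicate `bilobed_mean` and
#'   `bilobed_sem`.
#' @examples
#' summarize_phenotypes(rep(c("bilobed", "declustered"), c(8, 2)),
#'                      replicate = rep(1:2, 5))
#' @export
summarize_phenotypes <- function(calls, replicate) {
  values <- if (is.character(calls)) calls
    else vapply(calls, `[[`, "", "value")
  stopifnot(all(values %in% c("bilobed", "declustered")),
            length(replicate) == length(values))
  if (length(values) == 0) stop("no phenotype calls supplied")
  reps <- split(values == "bilobed", replicate)
  if (any(vapply(reps, length, 0L) == 0)) stop("empty replicate")
  frac <- vapply(reps, mean, numeric(1))
  list(per_replicate = data.frame(replicate = names(reps),
                                  n = vapply(reps, length, 0L),
                                  bilobed_fraction = as.numeric(frac),
                                  row.names = NULL),
       bilobed_mean = mean(frac),
       bilobed_sem = sem(frac))
}
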