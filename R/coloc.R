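#' Score pairwise track colocalization with a blinking reference
#'
#' Classifies a pair of tracks into `"always"`, `"partially"` or `"never"`
#' colocalized. Because the red reference fluorophore blinks, scoring is
#' restricted to frames where the reference is visible; a frame is
#' colocalized when both signals are present and within `dist_thresh` of
#' each other. `"always"`: every evaluated frame colocalizes. `"partially"`:
#' the reference initially appears alone, then the query appears on it and
#' stays colocalized for the remainder (>= `sustain_fraction` of the
#' remaining evaluated frames, tolerating blinking-induced gaps).
#' Everything else - including colocalization that is later lost - is
#' `"never"`.
#'
#' @param ref,query `kt_track` objects on a shared frame grid.
#' @param dist_thresh colocalization distance (um); default one kymograph
#'   pixel (0.0722 um).
#' @param sustain_fraction minimum colocalized fraction of the suffix for
#'   `"partially"` (and of the whole for `"always"` to tolerate isolated
#'   noise frames is *not* allowed: always means all frames).
#' @param prefix_max_fraction maximum colocalized fraction tolerated in the
#'   initial alone phase.
#' @return character scalar: `"always"`, `"partially"` or `"never"`.
#' @examples
#' a <- new_track("a", rep(1, 50)); b <- new_track("b", rep(1.01, 50))
#' score_colocalization(a, b)
#' @export
score_colocalization <- function(ref, query,
                                 dist_thresh = KYMO_PIXEL_NM / 1000,
                                 sustain_fraction = 0.9,
                                 prefix_max_fraction = 0.1) {
  stopifnot(inherits(ref, "kt_track"), inherits(query, "kt_track"))
  if (dist_thresh <= 0) stop("dist_thresh must be positive")
  if (length(ref$positions) != length(query$positions) ||
      !isTRUE(all.equal(ref$frames, query$frames)))
    stop("ref and query tracks must share the same frame grid")
  eval_idx <- which(ref$visible)
  if (!length(eval_idx)) stop("reference track is never visible")
  coloc <- query$visible[eval_idx] &
    abs(ref$positions[eval_idx] - query$positions[eval_idx]) <= dist_thresh
  m <- length(coloc)
  if (all(coloc)) return("always")
  # earliest onset whose suffix stays colocalized
  suffix_frac <- rev(cumsum(rev(coloc))) / rev(seq_len(m))
  onsets <- which(coloc & suffix_frac >= sustain_fraction)
  for (o in onsets) {
    prefix <- coloc[seq_len(o - 1L)]
    if (length(prefix) == 0L || mean(prefix) <= prefix_max_fraction)
      return(if (o == 1L) "always" else "partially")
  }
  "never"
}

#' Summarize colocalization categories for a set of track pairs
#'
#' @param categories character vector of per-pair categories from
#'   [score_colocalization()].
#' @return named counts (always, partially, never) with fractions.
#' @export
summarize_colocalization <- function(categories) {
  lv <- c("always", "partially", "never")
  stopifnot(all(categories %in% lv))
  counts <- table(factor(categories, levels = lv))
  list(counts = as.list(as.integer(counts)) |> stats::setNames(lv),
       fractions = as.list(as.numeric(counts) / length(categories)) |>
         stats::setNames(lv),
       n = length(categories))
}
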