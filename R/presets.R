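#' Genotype presets for the kinetochore motility model
#'
#' A `genotype_preset` bundles every rate, velocity and probability of the
#' two-state lateral-transport / end-on-conversion model for one lysate
#' condition. Velocities of the moving states and the motile fraction are
#' measured quantities; dwell-time means and the free microtubule dynamics
#' (growth velocity, catastrophe and rescue frequencies) are calibrated model
#' values, documented in the package configuration (see
#' `system.file("config", "presets.yaml", package = "kinetotrack")` and the
#' methods vignette).
#'
#' Fields (units in parentheses):
#' \describe{
#'   \item{name}{condition label.}
#'   \item{v_run}{lateral run velocity toward the plus end (um/min).}
#'   \item{t_run_mean, t_pause_mean}{mean exponential dwell times of the
#'     lateral run and pause states (s). Their ratio sets the side-bound
#'     moving-time fraction of motile kinetochores,
#'     `t_run_mean / (t_run_mean + t_pause_mean)`.}
#'   \item{p_motile}{probability that a laterally bound kinetochore is motile
#'     at all (dimensionless, in \[0, 1\]).}
#'   \item{v_tip_track}{tip-tracking velocity during kinetochore-coupled
#'     depolymerization (um/min, magnitude; motion is minus-end directed).}
#'   \item{t_tipmove_mean, t_tippause_mean}{mean dwell times of the tip
#'     moving / paused states (s).}
#'   \item{v_growth}{free plus-end growth velocity (um/min).}
#'   \item{f_cat}{catastrophe frequency of growing free plus ends (events/min).}
#'   \item{f_res}{rescue frequency of shrinking free plus ends (events/min);
#'     forced to zero after end-on conversion (a kinetochore-bound end never
#'     regrows).}
#'   \item{v_depol_free}{free depolymerization velocity (um/min).}
#'   \item{L0_range}{initial microtubule length range (um).}
#'   \item{x0_fraction_range}{initial kinetochore position as a fraction of
#'     the initial microtubule length.}
#' }
#'
#' @param name one of `"WT"`, `"kip3_null"`, `"kip3_dT_LZ"` (case sensitive),
#'   or any name present in `config`.
#' @param config optional named list of preset definitions overriding or
#'   extending the packaged defaults, e.g. as read by [read_preset_config()].
#' @return an object of class `genotype_preset`.
#'
#' @details The packaged conditions encode the lysate phenotypes: wild type
#'   (`WT`, Kip3-positive) with 0.56 um/min lateral runs, 77% motile
#'   kinetochores and 0.4 um/min tip tracking; the kinesin-8 deletion
#'   (`kip3_null`) with only 28% motile, 0.47 um/min runs, shorter run
#'   lengths and a reduced catastrophe frequency; and the tail-truncated
#'   motor (`kip3_dT_LZ`) with faster (0.76 um/min), longer (1.4 um) runs but
#'   few end arrivals because plus-end growth is rarely interrupted.
#'   A `mif2_like` preset scaling `v_run` by 0.71 is included for the slower
#'   inner-kinetochore proteins.
#' @examples
#' p <- make_preset("WT")
#' p$v_run                    # 0.56 um/min
#' p$t_run_mean / (p$t_run_mean + p$t_pause_mean)  # motile occupancy
#' @export
make_preset <- function(name, config = NULL) {
  defaults <- preset_defaults()
  if (!is.null(config)) {
    stopifnot(is.list(config))
    defaults[names(config)] <- lapply(names(config), function(nm) {
      base <- if (nm %in% names(defaults)) defaults[[nm]] else list(name = nm)
      utils::modifyList(base, config[[nm]])
    })
  }
  if (!name %in% names(defaults)) {
    stop("unknown genotype preset '", name, "'; available: ",
         paste(names(defaults), collapse = ", "), call. = FALSE)
  }
  p <- defaults[[name]]
  p$name <- name
  validate_preset(p)
}

# Packaged defaults. Velocities, motile fractions and the rescue probability
# are the measured condition values; dwell means, v_growth, f_cat and f_res
# are calibrated so that the full simulate -> render -> extract -> segment ->
# summarize pipeline reproduces the per-condition cohort statistics
# (calibration documented in the methods vignette).
preset_defaults <- function() {
  wt <- list(
    name = "WT",
    v_run = 0.56, t_run_mean = 45, t_pause_mean = 72,
    p_motile = 0.77,
    v_tip_track = 0.40, t_tipmove_mean = 62, t_tippause_mean = 90,
    v_growth = 0.50, f_cat = 0.38, f_res = 1.75, v_depol_free = 0.82,
    L0_range = c(2, 6), x0_fraction_range = c(0.1, 0.9)
  )
  k3 <- utils::modifyList(wt, list(
    name = "kip3_null",
    v_run = 0.47, t_run_mean = 35, t_pause_mean = 200,
    p_motile = 0.28,
    # tip-bound kinetochores in kip3-null lysates spend less time
    # depolymerizing; catastrophes are rarer without the kinesin-8
    t_tipmove_mean = 45, t_tippause_mean = 100,
    f_cat = 0.22, f_res = 1.5
  ))
  dtlz <- utils::modifyList(wt, list(
    name = "kip3_dT_LZ",
    v_run = 0.76, t_run_mean = 80, t_pause_mean = 110,
    f_cat = 0.05, f_res = 3.2
  ))
  mif2 <- utils::modifyList(wt, list(name = "mif2_like", v_run = 0.56 * 0.71))
  list(WT = wt, kip3_null = k3, kip3_dT_LZ = dtlz, mif2_like = mif2)
}

validate_preset <- function(p) {
  num_pos <- c("v_run", "t_run_mean", "t_pause_mean", "v_tip_track",
               "t_tipmove_mean", "t_tippause_mean", "v_growth",
               "v_depol_free")
  for (f in num_pos) {
    if (is.null(p[[f]]) || !is.numeric(p[[f]]) || length(p[[f]]) != 1 ||
        !is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("preset field '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  for (f in c("f_cat", "f_res")) {
    if (is.null(p[[f]]) || !is.numeric(p[[f]]) || p[[f]] < 0)
      stop("preset field '", f, "' must be a non-negative rate", call. = FALSE)
  }
  if (!is.numeric(p$p_motile) || p$p_motile < 0 || p$p_motile > 1)
    stop("p_motile must lie in [0, 1]", call. = FALSE)
  if (length(p$L0_range) != 2 || any(p$L0_range <= 0) || diff(p$L0_range) < 0)
    stop("L0_range must be an increasing positive length-2 range", call. = FALSE)
  x0 <- p$x0_fraction_range
  if (length(x0) != 2 || x0[1] < 0 || x0[2] >= 1 || diff(x0) < 0)
    stop("x0_fraction_range must be an increasing range within [0, 1)",
         call. = FALSE)
  structure(p, class = "genotype_preset")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat("<genotype_preset> ", x$name, "\n", sep = "")
  cat(sprintf("  lateral: v_run %.2f um/min, dwell run/pause %.0f/%.0f s, p_motile %.2f\n",
              x$v_run, x$t_run_mean, x$t_pause_mean, x$p_motile))
  cat(sprintf("  tip:     v_tip %.2f um/min, dwell move/pause %.0f/%.0f s\n",
              x$v_tip_track, x$t_tipmove_mean, x$t_tippause_mean))
  cat(sprintf("  microtubule: growth %.2f um/min, f_cat %.2f /min, f_res %.2f /min, depol %.2f um/min\n",
              x$v_growth, x$f_cat, x$f_res, x$v_depol_free))
  invisible(x)
}

#' Read or write genotype preset configuration as YAML
#'
#' Presets serialize to a YAML mapping of preset name to field values and
#' round-trip losslessly.
#'
#' @param path file path.
#' @param presets a named list of `genotype_preset` objects (or plain lists
#'   of fields) to write.
#' @return `read_preset_config()` returns a named list suitable for the
#'   `config` argument of [make_preset()]; `write_preset_config()` returns
#'   `path` invisibly.
#' @export
read_preset_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_preset_config
#' @export
write_preset_config <- function(presets, path) {
  stopifnot(is.list(presets), !is.null(names(presets)))
  plain <- lapply(presets, function(p) lapply(unclass(p), identity))
  yaml::write_yaml(plain, path)
  invisible(path)
}
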