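#' Kruskal-Wallis rank-sum comparison of two or more groups
#'
#' Group comparisons use the Kruskal-Wallis rank-based k-sample test (the
#' tie-corrected H statistic with a chi-square reference distribution),
#' the test used throughout the motility quantification. This wraps
#' [stats::kruskal.test()]; the degenerate case where every observation is
#' identical (tie correction factor 0) is defined as H = 0, p = 1.
#'
#' @param groups a named or unnamed list of at least two numeric vectors.
#' @return an object of class `group_comparison`: list with `statistic` (H),
#'   `df`, `p_value`, `test`, `group_labels`, `group_sizes`.
#' @examples
#' kruskal_wallis(list(wt = c(1, 2, 3), mut = c(101, 102, 103)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis needs a list of at least two groups")
  if (any(vapply(groups, length, 0L) < 1))
    stop("every group needs at least one observation")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, 0L)), levels = labels)
  if (length(unique(x)) == 1L) {
    h <- 0; p <- 1; df <- length(groups) - 1L
  } else {
    kt <- stats::kruskal.test(x, g)
    h <- unname(kt$statistic); p <- kt$p.value; df <- unname(kt$parameter)
  }
  structure(list(statistic = h, df = df, p_value = p,
                 test = "Kruskal-Wallis", group_labels = labels,
                 group_sizes = vapply(groups, length, 0L)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: H = %.4g, df = %d, p = %.4g  (%s)\n", x$test,
              x$statistic, x$df, x$p_value,
              paste(sprintf("%s n=%d", x$group_labels, x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Fixed-width histogram with half-open bins
#'
#' Bins values into `[k*w, (k+1)*w)` (values exactly on an edge go to the
#' upper bin), the 0.2-unit binning used for velocity and run-length
#' distributions. Counts always sum to the number of values.
#'
#' @param values numeric vector (NAs dropped).
#' @param bin_width bin width, default 0.2.
#' @return data.frame with `bin_left`, `bin_right`, `count`; empty input
#'   gives an empty data.frame.
#' @examples
#' make_histogram(c(0.1, 0.2, 0.3), 0.2)
#' @export
make_histogram <- function(values, bin_width = 0.2) {
  stopifnot(bin_width > 0)
  values <- values[!is.na(values)]
  if (!length(values))
    return(data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      count = integer(0)))
  k <- floor(values / bin_width + 1e-9)
  rng <- min(k):max(k)
  counts <- tabulate(match(k, rng), nbins = length(rng))
  data.frame(bin_left = rng * bin_width, bin_right = (rng + 1) * bin_width,
             count = counts)
}
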