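#' @title Ensemble summaries and apo/holo comparison
#' @description
#' Summary statistics over descriptor series and two-ensemble comparison
#' reports: difference of means, ratio of standard deviations, and an overlap
#' fraction (how much of one ensemble's values fall inside the other's Tukey
#' fences). These are the quantities that state whether a metal locks a
#' descriptor: a metal-bound ensemble shows both a shifted mean and a
#' markedly smaller spread of the DNA-binding-helix dihedral.
#' @name ensemble
NULL

#' Summary statistics of a descriptor series
#'
#' Mean, sample SD (divisor n-1), extrema, and quartiles (linear-interpolation
#' convention, `stats::quantile` type 7).
#'
#' @param series a [descriptor_series()] (or bare numeric vector)
#' @return object of class `ensemble_summary`
#' @export
summarize_series <- function(series) {
  v <- if (inherits(series, "descriptor_series")) series$values else as.numeric(series)
  if (length(v) < 2)
    stop_mnt("need at least two values to summarise", "mnt_insufficient_data")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(
    name = if (inherits(series, "descriptor_series")) series$name else "series",
    units = if (inherits(series, "descriptor_series")) series$units else "",
    n = length(v), mean = mean(v), sd = stats::sd(v),
    min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v)
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %s: n=%d  mean=%.3f  sd=%.3f  [%.3f | %.3f %.3f %.3f | %.3f] %s\n",
              x$name, x$n, x$mean, x$sd, x$min, x$q1, x$median, x$q3, x$max, x$units))
  invisible(x)
}

tukey_fences <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
}

#' Compare two labelled ensembles on one descriptor
#'
#' Both series must carry the same descriptor name and units. The difference
#' of means is `mean(a) - mean(b)`; the SD ratio is `sd(a) / sd(b)`; the
#' overlap fraction is the fraction of ensemble A's values inside ensemble
#' B's Tukey fences `[q1 - 1.5 IQR, q3 + 1.5 IQR]` (a computable version of
#' "the ensembles occasionally overlap").
#'
#' @param label_a,label_b ensemble labels (e.g. `"apo"`, `"mn"`)
#' @param series_a,series_b [descriptor_series()] objects of the same
#'   descriptor
#' @return object of class `comparison_report`
#' @export
compare_ensembles <- function(label_a, series_a, label_b, series_b) {
  if (inherits(series_a, "descriptor_series") &&
      inherits(series_b, "descriptor_series") &&
      (series_a$units != series_b$units || series_a$name != series_b$name))
    stop_mnt("series measure different descriptors or units", "mnt_unit_error")
  sa <- summarize_series(series_a)
  sb <- summarize_series(series_b)
  va <- if (inherits(series_a, "descriptor_series")) series_a$values else series_a
  fb <- tukey_fences(if (inherits(series_b, "descriptor_series")) series_b$values else series_b)
  structure(list(
    descriptor = sa$name, units = sa$units,
    labels = c(label_a, label_b),
    summary_a = sa, summary_b = sb,
    difference_of_means = sa$mean - sb$mean,
    sd_ratio = sa$sd / sb$sd,
    overlap_fraction = mean(va >= fb[1] & va <= fb[2])
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}

#' Render a comparison report as a plain-text table
#' @param report a `comparison_report`
#' @return character vector of lines
#' @export
format_comparison <- function(report) {
  sa <- report$summary_a; sb <- report$summary_b
  c(sprintf("descriptor: %s (%s)", report$descriptor, report$units),
    sprintf("%-12s %8s %8s %8s %8s", "ensemble", "n", "mean", "sd", "median"),
    sprintf("%-12s %8d %8.3f %8.3f %8.3f", report$labels[1], sa$n, sa$mean, sa$sd, sa$median),
    sprintf("%-12s %8d %8.3f %8.3f %8.3f", report$labels[2], sb$n, sb$mean, sb$sd, sb$median),
    sprintf("difference of means (%s - %s): %.3f", report$labels[1], report$labels[2],
            report$difference_of_means),
    sprintf("sd ratio: %.3f   overlap fraction: %.3f",
            report$sd_ratio, report$overlap_fraction))
}

#' Export a comparison report as JSON
#' @param report a `comparison_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_comparison_json <- function(report, path) {
  strip <- function(s) unclass(s)
  jsonlite::write_json(
    list(descriptor = report$descriptor, units = report$units,
         labels = report$labels,
         summaries = list(strip(report$summary_a), strip(report$summary_b)),
         difference_of_means = report$difference_of_means,
         sd_ratio = report$sd_ratio,
         overlap_fraction = report$overlap_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export boxplot-ready long-format CSV for two ensembles
#' @inheritParams compare_ensembles
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_boxplot_csv <- function(label_a, series_a, label_b, series_b, path) {
  va <- if (inherits(series_a, "descriptor_series")) series_a$values else series_a
  vb <- if (inherits(series_b, "descriptor_series")) series_b$values else series_b
  df <- data.frame(label = c(rep(label_a, length(va)), rep(label_b, length(vb))),
                   value = c(va, vb))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
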