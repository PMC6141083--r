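## Time-series container helpers, running averages and TSV I/O.

#' Construct a Series
#'
#' @param times ps, strictly increasing.
#' @param values scalar values.
#' @param label description, conventionally "quantity_unit".
#' @return a [Series-class].
#' @export
newSeries <- function(times, values, label = "") {
  if (any(diff(times) <= 0))
    oxStop("times must be strictly increasing", "oxfold_domain_error")
  new("Series", times = as.numeric(times), values = as.numeric(values),
      label = label)
}

#' Centered running average of a series
#'
#' For each sample time t the mean of all samples within [t - window/2,
#' t + window/2] (boundaries inclusive), truncated at the series edges.
#' Output times are unchanged.  A window smaller than the sampling
#' interval returns the series unchanged.
#'
#' @param series a [Series-class].
#' @param window full averaging window, ps (e.g. 20 ps for rupture-trace
#'   smoothing).
#' @return a [Series-class].
#' @export
runningAverage <- function(series, window) {
  stopifnot(is(series, "Series"))
  if (window < 0) oxStop("window must be >= 0", "oxfold_domain_error")
  t <- series@times
  v <- series@values
  half <- window / 2 + 1e-9
  out <- vapply(seq_along(t), function(i)
    mean(v[t >= t[i] - half & t <= t[i] + half]), numeric(1))
  new("Series", times = t, values = out, label = series@label)
}

#' Write / read a series as TSV
#'
#' Columns `time_ps`, `value`, `label`.
#'
#' @param series a [Series-class].
#' @param path TSV file.
#' @return `path` invisibly (write) or a [Series-class] (read).
#' @export
writeSeriesTSV <- function(series, path) {
  d <- data.frame(time_ps = series@times, value = series@values,
                  label = series@label)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSeriesTSV
#' @export
readSeriesTSV <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  newSeries(d$time_ps, d$value,
            if ("label" %in% names(d)) as.character(d$label[1]) else "")
}
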