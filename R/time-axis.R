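# Month-serial time axis shared by all gridded and regional series.
# Convention: t = 12*(year - y0) + month, 1-based within an object whose
# first month is (y0, 1). All series in one analysis share a common axis.

#' Build a contiguous monthly time axis
#'
#' @param start_year first calendar year.
#' @param n_months number of months, starting in January of `start_year`.
#' @return data.frame with integer columns `year` and `month` (1-12).
#' @export
month_axis <- function(start_year, n_months) {
  stopifnot(n_months >= 1)
  t <- seq_len(n_months) - 1L
  data.frame(year = as.integer(start_year + t %/% 12L),
             month = as.integer(t %% 12L + 1L))
}

#' Serial month index of (year, month) on an axis starting at `y0` January
#' @param year,month integer vectors.
#' @param y0 first year of the axis.
#' @return 1-based serial index.
#' @export
month_index <- function(year, month, y0) {
  12L * (as.integer(year) - as.integer(y0)) + as.integer(month)
}

# logical mask of axis rows whose year lies in the closed window [w1, w2]
in_window <- function(axis, window) {
  axis$year >= window[1] & axis$year <= window[2]
}

check_window <- function(axis, window) {
  if (length(window) != 2 || window[1] > window[2])
    stop("window must be c(start_year, end_year) with start <= end")
  if (window[1] < min(axis$year) || window[2] > max(axis$year))
    stop("window [", window[1], ", ", window[2],
         "] lies outside the series span [", min(axis$year), ", ",
         max(axis$year), "]")
  invisible(window)
}
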