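# Gridded monthly fields on an aligned 1-degree grid.
# Cell (i, j) spans [-90+i-1, -90+i) x [-180+j-1, -180+j) degrees
# (half-open, 1-based indices); centers sit at half-degrees.

#' Construct a gridded monthly field
#'
#' Container for monthly values on the aligned 1-degree grid. Emission
#' fields carry Tg C/month per cell; VPD fields carry hPa.
#'
#' @param values numeric array `[n_time, n_lat, n_lon]`; `NA` marks missing.
#' @param start_year calendar year of the first (January) time slice.
#' @param what `"emissions"` or `"vpd"`; sets units and the subclass.
#' @return object of class `grid_field` (and `emission_field`/`vpd_field`).
#' @export
grid_field <- function(values, start_year, what = c("emissions", "vpd")) {
  what <- match.arg(what)
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (what == "emissions" && any(values < 0, na.rm = TRUE))
    stop("emission values must be non-negative")
  n_time <- dim(values)[1]
  axis <- month_axis(start_year, n_time)
  structure(
    list(values = values,
         axis = axis,
         lat = -90 + seq_len(dim(values)[2]) - 0.5,
         lon = -180 + seq_len(dim(values)[3]) - 0.5,
         units = if (what == "emissions") "Tg C/month" else "hPa",
         what = what),
    class = c(if (what == "emissions") "emission_field" else "vpd_field",
              "grid_field"))
}

#' @export
print.grid_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s field> %d months (%d-%02d to %d-%02d), %d x %d grid [%s]\n",
              x$what, d[1], x$axis$year[1], x$axis$month[1],
              x$axis$year[d[1]], x$axis$month[d[1]], d[2], d[3], x$units))
  invisible(x)
}

#' Dimensions of a gridded field
#' @param field a `grid_field`.
#' @return integer vector (n_time, n_lat, n_lon).
#' @export
field_dim <- function(field) dim(field$values)

#' Calendar-year sums of a gridded field
#'
#' @param field an `emission_field`.
#' @param window optional `c(start_year, end_year)` restriction.
#' @return array `[n_years, n_lat, n_lon]` of annual totals (Tg C/yr per
#'   cell); missing months count as zero, matching how regional sums treat
#'   missing emissions.
#' @export
annual_sums <- function(field, window = NULL) {
  axis <- field$axis
  keep <- if (is.null(window)) rep(TRUE, nrow(axis)) else in_window(axis, window)
  yrs <- sort(unique(axis$year[keep]))
  v <- field$values
  v[is.na(v)] <- 0
  out <- array(0, c(length(yrs), dim(v)[2], dim(v)[3]))
  for (k in seq_along(yrs)) {
    rows <- which(keep & axis$year == yrs[k])
    out[k, , ] <- colSums(v[rows, , , drop = FALSE], dims = 1)
  }
  dimnames(out) <- list(year = yrs, NULL, NULL)
  out
}

# cosine-latitude area weights for a set of 1-degree row indices
coslat_weights <- function(lat_centers) {
  w <- cos(lat_centers * pi / 180)
  pmax(w, 0)
}
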