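# Readers and writers for the system's artifacts: NetCDF for gridded
# monthly fields and masks (CF-style time axis in months since the first
# January), CSV for index series, forecasts and reports, CSV+JSON for
# lookup tables. All reader/writer pairs are inverses on valid input.

nc_time_vals <- function(axis) {
  y0 <- axis$year[1]
  month_index(axis$year, axis$month, y0) - 1L
}

#' Write a gridded monthly field to NetCDF
#'
#' Dimensions `(lon, lat, time)`; time is `months since <y0>-01-01` and must
#' be contiguous monthly. Missing values are stored with a fill value.
#'
#' @param field a `grid_field`.
#' @param path output path; `variable` NetCDF variable name (defaults to
#'   `"emissions"`/`"vpd"` by field type).
#' @return `path`, invisibly.
#' @export
write_grid <- function(field, path, variable = field$what) {
  d <- field_dim(field)
  y0 <- field$axis$year[1]
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dim_time <- ncdf4::ncdim_def("time", sprintf("months since %d-01-01", y0),
                               nc_time_vals(field$axis), unlim = TRUE)
  var <- ncdf4::ncvar_def(variable, field$units,
                          list(dim_lon, dim_lat, dim_time),
                          missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, aperm(field$values, c(3, 2, 1)))
  ncdf4::ncatt_put(nc, 0, "start_year", y0)
  ncdf4::ncatt_put(nc, 0, "field_what", field$what)
  invisible(path)
}

#' Read a gridded monthly field from NetCDF
#'
#' @param path file written by [write_grid()] (or any file with a
#'   `(lon, lat, time)` variable and a monthly `months since` time axis).
#' @param variable variable name; must exist in the file.
#' @return a `grid_field`.
#' @export
read_grid <- function(path, variable) {
  if (!file.exists(path)) stop("no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop("variable '", variable, "' not present in ", path)
  tdef <- nc$dim$time
  tu <- tdef$units
  if (!grepl("^months since ", tu))
    stop("unsupported time units (need 'months since ...'): ", tu)
  tv <- as.integer(tdef$vals)
  if (length(tv) > 1 && any(diff(tv) != 1L))
    stop("time axis is not contiguous monthly")
  y0 <- as.integer(substr(sub("^months since ", "", tu), 1, 4)) +
    tv[1] %/% 12L
  m0 <- tv[1] %% 12L   # offset within the first year (0 = January)
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  vals <- aperm(vals, c(3, 2, 1))
  what <- ncdf4::ncatt_get(nc, 0, "field_what")
  what <- if (isTRUE(what$hasatt)) what$value
          else if (variable == "vpd") "vpd" else "emissions"
  f <- grid_field(vals, y0, what)
  if (m0 != 0) {                       # non-January start: rebuild the axis
    f$axis <- data.frame(year = y0 + (tv + m0) %/% 12L,
                         month = (tv + m0) %% 12L + 1L)
  }
  f
}

#' Write / read an integer grid mask (country codes or FCR ids)
#' @param mask integer matrix `[n_lat, n_lon]` (`NA` allowed).
#' @param path file path; `variable` NetCDF variable name.
#' @return the path (write) or the integer matrix (read).
#' @export
write_mask <- function(mask, path, variable = "mask") {
  n_lat <- nrow(mask); n_lon <- ncol(mask)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east",
                              -180 + seq_len(n_lon) - 0.5)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north",
                              -90 + seq_len(n_lat) - 0.5)
  var <- ncdf4::ncvar_def(variable, "", list(dim_lon, dim_lat),
                          missval = -1L, prec = "integer")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, t(mask))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, variable = "mask") {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  m <- t(ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)[, , drop = TRUE])
  storage.mode(m) <- "integer"
  m
}

#' Write / read an OCI set as CSV
#'
#' Columns: `year`, `month`, then one column per index.
#'
#' @param ocis an `oci_set`; `path` file path.
#' @param exclude index names to mark unusable on read (never selectable as
#'   predictors).
#' @return the path (write) or an `oci_set` (read).
#' @export
write_oci_csv <- function(ocis, path) {
  df <- cbind(ocis$axis, as.data.frame(ocis$values))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oci_csv
#' @export
read_oci_csv <- function(path, exclude = character(0)) {
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("year", "month") %in% names(df)))
    stop("OCI CSV must declare year and month columns")
  idx <- setdiff(names(df), c("year", "month"))
  if (!length(idx)) stop("OCI CSV declares no index columns")
  vals <- as.matrix(df[, idx, drop = FALSE])
  t0 <- month_index(df$year, df$month, df$year[1])
  if (any(diff(t0) != 1L)) stop("OCI time axis is not contiguous monthly")
  out <- oci_set(vals, df$year[1], usable_names = setdiff(idx, exclude))
  out$axis <- df[, c("year", "month")]
  out
}

#' Write / read the optimal-predictor lookup (CSV and JSON)
#'
#' Both serializations carry identical content; duplicate (fcr_id, lead)
#' rows are an integrity error on read.
#'
#' @param lookup data.frame from [build_lookup()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @param path file to read (`.json` or `.csv` by extension).
#' @return paths (write) or the lookup data.frame (read).
#' @export
write_lookup <- function(lookup, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(lookup, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(lookup, json_path, dataframe = "rows", digits = NA,
                         na = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  lookup <- if (grepl("\\.json$", path))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else read.csv(path)
  if (anyDuplicated(lookup[, c("fcr_id", "lead")]))
    stop("duplicate (fcr_id, lead) rows in lookup: integrity error")
  lookup
}

#' Write / read forecast records as CSV
#'
#' Rows are sorted by (fcr_id, origin, lead).
#'
#' @param records a `forecast_records` data.frame; `path` file path.
#' @return the path (write) or the records (read).
#' @export
write_forecasts <- function(records, path) {
  records <- records[order(records$fcr_id, records$origin_year,
                           records$origin_month, records$lead), ]
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forecasts
#' @export
read_forecasts <- function(path) {
  out <- read.csv(path)
  class(out) <- c("forecast_records", "data.frame")
  out
}

#' Write an FCR map: NetCDF id grid plus CSV region table
#'
#' @param fcr_map an `fcr_map`.
#' @param nc_path NetCDF output (variables `fcr_id` and `level_code`,
#'   with levels 1/2/4/8 coded as themselves and `8r` as 9).
#' @param csv_path region-table CSV (fcr_id, level, country, n_cells,
#'   mean_annual).
#' @return the paths, invisibly.
#' @export
write_fcr_map <- function(fcr_map, nc_path, csv_path) {
  level_code <- matrix(NA_integer_, fcr_map$n_lat, fcr_map$n_lon)
  codes <- c(`1` = 1L, `2` = 2L, `4` = 4L, `8` = 8L, `8r` = 9L)
  for (i in seq_len(nrow(fcr_map$regions))) {
    r <- fcr_map$regions[i, ]
    level_code[fcr_map$fcr_id == r$fcr_id] <- codes[[r$level]]
  }
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east",
                              -180 + seq_len(fcr_map$n_lon) - 0.5)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north",
                              -90 + seq_len(fcr_map$n_lat) - 0.5)
  v1 <- ncdf4::ncvar_def("fcr_id", "", list(dim_lon, dim_lat),
                         missval = -1L, prec = "integer")
  v2 <- ncdf4::ncvar_def("level_code", "", list(dim_lon, dim_lat),
                         missval = -1L, prec = "integer")
  nc <- ncdf4::nc_create(nc_path, list(v1, v2))
  ncdf4::ncvar_put(nc, v1, t(fcr_map$fcr_id))
  ncdf4::ncvar_put(nc, v2, t(level_code))
  ncdf4::nc_close(nc)
  write.csv(fcr_map$regions, csv_path, row.names = FALSE)
  invisible(c(nc = nc_path, csv = csv_path))
}
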