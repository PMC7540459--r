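# Monthly climatology and the bounded anomaly transform.
# Emission anomalies are standardized per calendar month and mapped through
# a scaled hyperbolic tangent, y_hat = 2*tanh((y - mean_m)/(2*sd_m)), which
# confines them to [-2, 2] and tames the right-skewed marginal distribution
# of fire emissions; VPD is only standardized (its marginal is near-normal).

#' Monthly climatology of a regional series
#'
#' Across-year mean and sample (n-1) standard deviation of each calendar
#' month's values, computed strictly inside the development window.
#'
#' @param y numeric vector of monthly values.
#' @param axis data.frame with `year`/`month`, same length as `y`.
#' @param dev_window `c(start_year, end_year)`.
#' @return a `monthly_clim`: list with `mean[12]`, `sd[12]`, `dev_window`.
#' @export
monthly_climatology <- function(y, axis, dev_window) {
  check_window(axis, dev_window)
  keep <- in_window(axis, dev_window)
  mu <- sg <- numeric(12)
  for (m in 1:12) {
    v <- y[keep & axis$month == m]
    if (length(v) < 2)
      stop("fewer than 2 samples for month ", m, " in the development window")
    mu[m] <- mean(v); sg[m] <- sd(v)
  }
  structure(list(mean = mu, sd = sg, dev_window = dev_window),
            class = "monthly_clim")
}

#' Standardize-and-tanh transform of monthly emissions
#'
#' `y_hat = 2*tanh((y - mean_m)/(2*sd_m))`; months with zero climatological
#' sd map to 0. The result is bounded to `[-2, 2]`.
#'
#' @param y monthly emissions (Tg C/month).
#' @param axis time axis of `y`.
#' @param clim a [monthly_climatology()].
#' @return numeric vector of transformed anomalies.
#' @export
transform_anomaly <- function(y, axis, clim) {
  m <- axis$month
  sg <- clim$sd[m]
  out <- ifelse(sg > 0, 2 * tanh((y - clim$mean[m]) / (2 * sg)), 0)
  out[is.na(y)] <- NA_real_
  out
}

#' Inverse of the anomaly transform
#'
#' `y = mean_m + 2*sd_m*atanh(y_hat/2)`, with the argument of `atanh`
#' clipped to `1 - 1e-6` in magnitude (the forward map saturates) and the
#' result floored at 0 Tg C/month (emissions are non-negative).
#'
#' @param y_hat transformed anomalies.
#' @param axis time axis of `y_hat`.
#' @param clim a [monthly_climatology()].
#' @return emissions on the original scale.
#' @export
inverse_transform <- function(y_hat, axis, clim) {
  m <- axis$month
  z <- pmax(pmin(y_hat / 2, 1 - 1e-6), -(1 - 1e-6))
  out <- ifelse(clim$sd[m] > 0,
                clim$mean[m] + 2 * clim$sd[m] * atanh(z),
                clim$mean[m])
  pmax(out, 0)
}

#' Standardize a VPD series against its monthly climatology
#'
#' `z = (v - mean_m)/sd_m`; months with zero sd map to 0. No tanh here.
#'
#' @param v monthly VPD (hPa).
#' @param axis time axis of `v`.
#' @param clim a [monthly_climatology()] of the VPD series.
#' @return standardized series (unitless).
#' @export
standardize_vpd <- function(v, axis, clim) {
  m <- axis$month
  sg <- clim$sd[m]
  out <- ifelse(sg > 0, (v - clim$mean[m]) / sg, 0)
  out[is.na(v)] <- NA_real_
  out
}

#' Climatologies for every region in a `region_series`
#'
#' @param rs a `region_series`.
#' @param dev_window development years.
#' @return list with `emissions` and (if present) `vpd`: each a list of
#'   [monthly_climatology()] objects indexed by region.
#' @export
region_climatologies <- function(rs, dev_window) {
  em <- lapply(seq_along(rs$fcr_ids), function(k)
    monthly_climatology(rs$emissions[, k], rs$axis, dev_window))
  names(em) <- rs$fcr_ids
  vp <- NULL
  if (!is.null(rs$vpd)) {
    vp <- lapply(seq_along(rs$fcr_ids), function(k)
      monthly_climatology(rs$vpd[, k], rs$axis, dev_window))
    names(vp) <- rs$fcr_ids
  }
  list(emissions = em, vpd = vp, dev_window = dev_window)
}

#' Transformed targets and standardized VPD for every region
#'
#' @param rs a `region_series`.
#' @param clims output of [region_climatologies()].
#' @return list with `y_hat` (matrix `[n_time, n_fcr]` of transformed
#'   emission anomalies) and `vpd_z` (standardized VPD, or `NULL`).
#' @export
region_anomalies <- function(rs, clims) {
  y_hat <- sapply(seq_along(rs$fcr_ids), function(k)
    transform_anomaly(rs$emissions[, k], rs$axis, clims$emissions[[k]]))
  y_hat <- matrix(y_hat, nrow = nrow(rs$emissions))
  colnames(y_hat) <- rs$fcr_ids
  vpd_z <- NULL
  if (!is.null(rs$vpd)) {
    vpd_z <- sapply(seq_along(rs$fcr_ids), function(k)
      standardize_vpd(rs$vpd[, k], rs$axis, clims$vpd[[k]]))
    vpd_z <- matrix(vpd_z, nrow = nrow(rs$vpd))
    colnames(vpd_z) <- rs$fcr_ids
  }
  list(y_hat = y_hat, vpd_z = vpd_z)
}
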