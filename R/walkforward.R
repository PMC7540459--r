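# Walk-forward forecasting. Every month of the prediction window is a
# forecast origin: coefficients are re-optimized on all data available at
# the origin (hyperparameters stay frozen from the development window), the
# model is iterated 1-6 steps ahead through the Kalman recursions, and the
# bounded anomaly prediction is mapped back to emissions.

VARIANTS <- c("OCIVPDAR", "OCIAR", "VPDAR", "ARonly", "Xonly",
              "Clim", "Persistence")

#' Forecast-model variant specification
#'
#' The seven model configurations compared by the system: the full ARIMAX
#' with both exogenous predictors, single-predictor and AR-only reductions,
#' a pure regression (`Xonly`, orders forced to zero), and the climatology
#' and persistence baselines.
#'
#' @param name one of `"OCIVPDAR"`, `"OCIAR"`, `"VPDAR"`, `"ARonly"`,
#'   `"Xonly"`, `"Clim"`, `"Persistence"`.
#' @return list with `name`, `use_oci`, `use_vpd`, `arima` (`"optimal"`,
#'   `"zero"`, or `"none"`).
#' @export
variant_spec <- function(name) {
  name <- match.arg(name, VARIANTS)
  switch(name,
    OCIVPDAR    = list(name = name, use_oci = TRUE,  use_vpd = TRUE,  arima = "optimal"),
    OCIAR       = list(name = name, use_oci = TRUE,  use_vpd = FALSE, arima = "optimal"),
    VPDAR       = list(name = name, use_oci = FALSE, use_vpd = TRUE,  arima = "optimal"),
    ARonly      = list(name = name, use_oci = FALSE, use_vpd = FALSE, arima = "optimal"),
    Xonly       = list(name = name, use_oci = TRUE,  use_vpd = TRUE,  arima = "zero"),
    Clim        = list(name = name, use_oci = FALSE, use_vpd = FALSE, arima = "none"),
    Persistence = list(name = name, use_oci = FALSE, use_vpd = FALSE, arima = "none"))
}

# lag-shifted exogenous matrix over the full axis for one region and lead:
# column value at t is the predictor observed at t - lag (NA before that).
shifted_exog <- function(entry, spec, oci_values, vpd_z_col, n_time) {
  cols <- list()
  if (spec$use_oci && !is.na(entry$oci_name) &&
      entry$oci_name %in% colnames(oci_values)) {
    x <- oci_values[, entry$oci_name]
    lag <- entry$oci_lag
    cols$oci <- c(rep(NA_real_, lag), x[seq_len(n_time - lag)])
  }
  if (spec$use_vpd && !is.null(vpd_z_col) && !is.na(entry$vpd_lag)) {
    lag <- entry$vpd_lag
    cols$vpd <- c(rep(NA_real_, lag), vpd_z_col[seq_len(n_time - lag)])
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Select frozen ARIMAX orders per region and lead
#'
#' AIC order selection on development-window data with the lead-specific
#' exogenous columns of one variant; the chosen orders are frozen and used
#' unchanged at every forecast origin.
#'
#' @param y_hat matrix of transformed anomalies `[n_time, n_fcr]`.
#' @param ocis an `oci_set`; `vpd_z` standardized VPD matrix or `NULL`.
#' @param lag_lookup output of [build_lookup()].
#' @param axis shared time axis; `dev_window` development years.
#' @param leads integer leads.
#' @param variant variant name whose exogenous structure is used
#'   (default `"OCIVPDAR"`).
#' @param method estimation method for the candidate fits.
#' @param vpd_z standardized VPD matrix or `NULL`.
#' @return data.frame: fcr_id, lead, p, d, q.
#' @export
build_order_lookup <- function(y_hat, ocis, vpd_z = NULL, lag_lookup, axis,
                               dev_window, leads = 1:6,
                               variant = "OCIVPDAR", method = "CSS-ML") {
  spec <- variant_spec(variant)
  if (spec$arima != "optimal")
    stop("order lookup applies only to variants with optimal orders")
  fcr_ids <- as.integer(colnames(y_hat))
  dev_rows <- which(in_window(axis, dev_window))
  n_time <- nrow(y_hat)
  rows <- list()
  for (k in seq_along(fcr_ids)) {
    for (L in leads) {
      entry <- lag_lookup[lag_lookup$fcr_id == fcr_ids[k] &
                            lag_lookup$lead == L, ]
      X <- shifted_exog(entry, spec, ocis$values,
                        if (is.null(vpd_z)) NULL else vpd_z[, k], n_time)
      use <- dev_rows
      if (!is.null(X)) use <- use[rowSums(is.na(X[use, , drop = FALSE])) == 0]
      sel <- select_order(y_hat[use, k],
                          if (is.null(X)) NULL else X[use, , drop = FALSE],
                          method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        fcr_id = fcr_ids[k], lead = L,
        p = sel$order[1], d = sel$order[2], q = sel$order[3])
    }
  }
  do.call(rbind, rows)
}

#' Forecasts from a single origin for one region
#'
#' Fits on all transformed anomalies up to the origin (with the
#' lead-specific lag-shifted exogenous columns) and iterates the model
#' `L` steps ahead per lead. Anomalies are clipped to `[-2, 2]` and mapped
#' back to emissions with the development-period climatology.
#'
#' @param y_hat full transformed anomaly series of the region.
#' @param axis time axis of `y_hat`.
#' @param t0 origin as a serial row index into `axis` (forecast date).
#' @param variant variant name.
#' @param lag_entries rows of the lag lookup for this region (all leads).
#' @param order_entries rows of the order lookup for this region, or `NULL`
#'   for variants without an ARIMA part.
#' @param oci_values matrix of OCI series; `vpd_z_col` the region's
#'   standardized VPD series (or `NULL`).
#' @param clim the region's emission [monthly_climatology()].
#' @param leads integer leads.
#' @param refit_method estimation method for the per-origin refits
#'   (default `"CSS"`; see the methods vignette).
#' @return data.frame of records: origin_year, origin_month, lead,
#'   target_year, target_month, variant, anomaly_pred, emission_pred,
#'   fallback (TRUE when the frozen order failed to converge at this
#'   origin and (0,0,0) was substituted).
#' @export
forecast_origin <- function(y_hat, axis, t0, variant, lag_entries = NULL,
                            order_entries = NULL, oci_values = NULL,
                            vpd_z_col = NULL, clim, leads = 1:6,
                            refit_method = "CSS") {
  spec <- variant_spec(variant)
  n_time <- length(y_hat)
  stopifnot(t0 >= 1, t0 <= n_time)
  origin <- axis[t0, ]
  out <- vector("list", length(leads))
  for (li in seq_along(leads)) {
    L <- leads[li]
    tm <- 12L * origin$year + (origin$month - 1L) + L   # absolute month
    target_year <- tm %/% 12L
    target_month <- tm %% 12L + 1L
    fallback <- FALSE
    if (spec$name == "Clim") {
      anom <- 0
    } else if (spec$name == "Persistence") {
      anom <- y_hat[t0]
    } else {
      entry <- lag_entries[lag_entries$lead == L, ]
      X <- shifted_exog(entry, spec, oci_values, vpd_z_col, n_time)
      ord <- if (spec$arima == "zero") c(0L, 0L, 0L) else {
        oe <- order_entries[order_entries$lead == L, ]
        c(oe$p, oe$d, oe$q)
      }
      start <- 1L
      if (!is.null(X)) {
        defined <- rowSums(is.na(X)) == 0
        start <- which(defined)[1]
      }
      ytr <- y_hat[start:t0]
      Xtr <- if (is.null(X)) NULL else X[start:t0, , drop = FALSE]
      fit <- fit_arimax(ytr, Xtr, ord, method = refit_method)
      if (!fit$converged && !all(ord == 0L)) {
        fallback <- TRUE
        fit <- fit_arimax(ytr, Xtr, c(0L, 0L, 0L), method = refit_method)
      }
      if (fit$converged) {
        Xnew <- if (is.null(X)) NULL else {
          idx <- t0 + seq_len(L)
          if (max(idx) > n_time) {   # extend shifted columns past the record
            ext <- matrix(NA_real_, max(idx) - n_time, ncol(X),
                          dimnames = list(NULL, colnames(X)))
            for (cn in colnames(X)) {
              lag <- if (cn == "oci") entry$oci_lag else entry$vpd_lag
              src <- if (cn == "oci") oci_values[, entry$oci_name] else vpd_z_col
              for (r in seq_len(nrow(ext)))
                ext[r, cn] <- src[n_time + r - lag]
            }
            rbind(X, ext)[idx, , drop = FALSE]
          } else X[idx, , drop = FALSE]
        }
        anom <- predict_arimax(fit, L, Xnew)[L]
      } else {
        fallback <- TRUE
        anom <- 0                     # degenerate origin: climatology value
      }
    }
    anom <- max(min(anom, 2), -2)
    target_axis <- data.frame(year = target_year, month = target_month)
    emis <- inverse_transform(anom, target_axis, clim)
    out[[li]] <- data.frame(origin_year = origin$year,
                            origin_month = origin$month,
                            lead = L, target_year = target_year,
                            target_month = target_month,
                            variant = spec$name,
                            anomaly_pred = anom, emission_pred = emis,
                            fallback = fallback)
  }
  do.call(rbind, out)
}

#' Run one variant's walk-forward sweep over all regions
#'
#' @param anom output of [region_anomalies()] (`y_hat`, `vpd_z`).
#' @param clims output of [region_climatologies()].
#' @param ocis an `oci_set`.
#' @param lag_lookup output of [build_lookup()].
#' @param order_lookup output of [build_order_lookup()] for this variant
#'   (ignored for variants without an ARIMA part; `Xonly` forces zeros).
#' @param axis shared time axis.
#' @param prediction_window `c(start_year, end_year)`; every month inside
#'   is a forecast origin.
#' @param variant variant name; `leads` integer leads.
#' @param refit_method estimation method for per-origin refits.
#' @return `forecast_records` data.frame with one row per
#'   (region, origin, lead): columns fcr_id, origin/target dates, variant,
#'   anomaly_pred, emission_pred, fallback, verifiable (target month inside
#'   the observed record).
#' @export
run_variant <- function(anom, clims, ocis, lag_lookup, order_lookup = NULL,
                        axis, prediction_window, variant, leads = 1:6,
                        refit_method = "CSS") {
  spec <- variant_spec(variant)
  check_window(axis, prediction_window)
  fcr_ids <- as.integer(colnames(anom$y_hat))
  origins <- which(in_window(axis, prediction_window))
  n_time <- nrow(anom$y_hat)
  res <- vector("list", length(fcr_ids))
  if (spec$name %in% c("Clim", "Persistence")) {
    # baselines have closed forms; build their records vectorized
    ogrid <- expand.grid(lead = leads, t0 = origins)
    tm <- 12L * axis$year[ogrid$t0] + (axis$month[ogrid$t0] - 1L) + ogrid$lead
    for (k in seq_along(fcr_ids)) {
      anomaly <- if (spec$name == "Clim") rep(0, nrow(ogrid))
                 else pmax(pmin(anom$y_hat[ogrid$t0, k], 2), -2)
      target_axis <- data.frame(year = tm %/% 12L, month = tm %% 12L + 1L)
      res[[k]] <- data.frame(
        fcr_id = fcr_ids[k], origin_year = axis$year[ogrid$t0],
        origin_month = axis$month[ogrid$t0], lead = ogrid$lead,
        target_year = target_axis$year, target_month = target_axis$month,
        variant = spec$name, anomaly_pred = anomaly,
        emission_pred = inverse_transform(anomaly, target_axis,
                                          clims$emissions[[k]]),
        fallback = FALSE)
    }
    out <- do.call(rbind, res)
    tmax <- 12L * axis$year[n_time] + axis$month[n_time]
    out$verifiable <- 12L * out$target_year + out$target_month <= tmax
    out <- out[order(out$fcr_id, out$origin_year, out$origin_month,
                     out$lead), ]
    rownames(out) <- NULL
    class(out) <- c("forecast_records", "data.frame")
    return(out)
  }
  for (k in seq_along(fcr_ids)) {
    id <- fcr_ids[k]
    le <- lag_lookup[lag_lookup$fcr_id == id, ]
    oe <- if (spec$arima == "optimal")
            order_lookup[order_lookup$fcr_id == id, ] else NULL
    vz <- if (is.null(anom$vpd_z)) NULL else anom$vpd_z[, k]
    per_origin <- lapply(origins, function(t0)
      forecast_origin(anom$y_hat[, k], axis, t0, variant, le, oe,
                      ocis$values, vz, clims$emissions[[k]], leads,
                      refit_method))
    rk <- do.call(rbind, per_origin)
    rk <- cbind(data.frame(fcr_id = id), rk)
    res[[k]] <- rk
  }
  out <- do.call(rbind, res)
  tmax <- 12L * axis$year[n_time] + axis$month[n_time]
  out$verifiable <- 12L * out$target_year + out$target_month <= tmax
  out <- out[order(out$fcr_id, out$origin_year, out$origin_month, out$lead), ]
  rownames(out) <- NULL
  class(out) <- c("forecast_records", "data.frame")
  out
}

#' In-sample one-step-ahead hindcast over the development window
#'
#' Fits each region's model once on the full development data and returns
#' the Kalman one-step-ahead fitted values (observation minus innovation)
#' as lead-1 records.
#'
#' @inheritParams run_variant
#' @param dev_window development years.
#' @return `forecast_records` data.frame (lead 1, in-sample).
#' @export
hindcast_insample <- function(anom, clims, ocis, lag_lookup,
                              order_lookup = NULL, axis, dev_window,
                              variant = "OCIVPDAR") {
  spec <- variant_spec(variant)
  fcr_ids <- as.integer(colnames(anom$y_hat))
  dev_rows <- which(in_window(axis, dev_window))
  n_time <- nrow(anom$y_hat)
  res <- list()
  for (k in seq_along(fcr_ids)) {
    id <- fcr_ids[k]
    y <- anom$y_hat[, k]
    clim <- clims$emissions[[k]]
    if (spec$name %in% c("Clim", "Persistence")) {
      fitted_anom <- if (spec$name == "Clim") rep(0, length(dev_rows))
        else c(0, y[dev_rows[-length(dev_rows)]])
      use <- dev_rows
    } else {
      entry <- lag_lookup[lag_lookup$fcr_id == id & lag_lookup$lead == 1, ]
      X <- shifted_exog(entry, spec, ocis$values,
                        if (is.null(anom$vpd_z)) NULL else anom$vpd_z[, k],
                        n_time)
      ord <- if (spec$arima == "zero") c(0L, 0L, 0L) else {
        oe <- order_lookup[order_lookup$fcr_id == id & order_lookup$lead == 1, ]
        c(oe$p, oe$d, oe$q)
      }
      use <- dev_rows
      if (!is.null(X)) use <- use[rowSums(is.na(X[use, , drop = FALSE])) == 0]
      fit <- fit_arimax(y[use], if (is.null(X)) NULL else X[use, , drop = FALSE],
                        ord, method = "CSS-ML")
      if (!fit$converged)
        fit <- fit_arimax(y[use], if (is.null(X)) NULL
                          else X[use, , drop = FALSE], c(0L, 0L, 0L))
      fitted_anom <- y[use] - as.numeric(residuals(fit$model))
    }
    fitted_anom <- pmax(pmin(fitted_anom, 2), -2)
    ax <- axis[use, ]
    res[[length(res) + 1L]] <- data.frame(
      fcr_id = id, origin_year = ax$year, origin_month = ax$month,
      lead = 1L, target_year = ax$year, target_month = ax$month,
      variant = spec$name, anomaly_pred = fitted_anom,
      emission_pred = inverse_transform(fitted_anom, ax, clim),
      fallback = FALSE, verifiable = TRUE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("forecast_records", "data.frame")
  out
}
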