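# Lagged cross-correlation analysis and the per-region, per-lead lookup of
# the optimal OCI (type + lag) and optimal VPD lag. Diagnostics scan lags
# 0-11; operational selection for lead L is restricted to lags in [L, 11]
# so every selected predictor is observed by the forecast origin.

#' Lagged cross-correlations of a target with one predictor
#'
#' Pearson correlation of pairs `(y[t], x[t - lag])` over months `t` inside
#' the development window where both are defined, for each lag.
#'
#' @param target monthly target series (transformed anomalies).
#' @param predictor monthly predictor series on the same axis.
#' @param axis shared time axis.
#' @param dev_window development years.
#' @param lags integer lags (default 0:11).
#' @return data.frame with `lag`, `r`, `n`, and `flag` (`TRUE` when the
#'   correlation is undefined - zero variance or too few pairs - in which
#'   case `r` is reported as 0).
#' @export
lagged_xcorr <- function(target, predictor, axis, dev_window, lags = 0:11) {
  check_window(axis, dev_window)
  keep <- which(in_window(axis, dev_window))
  out <- data.frame(lag = lags, r = 0, n = 0L, flag = FALSE)
  for (k in seq_along(lags)) {
    lag <- lags[k]
    t_ok <- keep[keep - lag >= 1]
    y <- target[t_ok]; x <- predictor[t_ok - lag]
    ok <- is.finite(y) & is.finite(x)
    y <- y[ok]; x <- x[ok]
    out$n[k] <- length(y)
    if (length(y) < 3 || sd(y) == 0 || sd(x) == 0) {
      out$flag[k] <- TRUE
    } else {
      out$r[k] <- cor(y, x)
    }
  }
  out
}

#' Select the optimal OCI and VPD lags for one region and lead
#'
#' Over lags in `[lead, 11]`, the OCI entry maximizes `|r|` jointly over
#' (usable index, lag); the VPD entry maximizes `|r|` over lag only. Signed
#' correlations are stored. Ties break to the smaller lag, then to the
#' earlier name in the canonical index order (the order of `usable_names`).
#'
#' @param oci_r matrix `[n_oci, 12]` of correlations at lags 0-11, rows
#'   named by index; from [lagged_xcorr()].
#' @param oci_flag logical matrix like `oci_r` marking undefined entries.
#' @param vpd_r,vpd_flag length-12 vectors for the VPD predictor (may be
#'   `NULL` when no VPD is used).
#' @param lead forecast lead in months (1-6).
#' @param usable_names canonical order of selectable indices.
#' @return one-row data.frame: `oci_name`, `oci_lag`, `oci_r`, `vpd_lag`,
#'   `vpd_r`; `NA` entries when every candidate is flagged.
#' @export
select_optimal <- function(oci_r, oci_flag, vpd_r = NULL, vpd_flag = NULL,
                           lead, usable_names = rownames(oci_r)) {
  stopifnot(lead >= 1, lead <= 6)
  lag_cols <- (lead:11) + 1L            # column l+1 holds lag l
  best_oci <- list(name = NA_character_, lag = NA_integer_, r = NA_real_)
  for (col in lag_cols) {               # ascending lag; smaller lag wins ties
    for (nm in usable_names) {          # then canonical index order
      if (oci_flag[nm, col]) next
      r <- oci_r[nm, col]
      if (is.na(best_oci$r) || abs(r) > abs(best_oci$r) + 1e-12) {
        best_oci <- list(name = nm, lag = col - 1L, r = r)
      }
    }
  }
  best_vpd <- list(lag = NA_integer_, r = NA_real_)
  if (!is.null(vpd_r)) {
    for (col in lag_cols) {
      if (vpd_flag[col]) next
      r <- vpd_r[col]
      if (is.na(best_vpd$r) || abs(r) > abs(best_vpd$r) + 1e-12)
        best_vpd <- list(lag = col - 1L, r = r)
    }
  }
  data.frame(oci_name = best_oci$name, oci_lag = best_oci$lag,
             oci_r = best_oci$r, vpd_lag = best_vpd$lag, vpd_r = best_vpd$r)
}

#' Build the optimal-predictor lookup for all regions and leads
#'
#' One entry per (region, lead): the chosen OCI, its lag and correlation,
#' and the chosen VPD lag and correlation, all frozen from the development
#' window. Deterministic given identical inputs.
#'
#' @param y_hat matrix `[n_time, n_fcr]` of transformed emission anomalies.
#' @param ocis an `oci_set` on the same axis.
#' @param vpd_z matrix of standardized regional VPD (or `NULL`).
#' @param axis shared time axis.
#' @param dev_window development years.
#' @param leads integer leads (default 1:6).
#' @param fcr_ids region ids matching the columns of `y_hat`.
#' @return `lag_lookup` data.frame: fcr_id, lead, oci_name, oci_lag, oci_r,
#'   vpd_lag, vpd_r.
#' @export
build_lookup <- function(y_hat, ocis, vpd_z = NULL, axis, dev_window,
                         leads = 1:6,
                         fcr_ids = as.integer(colnames(y_hat))) {
  usable <- ocis$usable_names
  rows <- vector("list", ncol(y_hat) * length(leads))
  pos <- 1L
  for (k in seq_len(ncol(y_hat))) {
    oci_r <- matrix(0, length(usable), 12, dimnames = list(usable, NULL))
    oci_flag <- matrix(TRUE, length(usable), 12, dimnames = list(usable, NULL))
    for (nm in usable) {
      tb <- lagged_xcorr(y_hat[, k], ocis$values[, nm], axis, dev_window)
      oci_r[nm, ] <- tb$r; oci_flag[nm, ] <- tb$flag
    }
    vpd_r <- vpd_flag <- NULL
    if (!is.null(vpd_z)) {
      tb <- lagged_xcorr(y_hat[, k], vpd_z[, k], axis, dev_window)
      vpd_r <- tb$r; vpd_flag <- tb$flag
    }
    for (L in leads) {
      ent <- select_optimal(oci_r, oci_flag, vpd_r, vpd_flag, L, usable)
      rows[[pos]] <- cbind(data.frame(fcr_id = fcr_ids[k], lead = L), ent)
      pos <- pos + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
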