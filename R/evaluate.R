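# Diagnostics (trend, KPSS stationarity, ACF/PACF) and forecast
# verification (anomaly correlation, RMSE, percent RMSE change against the
# climatology baseline, global-sum series, best-model tables). Observed
# anomalies are always measured against the development-period climatology,
# including during the prediction window.

#' Autocorrelation and partial autocorrelation of a monthly series
#'
#' ACF is the lagged sample autocorrelation; PACF comes from the
#' Durbin-Levinson recursion (as implemented by [stats::pacf()]).
#'
#' @param y numeric series (deseasonalized anomalies).
#' @param max_lag maximum lag; series must be longer than `max_lag + 2`.
#' @return list with `acf` (lags 0..max_lag) and `pacf` (lags 1..max_lag);
#'   `flag = TRUE` when the series is constant and both are undefined.
#' @export
acf_pacf <- function(y, max_lag = 24) {
  if (length(y) <= max_lag + 2) stop("series too short for max_lag")
  if (sd(y) == 0)
    return(list(acf = rep(NA_real_, max_lag + 1),
                pacf = rep(NA_real_, max_lag), flag = TRUE))
  a <- as.numeric(acf(y, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf)
  p <- as.numeric(pacf(y, lag.max = max_lag, plot = FALSE)$acf)
  list(acf = a, pacf = p, flag = FALSE)
}

# KPSS statistic: T^-2 * sum(S_t^2) / lrv, with S_t the partial sums of the
# level- or trend-regression residuals and lrv the Bartlett/Newey-West
# long-run variance at bandwidth floor(4*(T/100)^0.25).
kpss_stat <- function(y, type = c("level", "trend")) {
  type <- match.arg(type)
  n <- length(y)
  e <- if (type == "level") y - mean(y) else residuals(lm(y ~ seq_len(n)))
  s <- cumsum(e)
  l <- floor(4 * (n / 100)^0.25)
  g0 <- sum(e^2) / n
  # residuals that are zero to machine precision: perfectly stationary
  if (g0 <= .Machine$double.eps * max(mean(y^2), 1)) return(0)
  lrv <- g0
  if (l > 0) for (j in seq_len(l))
    lrv <- lrv + 2 * (1 - j / (l + 1)) * sum(e[(j + 1):n] * e[1:(n - j)]) / n
  sum(s^2) / (n^2 * lrv)
}

#' Linear trend and KPSS stationarity tests of a regional series
#'
#' The trend slope is an OLS fit of calendar-year totals on year. KPSS
#' statistics are computed for the level and trend null hypotheses on the
#' monthly series and compared with the standard 5 percent critical values
#' (0.463 level, 0.146 trend); rejection means evidence of nonstationarity.
#'
#' @param y monthly emissions; `axis` its time axis (>= 5 years).
#' @param axis time axis data.frame.
#' @return list: `slope` (per year, on annual totals), `kpss_level`,
#'   `kpss_trend`, `reject_level`, `reject_trend`.
#' @export
trend_and_kpss <- function(y, axis) {
  yrs <- sort(unique(axis$year))
  if (length(yrs) < 5) stop("need at least 5 years")
  annual <- vapply(yrs, function(yy) sum(y[axis$year == yy]), 0)
  slope <- unname(coef(lm(annual ~ yrs))[2])
  kl <- kpss_stat(y, "level")
  kt <- kpss_stat(y, "trend")
  list(slope = slope, kpss_level = kl, kpss_trend = kt,
       reject_level = kl > 0.463, reject_trend = kt > 0.146)
}

# observed regional emissions for each record's target month, NA outside
# the observed record
observed_for_records <- function(records, rs) {
  y0 <- rs$axis$year[1]
  t_target <- month_index(records$target_year, records$target_month, y0)
  col <- match(records$fcr_id, as.integer(rs$fcr_ids))
  ok <- t_target >= 1 & t_target <= nrow(rs$emissions) & !is.na(col)
  out <- rep(NA_real_, nrow(records))
  out[ok] <- rs$emissions[cbind(t_target[ok], col[ok])]
  out
}

# climatological mean emission of each record's target month
clim_for_records <- function(records, clims) {
  vapply(seq_len(nrow(records)), function(i)
    clims$emissions[[as.character(records$fcr_id[i])]]$mean[records$target_month[i]],
    0)
}

#' Anomaly correlation of a set of forecast records
#'
#' Pearson correlation between predicted and observed emissions after
#' subtracting the development-period climatological mean of each target
#' month. Only verifiable records enter.
#'
#' @param records `forecast_records` (one variant/lead/scope slice).
#' @param rs the observed `region_series`.
#' @param clims output of [region_climatologies()].
#' @return list with `r` (`NA` with `flag = TRUE` when either side has zero
#'   variance) and `n`.
#' @export
anomaly_corr <- function(records, rs, clims) {
  obs <- observed_for_records(records, rs)
  use <- records$verifiable & !is.na(obs)
  if (sum(use) < 3) return(list(r = NA_real_, n = sum(use), flag = TRUE))
  cm <- clim_for_records(records[use, ], clims)
  pa <- records$emission_pred[use] - cm
  oa <- obs[use] - cm
  if (sd(pa) == 0 || sd(oa) == 0)
    return(list(r = NA_real_, n = sum(use), flag = TRUE))
  list(r = cor(pa, oa), n = sum(use), flag = FALSE)
}

#' RMSE of forecast records against observations
#' @inheritParams anomaly_corr
#' @return list with `rmse` (Tg C/month) and `n`; `NA`/flagged when no
#'   verifiable records exist.
#' @export
rmse_records <- function(records, rs) {
  obs <- observed_for_records(records, rs)
  use <- records$verifiable & !is.na(obs)
  if (!sum(use)) return(list(rmse = NA_real_, n = 0L, flag = TRUE))
  list(rmse = sqrt(mean((records$emission_pred[use] - obs[use])^2)),
       n = sum(use), flag = FALSE)
}

#' Percent RMSE change of a variant relative to the climatology baseline
#'
#' `100 * (variant_rmse - clim_rmse) / clim_rmse`; negative values mean the
#' variant outperforms the climatology.
#'
#' @param variant_rmse,clim_rmse RMSEs on identical record sets.
#' @return percent change.
#' @export
pct_rmse_vs_clim <- function(variant_rmse, clim_rmse) {
  if (!is.finite(clim_rmse) || clim_rmse <= 0)
    stop("climatology RMSE must be positive")
  100 * (variant_rmse - clim_rmse) / clim_rmse
}

#' Global-sum predicted and observed series for one variant and lead
#'
#' Sums `emission_pred` over all regions per target month (months with an
#' incomplete set of regions are dropped) and pairs them with the observed
#' global sums and the summed development-period climatology.
#'
#' @param records `forecast_records` filtered to one variant and lead.
#' @param rs observed `region_series`; `clims` climatologies.
#' @return data.frame: target_year, target_month, predicted, observed,
#'   climatology.
#' @export
global_series <- function(records, rs, clims) {
  rec <- records[records$verifiable, ]
  key <- paste(rec$target_year, rec$target_month)
  n_fcr <- length(rs$fcr_ids)
  counts <- table(key)
  full <- names(counts)[counts == n_fcr]
  rec <- rec[key %in% full, ]
  agg <- stats::aggregate(emission_pred ~ target_year + target_month,
                          rec, sum)
  agg <- agg[order(agg$target_year, agg$target_month), ]
  y0 <- rs$axis$year[1]
  t_target <- month_index(agg$target_year, agg$target_month, y0)
  agg$observed <- rowSums(rs$emissions)[t_target]
  agg$climatology <- vapply(seq_len(nrow(agg)), function(i)
    sum(vapply(clims$emissions, function(cl) cl$mean[agg$target_month[i]], 0)),
    0)
  names(agg)[names(agg) == "emission_pred"] <- "predicted"
  agg
}

#' Skill report over variants, leads and scopes
#'
#' For every (variant, lead) present in `records`: global-scope scores on
#' the global-sum series (anomalies relative to the summed development
#' climatology) and per-region scores, with RMSE, anomaly correlation and
#' percent RMSE change against the `Clim` variant when present.
#'
#' @param records `forecast_records` covering one or more variants.
#' @param rs observed `region_series`; `clims` climatologies.
#' @return data.frame: variant, lead, scope (`"global"` or the fcr id), n,
#'   r_anomaly, rmse, pct_rmse_vs_clim.
#' @export
skill_report <- function(records, rs, clims) {
  combos <- unique(records[, c("variant", "lead")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    v <- combos$variant[i]; L <- combos$lead[i]
    sub <- records[records$variant == v & records$lead == L, ]
    gs <- global_series(sub, rs, clims)
    ganom_p <- gs$predicted - gs$climatology
    ganom_o <- gs$observed - gs$climatology
    g_r <- if (nrow(gs) >= 3 && sd(ganom_p) > 0 && sd(ganom_o) > 0)
      cor(ganom_p, ganom_o) else NA_real_
    g_rmse <- if (nrow(gs)) sqrt(mean((gs$predicted - gs$observed)^2))
      else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, lead = L, scope = "global", n = nrow(gs),
      r_anomaly = g_r, rmse = g_rmse)
    for (id in rs$fcr_ids) {
      rsub <- sub[sub$fcr_id == id, ]
      ac <- anomaly_corr(rsub, rs, clims)
      rm <- rmse_records(rsub, rs)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, lead = L, scope = as.character(id), n = rm$n,
        r_anomaly = ac$r, rmse = rm$rmse)
    }
  }
  out <- do.call(rbind, rows)
  out$pct_rmse_vs_clim <- NA_real_
  if ("Clim" %in% out$variant) {
    base <- out[out$variant == "Clim", c("lead", "scope", "rmse")]
    names(base)[3] <- "clim_rmse"
    out <- merge(out, base, by = c("lead", "scope"), all.x = TRUE,
                 sort = FALSE)
    ok <- is.finite(out$clim_rmse) & out$clim_rmse > 0 & is.finite(out$rmse)
    out$pct_rmse_vs_clim[ok] <-
      100 * (out$rmse[ok] - out$clim_rmse[ok]) / out$clim_rmse[ok]
    out$clim_rmse <- NULL
  }
  out <- out[order(out$variant, out$lead,
                   suppressWarnings(as.numeric(out$scope))), ]
  rownames(out) <- NULL
  out[, c("variant", "lead", "scope", "n", "r_anomaly", "rmse",
          "pct_rmse_vs_clim")]
}

#' Best model per region at a given lead
#'
#' The variant with minimal per-region RMSE; ties break to the canonical
#' variant order (full model first, then reduced models, then baselines).
#'
#' @param report output of [skill_report()].
#' @param lead forecast lead to tabulate.
#' @return data.frame: fcr_id, best_variant, rmse.
#' @export
best_model_map <- function(report, lead) {
  sub <- report[report$lead == lead & report$scope != "global" &
                  is.finite(report$rmse), ]
  sub$variant <- factor(sub$variant, levels = VARIANTS)
  out <- lapply(split(sub, sub$scope), function(g) {
    g <- g[order(g$rmse, as.integer(g$variant)), ]
    data.frame(fcr_id = as.integer(g$scope[1]),
               best_variant = as.character(g$variant[1]), rmse = g$rmse[1])
  })
  out <- do.call(rbind, out)
  out <- out[order(out$fcr_id), ]
  rownames(out) <- NULL
  out
}
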