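# Walk-forward forecasting protocol: baseline oracles, the closed-form
# lead-1 AR prediction, record bookkeeping, and the no-look-ahead contract.

make_forecast_setup <- function(seed = 20) {
  su <- make_coupled_setup(n_fcr = 2, n_years = 22, lag = 3, coef = 0.7,
                           seed = seed)
  n <- nrow(su$y_hat)
  # wrap the transformed targets in region-series scaffolding so the
  # climatology/inverse-transform machinery can run on emission-like scales
  emissions <- 5 + 2 * su$y_hat + 3  # affine, strictly positive
  rs <- structure(list(emissions = emissions, vpd = NULL, axis = su$axis,
                       fcr_ids = as.integer(colnames(su$y_hat))),
                  class = "region_series")
  clims <- region_climatologies(rs, su$dev_window)
  anom <- region_anomalies(rs, clims)
  lk <- build_lookup(anom$y_hat, su$ocis, NULL, su$axis, su$dev_window)
  list(su = su, rs = rs, clims = clims, anom = anom, lk = lk)
}

test_that("persistence and climatology baselines are exactly reproducible by hand", {
  st <- make_forecast_setup()
  su <- st$su
  per <- run_variant(st$anom, st$clims, su$ocis, st$lk, NULL, su$axis,
                     su$pred_window, "Persistence")
  cl <- run_variant(st$anom, st$clims, su$ocis, st$lk, NULL, su$axis,
                    su$pred_window, "Clim")
  # climatology: zero anomaly, monthly climatological mean emission
  expect_true(all(cl$anomaly_pred == 0))
  for (i in sample(nrow(cl), 25)) {
    r <- cl[i, ]
    clim <- st$clims$emissions[[as.character(r$fcr_id)]]
    expect_equal(r$emission_pred, clim$mean[r$target_month], tolerance = 1e-12)
  }
  # persistence: the origin anomaly carried to every lead
  y0 <- su$axis$year[1]
  for (i in sample(nrow(per), 25)) {
    r <- per[i, ]
    t0 <- month_index(r$origin_year, r$origin_month, y0)
    k <- which(st$rs$fcr_ids == r$fcr_id)
    expect_equal(r$anomaly_pred, unname(st$anom$y_hat[t0, k]), tolerance = 1e-12)
  }
  one <- per[per$fcr_id == 1 & per$origin_year == per$origin_year[1] &
               per$origin_month == 2, ]
  expect_equal(length(unique(one$anomaly_pred)), 1L)
})

test_that("record counts and verifiability bookkeeping follow the window", {
  st <- make_forecast_setup()
  su <- st$su
  rec <- run_variant(st$anom, st$clims, su$ocis, st$lk, NULL, su$axis,
                     su$pred_window, "Persistence")
  expect_identical(nrow(rec), 2L * 48L * 6L)      # regions x origins x leads
  # unverifiable records: for lead L the last L origins overshoot the
  # observed record, so 1+2+...+6 = 21 per region
  last <- rec[!rec$verifiable, ]
  expect_identical(nrow(last), 2L * 21L)
  expect_true(all(12 * last$target_year + last$target_month >
                    12 * max(su$axis$year) + 12))
})

test_that("the AR-only lead-1 forecast equals its closed form", {
  st <- make_forecast_setup()
  su <- st$su
  ords <- data.frame(fcr_id = rep(1:2, each = 6), lead = rep(1:6, 2),
                     p = 1L, d = 0L, q = 0L)
  t0 <- which(in_window(su$axis, su$pred_window))[5]
  rec <- forecast_origin(st$anom$y_hat[, 1], su$axis, t0, "ARonly",
                         st$lk[st$lk$fcr_id == 1, ], ords[ords$fcr_id == 1, ],
                         su$ocis$values, NULL, st$clims$emissions[["1"]],
                         leads = 1, refit_method = "CSS-ML")
  fit <- fit_arimax(st$anom$y_hat[1:t0, 1], NULL, c(1, 0, 0),
                    method = "CSS-ML")
  mu <- unname(fit$coef["intercept"]); a1 <- unname(fit$coef["ar1"])
  # Eq-1 style intercept: c = mu (1 - a1); prediction c + a1 * y_t0
  closed <- unname(mu * (1 - a1) + a1 * st$anom$y_hat[t0, 1])
  expect_equal(rec$anomaly_pred, closed, tolerance = 1e-8)
})

test_that("forecasts never look past their origin", {
  st <- make_forecast_setup()
  su <- st$su
  t0 <- which(in_window(su$axis, su$pred_window))[3]
  args <- list(st$anom$y_hat[, 1], su$axis, t0, "OCIVPDAR",
               st$lk[st$lk$fcr_id == 1, ],
               data.frame(lead = 1:6, p = 1L, d = 0L, q = 1L),
               su$ocis$values, NULL, st$clims$emissions[["1"]], 1:6, "CSS-ML")
  base <- do.call(forecast_origin, args)
  # mutate the target and the exogenous series strictly after the origin
  y_mut <- st$anom$y_hat[, 1]; y_mut[(t0 + 1):length(y_mut)] <- 9
  oci_mut <- su$ocis$values; oci_mut[(t0 + 1):nrow(oci_mut), ] <- -9
  args_mut <- args; args_mut[[1]] <- y_mut; args_mut[[7]] <- oci_mut
  mut <- do.call(forecast_origin, args_mut)
  expect_same_records(base, mut)
})

test_that("Xonly uses zero orders and OCIAR/VPDAR drop one predictor", {
  st <- make_forecast_setup()
  su <- st$su
  t0 <- which(in_window(su$axis, su$pred_window))[1]
  xo <- forecast_origin(st$anom$y_hat[, 1], su$axis, t0, "Xonly",
                        st$lk[st$lk$fcr_id == 1, ], NULL,
                        su$ocis$values, NULL, st$clims$emissions[["1"]],
                        leads = 1, refit_method = "CSS-ML")
  # oracle: plain regression of y on the shifted OCI (no ARMA terms)
  entry <- st$lk[st$lk$fcr_id == 1 & st$lk$lead == 1, ]
  x <- su$ocis$values[, entry$oci_name]
  n <- length(st$anom$y_hat[, 1])
  xs <- c(rep(NA, entry$oci_lag), x[seq_len(n - entry$oci_lag)])
  use <- which(!is.na(xs))[1]:t0
  co <- coef(lm(st$anom$y_hat[use, 1] ~ xs[use]))
  pred <- unname(co[1] + co[2] * xs[t0 + 1])
  expect_equal(xo$anomaly_pred, pred, tolerance = 1e-6)
})

test_that("anomaly predictions are clipped and emissions non-negative", {
  st <- make_forecast_setup(seed = 23)
  su <- st$su
  ords <- data.frame(fcr_id = rep(1:2, each = 6), lead = rep(1:6, 2),
                     p = 1L, d = 0L, q = 0L)
  rec <- run_variant(st$anom, st$clims, su$ocis, st$lk, ords, su$axis,
                     su$pred_window, "OCIAR", leads = c(1, 3))
  expect_true(all(abs(rec$anomaly_pred) <= 2))
  expect_true(all(rec$emission_pred >= 0))
})

test_that("in-sample hindcast has one record per usable month and can be perfect", {
  st <- make_forecast_setup()
  su <- st$su
  ords <- data.frame(fcr_id = rep(1:2, each = 6), lead = rep(1:6, 2),
                     p = 1L, d = 0L, q = 0L)
  h <- hindcast_insample(st$anom, st$clims, su$ocis, st$lk, ords, su$axis,
                         su$dev_window, "ARonly")
  n_dev <- sum(in_window(su$axis, su$dev_window))
  expect_identical(nrow(h), 2L * n_dev)
  expect_true(all(h$verifiable))

  # a deterministic AR(1) target is fit almost exactly in-sample
  n <- nrow(su$axis)
  det <- 0.9 * sin(2 * pi * seq_len(n) / 7)
  anom2 <- list(y_hat = matrix(det, n, 1, dimnames = list(NULL, "1")),
                vpd_z = NULL)
  h2 <- hindcast_insample(anom2, st$clims, su$ocis,
                          st$lk[st$lk$fcr_id == 1, ],
                          data.frame(fcr_id = 1L, lead = 1L, p = 2L, d = 0L,
                                     q = 2L),
                          su$axis, su$dev_window, "ARonly")
  resid <- h2$anomaly_pred - det[in_window(su$axis, su$dev_window)]
  expect_lt(sqrt(mean(resid^2)), 0.05)
})
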