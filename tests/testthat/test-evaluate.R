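# Diagnostics and verification scores.

test_that("ACF/PACF match theory and the OLS autoregression oracle", {
  set.seed(30)
  y <- as.numeric(arima.sim(list(ar = 0.8), 5000))
  ap <- acf_pacf(y, max_lag = 10)
  expect_equal(ap$acf[1], 1)
  expect_lt(abs(ap$pacf[1] - 0.8), 0.05)
  expect_lt(max(abs(ap$pacf[2:10])), 0.06)

  set.seed(31)
  y2 <- as.numeric(arima.sim(list(ar = c(0.5, 0.2)), 800))
  ap2 <- acf_pacf(y2, max_lag = 5)
  for (k in 1:3)
    expect_equal(ap2$pacf[k], oracle_pacf_ols(y2, k), tolerance = 0.02)

  expect_true(acf_pacf(rep(3, 100), 5)$flag)
  expect_error(acf_pacf(rnorm(10), 10), "too short")
})

test_that("KPSS rejects trending series, keeps its size on noise, and the slope is exact", {
  ax <- month_axis(2000, 240)
  set.seed(32)
  ramp <- seq_len(240) + rnorm(240, sd = 3)
  tr <- trend_and_kpss(ramp, ax)
  expect_true(tr$reject_level)          # a ramp is not level-stationary
  expect_false(tr$reject_trend)         # but is stationary around a trend

  # per-year slope on annual totals: y = 2 t (monthly) has annual sums
  # rising by 2 * 144 each year
  lin <- trend_and_kpss(2 * seq_len(240), ax)
  expect_equal(lin$slope, 2 * 144, tolerance = 1e-9)

  set.seed(33)
  rej <- replicate(100, {
    z <- trend_and_kpss(rnorm(240), ax)
    c(z$reject_level, z$reject_trend)
  })
  expect_lt(mean(rej[1, ]), 0.15)       # size close to the 5% nominal level
  expect_lt(mean(rej[2, ]), 0.15)
  expect_gte(mean(!rej[1, ] & !rej[2, ]), 0.85)
  expect_error(trend_and_kpss(rnorm(24), month_axis(2000, 24)), "5 years")
})

# small verification fixture: 2 regions, 1 variant-like record set
make_eval_fixture <- function() {
  n <- 12 * 20
  axis <- month_axis(1997, n)
  set.seed(40)
  em <- cbind(`1` = 5 + 2 * sin(2 * pi * seq_len(n) / 12) + rnorm(n, 0, 0.5),
              `2` = 3 + cos(2 * pi * seq_len(n) / 12) + rnorm(n, 0, 0.3))
  em <- pmax(em, 0)
  rs <- structure(list(emissions = em, vpd = NULL, axis = axis,
                       fcr_ids = 1:2), class = "region_series")
  clims <- region_climatologies(rs, c(1997, 2012))
  list(rs = rs, clims = clims, axis = axis)
}

records_from_truth <- function(fx, variant, window = c(2013, 2016),
                               perturb = 0) {
  rows <- which(in_window(fx$axis, window))
  do.call(rbind, lapply(1:2, function(k) {
    ax <- fx$axis[rows, ]
    obs <- fx$rs$emissions[rows, k]
    cm <- fx$clims$emissions[[k]]$mean[ax$month]
    pred <- if (variant == "Clim") cm else obs + perturb
    data.frame(fcr_id = k, origin_year = ax$year, origin_month = ax$month,
               lead = 1L, target_year = ax$year, target_month = ax$month,
               variant = variant, anomaly_pred = 0,
               emission_pred = pred, fallback = FALSE, verifiable = TRUE)
  }))
}

test_that("anomaly correlation and RMSE behave on exact and hand-computed cases", {
  fx <- make_eval_fixture()
  perfect <- records_from_truth(fx, "OCIVPDAR")
  expect_equal(anomaly_corr(perfect, fx$rs, fx$clims)$r, 1)
  expect_equal(rmse_records(perfect, fx$rs)$rmse, 0)

  clim <- records_from_truth(fx, "Clim")
  ac <- anomaly_corr(clim, fx$rs, fx$clims)
  expect_true(ac$flag)                  # zero-variance predicted anomalies

  # hand-computed toy: predicted anomalies 1,2,3 vs observed 1,2,3.5
  toy <- perfect[1:3, ]
  toy$fcr_id <- 1
  cm <- clim_for <- sapply(1:3, function(i)
    fx$clims$emissions[["1"]]$mean[toy$target_month[i]])
  toy$emission_pred <- cm + c(1, 2, 3)
  rs_toy <- fx$rs
  y0 <- fx$axis$year[1]
  tt <- month_index(toy$target_year, toy$target_month, y0)
  rs_toy$emissions[tt, 1] <- cm + c(1, 2, 3.5)
  expect_equal(anomaly_corr(toy, rs_toy, fx$clims)$r,
               cor(c(1, 2, 3), c(1, 2, 3.5)))

  # rmse of errors {3, 4} = sqrt(12.5)
  toy2 <- perfect[1:2, ]
  obs <- observed_for <- fx$rs$emissions[month_index(toy2$target_year,
                                                     toy2$target_month, y0), 1]
  toy2$emission_pred <- obs + c(3, 4)
  expect_equal(rmse_records(toy2, fx$rs)$rmse, sqrt(12.5))

  expect_equal(pct_rmse_vs_clim(0, 2), -100)
  expect_equal(pct_rmse_vs_clim(2, 2), 0)
  expect_error(pct_rmse_vs_clim(1, 0), "positive")
})

test_that("global series sums regions and conserves totals", {
  fx <- make_eval_fixture()
  rec <- records_from_truth(fx, "OCIVPDAR")
  gs <- global_series(rec, fx$rs, fx$clims)
  y0 <- fx$axis$year[1]
  tt <- month_index(gs$target_year, gs$target_month, y0)
  expect_equal(gs$predicted, rowSums(fx$rs$emissions)[tt], tolerance = 1e-10)
  expect_equal(gs$observed, gs$predicted, tolerance = 1e-10)

  clim_rec <- records_from_truth(fx, "Clim")
  gc <- global_series(clim_rec, fx$rs, fx$clims)
  expect_equal(gc$predicted, gc$climatology, tolerance = 1e-10)

  # months missing one region are excluded
  rec_part <- rec[!(rec$fcr_id == 2 & rec$target_month == 5), ]
  gp <- global_series(rec_part, fx$rs, fx$clims)
  expect_false(any(gp$target_month == 5))
})

test_that("skill report and best-model table rank variants coherently", {
  fx <- make_eval_fixture()
  good <- records_from_truth(fx, "OCIVPDAR", perturb = 0.1)
  bad <- records_from_truth(fx, "Persistence", perturb = 1.5)
  clim <- records_from_truth(fx, "Clim")
  rep <- skill_report(rbind(good, bad, clim), fx$rs, fx$clims)
  expect_true(all(abs(rep$r_anomaly) <= 1, na.rm = TRUE))
  expect_true(all(rep$rmse >= 0, na.rm = TRUE))
  g <- rep[rep$scope == "global", ]
  expect_lt(g$rmse[g$variant == "OCIVPDAR"], g$rmse[g$variant == "Persistence"])
  pc <- rep$pct_rmse_vs_clim[rep$variant == "Clim"]
  expect_true(all(abs(pc) < 1e-10))

  bm <- best_model_map(rep, lead = 1)
  expect_identical(bm$best_variant, rep("OCIVPDAR", 2))
  expect_identical(best_model_map(rep, 1), bm)   # deterministic re-run
})
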