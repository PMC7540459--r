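# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (plain loops, direct enumeration) so they
# share no code path with the implementation they check.

# Brute-force FCR derivation: a literal transliteration of the iteration
# rules on the annual-sum array. Returns a list of regions, each
# list(cells = 2-col matrix, level, country), in assignment order.
oracle_fcrs <- function(ann, mask, e_min, nonzero_frac = 0.9, cv_max = 2,
                        e_min_8r = 0.12) {
  n_lat <- dim(ann)[2]; n_lon <- dim(ann)[3]
  taken <- matrix(FALSE, n_lat, n_lon)
  regions <- list()
  passes <- function(series) {
    mean(series) >= e_min &&
      sum(series > 0) / length(series) >= nonzero_frac &&
      (mean(series) > 0 && sd(series) / mean(series) < cv_max)
  }
  series_of <- function(cells) {
    s <- rep(0, dim(ann)[1])
    for (r in seq_len(nrow(cells)))
      s <- s + ann[, cells[r, 1], cells[r, 2]]
    s
  }
  claim <- function(cells, level) {
    for (cc in sort(unique(mask[cells]))) {
      part <- cells[mask[cells] == cc, , drop = FALSE]
      for (r in seq_len(nrow(part))) taken[part[r, 1], part[r, 2]] <<- TRUE
      regions[[length(regions) + 1L]] <<-
        list(cells = part, level = level, country = cc)
    }
  }
  blocks <- function(b) {
    out <- list()
    row_starts <- seq(1, n_lat, by = b)
    for (i0 in row_starts) for (j0 in seq(1, n_lon, by = b)) {
      h <- min(b, n_lat - i0 + 1)
      w <- min(b, n_lon - j0 + 1)
      cells <- NULL
      for (i in i0:(i0 + h - 1)) for (j in j0:(j0 + w - 1))
        cells <- rbind(cells, c(i, j))
      out[[length(out) + 1L]] <- cells
    }
    out
  }
  for (b in c(1, 2, 4, 8)) {
    for (cells in blocks(b)) {
      free <- !taken[cells]
      if (!any(free)) next
      cells <- cells[free, , drop = FALSE]
      s <- series_of(cells)
      if (all(s == 0)) next
      if (passes(s)) claim(cells, as.character(b))
    }
  }
  for (cells in blocks(8)) {
    free <- !taken[cells]
    if (!any(free)) next
    cells <- cells[free, , drop = FALSE]
    if (mean(series_of(cells)) > e_min_8r) claim(cells, "8r")
  }
  regions
}

# PACF at lag k as the last coefficient of an order-k OLS autoregression.
oracle_pacf_ols <- function(y, k) {
  y <- y - mean(y)
  n <- length(y)
  X <- sapply(seq_len(k), function(l) y[(k - l + 1):(n - l)])
  fit <- lm.fit(cbind(1, as.matrix(X)), y[(k + 1):n])
  unname(fit$coefficients[k + 1])
}

# quick synthetic regional setup shared by predictor/forecast tests:
# an AR-flavored transformed target coupled to one OCI at a known lag
make_coupled_setup <- function(n_fcr = 3, n_years = 22, lag = 3,
                               coef = 0.6, seed = 42) {
  n <- 12 * n_years
  axis <- month_axis(1997, n)
  ocis <- gen_oci_set(4, n, ar1_phi = 0.8, seed = seed)
  set.seed(seed)
  y_hat <- sapply(seq_len(n_fcr), function(k) {
    x <- ocis$values[, "OCI02"]
    e <- as.numeric(arima.sim(list(ar = 0.4), n, sd = 0.4))
    y <- coef * c(rep(0, lag), x[seq_len(n - lag)]) + e
    2 * tanh(y / 2)
  })
  colnames(y_hat) <- seq_len(n_fcr)
  list(y_hat = y_hat, ocis = ocis, axis = axis,
       dev_window = c(1997, 1997 + n_years - 5),
       pred_window = c(1997 + n_years - 4, 1997 + n_years - 1))
}

expect_same_records <- function(a, b) {
  expect_equal(a$anomaly_pred, b$anomaly_pred, tolerance = 1e-12)
  expect_equal(a$emission_pred, b$emission_pred, tolerance = 1e-12)
}
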