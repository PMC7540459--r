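# ARIMAX engine: regression with ARIMA(p,d,q) errors, fit by Gaussian
# maximum likelihood through the Kalman filter of stats::arima. The
# intercept is always estimated: with d = 1 it enters as a drift term
# (a linear time column appended to the exogenous matrix, so its
# coefficient is the per-month drift of the undifferenced series).

#' Fit a regression-with-ARIMA-errors model
#'
#' @param y numeric target series (transformed anomalies); leading/trailing
#'   `NA`s are not allowed - trim before fitting.
#' @param xreg exogenous predictor matrix aligned to `y` (already shifted by
#'   their lookup lags), or `NULL`.
#' @param order integer `c(p, d, q)` with `p, q` in 0-2 and `d` in 0-1.
#' @param method estimation method passed to [stats::arima()]: `"CSS-ML"`
#'   (default, full ML after CSS initialization), `"ML"`, or `"CSS"` (fast
#'   conditional sum of squares, used for repeated walk-forward refits).
#' @return an `arimax_fit`: list with `model` (the `Arima` object), `order`,
#'   `coef`, `sigma2`, `loglik`, `aic` (`NA` under `"CSS"`), `n_obs`,
#'   `converged`, `drift` (whether a drift column was added).
#' @export
fit_arimax <- function(y, xreg = NULL, order = c(1, 0, 0),
                       method = c("CSS-ML", "ML", "CSS")) {
  method <- match.arg(method)
  stopifnot(length(order) == 3, order[1] %in% 0:2, order[2] %in% 0:1,
            order[3] %in% 0:2)
  n <- length(y)
  drift <- order[2] == 1
  X <- xreg
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    # drop constant (singular) exogenous columns with a warning
    keep <- apply(X, 2, function(col) sd(col) > 0)
    if (!all(keep)) {
      warning("dropping constant exogenous column(s): ",
              paste(colnames(X)[!keep], collapse = ", "))
      X <- X[, keep, drop = FALSE]
      if (ncol(X) == 0) X <- NULL
    }
  }
  if (drift) {
    X <- cbind(X, drift = seq_len(n))
  }
  fit <- tryCatch(
    suppressWarnings(
      stats::arima(y, order = order, xreg = X, include.mean = TRUE,
                   method = method)),
    error = function(e) e)
  if (inherits(fit, "error") || !is.finite(fit$loglik) ||
      (!is.null(fit$code) && fit$code != 0)) {
    return(structure(list(model = NULL, order = order, coef = NULL,
                          sigma2 = NA_real_, loglik = NA_real_,
                          aic = NA_real_, n_obs = n, converged = FALSE,
                          drift = drift,
                          error = if (inherits(fit, "error"))
                            conditionMessage(fit) else "non-finite likelihood"),
                     class = "arimax_fit"))
  }
  structure(list(model = fit, order = order, coef = coef(fit),
                 sigma2 = fit$sigma2, loglik = fit$loglik,
                 aic = if (is.null(fit$aic)) NA_real_ else fit$aic,
                 n_obs = n, converged = TRUE, drift = drift),
            class = "arimax_fit")
}

#' @export
print.arimax_fit <- function(x, ...) {
  cat(sprintf("<arimax_fit> order (%d,%d,%d), n = %d, %s\n",
              x$order[1], x$order[2], x$order[3], x$n_obs,
              if (x$converged)
                sprintf("loglik = %.2f, aic = %.2f", x$loglik, x$aic)
              else paste("NOT converged:", x$error)))
  invisible(x)
}

#' Multi-step forecast from an `arimax_fit`
#'
#' State-space (Kalman) forecast `n_ahead` steps past the end of the
#' training series; drift columns added at fit time are extended
#' automatically.
#'
#' @param fit a converged `arimax_fit`.
#' @param n_ahead number of steps.
#' @param newxreg exogenous values for the forecast months, matrix
#'   `[n_ahead, n_exog]` matching the fit's (non-drift) columns; `NULL`
#'   when the fit used none.
#' @return numeric vector of length `n_ahead`.
#' @export
predict_arimax <- function(fit, n_ahead, newxreg = NULL) {
  if (!fit$converged) stop("cannot forecast from a non-converged fit")
  X <- newxreg
  if (!is.null(X)) X <- as.matrix(X)
  if (fit$drift) {
    dr <- matrix(fit$n_obs + seq_len(n_ahead), ncol = 1,
                 dimnames = list(NULL, "drift"))
    X <- if (is.null(X)) dr else cbind(X, dr)
  }
  # predict.Arima warns when a CSS fit sits on the invertibility boundary;
  # the point forecast is still the Kalman forecast
  p <- suppressWarnings(predict(fit$model, n.ahead = n_ahead, newxreg = X))
  as.numeric(p$pred)
}

#' AIC grid search over ARIMAX orders
#'
#' Fits every (p, d, q) combination on the grid and returns the converged
#' fit with minimal AIC. Exact AIC ties break to the smaller `p + d + q`,
#' then smaller `p`, then smaller `q`. If every candidate fails, the
#' fallback order (0, 0, 0) is returned.
#'
#' Candidate fits that converge only on the stationarity/invertibility
#' boundary (an AR or MA root with modulus below 1.001) are treated as
#' degenerate and excluded, the admissibility screen customary in automatic
#' ARIMA selection.
#'
#' @param y target series.
#' @param xreg exogenous matrix or `NULL`.
#' @param p_grid,d_grid,q_grid candidate orders (defaults 0:2, 0:1, 0:2).
#' @param method estimation method for the candidate fits.
#' @return list with `order` (`c(p, d, q)`), `aic`, and `table` (all
#'   candidates with their AICs and convergence flags).
#' @export
select_order <- function(y, xreg = NULL, p_grid = 0:2, d_grid = 0:1,
                         q_grid = 0:2, method = "CSS-ML") {
  admissible <- function(f) {
    cf <- f$coef
    for (part in c("^ar[0-9]+$", "^ma[0-9]+$")) {
      co <- cf[grep(part, names(cf))]
      if (length(co)) {
        roots <- polyroot(c(1, if (grepl("ar", part)) -co else co))
        if (any(Mod(roots) < 1.001)) return(FALSE)
      }
    }
    TRUE
  }
  cand <- expand.grid(p = p_grid, d = d_grid, q = q_grid)
  cand$aic <- NA_real_
  cand$converged <- FALSE
  for (i in seq_len(nrow(cand))) {
    f <- fit_arimax(y, xreg, c(cand$p[i], cand$d[i], cand$q[i]),
                    method = method)
    if (f$converged && is.finite(f$aic) && admissible(f)) {
      cand$aic[i] <- f$aic
      cand$converged[i] <- TRUE
    }
  }
  ok <- which(cand$converged)
  if (!length(ok))
    return(list(order = c(0L, 0L, 0L), aic = NA_real_, table = cand))
  sub <- cand[ok, ]
  best_aic <- min(sub$aic)
  tied <- sub[sub$aic <= best_aic + 1e-9, ]
  tied <- tied[order(tied$p + tied$d + tied$q, tied$p, tied$q), ]
  list(order = as.integer(c(tied$p[1], tied$d[1], tied$q[1])),
       aic = tied$aic[1], table = cand)
}
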