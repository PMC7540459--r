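# Vapor pressure deficit from 2 m meteorology.
# VPD = e_s(T) - e_a(Qv, Ps): the gap between how much moisture the air
# could hold at saturation and how much it actually holds; a standard proxy
# for fuel moisture stress.

#' Saturation vapor pressure (Clausius-Clapeyron, Bolton form)
#'
#' `e_s = 6.112 * exp(17.67 * T / (T + 243.5))`.
#'
#' @param temp_c air temperature in degrees Celsius; must exceed -243.5.
#' @return saturation vapor pressure in hPa.
#' @export
saturation_vp <- function(temp_c) {
  if (any(temp_c <= -243.5, na.rm = TRUE))
    stop("temperature at or below -243.5 C is outside the formula's domain")
  6.112 * exp(17.67 * temp_c / (temp_c + 243.5))
}

#' Actual vapor pressure from specific humidity and surface pressure
#'
#' `e_a = Qv * Ps / 0.622`, with 0.622 the molecular weight ratio of water
#' vapor to dry air.
#'
#' @param qv specific humidity (g/g), non-negative.
#' @param ps surface pressure (hPa), positive.
#' @return actual vapor pressure in hPa.
#' @export
actual_vp <- function(qv, ps) {
  if (any(qv < 0, na.rm = TRUE)) stop("specific humidity must be non-negative")
  if (any(ps <= 0, na.rm = TRUE)) stop("surface pressure must be positive")
  qv * ps / 0.622
}

#' Gridded VPD from temperature, humidity and pressure fields
#'
#' VPD is computed per source cell as `e_s(T) - e_a(Qv, Ps)`, floored at 0,
#' then block-averaged onto the coarser 1-degree target grid with
#' cosine-latitude area weights. The source grid must refine each target
#' cell by an integer factor.
#'
#' @param temp,qv,ps numeric arrays `[n_time, n_lat_src, n_lon_src]` with
#'   aligned time axes (Celsius, g/g, hPa).
#' @param start_year first calendar year of the time axis.
#' @param refine integer refinement factor: `refine^2` source cells average
#'   into one target cell (default 1, source already at 1 degree).
#' @return a `vpd_field` on the target grid.
#' @export
vpd_field <- function(temp, qv, ps, start_year, refine = 1L) {
  if (!all(dim(temp) == dim(qv)) || !all(dim(temp) == dim(ps)))
    stop("meteorology grids must share one shape")
  refine <- as.integer(refine)
  d <- dim(temp)
  if (d[2] %% refine != 0 || d[3] %% refine != 0)
    stop("source grid is not an integer refinement of the target grid")
  vpd <- pmax(saturation_vp(temp) - actual_vp(qv, ps), 0)
  if (refine == 1L) return(grid_field(vpd, start_year, "vpd"))
  n_lat <- d[2] %/% refine; n_lon <- d[3] %/% refine
  src_lat <- -90 + (seq_len(d[2]) - 0.5) / refine  # source-cell centers
  w_lat <- coslat_weights(src_lat)
  out <- array(NA_real_, c(d[1], n_lat, n_lon))
  for (i in seq_len(n_lat)) {
    ii <- (i - 1L) * refine + seq_len(refine)
    w <- w_lat[ii]
    for (j in seq_len(n_lon)) {
      jj <- (j - 1L) * refine + seq_len(refine)
      blk <- vpd[, ii, jj, drop = FALSE]
      wm <- array(rep(w, each = d[1]), dim(blk))
      wm[is.na(blk)] <- 0
      blk[is.na(blk)] <- 0
      out[, i, j] <- rowSums(blk * wm, dims = 1) / rowSums(wm, dims = 1)
    }
  }
  grid_field(out, start_year, "vpd")
}
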