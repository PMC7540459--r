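# Fire cohesive regions (FCRs): iterative multi-resolution derivation.
# Candidate blocks at 1, 2, 4, 8 degrees are tested against magnitude,
# continuity and variability criteria on their summed emissions; passing
# blocks become regions (split along country borders), cells already
# assigned at a finer level are excluded, and leftover 8-degree blocks with
# modest emissions enter as a relaxed "8r" level.

#' FCR acceptance criteria
#'
#' @param e_min minimum mean annual emissions (Tg C/yr) a candidate must
#'   reach; if `NA`, derive it from the data via [derive_e_min()].
#' @param top_pct fraction of land cells used to derive `e_min` when not
#'   supplied (default 0.02, i.e. the top 2 percent cutoff).
#' @param nonzero_year_frac minimum fraction of years with nonzero
#'   emissions (default 0.90, i.e. 17 of 18 years).
#' @param cv_max maximum coefficient of variation (sd/mean) of the annual
#'   series (default 2).
#' @param e_min_8r relaxed mean-annual-emission threshold (Tg C/yr) for
#'   leftover 8-degree blocks (default 0.12).
#' @param series `"annual"` (default) or `"monthly"`: which series the
#'   continuity and variability criteria are evaluated on.
#' @return an `fcr_criteria` list.
#' @export
fcr_criteria <- function(e_min = NA_real_, top_pct = 0.02,
                         nonzero_year_frac = 0.90, cv_max = 2,
                         e_min_8r = 0.12, series = c("annual", "monthly")) {
  series <- match.arg(series)
  stopifnot(top_pct > 0, top_pct <= 1, cv_max > 0, e_min_8r > 0,
            nonzero_year_frac > 0, nonzero_year_frac <= 1)
  if (!is.na(e_min) && e_min <= 0) stop("e_min must be positive")
  structure(list(e_min = e_min, top_pct = top_pct,
                 nonzero_year_frac = nonzero_year_frac, cv_max = cv_max,
                 e_min_8r = e_min_8r, series = series),
            class = "fcr_criteria")
}

#' Multi-resolution grid hierarchy
#'
#' Block tilings of the 1-degree grid at 2, 4 and 8 degrees. All levels
#' tile from the south-west corner; when the number of rows is not a
#' multiple of 8, the northernmost 8-degree band is truncated to a height
#' of 4 rows (those blocks have two 4-degree children instead of four).
#'
#' @param n_lat,n_lon 1-degree grid dimensions; both must be divisible by
#'   4, `n_lon` by 8, and `n_lat` congruent to 0 or 4 modulo 8.
#' @return a `multires_grid`: per level (`"2"`, `"4"`, `"8"`), a list with
#'   `row_start`/`row_height`/`col_start`/`col_width` block edge vectors.
#' @export
build_multires_grid <- function(n_lat, n_lon) {
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  if (n_lat %% 4 != 0 || n_lon %% 4 != 0 ||
      !(n_lat %% 8 %in% c(0L, 4L)) || !(n_lon %% 8 %in% c(0L, 4L)))
    stop("grid dimensions incompatible with the 2/4/8-degree hierarchy")
  lv <- function(b) {
    rs <- seq(1L, n_lat, by = b)
    cs <- seq(1L, n_lon, by = b)
    list(row_start = rs, row_height = as.integer(pmin(b, n_lat - rs + 1L)),
         col_start = cs, col_width = as.integer(pmin(b, n_lon - cs + 1L)))
  }
  structure(list(`2` = lv(2L), `4` = lv(4L), `8` = lv(8L),
                 n_lat = n_lat, n_lon = n_lon),
            class = "multires_grid")
}

#' Derive the level-entry emission threshold from the data
#'
#' The cutoff for the top `top_pct` of land cells: the k-th largest mean
#' annual cell total with `k = ceiling(top_pct * n)`, taken over land cells
#' with any burning (nearest-rank rule, deterministic).
#'
#' @param field an `emission_field`.
#' @param top_pct fraction (default 0.02).
#' @param window development window `c(start_year, end_year)`; default all.
#' @param land optional logical/integer matrix marking land cells; default
#'   every cell.
#' @return threshold in Tg C/yr.
#' @export
derive_e_min <- function(field, top_pct = 0.02, window = NULL, land = NULL) {
  ann <- annual_sums(field, window)
  mean_annual <- colMeans(ann, dims = 1)
  if (!is.null(land)) mean_annual[!(land > 0)] <- NA
  vals <- mean_annual[!is.na(mean_annual) & mean_annual > 0]
  if (!length(vals)) stop("no land cell with positive emissions: threshold undefined")
  k <- max(1L, ceiling(top_pct * length(vals)))
  sort(vals, decreasing = TRUE)[k]
}

#' Test a candidate region's series against the three FCR criteria
#'
#' @param annual_series annual emission totals (Tg C/yr per year) of the
#'   candidate; at least 2 years.
#' @param criteria an [fcr_criteria()] with `e_min` resolved (not `NA`).
#' @param series optional monthly series; used for criteria 2-3 when
#'   `criteria$series == "monthly"`.
#' @return list with `pass` (logical) and `failed` (character vector naming
#'   failed criteria among `"magnitude"`, `"continuity"`, `"variability"`).
#' @export
criteria_pass <- function(annual_series, criteria, series = NULL) {
  if (length(annual_series) < 2) stop("need at least 2 years")
  if (is.na(criteria$e_min)) stop("criteria$e_min unresolved")
  s <- if (criteria$series == "monthly" && !is.null(series)) series
       else annual_series
  failed <- character(0)
  mu_a <- mean(annual_series)
  if (mu_a < criteria$e_min) failed <- c(failed, "magnitude")
  if (mean(annual_series > 0) < criteria$nonzero_year_frac)
    failed <- c(failed, "continuity")
  mu <- mean(s)
  cv <- if (mu > 0) sd(s) / mu else Inf
  if (!(cv < criteria$cv_max)) failed <- c(failed, "variability")
  list(pass = length(failed) == 0, failed = failed)
}

# assign one region per country among the passing block's member cells
split_by_country <- function(cells, mask) {
  codes <- mask[cells]
  lapply(sort(unique(codes)), function(cc) cells[codes == cc, , drop = FALSE])
}

#' Derive fire cohesive regions from a gridded emission field
#'
#' Levels are processed in order 1, 2, 4, 8 on calendar-year sums inside the
#' development window. At each coarser level a candidate block's series is
#' the sum over member 1-degree cells not already assigned; a passing
#' candidate spanning several countries is split into one region per country
#' (all keeping the level label). After level 8, any 8-degree block whose
#' remaining cells average more than `e_min_8r` Tg C/yr becomes a relaxed
#' level-"8r" region (split by country likewise). Remaining cells are
#' low-fire and stay unassigned. Ids are assigned level by level in
#' row-major scan order from the south-west corner, starting at 1, with
#' country fragments ordered by ascending country code.
#'
#' @param field an `emission_field` covering `dev_window`.
#' @param mask integer country-code matrix `[n_lat, n_lon]`.
#' @param criteria an [fcr_criteria()]; an `NA` `e_min` is derived from the
#'   field via [derive_e_min()].
#' @param dev_window `c(start_year, end_year)` development years.
#' @return an `fcr_map`: list with `fcr_id` (integer matrix, `NA` =
#'   unassigned), `regions` (data.frame: fcr_id, level, country, n_cells,
#'   mean_annual), and grid dimensions.
#' @export
derive_fcrs <- function(field, mask, criteria = fcr_criteria(),
                        dev_window = range(field$axis$year)) {
  check_window(field$axis, dev_window)
  d <- field_dim(field)
  n_lat <- d[2]; n_lon <- d[3]
  stopifnot(all(dim(mask) == c(n_lat, n_lon)))
  if (is.na(criteria$e_min))
    criteria$e_min <- derive_e_min(field, criteria$top_pct, dev_window,
                                   land = mask)
  ann <- annual_sums(field, dev_window)          # [years, lat, lon]
  monthly_keep <- in_window(field$axis, dev_window)
  grid <- build_multires_grid(n_lat, n_lon)
  id_map <- matrix(NA_integer_, n_lat, n_lon)
  regions <- list()
  next_id <- 1L

  blocks_at <- function(level) {
    if (level == 1L) {
      g <- expand.grid(i = seq_len(n_lat), j = seq_len(n_lon))
      g <- g[order(g$i, g$j), ]   # row-major from the south-west
      lapply(seq_len(nrow(g)), function(k)
        cbind(i = g$i[k], j = g$j[k]))
    } else {
      lv <- grid[[as.character(level)]]
      out <- list()
      for (bi in seq_along(lv$row_start)) for (bj in seq_along(lv$col_start)) {
        ii <- lv$row_start[bi] + seq_len(lv$row_height[bi]) - 1L
        jj <- lv$col_start[bj] + seq_len(lv$col_width[bj]) - 1L
        out[[length(out) + 1L]] <- as.matrix(expand.grid(i = ii, j = jj))
      }
      out
    }
  }
  block_annual <- function(cells) {
    idx <- cells[, 1] + (cells[, 2] - 1L) * n_lat
    if (length(idx) == 1L) ann[, idx] else rowSums(ann[, idx, drop = FALSE])
  }
  block_monthly <- function(cells) {
    v <- field$values[monthly_keep, , , drop = FALSE]
    v[is.na(v)] <- 0
    idx <- cells[, 1] + (cells[, 2] - 1L) * n_lat
    m <- matrix(v, nrow = sum(monthly_keep))[, idx, drop = FALSE]
    rowSums(m)
  }
  add_region <- function(cells, level) {
    for (part in split_by_country(cells, mask)) {
      id_map[part] <<- next_id
      regions[[length(regions) + 1L]] <<- data.frame(
        fcr_id = next_id, level = level,
        country = mask[part[1, , drop = FALSE]],
        n_cells = nrow(part),
        mean_annual = mean(block_annual(part)))
      next_id <<- next_id + 1L
    }
  }

  dim(ann) <- c(dim(ann)[1], n_lat * n_lon)
  for (level in c(1L, 2L, 4L, 8L)) {
    for (cells in blocks_at(level)) {
      free <- is.na(id_map[cells])
      if (!any(free)) next
      cells <- cells[free, , drop = FALSE]
      a <- block_annual(cells)
      if (all(a == 0)) next
      mser <- if (criteria$series == "monthly") block_monthly(cells) else NULL
      if (criteria_pass(a, criteria, mser)$pass) add_region(cells, as.character(level))
    }
  }
  for (cells in blocks_at(8L)) {                 # relaxed 8r sweep
    free <- is.na(id_map[cells])
    if (!any(free)) next
    cells <- cells[free, , drop = FALSE]
    a <- block_annual(cells)
    if (mean(a) > criteria$e_min_8r) add_region(cells, "8r")
  }
  regions <- if (length(regions)) do.call(rbind, regions)
    else data.frame(fcr_id = integer(0), level = character(0),
                    country = integer(0), n_cells = integer(0),
                    mean_annual = numeric(0))
  structure(list(fcr_id = id_map, regions = regions,
                 n_lat = n_lat, n_lon = n_lon, criteria = criteria),
            class = "fcr_map")
}

#' @export
print.fcr_map <- function(x, ...) {
  tab <- table(factor(x$regions$level, levels = c("1", "2", "4", "8", "8r")))
  cat(sprintf("<fcr_map> %d regions (%s); %d of %d cells assigned\n",
              nrow(x$regions),
              paste(sprintf("L%s: %d", names(tab), tab), collapse = ", "),
              sum(!is.na(x$fcr_id)), length(x$fcr_id)))
  invisible(x)
}

#' Aggregate gridded fields to per-region series
#'
#' Regional emissions are the sum of member-cell emissions per month
#' (missing cells count as zero); regional VPD is the cosine-latitude
#' area-weighted mean over member cells (missing cells excluded).
#'
#' @param field an `emission_field`.
#' @param vpd optional `vpd_field` on the same grid and axis.
#' @param fcr_map an `fcr_map` from [derive_fcrs()].
#' @return a `region_series`: list with `emissions` (matrix
#'   `[n_time, n_fcr]`), `vpd` (same shape or `NULL`), `axis`, `fcr_ids`.
#' @export
aggregate_series <- function(field, vpd = NULL, fcr_map) {
  d <- field_dim(field)
  stopifnot(fcr_map$n_lat == d[2], fcr_map$n_lon == d[3])
  if (!is.null(vpd)) stopifnot(all(field_dim(vpd) == d))
  ids <- fcr_map$regions$fcr_id
  if (!length(ids)) stop("fcr_map has no regions")
  n_time <- d[1]
  em <- matrix(0, n_time, length(ids))
  vp <- if (is.null(vpd)) NULL else matrix(NA_real_, n_time, length(ids))
  w_lat <- coslat_weights(field$lat)
  ev <- field$values; ev[is.na(ev)] <- 0
  dim(ev) <- c(n_time, d[2] * d[3])
  if (!is.null(vpd)) { vv <- vpd$values; dim(vv) <- c(n_time, d[2] * d[3]) }
  for (k in seq_along(ids)) {
    cells <- which(fcr_map$fcr_id == ids[k])
    if (!length(cells)) stop("region ", ids[k], " has no member cells")
    em[, k] <- rowSums(ev[, cells, drop = FALSE])
    if (!is.null(vpd)) {
      rows_i <- ((cells - 1L) %% d[2]) + 1L
      w <- w_lat[rows_i]
      sub <- vv[, cells, drop = FALSE]
      wm <- matrix(w, n_time, length(cells), byrow = TRUE)
      wm[is.na(sub)] <- 0
      sub[is.na(sub)] <- 0
      vp[, k] <- (sub %*% w) / rowSums(wm)
    }
  }
  colnames(em) <- ids
  if (!is.null(vp)) colnames(vp) <- ids
  structure(list(emissions = em, vpd = vp, axis = field$axis,
                 fcr_ids = ids),
            class = "region_series")
}

#' @export
print.region_series <- function(x, ...) {
  cat(sprintf("<region_series> %d regions x %d months%s\n",
              length(x$fcr_ids), nrow(x$emissions),
              if (is.null(x$vpd)) "" else " (+VPD)"))
  invisible(x)
}
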