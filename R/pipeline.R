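# Stage orchestration behind the command-line interface. Each stage reads
# its upstream artifacts from the output directory, writes its own, and
# records a manifest (config hash, inputs, warning counts) so a run is
# reproducible from its artifacts alone.

#' Load and validate a run configuration
#'
#' The YAML/JSON configuration mirrors the paper-style setup: an 18-year
#' development window followed by a 4-year prediction window, leads 1-6,
#' all seven variants, and the standard order grid.
#'
#' @param path YAML (or JSON) file, or a named list already in memory.
#' @return validated `run_config` list.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    output_dir = "fires2s-run",
    synthetic = list(n_lat = 8, n_lon = 8, n_years = 22, n_oci = 5,
                     n_countries = 2, coupled_oci = "OCI01",
                     coupled_lag = 2, coupled_coef = 0.5),
    dev_window = c(1997, 2014),
    prediction_window = c(2015, 2018),
    leads = 1:6,
    variants = VARIANTS,
    criteria = list(e_min = NA, top_pct = 0.02, nonzero_year_frac = 0.90,
                    cv_max = 2, e_min_8r = 0.12, series = "annual"),
    refit_method = "CSS",
    order_method = "CSS-ML",
    seed = 1)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$synthetic))
    if (is.null(cfg$synthetic[[nm]])) cfg$synthetic[[nm]] <- defaults$synthetic[[nm]]
  for (nm in names(defaults$criteria))
    if (is.null(cfg$criteria[[nm]])) cfg$criteria[[nm]] <- defaults$criteria[[nm]]
  cfg$dev_window <- as.numeric(unlist(cfg$dev_window))
  cfg$prediction_window <- as.numeric(unlist(cfg$prediction_window))
  cfg$leads <- as.integer(unlist(cfg$leads))
  if (cfg$dev_window[2] >= cfg$prediction_window[1])
    stop("development window must precede the prediction window")
  if (!all(cfg$leads %in% 1:6)) stop("leads must lie in 1..6")
  if (!all(cfg$variants %in% VARIANTS))
    stop("unknown variant(s): ",
         paste(setdiff(cfg$variants, VARIANTS), collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

write_manifest <- function(cfg, stage, outputs, warnings_n = 0) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stage = stage, config_hash = config_hash(cfg),
                   outputs = outputs, warnings = warnings_n,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(packageVersion("fires2s")))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir,
                                 paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

need_artifact <- function(cfg, file, producer) {
  p <- file.path(cfg$output_dir, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run the '", producer,
         "' stage first")
  p
}

#' Run pipeline stages
#'
#' Stages: `simulate` (synthetic inputs), `derive-regions`, `climatology`,
#' `lookups`, `orders`, `forecast`, `evaluate`, or `all`. Each writes its
#' artifacts plus a JSON manifest into `config$output_dir`.
#'
#' @param config a `run_config` (or path accepted by [load_config()]).
#' @param stage stage name.
#' @return invisibly, the stage's main artifact (object form).
#' @export
run_stage <- function(config, stage = c("all", "simulate", "derive-regions",
                                        "climatology", "lookups", "orders",
                                        "forecast", "evaluate")) {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  if (stage == "all") {
    for (s in c("simulate", "derive-regions", "climatology", "lookups",
                "orders", "forecast", "evaluate"))
      out <- run_stage(cfg, s)
    return(invisible(out))
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(f) file.path(cfg$output_dir, f)
  switch(stage,
    "simulate" = {
      sy <- cfg$synthetic
      n_months <- 12 * sy$n_years
      start_year <- cfg$dev_window[1]
      ocis <- gen_oci_set(sy$n_oci, n_months, seed = cfg$seed,
                          start_year = start_year)
      sc <- synth_config(
        sy$n_lat, sy$n_lon, sy$n_years,
        oci_coupling = list(list(lat = c(1, sy$n_lat), lon = c(1, sy$n_lon),
                                 oci = sy$coupled_oci, lag = sy$coupled_lag,
                                 coef = sy$coupled_coef)),
        start_year = start_year, seed = cfg$seed)
      gen <- gen_emission_field(sc, ocis)
      vpd <- gen_vpd_field(sc, gen$field)
      mask <- gen_country_mask(sy$n_lat, sy$n_lon, sy$n_countries)
      write_grid(gen$field, od("emissions.nc"))
      write_grid(vpd, od("vpd.nc"))
      write_oci_csv(ocis, od("ocis.csv"))
      write_mask(mask, od("country_mask.nc"), "country")
      write_manifest(cfg, stage,
                     c("emissions.nc", "vpd.nc", "ocis.csv",
                       "country_mask.nc"))
      invisible(gen$field)
    },
    "derive-regions" = {
      field <- read_grid(need_artifact(cfg, "emissions.nc", "simulate"),
                         "emissions")
      mask <- read_mask(od("country_mask.nc"), "country")
      crit <- do.call(fcr_criteria, cfg$criteria)
      fm <- derive_fcrs(field, mask, crit, cfg$dev_window)
      write_fcr_map(fm, od("fcr_map.nc"), od("fcr_regions.csv"))
      write_manifest(cfg, stage, c("fcr_map.nc", "fcr_regions.csv"))
      invisible(fm)
    },
    "climatology" = {
      prep <- pipeline_prep(cfg)
      clim_df <- do.call(rbind, lapply(names(prep$clims$emissions), function(id) {
        cl <- prep$clims$emissions[[id]]
        data.frame(fcr_id = as.integer(id), month = 1:12,
                   mean = cl$mean, sd = cl$sd)
      }))
      write.csv(clim_df, od("climatology.csv"), row.names = FALSE)
      write_manifest(cfg, stage, "climatology.csv")
      invisible(prep$clims)
    },
    "lookups" = {
      prep <- pipeline_prep(cfg)
      lk <- build_lookup(prep$anom$y_hat, prep$ocis, prep$anom$vpd_z,
                         prep$rs$axis, cfg$dev_window, cfg$leads)
      write_lookup(lk, od("lag_lookup.csv"), od("lag_lookup.json"))
      write_manifest(cfg, stage, c("lag_lookup.csv", "lag_lookup.json"))
      invisible(lk)
    },
    "orders" = {
      prep <- pipeline_prep(cfg)
      lk <- read_lookup(need_artifact(cfg, "lag_lookup.csv", "lookups"))
      for (v in intersect(cfg$variants,
                          c("OCIVPDAR", "OCIAR", "VPDAR", "ARonly"))) {
        ol <- build_order_lookup(prep$anom$y_hat, prep$ocis, prep$anom$vpd_z,
                                 lk, prep$rs$axis, cfg$dev_window, cfg$leads,
                                 variant = v, method = cfg$order_method)
        write.csv(ol, od(sprintf("orders_%s.csv", v)), row.names = FALSE)
      }
      write_manifest(cfg, stage, "orders_*.csv")
      invisible(NULL)
    },
    "forecast" = {
      prep <- pipeline_prep(cfg)
      lk <- read_lookup(need_artifact(cfg, "lag_lookup.csv", "lookups"))
      all_rec <- list()
      for (v in cfg$variants) {
        ol <- NULL
        if (variant_spec(v)$arima == "optimal") {
          op <- need_artifact(cfg, sprintf("orders_%s.csv", v), "orders")
          ol <- read.csv(op)
        }
        rec <- run_variant(prep$anom, prep$clims, prep$ocis, lk, ol,
                           prep$rs$axis, cfg$prediction_window, v,
                           cfg$leads, cfg$refit_method)
        dir.create(od(file.path("forecasts")), showWarnings = FALSE)
        write_forecasts(rec, od(file.path("forecasts",
                                          sprintf("%s.csv", v))))
        all_rec[[v]] <- rec
      }
      write_manifest(cfg, stage, "forecasts/*.csv",
                     warnings_n = sum(vapply(all_rec,
                                             function(r) sum(r$fallback),
                                             0)))
      invisible(do.call(rbind, all_rec))
    },
    "evaluate" = {
      prep <- pipeline_prep(cfg)
      fdir <- od("forecasts")
      if (!dir.exists(fdir))
        stop("missing artifact 'forecasts/': run the 'forecast' stage first")
      recs <- do.call(rbind, lapply(list.files(fdir, full.names = TRUE),
                                    read_forecasts))
      rep <- skill_report(recs, prep$rs, prep$clims)
      write.csv(rep, od("skill_report.csv"), row.names = FALSE)
      bm <- best_model_map(rep, min(cfg$leads))
      write.csv(bm, od("best_model.csv"), row.names = FALSE)
      write_manifest(cfg, stage, c("skill_report.csv", "best_model.csv"))
      invisible(rep)
    })
}

# shared stage prologue: load inputs, aggregate, transform
pipeline_prep <- function(cfg) {
  od <- function(f) file.path(cfg$output_dir, f)
  field <- read_grid(need_artifact(cfg, "emissions.nc", "simulate"),
                     "emissions")
  vpd <- read_grid(need_artifact(cfg, "vpd.nc", "simulate"), "vpd")
  ocis <- read_oci_csv(need_artifact(cfg, "ocis.csv", "simulate"))
  mask <- read_mask(od("country_mask.nc"), "country")
  crit <- do.call(fcr_criteria, cfg$criteria)
  fm <- derive_fcrs(field, mask, crit, cfg$dev_window)
  rs <- aggregate_series(field, vpd, fm)
  clims <- region_climatologies(rs, cfg$dev_window)
  anom <- region_anomalies(rs, clims)
  list(field = field, vpd = vpd, ocis = ocis, mask = mask, fm = fm,
       rs = rs, clims = clims, anom = anom)
}
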