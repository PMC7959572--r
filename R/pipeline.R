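#' Run configuration for the full analysis pipeline
#'
#' Bundles input tables (in-memory data frames or CSV paths), model constants
#' and Monte Carlo settings. Every default matches the study constants where
#' one exists: isotope constants 1.71 / -1.61 permil, 10,000 Monte Carlo
#' replicates, latitude 53.375 degrees N, 50-degree axis angle, 1990--2000
#' baseline, May--June and December--January downwelling seasons.
#'
#' @param isotopes,bsi Data frames (or CSV paths) for the isotope and BSi
#'   records.
#' @param wind Optional wind data frame or CSV path.
#' @param community,seasons Optional community matrix inputs: either the list
#'   returned by [read_community_csv()]/[make_community()] via `community`,
#'   or a CSV path plus a `seasons` sidecar path.
#' @param constants An [isotope_constants()] object.
#' @param ekman An [ekman_config()] object.
#' @param n_reps,seed Monte Carlo settings.
#' @param reference_age,tolerance Supply reference matching.
#' @param periods Named period bounds, default [climate_periods()].
#' @param out_dir Output directory for CSVs and the run manifest; `NULL`
#'   suppresses writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(isotopes, bsi, wind = NULL, community = NULL,
                       seasons = NULL, constants = isotope_constants(),
                       ekman = ekman_config(), n_reps = 10000, seed = 1,
                       reference_age = 2005, tolerance = 2,
                       periods = climate_periods(), out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

#' Run the full pipeline
#'
#' Executes the silicon-cycle stage (alignment, utilization, supply, Monte
#' Carlo), fits trends with simultaneous derivative bands to the utilization
#' and supply series, runs the between-period comparisons, and - when the
#' corresponding inputs are present - the Ekman transport stage (seasonal
#' anomalies plus a trend on the smoothed May--June anomaly) and the
#' community stage (PCA, autumn/spring ratio, partial RDA against supply with
#' time as covariable, correlations of taxa with turnover). Writes output
#' CSVs and a JSON run manifest when `out_dir` is set. No stage mutates its
#' inputs; all randomness derives from `config$seed`.
#'
#' @param config A [run_config()].
#' @return A list bundle: `supply` (per-sample table with MC uncertainty),
#'   `trend_utilization`, `trend_supply`, `period_tests`, `breakpoint`,
#'   `ekman` (seasonal table + trend), `ordination` (scores, ratio, RDA,
#'   correlations), `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- proc.time()[["elapsed"]]
  log_stage <- function(...) message(sprintf("[%7.2fs] ",
                                             proc.time()[["elapsed"]] -
                                               t_start), ...)

  iso <- resolve_input(config$isotopes, read_isotope_csv)
  bsi <- resolve_input(config$bsi, read_bsi_csv)
  if (is.null(bsi$mar))
    bsi$mar <- compute_bsi_mar(bsi$bsi_pct, bsi$dbd_g_cm3, bsi$sar_cm_yr)

  log_stage("silicon cycle: aligning and propagating uncertainty")
  paired <- align_series(iso, bsi)
  supply <- propagate_uncertainty(paired, config$constants,
                                  n_reps = config$n_reps,
                                  seed = config$seed,
                                  reference_age = config$reference_age,
                                  tolerance = config$tolerance)

  log_stage("trend fits on utilization and supply")
  tr_util <- derivative_band(
    fit_trend_car1(supply$age_ce, supply$utilization_pct),
    seed = config$seed)
  tr_sup <- derivative_band(
    fit_trend_car1(supply$age_ce, supply$supply_pct),
    seed = config$seed)

  per <- config$periods
  period_tests <- list()
  if (all(c("LIA", "Modern") %in% names(per))) {
    period_tests$LIA_vs_Modern <- tryCatch(
      compare_periods(supply$age_ce, supply$utilization_pct,
                      per$LIA, per$Modern),
      error = function(e) e$message)
  }
  bp <- tryCatch(fit_breakpoint(supply$age_ce, supply$supply_pct,
                                seed = config$seed),
                 error = function(e) e$message)

  ek <- NULL
  if (!is.null(config$wind)) {
    log_stage("Ekman transport stage")
    wind <- resolve_input(config$wind, read_wind_csv)
    seasonal <- ekman_seasonal(wind, config$ekman)
    mj <- seasonal[seasonal$season == "MJ" & !is.na(seasonal$anomaly), ]
    ek_trend <- if (nrow(mj) >= 10)
      derivative_band(fit_trend_car1(mj$year, mj$anomaly),
                      seed = config$seed) else NULL
    ek <- list(seasonal = seasonal, trend_mj = ek_trend)
  }

  ord <- NULL
  if (!is.null(config$community)) {
    log_stage("community ordination stage")
    comm <- if (is.character(config$community))
      read_community_csv(config$community, config$seasons) else
        config$community
    sq <- sqrt_transform(comm$abundance)
    pca <- pca_axis1(sq, ages = comm$ages)
    ratio <- autumn_spring_ratio(comm$abundance, comm$seasons,
                                 ages = comm$ages)
    supply_on_comm <- approx(supply$age_ce, supply$supply_pct,
                             xout = comm$ages, rule = 2)$y
    rda <- partial_rda(sq, supply_on_comm, comm$ages)
    ord <- list(pca1_scores = pca$scores,
                axis1_variance_fraction = pca$axis1_variance_fraction,
                autumn_spring = ratio, rda = rda,
                supply_on_community_ages = supply_on_comm,
                turnover_vs_supply = correlate_series(pca$scores,
                                                      supply_on_comm))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("baikalsi")),
    seed = config$seed, n_reps = config$n_reps,
    constants = unclass(config$constants),
    reference_age = config$reference_age,
    baseline = config$ekman$baseline)
  manifest$config_hash <- config_hash(manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_supply_csv(supply, file.path(config$out_dir,
                                       "supply_utilization.csv"))
    write_trend_csv(tr_sup, file.path(config$out_dir, "trend.csv"))
    if (!is.null(ek))
      write_ekman_csv(ek$seasonal, file.path(config$out_dir,
                                             "ekman_seasonal.csv"))
    if (!is.null(ord)) {
      write.csv(data.frame(age_ce = comm$ages, pca1_score = ord$pca1_scores,
                           autumn_spring_ratio = ord$autumn_spring$ratio,
                           flags = ord$autumn_spring$flag),
                file.path(config$out_dir, "ordination.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  log_stage("done")

  list(supply = supply, trend_utilization = tr_util, trend_supply = tr_sup,
       period_tests = period_tests, breakpoint = bp, ekman = ek,
       ordination = ord, manifest = manifest)
}

# md5 of the canonical JSON form of the manifest fields
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
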