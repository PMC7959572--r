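# CSV readers/writers with schema validation. CSV is the single interchange
# format; timestamps are ISO-8601 UTC, ages decimal calendar years CE.

check_columns <- function(df, need, file) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("file '", file, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read an isotope sample table
#'
#' Expects columns `sample_id`, `depth_cm`, `age_ce`, `d30si`,
#' `d30si_2sigma`. Ages must be strictly increasing; 2-sigma uncertainties
#' must be non-negative and values above 0.2 permil trigger a warning
#' (typical propagated uncertainties are below 0.11 permil).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_isotope_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "depth_cm", "age_ce", "d30si",
                      "d30si_2sigma"), path)
  check_strictly_increasing(df$age_ce, paste0("ages in '", path, "'"))
  if (any(df$d30si_2sigma < 0))
    stop("negative d30si_2sigma in '", path, "'", call. = FALSE)
  if (any(df$d30si_2sigma > 0.2))
    warning("d30si_2sigma above 0.2 permil in '", path,
            "' (unusually large for cleaned diatom opal)")
  df
}

#' Read a biogenic silica table
#'
#' Expects columns `depth_cm`, `age_ce`, `bsi_pct`, `dbd_g_cm3`,
#' `sar_cm_yr`; adds the derived `mar` column.
#'
#' @param path CSV path.
#' @return Validated data frame with `mar` appended.
#' @export
read_bsi_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("depth_cm", "age_ce", "bsi_pct", "dbd_g_cm3",
                      "sar_cm_yr"), path)
  check_strictly_increasing(df$age_ce, paste0("ages in '", path, "'"))
  if (any(df$bsi_pct < 0 | df$bsi_pct > 100))
    stop("bsi_pct outside [0, 100] in '", path, "'", call. = FALSE)
  if (any(df$dbd_g_cm3 <= 0) || any(df$sar_cm_yr <= 0))
    stop("dbd_g_cm3 and sar_cm_yr must be positive in '", path, "'",
         call. = FALSE)
  df$mar <- compute_bsi_mar(df$bsi_pct, df$dbd_g_cm3, df$sar_cm_yr)
  df
}

#' Read a wind time series
#'
#' Expects columns `timestamp_utc` (ISO-8601), `speed_ms`,
#' `direction_from_deg`; the grid step is inferred and must be constant.
#'
#' @param path CSV path.
#' @return Data frame with POSIXct `timestamp`, `speed_ms`,
#'   `direction_from_deg`.
#' @export
read_wind_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("timestamp_utc", "speed_ms", "direction_from_deg"),
                path)
  ts <- as.POSIXct(df$timestamp_utc, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(ts)))
    stop("unparseable timestamp_utc in '", path, "' (row ",
         which(is.na(ts))[1], ")", call. = FALSE)
  if (any(df$direction_from_deg < 0 | df$direction_from_deg >= 360))
    stop("direction_from_deg outside [0, 360) in '", path, "'",
         call. = FALSE)
  out <- data.frame(timestamp = ts, speed_ms = df$speed_ms,
                    direction_from_deg = df$direction_from_deg)
  validate_wind(out)
  out
}

#' Read a community matrix and its season labels
#'
#' `community.csv` holds `age_ce` plus one column per taxon (relative
#' abundance, %); the sidecar `taxa_seasons.csv` maps `taxon` to
#' `season_label`. Row sums must be within 1% of 100.
#'
#' @param path Community CSV path.
#' @param seasons_path Sidecar CSV path.
#' @return List with `abundance` matrix, `ages`, `seasons` named vector.
#' @export
read_community_csv <- function(path, seasons_path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, "age_ce", path)
  ages <- df$age_ce
  m <- as.matrix(df[, setdiff(names(df), "age_ce"), drop = FALSE])
  if (any(m < 0)) stop("negative abundances in '", path, "'", call. = FALSE)
  bad <- abs(rowSums(m) - 100) > 1
  if (any(bad))
    stop("row sums deviate from 100% by more than 1% in '", path,
         "' (row ", which(bad)[1], ")", call. = FALSE)
  sl <- read.csv(seasons_path, stringsAsFactors = FALSE)
  check_columns(sl, c("taxon", "season_label"), seasons_path)
  seasons <- setNames(sl$season_label, sl$taxon)
  list(abundance = m, ages = ages, seasons = seasons)
}

#' Write the supply/utilization result table
#'
#' Columns: `age_ce`, `utilization_pct`, `utilization_mc_sigma`,
#' `supply_pct`, `supply_mc_sigma`, `qc_flag`.
#'
#' @param result Output of [propagate_uncertainty()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_supply_csv <- function(result, path) {
  out <- data.frame(age_ce = result$age_ce,
                    utilization_pct = result$utilization_pct,
                    utilization_mc_sigma = result$utilization_mc_sigma,
                    supply_pct = result$supply_pct,
                    supply_mc_sigma = result$supply_mc_sigma,
                    qc_flag = result$qc_flag)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the seasonal Ekman transport table
#'
#' @param seasonal Output of [ekman_seasonal()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_ekman_csv <- function(seasonal, path) {
  out <- data.frame(year = seasonal$year, season = seasonal$season,
                    mean_event_mc_kg_per_m = seasonal$mean_event_mc,
                    n_events = seasonal$n_events,
                    anomaly = seasonal$anomaly,
                    smoothed_anomaly = seasonal$smoothed_anomaly)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted trend table
#'
#' @param fit A `trend_fit`, ideally after [derivative_band()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_trend_csv <- function(fit, path) {
  sig <- if (is.null(fit$deriv_lo)) rep(NA, length(fit$eval_times)) else
    fit$deriv_lo > 0 | fit$deriv_hi < 0
  out <- data.frame(age_ce = fit$eval_times, fitted = fit$fitted,
                    se = fit$fitted_se, deriv = fit$derivative,
                    deriv_lo = if (is.null(fit$deriv_lo)) NA else fit$deriv_lo,
                    deriv_hi = if (is.null(fit$deriv_hi)) NA else fit$deriv_hi,
                    significant = sig)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
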