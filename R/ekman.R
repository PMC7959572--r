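#' Configuration for the Ekman transport index
#'
#' Physical constants and geometry for computing wind-driven Ekman transport
#' at the barycentre of Lake Baikal. The lake's main axis runs at about 50
#' degrees counterclockwise from east, i.e. a compass bearing of 40 degrees;
#' persistent northeasterly winds blowing along this axis drive surface water
#' toward the steep northwest shore and trigger coastal downwelling (deep
#' ventilation). Downwelling occurs when the lake is weakly inversely
#' stratified: May--June after ice-out and December--January before freeze-up.
#'
#' @param latitude Degrees north for the Coriolis frequency (default 53.375,
#'   the lake barycentre).
#' @param axis_angle Lake-axis angle, degrees counterclockwise from east
#'   (default 50; equivalent compass bearing 90 - axis_angle = 40).
#' @param rho_water Water density, kg m^-3 (default 999.8).
#' @param rho_air Air density, kg m^-3 (default 1.2).
#' @param drag_coefficient Neutral 10-m drag coefficient over water,
#'   dimensionless (default 1.3e-3). Seasonal anomalies are invariant to this
#'   choice; it only scales absolute transport.
#' @param ne_sector Compass interval (direction-from, degrees) treated as
#'   northeast (default `c(22.5, 67.5)`, the NE octant). May wrap through 0.
#' @param max_gap_hours Interruptions by non-NE winds strictly shorter than
#'   this merge adjacent NE runs into one event (default 24, the "less than
#'   one day" rule).
#' @param baseline Years (inclusive) of the reference period for anomalies
#'   (default `c(1990, 2000)`).
#' @param omega Earth rotation rate, rad s^-1.
#' @param event_mean `"per_event"` (default) averages cumulative transport
#'   over events in a season; `"per_day"` divides seasonal total transport by
#'   total event days.
#' @return An object of class `ekman_config`.
#' @examples
#' ekman_config()
#' @export
ekman_config <- function(latitude = 53.375, axis_angle = 50,
                         rho_water = 999.8, rho_air = 1.2,
                         drag_coefficient = 1.3e-3,
                         ne_sector = c(22.5, 67.5), max_gap_hours = 24,
                         baseline = c(1990, 2000), omega = 7.2921e-5,
                         event_mean = c("per_event", "per_day")) {
  if (abs(latitude) > 90 || latitude == 0)
    stop("latitude must be nonzero and within [-90, 90]", call. = FALSE)
  if (drag_coefficient <= 0) stop("drag_coefficient must be > 0", call. = FALSE)
  if (max_gap_hours <= 0) stop("max_gap_hours must be > 0", call. = FALSE)
  structure(list(latitude = latitude, axis_angle = axis_angle,
                 axis_bearing = (90 - axis_angle) %% 360,
                 rho_water = rho_water, rho_air = rho_air,
                 drag_coefficient = drag_coefficient,
                 ne_sector = ne_sector %% 360,
                 max_gap_hours = max_gap_hours, baseline = baseline,
                 omega = omega, event_mean = match.arg(event_mean)),
            class = "ekman_config")
}

#' @export
print.ekman_config <- function(x, ...) {
  cat("Ekman transport configuration:\n")
  cat(sprintf("  latitude %.3f degN (f = %.4e s^-1), axis bearing %g deg\n",
              x$latitude, coriolis_frequency(x$latitude, x$omega),
              x$axis_bearing))
  cat(sprintf("  NE sector [%g, %g] deg, gap rule < %g h, baseline %d-%d\n",
              x$ne_sector[1], x$ne_sector[2], x$max_gap_hours,
              x$baseline[1], x$baseline[2]))
  invisible(x)
}

#' Coriolis frequency
#'
#' \eqn{f = 2 \Omega \sin(\phi)}. At the equator the frequency is zero and
#' Ekman transport is undefined; a warning flags this case.
#'
#' @param latitude Degrees north.
#' @param omega Earth rotation rate, rad s^-1 (default 7.2921e-5).
#' @return Frequency in s^-1.
#' @examples
#' coriolis_frequency(53.375)
#' @export
coriolis_frequency <- function(latitude, omega = 7.2921e-5) {
  if (any(abs(latitude) > 90))
    stop("latitude must be within [-90, 90]", call. = FALSE)
  f <- 2 * omega * sin(latitude * pi / 180)
  if (any(f == 0))
    warning("Coriolis frequency is zero at the equator; ",
            "Ekman transport is undefined there")
  f
}

#' Wind shear stress from the along-axis wind speed
#'
#' \eqn{\tau = \rho_a C_D W^2}, with \eqn{W} the wind speed component parallel
#' to the lake axis.
#'
#' @param w_axis Along-axis wind speed, m s^-1 (non-negative).
#' @param config An [ekman_config()].
#' @return Stress in N m^-2.
#' @examples
#' wind_stress(10, ekman_config())  # 0.156 N m^-2
#' @export
wind_stress <- function(w_axis, config = ekman_config()) {
  if (any(w_axis < 0, na.rm = TRUE))
    stop("along-axis wind speed must be non-negative", call. = FALSE)
  config$rho_air * config$drag_coefficient * w_axis^2
}

#' Ekman transport rate from wind stress
#'
#' \eqn{M = \tau / (f \rho)}: mass transport per metre of coastline per
#' second, directed 90 degrees to the right of the wind in the Northern
#' Hemisphere.
#'
#' @param tau Wind stress, N m^-2.
#' @param config An [ekman_config()].
#' @return Transport rate in kg m^-1 s^-1.
#' @examples
#' transport_rate(wind_stress(10), ekman_config())  # ~1.333 kg m^-1 s^-1
#' @export
transport_rate <- function(tau, config = ekman_config()) {
  if (any(tau < 0, na.rm = TRUE)) stop("stress must be non-negative",
                                       call. = FALSE)
  f <- 2 * config$omega * sin(config$latitude * pi / 180)
  if (f == 0) stop("Coriolis frequency is zero; transport undefined",
                   call. = FALSE)
  tau / (f * config$rho_water)
}

#' Wind speed component along the lake axis
#'
#' Projects the wind vector onto the lake's along-axis bearing (compass 40
#' degrees for the default 50-degree counterclockwise axis angle):
#' \eqn{W = speed \cos\Delta} where \eqn{\Delta} is the angular difference
#' between the meteorological direction-from and the axis bearing. Negative
#' projections (winds opposing the axis) floor at zero; the NE sector filter
#' already fixes the sign of interest.
#'
#' @param speed Wind speed, m s^-1.
#' @param direction_from Meteorological direction the wind blows from,
#'   degrees (0 = from north, 90 = from east).
#' @param config An [ekman_config()].
#' @return Along-axis speed, m s^-1 (>= 0).
#' @examples
#' axis_component(10, 40)   # along-axis: full speed
#' axis_component(10, 130)  # perpendicular: 0
#' @export
axis_component <- function(speed, direction_from, config = ekman_config()) {
  delta <- abs(((direction_from - config$axis_bearing + 180) %% 360) - 180)
  pmax(0, speed * cos(delta * pi / 180))
}

# TRUE where direction-from lies in the (possibly wrapping) compass sector
in_ne_sector <- function(direction_from, sector) {
  d <- direction_from %% 360
  lo <- sector[1]; hi <- sector[2]
  if (lo <= hi) d >= lo & d <= hi else d >= lo | d <= hi
}

validate_wind <- function(wind) {
  need <- c("timestamp", "speed_ms", "direction_from_deg")
  if (!all(need %in% names(wind)))
    stop("wind table must contain columns: ",
         paste(setdiff(need, names(wind)), collapse = ", "), call. = FALSE)
  if (nrow(wind) == 0) return(invisible(0))
  if (nrow(wind) == 1)
    stop("cannot infer the grid step from a single wind sample",
         call. = FALSE)
  if (any(wind$speed_ms < 0)) stop("wind speeds must be >= 0", call. = FALSE)
  steps <- as.numeric(diff(wind$timestamp), units = "secs")
  if (any(steps <= 0)) stop("timestamps must be strictly increasing",
                            call. = FALSE)
  if (length(unique(steps)) > 1)
    stop("wind series must be on a regular time grid (irregular step found)",
         call. = FALSE)
  invisible(steps[1])
}

#' Detect persistent northeast wind events
#'
#' Finds maximal runs of samples whose direction-from lies in the NE sector;
#' consecutive runs separated by non-NE interruptions strictly shorter than
#' `max_gap_hours` are merged into one event (the interruption itself
#' contributes no transport). Event `end` is the last NE sample time plus one
#' grid step, so `duration_s` covers the represented interval.
#'
#' @param wind Data frame with `timestamp` (POSIXct, regular grid),
#'   `speed_ms`, `direction_from_deg`.
#' @param config An [ekman_config()].
#' @return Data frame of events: `start`, `end`, `duration_s`, `start_idx`,
#'   `end_idx`, `n_ne_samples`. Empty input yields an empty table.
#' @export
detect_ne_events <- function(wind, config = ekman_config()) {
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_s = numeric(), start_idx = integer(),
                      end_idx = integer(), n_ne_samples = integer())
  if (nrow(wind) == 0) return(empty)
  step_s <- validate_wind(wind)
  ne <- in_ne_sector(wind$direction_from_deg, config$ne_sector)
  if (!any(ne)) return(empty)
  r <- rle(ne)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge NE runs across gaps strictly shorter than max_gap_hours
  gap_limit_samples <- config$max_gap_hours * 3600 / step_s
  merged_start <- runs$start[1]
  merged_end <- runs$end[1]
  out_s <- integer(); out_e <- integer()
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged_end - 1L
      if (gap < gap_limit_samples) {
        merged_end <- runs$end[i]
      } else {
        out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)
        merged_start <- runs$start[i]; merged_end <- runs$end[i]
      }
    }
  }
  out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)
  n_ne <- vapply(seq_along(out_s),
                 function(i) sum(ne[out_s[i]:out_e[i]]), integer(1))
  data.frame(start = wind$timestamp[out_s],
             end = wind$timestamp[out_e] + step_s,
             duration_s = as.numeric(wind$timestamp[out_e], units = "secs") -
               as.numeric(wind$timestamp[out_s], units = "secs") + step_s,
             start_idx = out_s, end_idx = out_e, n_ne_samples = n_ne)
}

#' Cumulative Ekman transport of one event
#'
#' Sums the transport rate over the event's NE samples times the grid step:
#' \eqn{M_c = \sum M(W_i) \Delta t}. Non-NE gap samples inside a merged event
#' contribute nothing.
#'
#' @param event One row of the [detect_ne_events()] table (or a list with
#'   `start_idx`, `end_idx`).
#' @param wind The wind data frame the event was detected in.
#' @param config An [ekman_config()].
#' @return Cumulative transport, kg m^-1.
#' @export
cumulative_event_transport <- function(event, wind, config = ekman_config()) {
  step_s <- validate_wind(wind)
  idx <- event$start_idx[1]:event$end_idx[1]
  ne <- in_ne_sector(wind$direction_from_deg[idx], config$ne_sector)
  w <- axis_component(wind$speed_ms[idx], wind$direction_from_deg[idx], config)
  m <- transport_rate(wind_stress(w[ne], config), config)
  sum(m * step_s)
}

# season windows: MJ = [May 1, Jul 1), DJ = [Dec 1 prev year, Feb 1)
season_of_start <- function(start) {
  lt <- as.POSIXlt(start, tz = "UTC")
  mon <- lt$mon + 1L
  year <- lt$year + 1900L
  season <- rep(NA_character_, length(mon))
  syear <- rep(NA_integer_, length(mon))
  mj <- mon %in% c(5L, 6L)
  season[mj] <- "MJ"; syear[mj] <- year[mj]
  dec <- mon == 12L
  season[dec] <- "DJ"; syear[dec] <- year[dec] + 1L
  jan <- mon == 1L
  season[jan] <- "DJ"; syear[jan] <- year[jan]
  data.frame(season = season, year = syear)
}

season_window <- function(season, year) {
  if (season == "MJ") {
    c(as.POSIXct(sprintf("%d-05-01 00:00:00", year), tz = "UTC"),
      as.POSIXct(sprintf("%d-07-01 00:00:00", year), tz = "UTC"))
  } else {
    c(as.POSIXct(sprintf("%d-12-01 00:00:00", year - 1L), tz = "UTC"),
      as.POSIXct(sprintf("%d-02-01 00:00:00", year), tz = "UTC"))
  }
}

#' Seasonal Ekman transport anomalies
#'
#' Assigns detected events to downwelling seasons by their start time (MJ =
#' May--June; DJ = December--January, labelled by the January year so each bin
#' is contiguous), truncating transport outside the season window. Cumulative
#' transport is averaged per (year, season) and normalized by that season's
#' mean over the baseline years to give a dimensionless anomaly; a centred
#' 5-year running mean is appended.
#'
#' @param wind Wind data frame (regular grid).
#' @param config An [ekman_config()].
#' @param events Optional pre-computed [detect_ne_events()] table.
#' @param smooth_window Width (years) of the centred running mean (default 5).
#' @return Data frame: `year`, `season`, `mean_event_mc`, `n_events`,
#'   `anomaly`, `smoothed_anomaly`. Years with no events carry `NA` means.
#' @export
ekman_seasonal <- function(wind, config = ekman_config(), events = NULL,
                           smooth_window = 5) {
  step_s <- validate_wind(wind)
  if (is.null(events)) events <- detect_ne_events(wind, config)
  if (nrow(events) == 0)
    stop("no NE wind events detected; cannot form seasonal anomalies",
         call. = FALSE)
  lab <- season_of_start(events$start)
  keep <- !is.na(lab$season)
  events <- events[keep, , drop = FALSE]
  lab <- lab[keep, , drop = FALSE]
  if (nrow(events) == 0)
    stop("no NE events start inside a downwelling season window",
         call. = FALSE)

  ne_all <- in_ne_sector(wind$direction_from_deg, config$ne_sector)
  w_all <- axis_component(wind$speed_ms, wind$direction_from_deg, config)
  m_all <- transport_rate(wind_stress(w_all, config), config)

  mc <- numeric(nrow(events))
  ev_days <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    win <- season_window(lab$season[i], lab$year[i])
    idx <- events$start_idx[i]:events$end_idx[i]
    inside <- wind$timestamp[idx] >= win[1] & wind$timestamp[idx] < win[2]
    use <- idx[inside & ne_all[idx]]
    mc[i] <- sum(m_all[use] * step_s)
    ev_days[i] <- sum(inside) * step_s / 86400
  }

  agg <- aggregate(cbind(mc = mc, days = ev_days),
                   by = list(year = lab$year, season = lab$season),
                   FUN = sum)
  cnt <- aggregate(list(n_events = mc),
                   by = list(year = lab$year, season = lab$season),
                   FUN = length)
  agg <- merge(agg, cnt, by = c("year", "season"))
  agg$mean_event_mc <- if (config$event_mean == "per_event")
    agg$mc / agg$n_events else agg$mc / agg$days

  out <- list()
  for (s in unique(agg$season)) {
    a <- agg[agg$season == s, , drop = FALSE]
    yrs <- seq(min(a$year), max(a$year))
    full <- data.frame(year = yrs, season = s)
    full <- merge(full, a[, c("year", "mean_event_mc", "n_events")],
                  by = "year", all.x = TRUE)
    full$n_events[is.na(full$n_events)] <- 0L
    base <- full$year >= config$baseline[1] & full$year <= config$baseline[2]
    base_vals <- full$mean_event_mc[base]
    base_vals <- base_vals[!is.na(base_vals)]
    if (length(base_vals) == 0)
      stop("baseline period ", config$baseline[1], "-", config$baseline[2],
           " contains no events for season ", s, call. = FALSE)
    full$anomaly <- full$mean_event_mc / mean(base_vals)
    full$smoothed_anomaly <- as.numeric(
      stats::filter(full$anomaly, rep(1 / smooth_window, smooth_window),
                    sides = 2))
    out[[s]] <- full
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$season, res$year), ]
}
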