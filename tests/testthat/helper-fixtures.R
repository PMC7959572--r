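# shared fixtures and independent oracles, built in code at test time

# regular 6-hourly wind series from direction/speed vectors
wind_series <- function(directions, speeds = 10, step_hours = 6,
                        start = "2000-05-01 00:00:00") {
  n <- length(directions)
  data.frame(
    timestamp = as.POSIXct(start, tz = "UTC") +
      (seq_len(n) - 1) * step_hours * 3600,
    speed_ms = rep_len(speeds, n),
    direction_from_deg = directions)
}

# independent brute-force NE event segmentation: walk the series sample by
# sample, tracking the open event and the running non-NE gap length
oracle_ne_events <- function(wind, sector = c(22.5, 67.5), max_gap_hours = 24,
                             step_hours = NULL) {
  if (is.null(step_hours))
    step_hours <- as.numeric(diff(wind$timestamp[1:2]), units = "hours")
  d <- wind$direction_from_deg %% 360
  ne <- if (sector[1] <= sector[2]) d >= sector[1] & d <= sector[2] else
    d >= sector[1] | d <= sector[2]
  events <- list()
  open_start <- NA_integer_; open_end <- NA_integer_; gap <- 0
  for (i in seq_along(ne)) {
    if (ne[i]) {
      if (is.na(open_start)) {
        open_start <- i
      } else if (gap * step_hours >= max_gap_hours) {
        events[[length(events) + 1]] <- c(open_start, open_end)
        open_start <- i
      }
      open_end <- i
      gap <- 0
    } else if (!is.na(open_start)) {
      gap <- gap + 1
    }
  }
  if (!is.na(open_start))
    events[[length(events) + 1]] <- c(open_start, open_end)
  if (length(events) == 0)
    return(data.frame(start_idx = integer(), end_idx = integer()))
  m <- do.call(rbind, events)
  data.frame(start_idx = m[, 1], end_idx = m[, 2])
}

# independent two-segment continuous least-squares search using lm()
oracle_breakpoint <- function(times, values, margin = 0.1) {
  ord <- order(times)
  t <- times[ord]; y <- values[ord]
  n <- length(t)
  lo <- max(2L, ceiling(margin * n)); hi <- min(n - 2L, floor((1 - margin) * n))
  cand <- unique(t[lo:hi])
  rss <- vapply(cand, function(cp) {
    sum(resid(lm(y ~ t + I(pmax(t - cp, 0))))^2)
  }, numeric(1))
  best <- which.min(rss)
  rss0 <- sum(resid(lm(y ~ t))^2)
  f <- ((rss0 - rss[best]) / 2) / (rss[best] / (n - 4))
  list(break_year = cand[best], f_statistic = f)
}

# small noise-free paired record with analytically simple truth
tiny_paired <- function() {
  iso <- data.frame(sample_id = c("a", "b", "c", "d"),
                    age_ce = c(1900, 1950, 2000, 2005),
                    d30si = c(1.388, 1.388, 1.388, 1.388),
                    d30si_2sigma = rep(0.1, 4))
  bsi <- data.frame(age_ce = c(1890, 1950, 2005),
                    bsi_pct = c(20, 20, 40),
                    dbd_g_cm3 = rep(0.5, 3), sar_cm_yr = rep(0.04, 3))
  align_series(iso, bsi)
}
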