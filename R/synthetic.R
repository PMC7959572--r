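# Synthetic data with known truth. The generators invert the analysis
# equations rather than simulating lake physics, so the truth is analytically
# known and the noise-free limit is exactly recoverable by the pipeline.

default_utilization_curve <- function() {
  # smooth utilization history (%) emulating the character of the south-basin
  # composite record: ~70-90% range, high plateau during the Little Ice Age,
  # low Medieval values, declining through the 20th century
  ctrl_age <- c(0, 150, 350, 500, 625, 750, 880, 1030, 1180, 1260, 1400,
                1550, 1700, 1840, 1900, 1950, 1980, 2013)
  ctrl_util <- c(72.5, 73.5, 75.5, 81, 83, 81.5, 76, 72, 75, 84, 86.5,
                 87.5, 87.5, 85.5, 81, 79, 77.5, 76.5)
  splinefun(ctrl_age, ctrl_util, method = "natural")
}

default_supply_curve <- function() {
  # relative supply (%): flat at 100 until 1850 CE, rising linearly to 160%
  # by 2005 and continuing at the same rate
  function(age) 100 + pmax(0, age - 1850) * (60 / (2005 - 1850))
}

#' Configuration for the synthetic sediment core generator
#'
#' Defaults describe a ~2,000-year composite record: 45 isotope samples
#' (denser toward the present, as in a core with compaction), 250 BSi
#' samples, isotope noise of 0.11 permil (2-sigma, so sd 0.055), BSi
#' concentration noise of 0.49% absolute, constant dry bulk density 0.25 g
#' cm^-3 and accumulation rate 0.03 cm yr^-1, ~30% BSi at the 2005 reference.
#' The truth curves are utilization drifting between roughly 70 and 90% and
#' supply flat at 100% until 1850 CE then rising to 160% by 2005.
#'
#' @param age_span `c(start, end)` years CE (default `c(0, 2013)`).
#' @param n_iso,n_bsi Sample counts for the isotope and BSi series.
#' @param iso_noise_2sigma Isotope measurement noise, permil 2-sigma
#'   (default 0.11).
#' @param bsi_noise_sigma BSi concentration noise, absolute % 1-sigma
#'   (default 0.49).
#' @param dbd,sar Dry bulk density (g cm^-3) and sediment accumulation rate
#'   (cm yr^-1), constants of the synthetic core.
#' @param bsi_ref_pct BSi concentration at the reference age (default 30%).
#' @param reference_age Reference year for the supply normalization (2005).
#' @param utilization_curve,supply_curve Functions of age (years CE)
#'   returning truth in percent.
#' @return A list of class `core_config`.
#' @export
core_config <- function(age_span = c(0, 2013), n_iso = 45, n_bsi = 250,
                        iso_noise_2sigma = 0.11, bsi_noise_sigma = 0.49,
                        dbd = 0.25, sar = 0.03, bsi_ref_pct = 30,
                        reference_age = 2005,
                        utilization_curve = default_utilization_curve(),
                        supply_curve = default_supply_curve()) {
  structure(as.list(environment()), class = "core_config")
}

# isotope sampling grid: denser toward the present, reference age snapped in
iso_age_grid <- function(config) {
  span <- config$age_span
  u <- seq(0, 1, length.out = config$n_iso)
  ages <- span[2] - (span[2] - span[1]) * u^1.15
  ages <- sort(ages)
  ages[which.min(abs(ages - config$reference_age))] <- config$reference_age
  ages
}

#' Generate a synthetic sediment core with known truth
#'
#' Inverts the analysis equations: isotope values are
#' \eqn{\delta^{30}Si = \delta_{lake} + \epsilon (1 - U(t)/100) + noise} and
#' BSi MAR follows \eqn{MAR = MAR_{ref} (S(t)/100) (U(t)/U_{ref})}, so that
#' the utilization and supply pipeline recovers the configured truth curves
#' exactly in the noise-free limit. The BSi age grid includes the isotope
#' ages, making the alignment interpolation exact.
#'
#' @param config A [core_config()].
#' @param seed Integer seed; identical (config, seed) pairs give identical
#'   tables.
#' @param constants An [isotope_constants()] object used for the inversion.
#' @return List with `isotopes` (data frame), `bsi` (data frame) and `truth`
#'   (ages, utilization %, supply % and supply relative to the reference
#'   sample).
#' @export
make_core <- function(config = core_config(), seed = 1,
                      constants = isotope_constants()) {
  stopifnot(inherits(config, "core_config"))
  set.seed(seed)
  iso_ages <- iso_age_grid(config)
  u_iso <- config$utilization_curve(iso_ages)
  if (any(u_iso <= 0 | u_iso > 100))
    stop("utilization truth curve must lie in (0, 100]%", call. = FALSE)

  d30_true <- constants$delta_lake + constants$epsilon * (1 - u_iso / 100)
  d30 <- d30_true + rnorm(length(iso_ages), 0, config$iso_noise_2sigma / 2)
  iso <- data.frame(
    sample_id = sprintf("SYN-%02d", seq_along(iso_ages)),
    depth_cm = round(seq(50, 0, length.out = length(iso_ages)), 2),
    age_ce = iso_ages, d30si = d30,
    d30si_2sigma = rep(config$iso_noise_2sigma, length(iso_ages)))

  # BSi grid contains the isotope ages so linear interpolation is exact
  bsi_ages <- sort(unique(c(
    seq(config$age_span[1], config$age_span[2],
        length.out = config$n_bsi - config$n_iso), iso_ages)))
  u_bsi <- config$utilization_curve(bsi_ages)
  s_bsi <- config$supply_curve(bsi_ages)
  u_ref <- config$utilization_curve(config$reference_age)
  s_ref <- config$supply_curve(config$reference_age)
  mar_ref <- (config$bsi_ref_pct / 100) * config$dbd * config$sar
  mar_true <- mar_ref * (s_bsi / s_ref) * (u_bsi / u_ref)
  bsi_pct_true <- 100 * mar_true / (config$dbd * config$sar)
  bsi_pct <- bsi_pct_true + rnorm(length(bsi_ages), 0, config$bsi_noise_sigma)
  bsi <- data.frame(
    depth_cm = round(seq(50, 0, length.out = length(bsi_ages)), 3),
    age_ce = bsi_ages, bsi_pct = bsi_pct,
    dbd_g_cm3 = rep(config$dbd, length(bsi_ages)),
    sar_cm_yr = rep(config$sar, length(bsi_ages)))

  s_iso <- config$supply_curve(iso_ages)
  truth <- list(seed = seed, age_ce = iso_ages, utilization_pct = u_iso,
                supply_pct = s_iso,
                supply_rel_reference = 100 * s_iso / s_ref,
                reference_age = config$reference_age)
  list(isotopes = iso, bsi = bsi, truth = truth)
}

#' Configuration for the synthetic wind generator
#'
#' A two-state persistence (Markov) process on a regular sub-daily grid:
#' in the NE state the direction is uniform inside the NE sector and the
#' speed Weibull-distributed; otherwise the direction is uniform outside the
#' sector with a lighter speed distribution. NE speeds carry a configurable
#' linear trend (percent per decade) emulating the 20th-century strengthening
#' of winds during the downwelling seasons.
#'
#' @param span Years CE covered, inclusive (default `c(1950, 2010)`).
#' @param step_hours Grid step; must divide 24 (default 6).
#' @param p_stay_ne Probability of remaining in the NE state per step
#'   (default 0.9, mean event length ~2.5 d at 6-h steps).
#' @param p_enter_ne Probability of entering the NE state (default 1/30,
#'   giving ~25% NE occupancy).
#' @param ne_shape,ne_scale Weibull parameters of NE wind speed (default
#'   shape 2, scale 8 m s^-1).
#' @param other_shape,other_scale Weibull parameters outside NE events
#'   (default shape 2, scale 5 m s^-1).
#' @param trend_pct_per_decade Linear trend applied to NE speeds from the
#'   start of the span (default 1).
#' @param ne_sector NE compass sector, degrees direction-from.
#' @return A list of class `wind_config`.
#' @export
wind_config <- function(span = c(1950, 2010), step_hours = 6,
                        p_stay_ne = 0.9, p_enter_ne = 1 / 30,
                        ne_shape = 2, ne_scale = 8,
                        other_shape = 2, other_scale = 5,
                        trend_pct_per_decade = 1,
                        ne_sector = c(22.5, 67.5)) {
  if (24 %% step_hours != 0)
    stop("step_hours must divide 24", call. = FALSE)
  structure(as.list(environment()), class = "wind_config")
}

#' Generate a synthetic wind series with known NE events
#'
#' @param config A [wind_config()].
#' @param seed Integer seed.
#' @return List with `wind` (data frame: `timestamp`, `speed_ms`,
#'   `direction_from_deg`) and `truth` (`state` vector, `events` = maximal
#'   NE-state runs, `merged_events` = runs merged across gaps shorter than
#'   one day, `trend_pct_per_decade`).
#' @export
make_wind <- function(config = wind_config(), seed = 1) {
  stopifnot(inherits(config, "wind_config"))
  set.seed(seed)
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", config$span[1]), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:59:59", config$span[2]), tz = "UTC")
  ts <- seq(t0, t1, by = config$step_hours * 3600)
  n <- length(ts)

  u_state <- runif(n)
  state <- logical(n)
  state[1] <- u_state[1] < config$p_enter_ne
  for (i in 2:n) {
    p <- if (state[i - 1]) config$p_stay_ne else config$p_enter_ne
    state[i] <- u_state[i] < p
  }

  lo <- config$ne_sector[1]; hi <- config$ne_sector[2]
  width <- (hi - lo) %% 360
  dir <- numeric(n)
  dir[state] <- lo + runif(sum(state)) * width
  dir[!state] <- (hi + runif(sum(!state)) * (360 - width)) %% 360

  years <- 1970 + as.numeric(ts) / (365.2425 * 86400)
  trend <- 1 + (config$trend_pct_per_decade / 100) *
    (years - config$span[1]) / 10
  speed <- numeric(n)
  speed[state] <- rweibull(sum(state), config$ne_shape, config$ne_scale) *
    trend[state]
  speed[!state] <- rweibull(sum(!state), config$other_shape,
                            config$other_scale)

  wind <- data.frame(timestamp = ts, speed_ms = speed,
                     direction_from_deg = dir)

  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- data.frame(start_idx = starts[r$values], end_idx = ends[r$values])
  merged <- merge_runs(ev, gap_limit = 24 / config$step_hours)
  truth <- list(seed = seed, state = state, events = ev,
                merged_events = merged,
                trend_pct_per_decade = config$trend_pct_per_decade)
  list(wind = wind, truth = truth)
}

# merge index runs whose gaps are strictly shorter than gap_limit samples
merge_runs <- function(runs, gap_limit) {
  if (nrow(runs) == 0) return(runs)
  out_s <- runs$start_idx[1]; out_e <- runs$end_idx[1]
  ss <- integer(); ee <- integer()
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start_idx[i] - out_e - 1L < gap_limit) {
        out_e <- runs$end_idx[i]
      } else {
        ss <- c(ss, out_s); ee <- c(ee, out_e)
        out_s <- runs$start_idx[i]; out_e <- runs$end_idx[i]
      }
    }
  }
  data.frame(start_idx = c(ss, out_s), end_idx = c(ee, out_e))
}

#' Configuration for the synthetic diatom community generator
#'
#' Eight planktonic taxa typical of a deep-lake assemblage, labelled by bloom
#' season, observed over 1800--2010 CE. A nutrient-supply signal (the part of
#' the supply curve not explained by a linear time trend) is injected so that
#' it accounts for a prescribed fraction of the community variance remaining
#' after time is partialled out; a separate long-term compositional trend and
#' unstructured noise make up the rest.
#'
#' @param ages Sample ages, years CE (default 64 samples over 1800--2010).
#' @param mean_abundance Named baseline composition, % summing to 100.
#' @param seasons Named season labels (`"spring"`, `"autumn"`, `"other"`).
#' @param supply_curve Driver function of age (% supply).
#' @param target_fraction Fraction of residual (time-partialled) community
#'   variance attributed to the supply signal (default 0.25; 0 removes the
#'   supply response entirely).
#' @param amplitude Total magnitude of supply signal plus noise in
#'   square-root-abundance units (default 6), split between the two by
#'   `target_fraction`.
#' @param trend_amplitude Amplitude of the time-trend component (default 2).
#' @return A list of class `community_config`.
#' @export
community_config <- function(
    ages = seq(1800, 2010, length.out = 64),
    mean_abundance = c(Aulacoseira_baicalensis = 25,
                       Aulacoseira_skvortzowii = 14,
                       Ulnaria_acus = 12,
                       Crateriportula_inconspicua = 15,
                       Cyclotella_minuta = 16,
                       Stephanodiscus_meyerii = 8,
                       Synedra_praegracilis = 4,
                       Nitzschia_acicularis = 6),
    seasons = c(Aulacoseira_baicalensis = "spring",
                Aulacoseira_skvortzowii = "spring",
                Ulnaria_acus = "spring",
                Crateriportula_inconspicua = "autumn",
                Cyclotella_minuta = "autumn",
                Stephanodiscus_meyerii = "spring",
                Synedra_praegracilis = "autumn",
                Nitzschia_acicularis = "other"),
    supply_curve = default_supply_curve(),
    target_fraction = 0.25, amplitude = 6, trend_amplitude = 2) {
  if (abs(sum(mean_abundance) - 100) > 1e-8)
    stop("mean_abundance must sum to 100", call. = FALSE)
  if (target_fraction < 0 || target_fraction >= 1)
    stop("target_fraction must lie in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "community_config")
}

#' Generate a synthetic diatom community matrix with known variance split
#'
#' Works in square-root-abundance space, where the downstream ordination
#' operates: a supply signal orthogonal to the time trend, a time-trend
#' component, and noise (projected orthogonal to both regressors and, in
#' taxon space, to the baseline composition so row sums stay at 100) are
#' combined with norms chosen so the supply signal accounts for exactly the
#' prescribed fraction of the residual variance. Squaring and renormalizing
#' rows to 100% yields the abundance matrix; the small closure distortion is
#' the only deviation from the prescribed split.
#'
#' @param config A [community_config()].
#' @param seed Integer seed.
#' @return List with `abundance` (samples x taxa matrix, rows sum to 100),
#'   `ages`, `seasons`, `supply` (driver series) and `truth`
#'   (`target_fraction`, construction norms).
#' @export
make_community <- function(config = community_config(), seed = 1) {
  stopifnot(inherits(config, "community_config"))
  set.seed(seed)
  ages <- config$ages
  n <- length(ages)
  m0 <- config$mean_abundance
  p <- length(m0)
  S <- sqrt(m0)

  x <- config$supply_curve(ages)
  tc <- ages - mean(ages)
  Z <- cbind(1, tc)
  xr <- drop(x - Z %*% qr.coef(qr(Z), x))     # supply minus linear trend
  if (config$target_fraction > 0 &&
      sum(xr^2) < 1e-8 * sum((x - mean(x))^2))
    stop("supply driver is collinear with time; no injectable signal",
         call. = FALSE)
  if (sum(xr^2) > 0) xr <- xr / sqrt(sum(xr^2))
  tn <- tc / sqrt(sum(tc^2))

  unit_orth_S <- function(v) {
    v <- v - S * sum(v * S) / sum(S^2)
    v / sqrt(sum(v^2))
  }
  # taxon response patterns: supply favours Ulnaria/A. skvortzowii at the
  # expense of autumn endemics; the long-term trend shifts spring vs autumn
  w_sig <- unit_orth_S(c(-0.2, 0.7, 0.8, -0.5, -0.6, 0.1, -0.1, 0.2))
  w_tr <- unit_orth_S(c(0.5, 0.2, 0.3, -0.7, -0.4, 0.3, -0.2, 0.1))

  E <- matrix(rnorm(n * p), n, p)
  H <- cbind(1, tn, xr)
  E <- E - H %*% qr.coef(qr(H), E)            # orthogonal to regressors
  E <- E - (E %*% S) %*% t(S) / sum(S^2)      # rows orthogonal to baseline
  sig_norm <- config$amplitude * sqrt(config$target_fraction)
  e_norm <- config$amplitude * sqrt(1 - config$target_fraction)
  E <- E * e_norm / sqrt(sum(E^2))

  A <- matrix(S, n, p, byrow = TRUE) +
    sig_norm * outer(xr, w_sig) +
    config$trend_amplitude * outer(tn, w_tr) + E
  A <- pmax(A, 0.05)
  abundance <- A^2
  abundance <- 100 * abundance / rowSums(abundance)
  colnames(abundance) <- names(m0)

  truth <- list(seed = seed, target_fraction = config$target_fraction,
                signal_norm = sig_norm, noise_norm = e_norm,
                supply_pattern = w_sig, trend_pattern = w_tr)
  list(abundance = abundance, ages = ages, seasons = config$seasons,
       supply = x, truth = truth)
}
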