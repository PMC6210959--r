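#' Configuration for the synthetic weir-pair generator
#'
#' Parameters of the statistical generator that emulates four years of
#' weekly monitoring at an upstream/downstream weir pair on a temperate
#' monsoonal river: sinusoidal annual cycles for air temperature and solar
#' radiation, right-skewed weekly rainfall with a summer monsoon peak,
#' mean-reverting nutrient series with rainfall pulses, and a chlorophyll-a
#' recursion with a saturating temperature-nutrient growth term, rainfall
#' flushing, one-week autocorrelation and lagged upstream-to-downstream
#' transfer.
#'
#' Defaults are calibrated to the published monitoring envelopes for
#' mid-river weirs: annual mean air temperature about 14 deg C, annual solar
#' radiation about 14.4 MJ/m2, annual rainfall roughly 1000-1450 mm, total
#' nitrogen 2.6-3.7 mg/L, total phosphorus about 0.05-0.06 mg/L, and
#' downstream chlorophyll-a averaging in the 19-26 ug/L band with maxima
#' near but below 150 ug/L.
#'
#' @param n_weeks series length (default 208, about 4 years).
#' @param start first week-start date (a Monday).
#' @param temp_mean,temp_amplitude,temp_noise_sd air-temperature cycle, deg C.
#' @param solar_mean,solar_amplitude,solar_noise_sd solar cycle, MJ/m2.
#' @param rain_shape,rain_scale_base weekly rainfall Gamma parameters (mm).
#' @param monsoon_peak_doy,monsoon_width_days,monsoon_factor summer
#'   inflation of the rainfall scale (peak day-of-year, Gaussian width,
#'   peak multiplier).
#' @param TN_mean,TN_seasonal,TN_ar,TN_noise_sd,TN_rain_pulse total-nitrogen
#'   process, mg/L.
#' @param TP_mean,TP_seasonal,TP_ar,TP_noise_sd,TP_rain_pulse total-phosphorus
#'   process, mg/L.
#' @param chl_base baseline chlorophyll input, ug/L per week.
#' @param chl_growth maximum weekly growth contribution, ug/L.
#' @param chl_temp_mid,chl_temp_scale logistic temperature gate (deg C).
#' @param chl_KTP phosphorus half-saturation (mg/L).
#' @param chl_solar_coef relative growth change per MJ/m2 of solar anomaly.
#' @param chl_flush rainfall washout rate per mm: each week the standing
#'   stock is diluted by `exp(-chl_flush * RF)` (storm flushing acts on
#'   concentration, so high-rainfall weeks wash out proportionally more
#'   biomass).
#' @param ar_coeff one-week chlorophyll autocorrelation, in `[0, 1)`.
#' @param coupling upstream-to-downstream transfer fraction, in `[0, 1]`.
#' @param coupling_lag transfer lag in weeks (default 1).
#' @param chl_noise_sd chlorophyll innovation noise, ug/L.
#' @param seed master seed; every sub-process derives its stream from it.
#' @return a validated `"synth_config"` list.
#' @export
synth_config <- function(n_weeks = 208L, start = as.Date("2013-01-07"),
                         temp_mean = 14, temp_amplitude = 12,
                         temp_noise_sd = 1.5,
                         solar_mean = 14.4, solar_amplitude = 7,
                         solar_noise_sd = 1.5,
                         rain_shape = 0.8, rain_scale_base = 15,
                         monsoon_peak_doy = 210, monsoon_width_days = 25,
                         monsoon_factor = 6,
                         TN_mean = 3.0, TN_seasonal = 0.5, TN_ar = 0.6,
                         TN_noise_sd = 0.35, TN_rain_pulse = 0.004,
                         TP_mean = 0.055, TP_seasonal = 0.010, TP_ar = 0.6,
                         TP_noise_sd = 0.02, TP_rain_pulse = 2e-4,
                         chl_base = 1.5, chl_growth = 44,
                         chl_temp_mid = 18, chl_temp_scale = 2,
                         chl_KTP = 0.06, chl_solar_coef = 0.02,
                         chl_flush = 0.01,
                         ar_coeff = 0.5, coupling = 0.5, coupling_lag = 1L,
                         chl_noise_sd = 1.5, seed = 1L) {
  cfg <- list(n_weeks = as.integer(n_weeks), start = as.Date(start),
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_noise_sd = temp_noise_sd,
              solar_mean = solar_mean, solar_amplitude = solar_amplitude,
              solar_noise_sd = solar_noise_sd,
              rain_shape = rain_shape, rain_scale_base = rain_scale_base,
              monsoon_peak_doy = monsoon_peak_doy,
              monsoon_width_days = monsoon_width_days,
              monsoon_factor = monsoon_factor,
              TN_mean = TN_mean, TN_seasonal = TN_seasonal, TN_ar = TN_ar,
              TN_noise_sd = TN_noise_sd, TN_rain_pulse = TN_rain_pulse,
              TP_mean = TP_mean, TP_seasonal = TP_seasonal, TP_ar = TP_ar,
              TP_noise_sd = TP_noise_sd, TP_rain_pulse = TP_rain_pulse,
              chl_base = chl_base, chl_growth = chl_growth,
              chl_temp_mid = chl_temp_mid, chl_temp_scale = chl_temp_scale,
              chl_KTP = chl_KTP, chl_solar_coef = chl_solar_coef,
              chl_flush = chl_flush,
              ar_coeff = ar_coeff, coupling = coupling,
              coupling_lag = as.integer(coupling_lag),
              chl_noise_sd = chl_noise_sd, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  bad <- character(0)
  if (cfg$n_weeks < 8L) bad <- c(bad, "n_weeks must be >= 8")
  sds <- c("temp_noise_sd", "solar_noise_sd", "TN_noise_sd", "TP_noise_sd",
           "chl_noise_sd")
  for (f in sds) if (cfg[[f]] < 0) bad <- c(bad, paste(f, "must be >= 0"))
  if (cfg$ar_coeff < 0 || cfg$ar_coeff >= 1)
    bad <- c(bad, "ar_coeff must be in [0, 1) (stable recursion)")
  if (cfg$coupling < 0 || cfg$coupling > 1)
    bad <- c(bad, "coupling must be in [0, 1]")
  if (cfg$coupling_lag < 1) bad <- c(bad, "coupling_lag must be >= 1")
  if (cfg$rain_shape <= 0 || cfg$rain_scale_base <= 0)
    bad <- c(bad, "rainfall Gamma parameters must be > 0")
  if (length(bad))
    stop("synth_config(): invalid configuration:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}

# derived per-component seeds so each stochastic stream is independent yet
# reproducible from the single master seed (kept well below 2^31)
sub_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 1000L + offset

week_doy <- function(cfg) {
  dates <- cfg$start + 7L * (seq_len(cfg$n_weeks) - 1L)
  list(dates = dates, doy = as.integer(format(dates, "%j")))
}

seasonal_cos <- function(doy, peak_doy) cos(2 * pi * (doy - peak_doy) / 365.25)

#' Generate weekly weather series
#'
#' Air temperature and solar radiation follow sinusoidal annual cycles
#' (peaking in late July) with Gaussian noise; weekly rainfall totals are
#' Gamma-distributed with a monsoon-season scale inflation, so they are
#' right-skewed and non-negative. Deterministic under the configuration
#' seed.
#'
#' @param config a `"synth_config"`.
#' @return data frame `week_start, AT, RF, SR`.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  wk <- week_doy(config)
  old <- local_seed(sub_seed(config, 1L))
  on.exit(restore_seed(old), add = TRUE)
  n <- config$n_weeks
  AT <- config$temp_mean +
    config$temp_amplitude * seasonal_cos(wk$doy, 210) +
    stats::rnorm(n, 0, config$temp_noise_sd)
  SR <- pmax(config$solar_mean +
    config$solar_amplitude * seasonal_cos(wk$doy, 180) +
    stats::rnorm(n, 0, config$solar_noise_sd), 0.1)
  monsoon <- exp(-(wk$doy - config$monsoon_peak_doy)^2 /
                   (2 * config$monsoon_width_days^2))
  scale_t <- config$rain_scale_base *
    (1 + (config$monsoon_factor - 1) * monsoon)
  RF <- stats::rgamma(n, shape = config$rain_shape, scale = scale_t)
  data.frame(week_start = wk$dates, AT = AT, RF = RF, SR = SR)
}

#' Generate daily weather records
#'
#' The same annual cycles as [generate_weather()] sampled daily — exists to
#' exercise the daily-to-weekly aggregation path.
#'
#' @param config a `"synth_config"`.
#' @param n_days number of days (default covers `n_weeks`).
#' @return data frame `date, air_temp, rainfall, solar`.
#' @export
generate_daily_weather <- function(config, n_days = config$n_weeks * 7L) {
  stopifnot(inherits(config, "synth_config"))
  old <- local_seed(sub_seed(config, 2L))
  on.exit(restore_seed(old), add = TRUE)
  dates <- config$start + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  air_temp <- config$temp_mean +
    config$temp_amplitude * seasonal_cos(doy, 210) +
    stats::rnorm(n_days, 0, config$temp_noise_sd)
  solar <- pmax(config$solar_mean +
    config$solar_amplitude * seasonal_cos(doy, 180) +
    stats::rnorm(n_days, 0, config$solar_noise_sd), 0.1)
  monsoon <- exp(-(doy - config$monsoon_peak_doy)^2 /
                   (2 * config$monsoon_width_days^2))
  scale_t <- config$rain_scale_base / 7 *
    (1 + (config$monsoon_factor - 1) * monsoon)
  rainfall <- stats::rgamma(n_days, shape = config$rain_shape, scale = scale_t)
  data.frame(date = dates, air_temp = air_temp, rainfall = rainfall,
             solar = solar)
}

#' Generate weekly nutrient series
#'
#' Total nitrogen and total phosphorus are mean-reverting AR(1) processes
#' around a seasonal mean, with positive rainfall-driven pulses (storm
#' loading) and positivity clamps; NP is their ratio.
#'
#' @param config a `"synth_config"`.
#' @param weather weekly weather from [generate_weather()].
#' @param stream_offset internal seed offset, letting the two sites of a
#'   pair draw independent nutrient noise.
#' @return data frame `week_start, TN, TP, NP`.
#' @export
generate_nutrients <- function(config, weather, stream_offset = 10L) {
  stopifnot(inherits(config, "synth_config"))
  old <- local_seed(sub_seed(config, stream_offset))
  on.exit(restore_seed(old), add = TRUE)
  n <- nrow(weather)
  doy <- as.integer(format(weather$week_start, "%j"))
  rf_anom <- weather$RF - mean(weather$RF)
  ar1 <- function(mean_t, ar, sd, pulse) {
    x <- numeric(n)
    x[1] <- mean_t[1] + stats::rnorm(1, 0, sd)
    for (t in 2:n)
      x[t] <- mean_t[t] + ar * (x[t - 1] - mean_t[t - 1]) +
        pulse * max(rf_anom[t], 0) + stats::rnorm(1, 0, sd)
    x
  }
  TN <- pmax(ar1(config$TN_mean + config$TN_seasonal * seasonal_cos(doy, 30),
                 config$TN_ar, config$TN_noise_sd, config$TN_rain_pulse), 0.3)
  TP <- pmax(ar1(config$TP_mean + config$TP_seasonal * seasonal_cos(doy, 210),
                 config$TP_ar, config$TP_noise_sd, config$TP_rain_pulse), 0.005)
  data.frame(week_start = weather$week_start, TN = TN, TP = TP, NP = TN / TP)
}

# weekly growth input: saturating temperature gate x phosphorus limitation
# x solar modulation
chl_driver <- function(config, AT, SR, TN, TP) {
  gate <- 1 / (1 + exp(-(AT - config$chl_temp_mid) / config$chl_temp_scale))
  plim <- TP / (TP + config$chl_KTP)
  solar <- pmax(1 + config$chl_solar_coef * (SR - config$solar_mean), 0)
  config$chl_base + config$chl_growth * gate * plim * solar
}

# standing stock (growth + carryover + upstream transfer) diluted by the
# rainfall washout factor exp(-chl_flush * RF); stable since
# ar_coeff * washout < 1
chl_recursion <- function(config, f, RF, upstream = NULL, noise) {
  n <- length(f)
  x <- numeric(n)
  lag <- config$coupling_lag
  wash <- exp(-config$chl_flush * RF)
  x[1] <- max(f[1] * wash[1] + noise[1], 0.1)
  for (t in 2:n) {
    up_term <- if (!is.null(upstream) && t > lag)
      config$coupling * upstream[t - lag] else 0
    x[t] <- max((f[t] + config$ar_coeff * x[t - 1] + up_term) * wash[t] +
                  noise[t], 0.1)
  }
  x
}

#' Generate a coupled upstream/downstream weir pair
#'
#' Both sites share the weekly weather (same catchment) but draw independent
#' nutrient and chlorophyll noise. Upstream chlorophyll follows
#' `Chla_u(t) = (f(drivers_t) + ar_coeff * Chla_u(t-1)) * exp(-chl_flush *
#' RF_t) + noise`, with `f` a saturating temperature-gated,
#' phosphorus-limited, solar-modulated growth term and the exponential
#' factor the rainfall washout (dilution of the standing stock); the
#' downstream site adds `coupling * Chla_u(t - coupling_lag)` inside the
#' washed-out stock — mass transported over the weir. Both series are
#' clamped at 0.1 ug/L. The noise-free latent series and the generating
#' coefficients are returned as ground truth for recovery tests.
#'
#' @param config a `"synth_config"`.
#' @param permute_upstream_noise diagnostic switch: permute the upstream
#'   chlorophyll noise draws (used to demonstrate that with `coupling = 0`
#'   the downstream series does not depend on them).
#' @return list with `up` and `down` (`"site_series"`) and `truth` (list
#'   with `chl_up_latent`, `chl_down_latent`, `config`).
#' @export
generate_pair <- function(config, permute_upstream_noise = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  weather <- generate_weather(config)
  nut_up <- generate_nutrients(config, weather, stream_offset = 10L)
  nut_dn <- generate_nutrients(config, weather, stream_offset = 11L)
  n <- config$n_weeks

  old <- local_seed(sub_seed(config, 20L))
  noise_up <- stats::rnorm(n, 0, config$chl_noise_sd)
  noise_dn <- stats::rnorm(n, 0, config$chl_noise_sd)
  restore_seed(old)
  if (permute_upstream_noise) noise_up <- rev(noise_up)

  f_up <- chl_driver(config, weather$AT, weather$SR, nut_up$TN, nut_up$TP)
  f_dn <- chl_driver(config, weather$AT, weather$SR, nut_dn$TN, nut_dn$TP)
  chl_up <- chl_recursion(config, f_up, weather$RF, noise = noise_up)
  chl_dn <- chl_recursion(config, f_dn, weather$RF, upstream = chl_up,
                          noise = noise_dn)
  if (!all(is.finite(chl_up)) || !all(is.finite(chl_dn)))
    stop("generate_pair(): chlorophyll recursion diverged; check ar_coeff",
         call. = FALSE)
  zero <- numeric(n)
  latent_up <- chl_recursion(config, f_up, weather$RF, noise = zero)
  latent_dn <- chl_recursion(config, f_dn, weather$RF, upstream = latent_up,
                             noise = zero)

  mk <- function(nut, chl, id) site_series(
    data.frame(week_start = weather$week_start, AT = weather$AT,
               RF = weather$RF, SR = weather$SR, TN = nut$TN, TP = nut$TP,
               NP = nut$NP, Chla = chl), site_id = id)
  list(up = mk(nut_up, chl_up, "synthetic_upstream"),
       down = mk(nut_dn, chl_dn, "synthetic_downstream"),
       truth = list(chl_up_latent = latent_up, chl_down_latent = latent_dn,
                    config = config))
}

#' Write the ground-truth sidecar CSV
#'
#' @param truth the `truth` element of [generate_pair()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  out <- data.frame(
    week = seq_along(truth$chl_up_latent),
    chl_up_latent = sprintf("%.17g", truth$chl_up_latent),
    chl_down_latent = sprintf("%.17g", truth$chl_down_latent))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
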