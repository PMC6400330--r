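# Synthetic pageview ensembles with known seasonal ground truth.
#
# The generative model is multiplicative on the count scale:
#   log mu(t) = baseline_log + trend_slope * t
#             + amplitude * cos(2 * pi * k * (doy(t) - phase_day) / 365)
#             + spike contributions
# with doy(t) = ((t - 1) mod 365) + 1 on the series' own clock (day 1 =
# first day of the series), and counts drawn negative-binomial with mean
# mu(t) and size = noise_dispersion. noise_dispersion = Inf disables noise
# (counts = round(mu)). Spikes are additive on the log scale with
# rectangular support, emulating short television/holiday bursts.

#' Specification of one synthetic daily pageview series
#'
#' @param n_days number of daily observations (default 1067, the length of a
#'   roughly three-year archive window). Series meant to be classifiable
#'   need at least 730 days (two full 365-day cycles).
#' @param baseline_log log-scale mean level of daily views.
#' @param trend_slope linear growth per day on the log scale.
#' @param peaks_per_year number of annual seasonal peaks k: 0 (non-seasonal),
#'   1 or 2.
#' @param amplitude seasonal amplitude on the log scale (>= 0). Must be 0
#'   exactly when `peaks_per_year = 0`.
#' @param phase_day day-of-year of the first seasonal maximum, in \[0, 365).
#'   A two-peak signal has maxima at `phase_day` and `phase_day + 182.5`.
#' @param noise_dispersion negative-binomial size parameter (> 0); smaller
#'   values mean more overdispersion. `Inf` disables noise entirely.
#' @param spikes list of spike events, each a list/vector with elements
#'   `day` (start index), `log_magnitude` and `width_days`.
#' @param seed integer seed; if non-NULL the generator seeds the RNG so the
#'   series is reproducible.
#' @return an object of class `"series_spec"`.
#' @export
series_spec <- function(n_days = 1067L, baseline_log = 3, trend_slope = 0,
                        peaks_per_year = 0L, amplitude = 0,
                        phase_day = 0, noise_dispersion = 10,
                        spikes = list(), seed = NULL) {
  if (!peaks_per_year %in% c(0L, 1L, 2L))
    stop("peaks_per_year must be 0, 1 or 2, got ", peaks_per_year)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if ((amplitude == 0) != (peaks_per_year == 0L))
    stop("amplitude must be 0 exactly when peaks_per_year is 0 (label soundness)")
  if (noise_dispersion <= 0) stop("noise_dispersion must be > 0")
  if (phase_day < 0 || phase_day >= 365) stop("phase_day must lie in [0, 365)")
  if (n_days < 1) stop("n_days must be positive")
  structure(list(n_days = as.integer(n_days), baseline_log = baseline_log,
                 trend_slope = trend_slope,
                 peaks_per_year = as.integer(peaks_per_year),
                 amplitude = amplitude, phase_day = phase_day,
                 noise_dispersion = noise_dispersion, spikes = spikes,
                 seed = seed),
            class = "series_spec")
}

#' Deterministic log-scale signal of a series specification
#'
#' The expected log mean at each day, before count noise.
#'
#' @param spec a [series_spec()].
#' @return numeric vector of length `spec$n_days`.
#' @export
series_log_signal <- function(spec) {
  t <- seq_len(spec$n_days)
  doy <- ((t - 1) %% 365) + 1
  sig <- spec$baseline_log + spec$trend_slope * t
  if (spec$peaks_per_year > 0)
    sig <- sig + spec$amplitude *
      cos(2 * pi * spec$peaks_per_year * (doy - spec$phase_day) / 365)
  for (sp in spec$spikes) {
    sp <- as.list(sp)
    idx <- seq(sp$day, length.out = sp$width_days)
    idx <- idx[idx >= 1 & idx <= spec$n_days]
    sig[idx] <- sig[idx] + sp$log_magnitude
  }
  sig
}

#' Generate one synthetic daily pageview series
#'
#' Draws negative-binomial counts around the exponentiated log signal of
#' `spec`. With `noise_dispersion = Inf` the counts are the rounded means
#' (noise disabled).
#'
#' @param spec a [series_spec()].
#' @param page_id,language,entity_id metadata carried on the output.
#' @param start_date first calendar day (leap days are skipped so every
#'   365 consecutive positions cover one full cycle).
#' @return a [pageview_series()].
#' @export
generate_pageview_series <- function(spec, page_id = "synthetic-1",
                                     language = "en", entity_id = NA_character_,
                                     start_date = as.Date("2015-07-01")) {
  stopifnot(inherits(spec, "series_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  mu <- exp(series_log_signal(spec))
  counts <- if (is.infinite(spec$noise_dispersion)) {
    round(mu)
  } else {
    rnbinom(spec$n_days, size = spec$noise_dispersion, mu = mu)
  }
  pageview_series(page_id = page_id, language = language,
                  dates = noleap_dates(start_date, spec$n_days),
                  counts = as.integer(counts), entity_id = entity_id)
}

#' Day length in hours for a daily sequence of days of year
#'
#' Closed-form astronomical day length from the solar declination
#' delta(d) = 23.44 * sin(2 * pi * (d - 80) / 365) degrees and the sunset
#' hour angle cos H = -tan(lat) * tan(delta). Used as a canonical
#' "known seasonal" fixture: a smooth single-peak annual cycle.
#'
#' @param latitude_deg latitude in degrees, strictly between -66.5 and 66.5
#'   (no polar day/night).
#' @param n_days number of daily values.
#' @param start_doy day of year of the first value (1-365).
#' @return numeric vector of day lengths in hours, all in (0, 24).
#' @export
generate_daylength_series <- function(latitude_deg, n_days = 730L,
                                      start_doy = 1L) {
  if (abs(latitude_deg) >= 66.5)
    stop("latitude must lie strictly within the polar circles (|lat| < 66.5)")
  d <- ((start_doy - 1 + seq_len(n_days) - 1) %% 365) + 1
  delta <- 23.44 * sin(2 * pi * (d - 80) / 365) * pi / 180
  cosH <- -tan(latitude_deg * pi / 180) * tan(delta)
  if (any(abs(cosH) > 1)) stop("polar day/night encountered; latitude too high")
  24 * acos(cosH) / pi
}

#' Series classes emitted by the labelled ensemble generator
#'
#' Three non-seasonal classes (flat, trend-only, spike-only) and two
#' seasonal ones (one or two annual peaks).
#'
#' @format character vector of length 5.
#' @export
ensemble_classes <- c("flat", "trend", "spike", "k1", "k2")

#' Generate a stratified, labelled ensemble of synthetic series
#'
#' Emits `n_per_class` series for each of five classes: non-seasonal flat,
#' non-seasonal trend-only, non-seasonal spike-only, seasonal with one
#' annual peak, and seasonal with two annual peaks. Labels record the
#' generating truth and are never re-derived from fits.
#'
#' @param n_per_class series per class (>= 1).
#' @param parameter_ranges named list of length-2 numeric ranges for
#'   `baseline_log`, `trend_slope`, `amplitude`, `noise_dispersion`,
#'   `spike_magnitude`, `spike_width`; missing entries take defaults.
#' @param seed integer seed.
#' @param n_days series length.
#' @param classes subset of classes to emit (default all five).
#' @return list with `series` (list of [pageview_series()]) and `labels`
#'   (data.frame: page_id, class, is_seasonal, true_k, true_amplitude,
#'   true_phase_day).
#' @export
generate_labeled_ensemble <- function(n_per_class, parameter_ranges = list(),
                                      seed = 1L, n_days = 1067L,
                                      classes = ensemble_classes) {
  stopifnot(n_per_class >= 1, all(classes %in% ensemble_classes))
  defaults <- list(baseline_log = c(2.5, 4.5), trend_slope = c(0, 5e-4),
                   amplitude = c(1, 2.5), noise_dispersion = c(5, 50),
                   spike_magnitude = c(1.5, 3), spike_width = c(2, 10))
  for (nm in names(parameter_ranges)) {
    rg <- parameter_ranges[[nm]]
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[2] < rg[1])
      stop("invalid parameter range for ", nm)
    defaults[[nm]] <- rg
  }
  pr <- defaults
  set.seed(seed)
  series <- list()
  labels <- list()
  i <- 0L
  runif2 <- function(rg) runif(1, rg[1], rg[2])
  for (cls in classes) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      k <- switch(cls, flat = 0L, trend = 0L, spike = 0L, k1 = 1L, k2 = 2L)
      amp <- if (k > 0) runif2(pr$amplitude) else 0
      phase <- if (k > 0) runif(1, 0, 365) else 0
      spikes <- if (cls == "spike") {
        list(list(day = sample.int(n_days - 20L, 1),
                  log_magnitude = runif2(pr$spike_magnitude),
                  width_days = round(runif2(pr$spike_width))))
      } else list()
      spec <- series_spec(
        n_days = n_days, baseline_log = runif2(pr$baseline_log),
        trend_slope = if (cls == "flat") 0 else runif2(pr$trend_slope),
        peaks_per_year = k, amplitude = amp, phase_day = phase,
        noise_dispersion = runif2(pr$noise_dispersion), spikes = spikes,
        seed = NULL)
      pid <- sprintf("page-%s-%03d", cls, j)
      series[[i]] <- generate_pageview_series(spec, page_id = pid)
      labels[[i]] <- data.frame(page_id = pid, class = cls,
                                is_seasonal = k > 0, true_k = k,
                                true_amplitude = amp, true_phase_day = phase,
                                stringsAsFactors = FALSE)
    }
  }
  list(series = series, labels = do.call(rbind, labels))
}

#' Generate a per-language latitude/seasonality table
#'
#' Emulates the language-level relationship between capital-city latitude
#' and the percentage of seasonal pages: absolute latitudes are uniform on
#' \[0, 65\] and percent seasonal follows a linear model with Gaussian noise,
#' truncated to \[0, 100\].
#'
#' Defaults restate the observed language-level relationship: slope 0.63 %%
#' per degree, intercept 0.24 %%, with `noise_sd` calibrated (under the
#' truncation below) so the expected refitted adjusted R-squared at 60
#' languages is 0.44. Note the \[0, 100\] truncation clips the low-latitude
#' noise tail, so refitted slopes are attenuated about 10%% below the
#' generating slope; see the methods vignette.
#'
#' @param n_langs number of languages (>= 3).
#' @param slope,intercept linear relation of percent seasonal on |latitude|.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns language, abs_latitude, percent_seasonal.
#' @export
generate_language_table <- function(n_langs = 60L, slope = 0.63,
                                    intercept = 0.24, noise_sd = 13.0,
                                    seed = 1L) {
  if (n_langs < 3) stop("n_langs must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  lat <- runif(n_langs, 0, 65)
  pct <- slope * lat + intercept + rnorm(n_langs, 0, noise_sd)
  pct <- pmin(pmax(pct, 0), 100)
  data.frame(language = sprintf("lang%03d", seq_len(n_langs)),
             abs_latitude = lat, percent_seasonal = pct,
             stringsAsFactors = FALSE)
}

#' Generate a coupled pageview / observation-frequency scenario
#'
#' Produces one synthetic pageview series together with a monthly
#' observation-frequency series whose latent signal mixes the series' own
#' standardized monthly totals (weight `coupling`) with independent noise
#' (weight `1 - coupling`), then maps the latent affinely into
#' \[0.05, 0.95\]. `coupling = 1` therefore forces an exactly linear
#' (slope 1 after standardization) relation between monthly frequency and
#' monthly pageview totals; `coupling = 0` makes them independent.
#'
#' @param spec a [series_spec()] covering at least 12 months (~365 days).
#' @param coupling mixing weight in \[0, 1\].
#' @param seed integer seed.
#' @param country country code attached to the frequency series.
#' @return list with `series` (a [pageview_series()]) and `frequency`
#'   (data.frame: entity_id, country, month, frequency).
#' @export
generate_ebird_scenario <- function(spec, coupling, seed = 1L,
                                    country = "US") {
  stopifnot(inherits(spec, "series_spec"))
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (spec$n_days < 365) stop("series must cover at least 12 months")
  spec$seed <- NULL
  set.seed(seed)
  ser <- generate_pageview_series(spec, page_id = paste0("ebird-", seed),
                                  entity_id = paste0("Q", seed))
  mt <- monthly_totals(ser)
  z <- as.numeric(scale(mt$views))
  if (any(!is.finite(z))) z <- rep(0, nrow(mt))
  latent <- coupling * z + (1 - coupling) * rnorm(nrow(mt))
  rng <- range(latent)
  freq <- if (diff(rng) == 0) rep(0.5, length(latent)) else
    0.05 + 0.9 * (latent - rng[1]) / diff(rng)
  list(series = ser,
       frequency = data.frame(entity_id = ser$entity_id, country = country,
                              month = mt$month, frequency = freq,
                              stringsAsFactors = FALSE))
}
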