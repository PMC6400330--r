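# Seasonality core: LOESS/AICc, annual consistency, detrending, harmonic
# fits, model selection, classification, sensitivity sweep.

test_that("fit_loess_aicc reproduces exact structure and matches a grid oracle", {
  x <- 1:120
  # exactly linear: every span reproduces the line; tie-break -> largest span
  y <- 2 * x + 5
  f <- fit_loess_aicc(x, y, span_grid = c(0.3, 0.6, 0.9))
  expect_lt(max(abs(f$fitted - y)), 1e-8)
  expect_equal(f$span, 0.9)
  expect_identical(f$aicc, -Inf)

  # constant series: fitted constant, AICc -Inf convention
  fc <- fit_loess_aicc(x, rep(3, 120))
  expect_true(all(abs(fc$fitted - 3) < 1e-8))
  expect_identical(fc$aicc, -Inf)

  # noisy sinusoid: selected span equals an independent exhaustive AICc scan
  set.seed(9)
  y2 <- sin(2 * pi * x / 60) + rnorm(120, sd = 0.3)
  grid <- seq(0.1, 0.9, by = 0.1)
  f2 <- fit_loess_aicc(x, y2, span_grid = grid)
  oracle <- vapply(grid, function(s) {
    fit <- loess(y2 ~ x, span = s, degree = 1)
    nu <- fit$trace.hat
    s2 <- sum(resid(fit)^2) / length(y2)
    log(s2) + 1 + 2 * (nu + 1) / (length(y2) - nu - 2)
  }, numeric(1))
  expect_equal(f2$span, grid[which.min(oracle)])
  expect_equal(f2$aicc, min(oracle), tolerance = 1e-10)

  expect_error(fit_loess_aicc(1:10, rnorm(10)), "at least 30")
})

test_that("annual_consistency measures year-over-year repeatability", {
  base <- sin(2 * pi * (1:365) / 365) + 2
  # identical years
  r <- annual_consistency(c(base, base))
  expect_equal(r$adj_r2, 1, tolerance = 1e-12)
  expect_equal(r$slope_sign, 1)

  # affine second year: R2 still 1, slope positive
  r2 <- annual_consistency(c(base, 3 * base + 7))
  expect_equal(r2$adj_r2, 1, tolerance = 1e-12)
  expect_equal(r2$slope_sign, 1)

  # anti-phase year gets negative slope (guarded by the slope-sign rule)
  r3 <- annual_consistency(c(base, -base))
  expect_equal(r3$slope_sign, -1)

  # independent second year: matches closed-form OLS, near zero
  set.seed(21)
  y2 <- rnorm(365)
  r4 <- annual_consistency(c(base, y2))
  expect_equal(r4$adj_r2, oracle_ols(base, y2)$adj_r2, tolerance = 1e-10)
  expect_lt(abs(r4$adj_r2), 0.05)

  # degenerate year-1
  r5 <- annual_consistency(c(rep(1, 365), base))
  expect_true(r5$degenerate)
  expect_equal(r5$adj_r2, 0)

  expect_error(annual_consistency(1:700), "730")
})

test_that("detrend_linear removes exactly the OLS line", {
  t <- 1:50
  d <- detrend_linear(2 * t + 5)
  expect_lt(max(abs(d$residuals)), 1e-9)
  expect_equal(d$slope, 2, tolerance = 1e-12)

  # zero-mean periodic signal over whole years: slope is O(1/n), residuals
  # stay close to the signal (the incidental tilt shrinks with series length)
  y <- sin(2 * pi * (1:730) / 365)
  d2 <- detrend_linear(y)
  expect_lt(abs(d2$slope), 0.005)
  expect_gt(cor(d2$residuals, y), 0.9)
  expect_lt(abs(sum(d2$residuals)), 1e-9)

  set.seed(3)
  v <- rnorm(10)
  d3 <- detrend_linear(v)
  expect_equal(d3$residuals, oracle_ols(1:10, v)$residuals,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fit_sinusoid recovers exact harmonics and matches the brute-force oracle", {
  t <- 1:730
  # exact basis member
  y <- 2 * cos(2 * pi * (t - 100) / 365)
  f <- fit_sinusoid(y, 1)
  expect_equal(f$amplitude, 2, tolerance = 1e-6)
  expect_equal(f$phase_day, 100, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-6)

  # orthogonal harmonic: k=1 fit explains (almost) nothing
  y2 <- cos(4 * pi * t / 365)
  expect_lt(fit_sinusoid(y2, 1)$r2, 0.01)
  expect_gt(fit_sinusoid(y2, 2)$r2, 0.99)

  # two-peak phase convention: maxima at phase and phase + 182.5
  y3 <- 1.5 * cos(2 * pi * 2 * (t - 40) / 365)
  f3 <- fit_sinusoid(y3, 2)
  expect_equal(f3$phase_day, 40, tolerance = 1e-6)

  # noisy series equal the grid+refine oracle
  set.seed(14)
  for (k in 1:2) {
    yn <- 1.3 * cos(2 * pi * k * (t - 211) / 365) + rnorm(730, sd = 0.4)
    fit <- fit_sinusoid(yn, k)
    orc <- oracle_sinusoid(yn, k)
    expect_equal(fit$amplitude, orc$amplitude, tolerance = 1e-4)
    expect_equal(fit$phase_day, orc$phase_day, tolerance = 1e-4)
    expect_equal(fit$r2, orc$r2, tolerance = 1e-6)
    expect_equal(fit$adj_r2, orc$adj_r2, tolerance = 1e-6)
  }

  # degenerate all-zero residuals
  fz <- fit_sinusoid(rep(0, 100), 1)
  expect_true(fz$degenerate)
  expect_equal(fz$amplitude, 0)
  expect_equal(fz$adj_r2, 0)

  expect_error(fit_sinusoid(1:100, 3), "k must be")
})

test_that("loglik model selection picks the better harmonic", {
  t <- 1:730
  set.seed(5)
  y1 <- cos(2 * pi * t / 365) + rnorm(730, sd = 0.1)
  expect_equal(select_model(fit_sinusoid(y1, 1), fit_sinusoid(y1, 2)), 1L)
  y2 <- cos(4 * pi * t / 365) + rnorm(730, sd = 0.1)
  expect_equal(select_model(fit_sinusoid(y2, 1), fit_sinusoid(y2, 2)), 2L)

  # mixed signal: selection agrees with direct RSS comparison
  ym <- cos(2 * pi * t / 365) + 0.3 * cos(4 * pi * t / 365)
  f1 <- fit_sinusoid(ym, 1); f2 <- fit_sinusoid(ym, 2)
  rss1 <- oracle_sinusoid(ym, 1)$rss; rss2 <- oracle_sinusoid(ym, 2)$rss
  expect_equal(select_model(f1, f2), if (rss2 < rss1) 2L else 1L)

  expect_error(select_model(f1, fit_sinusoid(ym[1:100], 2)), "same series")
})

test_that("classify_page flags known seasonal and non-seasonal series", {
  # the day-length calibration anchor: 45N, recast as counts
  dl <- generate_daylength_series(45, 730, start_doy = 1)
  ser <- pageview_series("daylength-45N", "xx",
                         noleap_dates(as.Date("2015-01-01"), 730),
                         as.integer(round(100 * dl)))
  r <- classify_page(ser)
  expect_true(r$is_seasonal)
  expect_equal(r$selected_k, 1L)
  expect_gt(r$fit_k1$adj_r2, 0.95)
  expect_lt(abs(r$phase_day - 172), 3)

  # constant series: degenerate, never seasonal
  cons <- pageview_series("flat", "en",
                          noleap_dates(as.Date("2015-07-01"), 730),
                          rep(5L, 730))
  rc <- classify_page(cons)
  expect_false(rc$is_seasonal)
  expect_true(rc$degenerate)

  # two-peak synthetic with mild noise: correct k, adj R2 near the oracle fit
  s2 <- make_series(n_days = 730, baseline_log = 3.5, peaks_per_year = 2L,
                    amplitude = 1.2, phase_day = 30, noise_dispersion = 40,
                    seed = 77, page_id = "k2")
  r2 <- classify_page(s2)
  expect_true(r2$is_seasonal)
  expect_equal(r2$selected_k, 2L)
  orc <- oracle_sinusoid(detrend_linear(log1p(s2$counts))$residuals, 2)
  expect_equal(r2$selected_adj_r2, orc$adj_r2, tolerance = 1e-3)

  # the exposed switch reproduces the smoothed-target variant
  r2s <- classify_page(s2, use_loess_fitted = TRUE)
  lo <- fit_loess_aicc(1:730, log1p(s2$counts))
  orc2 <- oracle_sinusoid(detrend_linear(lo$fitted)$residuals, 2)
  expect_equal(r2s$selected_adj_r2, orc2$adj_r2, tolerance = 1e-3)

  expect_error(classify_page(make_series(n_days = 400, seed = 1)), "730")
})

test_that("sensitivity sweep is monotone and equals a counting oracle", {
  set.seed(31)
  mixed <- c(
    lapply(1:6, function(i) make_series(
      n_days = 730, baseline_log = 3, peaks_per_year = 1L,
      amplitude = runif(1, 0.3, 2), phase_day = runif(1, 0, 365),
      noise_dispersion = 15, page_id = paste0("s", i))),
    lapply(1:6, function(i) make_series(
      n_days = 730, baseline_log = 3, noise_dispersion = 15,
      page_id = paste0("n", i))))
  res <- classify_pages(mixed)
  df <- seasonality_table(res)
  sw <- sensitivity_sweep(res)
  expect_true(all(diff(sw$prop_seasonal) <= 0))
  # counting oracle over the stored per-page statistics
  for (i in seq_len(nrow(sw))) {
    s <- sw$single_threshold[i]
    expected <- sum(!df$degenerate & df$consistency_adj_r2 > 0.5 &
                      df$consistency_slope_sign > 0 &
                      ifelse(df$selected_k == 1, df$selected_adj_r2 > s,
                             df$selected_adj_r2 > 0.6 * s))
    expect_equal(sw$n_seasonal[i], expected)
  }

  # pure-noise ensemble: ~0 at every threshold
  noise <- lapply(1:5, function(i) make_series(
    n_days = 730, baseline_log = 3, noise_dispersion = 10,
    page_id = paste0("z", i)))
  swn <- sensitivity_sweep(classify_pages(noise))
  expect_true(all(swn$prop_seasonal <= 0.2))
})

test_that("adjusted R2 statistics are shift invariant and bounded", {
  set.seed(8)
  y <- cos(2 * pi * (1:730) / 365) + rnorm(730, sd = 0.5)
  f <- fit_sinusoid(y, 1)
  fshift <- fit_sinusoid(y + 100, 1)
  expect_lte(f$adj_r2, f$r2)
  expect_equal(f$r2, fshift$r2, tolerance = 1e-9)
  expect_equal(f$adj_r2, fshift$adj_r2, tolerance = 1e-9)
  expect_gte(f$r2, 0); expect_lte(f$r2, 1)
})
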