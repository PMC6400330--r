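# Per-page seasonality determination: LOESS/AICc smoothing, annual
# consistency, linear detrending, harmonic fits, model selection,
# threshold classification.

default_span_grid <- function() seq(0.05, 0.95, by = 0.05)

default_thresholds <- function()
  c(consistency = 0.5, single = 0.5, double = 0.3)

#' LOESS fit with AICc span selection
#'
#' Fits a local regression (tricube weights) for each candidate span and
#' keeps the span minimizing
#' `AICc = log(sigma2_hat) + 1 + 2 * (nu + 1) / (n - nu - 2)`
#' where `nu` is the trace of the smoother matrix (effective parameters)
#' and `sigma2_hat = RSS / n`. An exact interpolating fit (`sigma2_hat = 0`)
#' is assigned `AICc = -Inf`. Ties break to the largest span.
#'
#' @param x numeric predictor (day index).
#' @param y numeric response (logged views), at least 30 points.
#' @param span_grid candidate spans in (0, 1].
#' @param degree local polynomial degree (1 or 2).
#' @return list of class `"loess_aicc"`: span, degree, fitted, trace_L,
#'   aicc, and the full aicc_by_span table.
#' @export
fit_loess_aicc <- function(x, y, span_grid = default_span_grid(),
                           degree = 1L) {
  n <- length(y)
  stopifnot(length(x) == n)
  if (n < 30) stop("need at least 30 points for span selection")
  if (any(!is.finite(y))) stop("non-finite response values")
  if (any(span_grid <= 0 | span_grid > 1)) stop("spans must lie in (0, 1]")
  span_grid <- sort(span_grid)
  best <- NULL
  aiccs <- rep(NA_real_, length(span_grid))
  for (i in seq_along(span_grid)) {
    s <- span_grid[i]
    fit <- tryCatch(
      suppressWarnings(loess(y ~ x, span = s, degree = degree,
                             family = "gaussian")),
      error = function(e) NULL)
    if (is.null(fit)) next
    nu <- fit$trace.hat
    if (n - nu - 2 <= 0) next
    sigma2 <- sum(residuals(fit)^2) / n
    # scale-relative zero: an exact (to rounding) fit gets AICc = -Inf
    aicc <- if (sigma2 <= (1e-10 * (sd(y) + 1))^2) -Inf else
      log(sigma2) + 1 + 2 * (nu + 1) / (n - nu - 2)
    aiccs[i] <- aicc
    # <= keeps the largest span among ties (grid is ascending)
    if (is.null(best) || aicc <= best$aicc)
      best <- list(span = s, degree = degree, fitted = unname(fitted(fit)),
                   trace_L = nu, aicc = aicc)
  }
  if (is.null(best))
    stop("series too short for every span in the grid (n - nu - 2 <= 0)")
  best$aicc_by_span <- data.frame(span = span_grid, aicc = aiccs)
  class(best) <- "loess_aicc"
  best
}

#' Year-over-year annual consistency
#'
#' Regresses values at positions 366-730 on values at positions 1-365
#' (the same day of year one cycle apart) and reports the adjusted
#' R-squared (n = 365, one predictor) and the sign of the slope. A
#' consistent annual pattern repeats with positive slope.
#'
#' @param fitted numeric vector of at least 730 values (typically LOESS
#'   fitted values of logged views).
#' @return list: adj_r2, slope_sign (+1/-1), degenerate flag.
#' @export
annual_consistency <- function(fitted) {
  if (length(fitted) < 730) stop("need at least 730 values (two full years)")
  y1 <- fitted[1:365]
  y2 <- fitted[366:730]
  if (var(y1) == 0 || var(y2) == 0)
    return(list(adj_r2 = 0, slope_sign = NA_real_, degenerate = TRUE))
  f <- lm(y2 ~ y1)
  sm <- suppressWarnings(summary(f))  # exact year-over-year repeats are valid
  list(adj_r2 = sm$adj.r.squared, slope_sign = sign(coef(f)[[2]]),
       degenerate = FALSE)
}

#' Remove a linear trend by ordinary least squares
#'
#' Residuals of OLS of `y` on the day index; accounts for overall traffic
#' growth before harmonic fitting.
#'
#' @param y numeric vector (>= 3 points).
#' @return list: residuals, slope, intercept.
#' @export
detrend_linear <- function(y) {
  n <- length(y)
  if (n < 3) stop("need at least 3 points")
  t <- seq_len(n)
  f <- lm.fit(cbind(1, t), y)
  list(residuals = unname(f$residuals), slope = unname(f$coefficients[2]),
       intercept = unname(f$coefficients[1]))
}

#' Harmonic (sinusoidal) regression with k annual peaks
#'
#' OLS of the residual series on the basis
#' \{1, sin(2 pi k t / period), cos(2 pi k t / period)\}. Amplitude and
#' phase come from the two harmonic coefficients; `phase_day` is the day
#' (series clock, modulo `period / k`) of the first seasonal maximum.
#' Gaussian log-likelihood uses `sigma2_hat = RSS / n`.
#'
#' @param residuals detrended numeric series (>= 10 points).
#' @param k number of annual peaks, 1 or 2.
#' @param period cycle length in days (365).
#' @return list of class `"sinusoid_fit"`: k, beta_sin, beta_cos, intercept,
#'   amplitude, phase_day, r2, adj_r2, loglik, sigma2, n, degenerate.
#' @export
fit_sinusoid <- function(residuals, k, period = 365) {
  if (!k %in% c(1, 2)) stop("k must be 1 or 2")
  n <- length(residuals)
  if (n < 10) stop("need at least 10 points")
  t <- seq_len(n)
  w <- 2 * pi * k * t / period
  tss <- sum((residuals - mean(residuals))^2)
  if (tss == 0) {
    out <- list(k = as.integer(k), beta_sin = 0, beta_cos = 0,
                intercept = mean(residuals), amplitude = 0, phase_day = 0,
                r2 = 0, adj_r2 = 0, loglik = Inf, sigma2 = 0, n = n,
                degenerate = TRUE)
    class(out) <- "sinusoid_fit"
    return(out)
  }
  X <- cbind(1, sin(w), cos(w))
  f <- lm.fit(X, residuals)
  b <- unname(f$coefficients)
  rss <- sum(f$residuals^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 3)
  sigma2 <- rss / n
  loglik <- if (sigma2 <= 0) Inf else -n / 2 * (log(2 * pi * sigma2) + 1)
  amplitude <- sqrt(b[2]^2 + b[3]^2)
  # signal = A*cos(2 pi k (t - phi)/period): beta_cos = A cos(theta),
  # beta_sin = A sin(theta) with theta = 2 pi k phi / period
  phase <- (atan2(b[2], b[3]) * period / (2 * pi * k)) %% (period / k)
  out <- list(k = as.integer(k), beta_sin = b[2], beta_cos = b[3],
              intercept = b[1], amplitude = amplitude, phase_day = phase,
              r2 = r2, adj_r2 = adj_r2, loglik = loglik, sigma2 = sigma2,
              n = n, degenerate = FALSE)
  class(out) <- "sinusoid_fit"
  out
}

#' Select between one- and two-peak harmonic models
#'
#' Both models have the same parameter count, so the log-likelihood
#' comparison reduces to choosing the smaller residual variance. Ties go
#' to the single-peak model.
#'
#' @param fit_k1,fit_k2 [fit_sinusoid()] results on the same series.
#' @return 1L or 2L.
#' @export
select_model <- function(fit_k1, fit_k2) {
  stopifnot(inherits(fit_k1, "sinusoid_fit"), inherits(fit_k2, "sinusoid_fit"))
  if (fit_k1$n != fit_k2$n) stop("fits must be on the same series")
  if (fit_k2$loglik > fit_k1$loglik) 2L else 1L
}

#' Classify one page as seasonal or not
#'
#' Full pipeline on a calendar-aligned series of at least 730 days:
#' log(views + 1), LOESS smooth with AICc span selection, annual-consistency
#' regression on the smoothed values (adjusted R-squared above the
#' consistency threshold AND positive slope required), linear detrending,
#' harmonic fits with one and two annual peaks, log-likelihood model
#' selection, and an adjusted R-squared threshold on the selected fit
#' (default > 0.5 for a single peak, > 0.3 for a double peak).
#'
#' @param series a calendar-aligned [pageview_series()] (>= 730 days) that
#'   passed the traffic filter.
#' @param thresholds named vector: consistency, single, double; strict
#'   inequalities.
#' @param span_grid LOESS candidate spans.
#' @param use_loess_fitted if FALSE (default) the harmonic models are fitted
#'   to the detrended raw logged views; if TRUE, to the detrended LOESS
#'   fitted values. The default keeps the false-positive rate of the
#'   classifier at its nominal level: adjusted R-squared is scale-free, so
#'   on a non-seasonal series the smoothed noise wiggle can fit a sinusoid
#'   spuriously well, whereas raw residual noise cannot.
#' @return list of class `"seasonality_result"` recording every
#'   intermediate statistic.
#' @export
classify_page <- function(series, thresholds = default_thresholds(),
                          span_grid = default_span_grid(),
                          use_loess_fitted = FALSE) {
  stopifnot(inherits(series, "pageview_series"))
  n <- length(series$counts)
  if (n < 730) stop("need at least 730 days to classify page ", series$page_id)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  y <- log1p(series$counts)
  if (var(y) == 0) {
    f0 <- fit_sinusoid(rep(0, n), 1)
    f0b <- fit_sinusoid(rep(0, n), 2)
    out <- list(page_id = series$page_id, language = series$language,
                entity_id = series$entity_id, loess_span = NA_real_,
                consistency_adj_r2 = 0, consistency_slope_sign = NA_real_,
                consistency_pass = FALSE, detrend_slope = 0,
                fit_k1 = f0, fit_k2 = f0b, selected_k = 1L,
                selected_adj_r2 = 0, amplitude = 0, phase_day = 0,
                is_seasonal = FALSE, degenerate = TRUE,
                thresholds_used = thresholds,
                total_views = sum(as.numeric(series$counts)))
    class(out) <- "seasonality_result"
    return(out)
  }
  lo <- fit_loess_aicc(seq_len(n), y, span_grid = span_grid)
  cons <- annual_consistency(lo$fitted)
  target <- if (use_loess_fitted) lo$fitted else y
  dt <- detrend_linear(target)
  f1 <- fit_sinusoid(dt$residuals, 1)
  f2 <- fit_sinusoid(dt$residuals, 2)
  sel <- select_model(f1, f2)
  fsel <- if (sel == 1L) f1 else f2
  sel_threshold <- unname(if (sel == 1L) thresholds["single"] else thresholds["double"])
  consistency_pass <- !cons$degenerate &&
    cons$adj_r2 > thresholds[["consistency"]] && cons$slope_sign > 0
  seasonal <- consistency_pass && !fsel$degenerate &&
    fsel$adj_r2 > sel_threshold
  out <- list(page_id = series$page_id, language = series$language,
              entity_id = series$entity_id,
              loess_span = lo$span,
              consistency_adj_r2 = cons$adj_r2,
              consistency_slope_sign = cons$slope_sign,
              consistency_pass = consistency_pass,
              detrend_slope = dt$slope,
              fit_k1 = f1, fit_k2 = f2, selected_k = sel,
              selected_adj_r2 = fsel$adj_r2,
              amplitude = fsel$amplitude, phase_day = fsel$phase_day,
              is_seasonal = seasonal,
              degenerate = cons$degenerate || fsel$degenerate,
              thresholds_used = thresholds,
              total_views = sum(as.numeric(series$counts)))
  class(out) <- "seasonality_result"
  out
}

#' @export
print.seasonality_result <- function(x, ...) {
  cat(sprintf(
    "<seasonality_result> %s [%s]: %s (k=%d, adj R2=%.3f, consistency=%.3f)\n",
    x$page_id, x$language, if (x$is_seasonal) "SEASONAL" else "not seasonal",
    x$selected_k, x$selected_adj_r2, x$consistency_adj_r2))
  invisible(x)
}

#' Classify many pages
#'
#' @param series_list list of aligned [pageview_series()].
#' @param ... passed to [classify_page()].
#' @return list of `"seasonality_result"`.
#' @export
classify_pages <- function(series_list, ...) {
  lapply(series_list, classify_page, ...)
}

#' Flatten seasonality results to a data.frame
#'
#' One row per page with every scalar statistic of the classification.
#'
#' @param results list of `"seasonality_result"`.
#' @return data.frame.
#' @export
seasonality_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    page_id = r$page_id, language = r$language, entity_id = r$entity_id,
    loess_span = r$loess_span,
    consistency_adj_r2 = r$consistency_adj_r2,
    consistency_slope_sign = r$consistency_slope_sign,
    consistency_pass = r$consistency_pass,
    detrend_slope = r$detrend_slope,
    k1_adj_r2 = r$fit_k1$adj_r2, k2_adj_r2 = r$fit_k2$adj_r2,
    k1_amplitude = r$fit_k1$amplitude, k2_amplitude = r$fit_k2$amplitude,
    k1_phase_day = r$fit_k1$phase_day, k2_phase_day = r$fit_k2$phase_day,
    selected_k = r$selected_k, selected_adj_r2 = r$selected_adj_r2,
    amplitude = r$amplitude, phase_day = r$phase_day,
    is_seasonal = r$is_seasonal, degenerate = r$degenerate,
    total_views = r$total_views,
    stringsAsFactors = FALSE)))
}

#' Seasonal proportion under alternative adjusted R-squared thresholds
#'
#' Re-evaluates the seasonal flag from stored statistics (no refitting) at
#' each single-peak threshold, scaling the double-peak threshold
#' proportionally (by the default 0.3/0.5 ratio). The consistency threshold
#' is held at its default.
#'
#' @param results list of `"seasonality_result"` or a [seasonality_table()]
#'   data.frame.
#' @param single_thresholds thresholds applied to the single-peak adjusted
#'   R-squared.
#' @param consistency_threshold annual-consistency threshold (fixed).
#' @return data.frame: single_threshold, double_threshold, n, n_seasonal,
#'   prop_seasonal.
#' @export
sensitivity_sweep <- function(results,
                              single_thresholds = c(0.3, 0.5, 0.7),
                              consistency_threshold = 0.5) {
  df <- if (is.data.frame(results)) results else seasonality_table(results)
  if (nrow(df) == 0) stop("no classifiable series supplied")
  ratio <- 0.3 / 0.5
  rows <- lapply(sort(single_thresholds), function(s) {
    dbl <- s * ratio
    pass_cons <- !df$degenerate & df$consistency_adj_r2 > consistency_threshold &
      df$consistency_slope_sign > 0
    pass_fit <- ifelse(df$selected_k == 1L, df$selected_adj_r2 > s,
                       df$selected_adj_r2 > dbl)
    ns <- sum(pass_cons & pass_fit, na.rm = TRUE)
    data.frame(single_threshold = s, double_threshold = dbl,
               n = nrow(df), n_seasonal = ns, prop_seasonal = ns / nrow(df))
  })
  do.call(rbind, rows)
}
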