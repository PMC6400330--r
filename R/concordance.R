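# Concordance between monthly pageview totals and monthly observation
# frequency (eBird-style), with BH false-discovery-rate control.

#' Calendar-month totals of a daily pageview series
#'
#' Sums daily views within each calendar month. Months only partially
#' covered at the window edges are retained but flagged.
#'
#' @param series a [pageview_series()].
#' @return data.frame: month ("YYYY-MM"), views, n_days, partial.
#' @export
monthly_totals <- function(series) {
  stopifnot(inherits(series, "pageview_series"))
  if (length(series$counts) == 0) stop("empty series")
  mo <- format(series$dates, "%Y-%m")
  views <- tapply(as.numeric(series$counts), mo, sum)
  ndays <- tapply(series$counts, mo, length)
  months <- names(views)
  # expected day count per month on the no-leap calendar
  exp_days <- vapply(months, function(m) {
    mm <- as.integer(substr(m, 6, 7))
    if (mm == 2) return(28L)  # leap days are dropped on alignment
    first <- as.Date(paste0(m, "-01"))
    as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1, "%d"))
  }, integer(1))
  out <- data.frame(month = months, views = as.numeric(views),
                    n_days = as.integer(ndays),
                    partial = as.integer(ndays) < exp_days,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$month), ]
}

#' Per-page concordance regression
#'
#' Standardizes (z-scores) monthly pageview totals and monthly observation
#' frequency and regresses views on frequency by OLS. The slope on
#' standardized variables (the "scaled coefficient") equals the Pearson
#' correlation; adjusted R-squared and a two-sided slope p-value are
#' reported. Constant inputs give a degenerate result that is excluded from
#' the FDR pool.
#'
#' @param monthly_views numeric vector of monthly pageview totals.
#' @param monthly_frequency numeric vector in \[0, 1\], same months.
#' @return list: scaled_coefficient, adj_r2, p, n, degenerate.
#' @export
page_concordance <- function(monthly_views, monthly_frequency) {
  n <- length(monthly_views)
  if (length(monthly_frequency) != n) stop("month vectors differ in length")
  if (n < 6) stop("need at least 6 overlapping months")
  if (any(monthly_frequency < 0 | monthly_frequency > 1))
    stop("frequencies must lie in [0, 1]")
  if (var(monthly_views) == 0 || var(monthly_frequency) == 0)
    return(list(scaled_coefficient = NA_real_, adj_r2 = NA_real_,
                p = NA_real_, n = n, degenerate = TRUE))
  zv <- as.numeric(scale(monthly_views))
  zf <- as.numeric(scale(monthly_frequency))
  f <- lm(zv ~ zf)
  sm <- suppressWarnings(summary(f))  # "essentially perfect fit" is fine here
  list(scaled_coefficient = unname(coef(f)[2]), adj_r2 = sm$adj.r.squared,
       p = sm$coefficients[2, 4], n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: for ordered p-values p_(1) <= ... <= p_(m),
#' q_(i) = min over j >= i of (m * p_(j) / j), capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(m * p_values[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Run concordance tests for a set of pages
#'
#' Applies [page_concordance()] per (page, country), pools the non-degenerate
#' p-values for a single BH adjustment, and flags significant positive
#' relationships (q < alpha and positive scaled coefficient).
#'
#' @param pairs list of lists, each with elements `page_id`, `country`,
#'   optionally `entity_id`, `monthly_views`, `monthly_frequency`.
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame, one row per pair, with q and significance flags.
#' @export
concordance_tests <- function(pairs, alpha = 0.05) {
  rows <- lapply(pairs, function(pp) {
    r <- page_concordance(pp$monthly_views, pp$monthly_frequency)
    data.frame(page_id = pp$page_id, country = pp$country,
               entity_id = if (is.null(pp$entity_id)) NA_character_ else pp$entity_id,
               scaled_coefficient = r$scaled_coefficient, adj_r2 = r$adj_r2,
               p = r$p, n = r$n, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$q <- NA_real_
  ok <- !df$degenerate
  df$q[ok] <- fdr_adjust(df$p[ok])
  df$significant <- !df$degenerate & df$q < alpha
  df$significant_positive <- df$significant & df$scaled_coefficient > 0
  df
}

#' Summarize concordance results
#'
#' Overall and per-country proportions of significant and significant
#' positive relationships, means of the scaled coefficient and adjusted
#' R-squared among significant positive pages, and (when entities recur in
#' several countries) the share of multi-country species with a significant
#' positive relationship in more than one country.
#'
#' @param results data.frame from [concordance_tests()].
#' @return list of summary statistics; `by_country` is a data.frame.
#' @export
summarize_concordance <- function(results) {
  if (nrow(results) == 0) stop("empty results")
  tested <- results[!results$degenerate, ]
  sig <- tested[tested$significant, ]
  by_country <- do.call(rbind, lapply(split(tested, tested$country),
                                      function(g) data.frame(
    country = g$country[1], n = nrow(g),
    percent_significant_positive = 100 * mean(g$significant_positive),
    stringsAsFactors = FALSE)))
  rownames(by_country) <- NULL
  multi <- NA_real_
  if (!all(is.na(tested$entity_id))) {
    per_ent <- split(tested, tested$entity_id)
    multi_ent <- per_ent[vapply(per_ent, function(g)
      length(unique(g$country)) >= 2, logical(1))]
    if (length(multi_ent) > 0)
      multi <- 100 * mean(vapply(multi_ent, function(g)
        sum(g$significant_positive) >= 2, logical(1)))
  }
  list(n_pages = nrow(tested),
       percent_significant = 100 * mean(tested$significant),
       percent_positive_of_significant =
         if (nrow(sig) > 0) 100 * mean(sig$scaled_coefficient > 0) else NA_real_,
       percent_significant_positive = 100 * mean(tested$significant_positive),
       mean_scaled_coefficient =
         mean(tested$scaled_coefficient[tested$significant_positive]),
       mean_adj_r2 = mean(tested$adj_r2[tested$significant_positive]),
       by_country = by_country,
       percent_multi_country_consistent = multi)
}

#' Model what predicts a positive pageview/frequency relationship
#'
#' Maximum-likelihood logistic regression of the significant-positive
#' indicator on the page's seasonality (single-peak adjusted R-squared) and
#' its total views, with Wald standard errors. Complete separation is
#' flagged and no estimates are reported in that case.
#'
#' @param indicator logical/0-1 vector, one per page.
#' @param seasonality_adj_r2 numeric vector.
#' @param total_views numeric vector.
#' @return list: coefficients, se, p (named vectors), n, separation flag.
#' @export
positive_relationship_model <- function(indicator, seasonality_adj_r2,
                                        total_views) {
  n <- length(indicator)
  if (n < 20) stop("need at least 20 pages")
  ind <- as.integer(indicator)
  if (length(unique(ind)) < 2) stop("both outcome classes must be present")
  dat <- data.frame(y = ind, adj_r2 = seasonality_adj_r2,
                    views = total_views)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ adj_r2 + views, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || sep || any(abs(coef(fit)[-1] * sd(dat$adj_r2)) > 50))
    return(list(coefficients = NULL, se = NULL, p = NULL, n = n,
                separation = TRUE))
  sm <- summary(fit)
  list(coefficients = coef(fit), se = sm$coefficients[, 2],
       p = sm$coefficients[, 4], n = n, separation = FALSE)
}
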