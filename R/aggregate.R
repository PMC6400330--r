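# Species-, class- and language-level aggregation of per-page results,
# comparison statistics, latitude regression, rank-popularity trajectories.

#' Species-level seasonality summary
#'
#' Aggregates per-page classification over the language editions of each
#' species. A species shows a "uniform pattern" when every one of its pages
#' is seasonal with the same number of annual peaks.
#'
#' @param results_df a [seasonality_table()] data.frame.
#' @param page_map data.frame (page_id, language, entity_id) mapping every
#'   page to exactly one taxon entity. If `results_df` already carries a
#'   non-NA entity_id column the map may be omitted.
#' @return data.frame (one row per entity): n_pages, n_seasonal,
#'   seasonal_any, percent_seasonal_pages, uniform_pattern; with attribute
#'   `summary` (percent of species seasonal in >= 1 edition, mean percent
#'   seasonal pages among those, share with a uniform pattern).
#' @export
species_seasonality <- function(results_df, page_map = NULL) {
  df <- results_df
  if (!is.null(page_map)) {
    key <- if ("language" %in% names(page_map))
      paste(df$page_id, df$language) else df$page_id
    mkey <- if ("language" %in% names(page_map))
      paste(page_map$page_id, page_map$language) else page_map$page_id
    m <- match(key, mkey)
    if (anyNA(m))
      stop("pages without an entity mapping: ",
           paste(head(df$page_id[is.na(m)], 5), collapse = ", "))
    df$entity_id <- page_map$entity_id[m]
  }
  if (anyNA(df$entity_id) || any(df$entity_id == "NA"))
    stop("pages without an entity mapping: ",
         paste(head(df$page_id[is.na(df$entity_id) | df$entity_id == "NA"], 5),
               collapse = ", "))
  out <- do.call(rbind, lapply(split(df, df$entity_id), function(g) {
    ns <- sum(g$is_seasonal)
    data.frame(entity_id = g$entity_id[1], n_pages = nrow(g), n_seasonal = ns,
               seasonal_any = ns >= 1,
               percent_seasonal_pages = 100 * ns / nrow(g),
               uniform_pattern = ns == nrow(g) && ns >= 1 &&
                 length(unique(g$selected_k)) == 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_species = nrow(out),
    percent_species_seasonal = 100 * mean(out$seasonal_any),
    mean_percent_seasonal_pages =
      mean(out$percent_seasonal_pages[out$seasonal_any]),
    percent_uniform_pattern = 100 * mean(out$uniform_pattern))
  out
}

#' Taxonomic-class distribution of single-peak seasonality
#'
#' Per class (with at least `min_species` species): median, quartiles and
#' 1.5 x IQR whisker bounds of the single-peak adjusted R-squared across
#' pages, plus percent seasonal pages.
#'
#' @param results_df [seasonality_table()] data.frame with entity_id.
#' @param taxa data.frame (entity_id, taxon_class, ...).
#' @param min_species minimum species per retained class (default 100).
#' @return data.frame, one row per retained class.
#' @export
class_level_summary <- function(results_df, taxa, min_species = 100L) {
  m <- match(results_df$entity_id, taxa$entity_id)
  if (anyNA(m))
    stop("entities missing from taxon table: ",
         paste(head(unique(results_df$entity_id[is.na(m)]), 5), collapse = ", "))
  df <- cbind(results_df, taxon_class = taxa$taxon_class[m])
  out <- do.call(rbind, lapply(split(df, df$taxon_class), function(g) {
    n_species <- length(unique(g$entity_id))
    if (n_species < min_species) return(NULL)
    q <- unname(quantile(g$k1_adj_r2, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    data.frame(taxon_class = as.character(g$taxon_class[1]),
               n_species = n_species, n_pages = nrow(g),
               q1 = q[1], median = q[2], q3 = q[3],
               whisker_low = max(min(g$k1_adj_r2), q[1] - 1.5 * iqr),
               whisker_high = min(max(g$k1_adj_r2), q[3] + 1.5 * iqr),
               percent_seasonal = 100 * mean(g$is_seasonal),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) stop("no class reaches the minimum species count")
  rownames(out) <- NULL
  out
}

#' Regress language-level seasonality on capital-city latitude
#'
#' OLS of the chosen response on the absolute latitude of the capital of
#' the country dominating each language's readership.
#'
#' @param language_table data.frame with `abs_latitude` and the response
#'   column.
#' @param response column name, e.g. "percent_seasonal" or
#'   "mean_k1_adj_r2".
#' @return list: slope, intercept, adj_r2, p (two-sided slope p-value), n.
#' @export
latitude_regression <- function(language_table,
                                response = "percent_seasonal") {
  if (nrow(language_table) < 3) stop("need at least 3 languages")
  if (!response %in% names(language_table))
    stop("no column '", response, "' in language table")
  if (var(language_table$abs_latitude) == 0)
    stop("zero variance in latitude")
  f <- lm(reformulate("abs_latitude", response), data = language_table)
  sm <- suppressWarnings(summary(f))  # noiseless tables fit exactly
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       adj_r2 = sm$adj.r.squared, p = sm$coefficients[2, 4],
       n = nrow(language_table))
}

#' Correlation between language size and number of seasonal pages
#'
#' @param language_table data.frame with n_pages and n_seasonal columns.
#' @return list: pearson_r, p, n.
#' @export
size_correlation <- function(language_table) {
  if (nrow(language_table) < 3) stop("need at least 3 languages")
  x <- language_table$n_pages
  y <- language_table$n_seasonal
  if (var(x) == 0 || var(y) == 0) stop("zero variance in counts")
  ct <- cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pearson chi-square comparison of two seasonal proportions
#'
#' 2 x 2 chi-square without continuity correction on
#' (seasonal, non-seasonal) x (group 1, group 2).
#'
#' @param k1,n1 seasonal count and total in group 1.
#' @param k2,n2 seasonal count and total in group 2.
#' @return list: chi2, df (= 1), p.
#' @export
compare_seasonal_proportions <- function(k1, n1, k2, n2) {
  if (k1 > n1 || k2 > n2 || n1 <= 0 || n2 <= 0)
    stop("need 0 <= k <= n and n > 0")
  O <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
              dimnames = list(c("seasonal", "not"), c("g1", "g2")))
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("zero margin in the 2x2 table")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Pooled-variance two-sample t comparison of adjusted R-squared values
#'
#' Student t with df = nA + nB - 2 (pooled variance), with group means and
#' standard errors.
#'
#' @param groupA,groupB numeric vectors (>= 2 values each).
#' @return list: t, df, p, mean_a, mean_b, se_a, se_b.
#' @export
compare_adj_r2_means <- function(groupA, groupB) {
  na <- length(groupA); nb <- length(groupB)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * var(groupA) + (nb - 1) * var(groupB)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance")
  t <- (mean(groupA) - mean(groupB)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean_a = mean(groupA), mean_b = mean(groupB),
       se_a = sd(groupA) / sqrt(na), se_b = sd(groupB) / sqrt(nb))
}

#' Monthly rank-popularity trajectories
#'
#' Ranks species within each month by total views (rank 1 = most viewed,
#' ties get the average rank) and summarizes how much each species' rank
#' moves: the population standard deviation of its monthly ranks. The mean
#' rank SD divided by the number of species (x100) is reported as the mean
#' percent shift in relative popularity.
#'
#' @param totals numeric matrix of monthly view totals, species in rows
#'   (rownames = entity ids), months in columns; no missing cells.
#' @return data.frame (entity_id, total_views, rank_sd, quartile) with
#'   attribute `summary` (mean_rank_sd, percent_shift, mean rank SD per
#'   view quartile).
#' @export
monthly_rank_trajectories <- function(totals) {
  if (anyNA(totals)) stop("every species needs a total for every month")
  if (is.data.frame(totals)) totals <- as.matrix(totals)
  n <- nrow(totals)
  ranks <- apply(totals, 2, function(v) rank(-v, ties.method = "average"))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rank_sd <- apply(ranks, 1, pop_sd)
  tot <- rowSums(totals)
  quart <- cut(rank(tot, ties.method = "first"),
               breaks = quantile(rank(tot, ties.method = "first"),
                                 probs = seq(0, 1, 0.25)),
               include.lowest = TRUE, labels = 1:4)
  out <- data.frame(entity_id = if (is.null(rownames(totals)))
    sprintf("sp%04d", seq_len(n)) else rownames(totals),
    total_views = tot, rank_sd = rank_sd,
    quartile = as.integer(quart), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    mean_rank_sd = mean(rank_sd),
    percent_shift = rank_percent_shift(mean(rank_sd), n),
    mean_rank_sd_by_quartile =
      tapply(out$rank_sd, out$quartile, mean))
  out
}

#' Mean percent shift in relative popularity
#'
#' The documented summary definition: mean rank standard deviation divided
#' by the number of ranked species, times 100.
#'
#' @param mean_rank_sd mean across species of the SD of monthly ranks.
#' @param n_species number of species ranked.
#' @return percent shift (scalar).
#' @export
rank_percent_shift <- function(mean_rank_sd, n_species) {
  100 * mean_rank_sd / n_species
}

#' Language-level summary of per-page results
#'
#' Per language (with at least `min_pages` pages): page and seasonal counts,
#' percent seasonal, and the mean single-peak adjusted R-squared; joined to
#' capital-city absolute latitude when a latitude table is supplied.
#'
#' @param results_df [seasonality_table()] data.frame.
#' @param latitude_table optional data.frame (language, abs_latitude).
#' @param min_pages minimum pages per retained language (default 100,
#'   mirroring the "more than 100 species pages" inclusion rule).
#' @return data.frame, one row per retained language.
#' @export
language_summary <- function(results_df, latitude_table = NULL,
                             min_pages = 100L) {
  out <- do.call(rbind, lapply(split(results_df, results_df$language),
                               function(g) {
    if (nrow(g) < min_pages) return(NULL)
    data.frame(language = g$language[1], n_pages = nrow(g),
               n_seasonal = sum(g$is_seasonal),
               percent_seasonal = 100 * mean(g$is_seasonal),
               mean_k1_adj_r2 = mean(g$k1_adj_r2),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) stop("no language reaches the minimum page count")
  rownames(out) <- NULL
  if (!is.null(latitude_table)) {
    m <- match(out$language, latitude_table$language)
    out$abs_latitude <- latitude_table$abs_latitude[m]
  }
  out
}
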