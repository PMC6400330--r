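# Reading, writing and aligning daily pageview series; traffic filter.

#' Daily pageview series container
#'
#' @param page_id opaque page identifier.
#' @param language language code of the edition.
#' @param dates Date vector, strictly increasing.
#' @param counts non-negative integer views, one per date.
#' @param entity_id optional taxon entity identifier.
#' @return object of class `"pageview_series"`.
#' @export
pageview_series <- function(page_id, language, dates, counts,
                            entity_id = NA_character_) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable date in series for page ", page_id)
  if (length(dates) != length(counts))
    stop("dates and counts differ in length for page ", page_id)
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be strictly increasing for page ", page_id)
  if (any(counts < 0)) stop("negative view counts for page ", page_id)
  structure(list(page_id = as.character(page_id),
                 language = as.character(language),
                 entity_id = as.character(entity_id),
                 dates = dates, counts = as.integer(counts)),
            class = "pageview_series")
}

#' @export
print.pageview_series <- function(x, ...) {
  cat(sprintf("<pageview_series> %s [%s] %d days (%s to %s), median %s views/day\n",
              x$page_id, x$language, length(x$counts),
              format(min(x$dates)), format(max(x$dates)),
              format(median(x$counts))))
  invisible(x)
}

#' Consecutive calendar dates without leap days
#'
#' Daily date sequence from `start_date` with every Feb 29 skipped, so each
#' 365 consecutive positions span one full annual cycle.
#'
#' @param start_date first date.
#' @param n_days number of dates.
#' @return Date vector of length `n_days`.
#' @export
noleap_dates <- function(start_date, n_days) {
  start_date <- as.Date(start_date)
  d <- seq(start_date, by = "day", length.out = n_days + ceiling(n_days / 365) + 2)
  d <- d[format(d, "%m-%d") != "02-29"]
  d[seq_len(n_days)]
}

#' Read daily pageview series from CSV
#'
#' Expects a header `page_id,language,date,views` with ISO-8601 dates.
#' Lines starting with `#` are treated as provenance comments. One series is
#' returned per (page_id, language) pair, sorted by date.
#'
#' @param path CSV file path.
#' @param entity_map optional data.frame (page_id, entity_id) used to attach
#'   taxon entities.
#' @return list of [pageview_series()].
#' @export
read_pageviews <- function(path, entity_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("page_id", "language", "date", "views")
  if (!all(need %in% names(df)))
    stop("pageview CSV must have columns ", paste(need, collapse = ", "))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop("malformed date '", df$date[bad], "' at data row ", bad)
  }
  if (any(df$views < 0)) {
    bad <- which(df$views < 0)[1]
    stop("negative views at data row ", bad, " (page ", df$page_id[bad], ")")
  }
  df$date <- dates
  key <- paste(df$page_id, df$language, sep = "\r")
  dup <- df[duplicated(df[c("page_id", "language", "date")]), ]
  if (nrow(dup) > 0)
    stop("duplicated (page, date) rows, e.g. page ", dup$page_id[1],
         " language ", dup$language[1], " date ", format(dup$date[1]))
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g$date), ]
    eid <- NA_character_
    if (!is.null(entity_map)) {
      m <- match(g$page_id[1], entity_map$page_id)
      if (!is.na(m)) eid <- entity_map$entity_id[m]
    }
    pageview_series(g$page_id[1], g$language[1], g$date, g$views, eid)
  })
  names(out) <- NULL
  out
}

#' Write pageview series to CSV
#'
#' Canonical long format: page_id,language,date,views. Optional `#`-prefixed
#' provenance header lines.
#'
#' @param series_list list of [pageview_series()].
#' @param path output path.
#' @param header_lines character vector written first, each prefixed `#`.
#' @export
write_pageviews <- function(series_list, path, header_lines = character()) {
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(page_id = s$page_id, language = s$language,
               date = format(s$dates, "%Y-%m-%d"), views = s$counts,
               stringsAsFactors = FALSE)))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a series to a gap-free daily window
#'
#' Reindexes the series onto `n_days` consecutive calendar days starting at
#' `start_date`, excluding Feb 29. Missing days are filled with 0 views
#' (archives omit zero-traffic days); leap-day entries are dropped so every
#' year occupies exactly 365 positions.
#'
#' @param series a [pageview_series()].
#' @param start_date first day of the window.
#' @param n_days window length in (non-leap) days.
#' @return aligned [pageview_series()] of exactly `n_days` days.
#' @export
calendar_align <- function(series, start_date = min(series$dates),
                           n_days = 1067L) {
  grid <- noleap_dates(start_date, n_days)
  m <- match(series$dates, grid)
  if (all(is.na(m))) {
    keep <- format(series$dates, "%m-%d") != "02-29"
    if (!any(keep) || max(series$dates) < grid[1] || min(series$dates) > grid[n_days])
      stop("series for page ", series$page_id, " lies entirely outside the window")
  }
  counts <- integer(n_days)
  ok <- !is.na(m)
  counts[m[ok]] <- series$counts[ok]
  pageview_series(series$page_id, series$language, grid, counts,
                  series$entity_id)
}

#' Tukey biweight robust mean
#'
#' Iteratively reweighted biweight location estimate. With current estimate
#' T and S = median absolute deviation from the initial median, weights are
#' w_i = (1 - u_i^2)^2 for |u_i| < 1 (else 0) with u_i = (x_i - T)/(c*S),
#' and T is updated to the weighted mean until convergence. If S = 0 the
#' median is returned.
#'
#' @param x numeric vector, non-empty and finite.
#' @param c tuning constant (default 9, the dendrochronology convention).
#' @param tol convergence tolerance on the estimate.
#' @param max_iter maximum iterations.
#' @return the biweight location estimate (scalar).
#' @export
tukey_biweight_mean <- function(x, c = 9, tol = 1e-6, max_iter = 50L) {
  if (length(x) == 0) stop("empty input")
  if (any(!is.finite(x))) stop("non-finite values in input")
  med <- median(x)
  S <- median(abs(x - med))
  if (S == 0) return(med)
  T <- med
  for (i in seq_len(max_iter)) {
    u <- (x - T) / (c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(T)
    Tn <- sum(w * x) / sum(w)
    if (abs(Tn - T) < tol) return(Tn)
    T <- Tn
  }
  T
}

#' Minimum-traffic filter
#'
#' Retains series whose Tukey biweight mean daily views is at least
#' `min_mean` (default 1 view/day). The robust location means a series that
#' is quiet apart from one huge spike is still dropped.
#'
#' @param series_list list of calendar-aligned [pageview_series()].
#' @param min_mean retention threshold on the biweight mean.
#' @param ... passed to [tukey_biweight_mean()].
#' @return list with `retained` (list of series) and `dropped` (data.frame:
#'   page_id, language, estimate).
#' @export
filter_low_traffic <- function(series_list, min_mean = 1, ...) {
  est <- vapply(series_list, function(s) tukey_biweight_mean(s$counts, ...),
                numeric(1))
  keep <- est >= min_mean
  dropped <- data.frame(
    page_id = vapply(series_list[!keep], `[[`, character(1), "page_id"),
    language = vapply(series_list[!keep], `[[`, character(1), "language"),
    estimate = est[!keep], stringsAsFactors = FALSE)
  list(retained = series_list[keep], dropped = dropped)
}

#' Read a language-to-capital-latitude table
#'
#' CSV columns: language, country, capital, latitude (signed degrees).
#' The absolute value of latitude is taken on load.
#'
#' @param path CSV path.
#' @return data.frame with abs_latitude in \[0, 90\].
#' @export
read_language_latitude <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("language", "country", "capital", "latitude")
  if (!all(need %in% names(df)))
    stop("language-latitude CSV must have columns ", paste(need, collapse = ", "))
  df$abs_latitude <- abs(df$latitude)
  if (any(df$abs_latitude > 90)) stop("latitude outside [-90, 90]")
  df
}

#' Read a taxon metadata table (TSV)
#'
#' Columns: entity_id, scientific_name, taxon_class, taxon_family and
#' optionally conservation_status. entity_id must be unique.
#'
#' @param path TSV path.
#' @return data.frame of taxon records.
#' @export
read_taxa <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("entity_id", "scientific_name", "taxon_class", "taxon_family")
  if (!all(need %in% names(df)))
    stop("taxon TSV must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$entity_id))
    stop("duplicate entity_id in taxon table: ",
         df$entity_id[anyDuplicated(df$entity_id)])
  df
}
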