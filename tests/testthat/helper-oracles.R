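# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: straight loops, direct formulas, or
# brute-force searches.

# Biweight location: same definition as the spec (c * MAD scaling, MAD from
# the initial median, fixed-point iteration), written as a plain loop.
oracle_biweight <- function(x, c = 9, tol = 1e-6, max_iter = 50) {
  med <- median(x)
  S <- median(abs(x - med))
  if (S == 0) return(med)
  T <- med
  for (i in 1:max_iter) {
    num <- 0; den <- 0
    for (xi in x) {
      u <- (xi - T) / (c * S)
      if (abs(u) < 1) {
        w <- (1 - u^2)^2
        num <- num + w * xi
        den <- den + w
      }
    }
    if (den == 0) return(T)
    Tn <- num / den
    if (abs(Tn - T) < tol) return(Tn)
    T <- Tn
  }
  T
}

# Brute-force harmonic fit: grid over phase then golden-ratio refinement,
# profiling out amplitude and intercept by OLS for each phase.
oracle_sinusoid <- function(y, k, period = 365) {
  t <- seq_along(y)
  rss_at <- function(phi) {
    z <- cos(2 * pi * k * (t - phi) / period)
    f <- lm(y ~ z)
    sum(resid(f)^2)
  }
  grid <- seq(0, period / k, length.out = 721)
  r <- vapply(grid, rss_at, numeric(1))
  lo <- max(grid[which.min(r)] - 1, 0)
  hi <- min(grid[which.min(r)] + 1, period / k)
  opt <- optimize(rss_at, c(lo, hi), tol = 1e-10)
  phi <- opt$minimum
  z <- cos(2 * pi * k * (t - phi) / period)
  f <- lm(y ~ z)
  A <- coef(f)[[2]]
  if (A < 0) { A <- -A; phi <- (phi + period / (2 * k)) %% (period / k) }
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - opt$objective / tss
  list(amplitude = A, phase_day = phi %% (period / k), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 3), rss = opt$objective)
}

# Direct step-up BH definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, m * p[o[j]] / j)
    q[o[i]] <- min(cand, 1)
  }
  q
}

# Four-cell chi-square by hand.
oracle_chi2 <- function(k1, n1, k2, n2) {
  O <- c(k1, n1 - k1, k2, n2 - k2)
  rs <- c(k1 + k2, (n1 - k1) + (n2 - k2))
  cs <- c(n1, n2)
  N <- n1 + n2
  E <- c(rs[1] * cs[1], rs[2] * cs[1], rs[1] * cs[2], rs[2] * cs[2]) / N
  O <- c(k1, n1 - k1, k2, n2 - k2)
  sum((O - E)^2 / E)
}

# Pooled two-sample t by the textbook formula.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Pearson r and its t-test p-value from the textbook identity.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Closed-form simple OLS via normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, residuals = res, r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# Small aligned synthetic series for reuse across tests.
make_series <- function(..., page_id = "p1", seed = NULL) {
  sp <- series_spec(..., seed = seed)
  generate_pageview_series(sp, page_id = page_id)
}
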