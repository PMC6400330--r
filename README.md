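# pagephen

Seasonality detection in daily pageview time series of species pages.

Human interest in plants and animals often tracks phenology: migratory
birds are looked up when they arrive, flowering plants when they bloom,
game species in the hunting season. Daily Wikipedia-style pageview counts
are a dense record of that interest across thousands of species and many
language editions. `pagephen` is for conservation-culturomics and
phenology researchers who want to classify such series as seasonal or
not, estimate peak number and timing, and summarize the results across
species, taxonomic classes and languages — plus test whether pageviews
track independent observation records (eBird-style monthly reporting
frequency).

## The method

For a page's daily counts $x_t$ over at least two full years (leap days
dropped, so each year is exactly 365 positions):

1. $y_t = \log(x_t + 1)$; pages must first pass a minimum-traffic filter
   (Tukey biweight mean ≥ 1 view/day, tuning constant 9).
2. LOESS smooth of $y_t$, span chosen from {0.05, …, 0.95} by
   $\mathrm{AICc} = \log\hat\sigma^2 + 1 + 2(\nu+1)/(n-\nu-2)$ with
   $\nu$ = trace of the smoother matrix.
3. Annual consistency: OLS of smoothed days 366–730 on days 1–365;
   requires adjusted $R^2 > 0.5$ and positive slope.
4. Linear detrend of $y_t$, then harmonic regression on
   $\{1, \sin(2\pi k t/365), \cos(2\pi k t/365)\}$ for $k = 1, 2$;
   the model with higher Gaussian log-likelihood wins (tie → $k = 1$).
5. Seasonal iff consistency passed and the selected fit has adjusted
   $R^2 > 0.5$ (single peak) or $> 0.3$ (double peak).

Downstream: species/class/language aggregation, latitude regression of
language-level seasonality, monthly rank-popularity trajectories,
2×2 chi-square and pooled-t comparisons, and per-page concordance
regressions of monthly pageviews on monthly observation frequency with
Benjamini–Hochberg FDR control. A fully labelled synthetic generator
(negative-binomial counts around log-scale trend + sinusoid + spikes)
makes everything testable offline. See the methods vignette
(`vignettes/seasonality-methods.Rmd`) for assumptions and design choices.

## Worked example

```r
library(pagephen)

spec <- series_spec(n_days = 1067, baseline_log = 3.5, peaks_per_year = 1L,
                    amplitude = 1.2, phase_day = 130,
                    noise_dispersion = 15, seed = 42)
ser <- generate_pageview_series(spec, page_id = "hirundo-rustica-en")
ser
#> <pageview_series> hirundo-rustica-en [en] 1067 days (2015-07-01 to 2018-06-02), median 35 views/day

res <- classify_page(calendar_align(ser))
res
#> <seasonality_result> hirundo-rustica-en [en]: SEASONAL (k=1, adj R2=0.835, consistency=0.997)
```

The classifier recovers the generating truth: the year-over-year
consistency regression is almost perfect (adjusted R² = 0.997, the page
repeats its annual pattern), the single-peak harmonic explains 83.5% of
the detrended variance versus 0.1% for the double peak (so k = 1 is
selected), and the fitted amplitude 1.129 and peak day 130.8 sit close to
the generating amplitude 1.2 and phase day 130 — a spring peak, as for a
migratory bird. Both thresholds are exceeded, so `is_seasonal` is TRUE.

The full pipeline runs from the command line, each stage writing CSVs
with a provenance header:

```sh
Rscript inst/cli/pagephen.R all --outdir out --seed 42
# stages: simulate | classify | aggregate | concordance | all
```

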