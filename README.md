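# infodemics

Quantifying how media coverage and epidemic incidence drive collective
online attention.

During a fast-moving epidemic, public attention — measured by encyclopedia
page views or discussion-platform comment volume — rises sharply and then
*saturates*: it decays even while case counts and news coverage remain
high. `infodemics` packages the statistical machinery to measure this
phenomenon and to compare what media outlets and platform users pay
attention to, for researchers in infodemiology and computational social
science working with news corpora, discussion-platform dumps and page-view
time series.

## What it computes

**Memory-kernel attention regression.** Daily attention volume `y_t` is
modeled by three linear models:

```
Model I:    y_t = α₁ · incidence_t             + u_t
Model II:   y_t = α₁ · news_t                  + u_t
Model III:  y_t = α₁ · news_t + α₂ · newsMEM_t + u_t
```

where the memory covariate is the exponentially decayed cumulative news
volume

```
newsMEM_t = Σ_{t' < t} news_{t'} · exp(−(t − t')/τ)
```

with time scale τ tuned over the integers 1–45 by maximizing adjusted R².
A negative α₂ quantifies attention saturation. Models are compared with the
F test (nested: II vs III) and the classical Cox test (non-nested: I vs
III), plus country-level Pearson correlation tables.

**Page-view normalization.** Per-article daily views from a language
project are attributed to a country by the project's monthly country share
(`v = S_p(d) · σ_{p,c}(m) / σ_p(m)`), summed over articles and projects,
with ISO-week aggregation.

**Corpus filtering and topic dynamics.** Keyword relevance filters,
discussion-platform quality rules (vote-score, minimum-length,
mass-duplicate removal), then TF-IDF + projected-gradient NMF
(`min ‖X − WH‖²_F, W,H ≥ 0`) on a reference corpus; the fixed basis `H`
projects a second corpus onto the same topics. Per-topic dynamics: daily
strength `s_k(t)` (comment-weighted for discussion platforms), relevance
`R_k = Σ_t s_k(t)`, half-relevance time `t½`, percentage interest shares
and their source-to-source differences, and a document co-occurrence
coherence score.

**Geolocation.** Self-report phrase extraction ("I live in …"), gazetteer
resolution with an all-reports-must-agree consistency rule, and
home-versus-foreign location-citation shares around a pivotal date.

**Synthetic data.** Seeded generators for every input — SIR incidence,
incidence-driven news, Model III attention with known (α₁, α₂, τ), corpora
with planted topic-term structure, temporal bumps and comment affinities,
and self-report sentences — each with a machine-readable truth record, so
the full pipeline is testable offline.

## Worked example

```r
library(infodemics)

cfg    <- sim_config(seed = 42)          # study-scale defaults: 98 days,
bundle <- gen_attention_bundle(cfg)      # α₁ = 1, α₂ = −0.45, τ = 10
report <- country_report(bundle, country = "SYN")

report$model_r2
#> # A tibble: 3 × 4
#>   country model   tau r2_adj
#> 1 SYN     I        NA  0.770
#> 2 SYN     II       NA  0.818
#> 3 SYN     III      10  0.986

report$coefficients[, c("term", "estimate", "conf.low", "conf.high")]
#> # A tibble: 2 × 4
#>   term     estimate conf.low conf.high
#> 1 news        1.30     1.27      1.33
#> 2 news_mem   -0.568   -0.601    -0.536
```

The incidence-only model explains least; adding the memory term lifts
adjusted R² from 0.82 to 0.99, and the tuner recovers the planted τ = 10
exactly. The memory coefficient is strongly negative — the saturation
signature. (With the default fully standardized fit, coefficients are on
the z-scored-response scale; recovery studies fit with
`standardize_response = FALSE` to read coefficients on the generator's
scale.) The model comparisons agree:

```r
report$comparisons[, c("test", "null", "statistic", "p.value", "winner")]
#> 1 f_nested      II       1201.   4.58e-56 III
#> 2 cox_nonnested model1    -39.7  0        model2   (I rejected vs III)
#> 3 cox_nonnested model2      1.46 1.43e-1  model2   (III not rejected)
```

Topic-side entry points: `build_vocabulary()` → `tfidf_matrix()` →
`nmf_fit()` → `nmf_transform()` → `topic_strength_series()` →
`topic_half_time()` / `interest_share_diff()`; see the methods vignette
(`vignettes/infodemics-methods.Rmd`) for the full account.

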