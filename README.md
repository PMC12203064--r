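# ecoTempo

Temporal community assembly analysis for longitudinal microbial surveys.

Microbial communities in estuarine and coastal waters are shaped by an
interplay of environmental selection (e.g. the salinity gradient) and
dispersal/demographic chance. Given multi-year, multi-station ASV count
tables with sample metadata, `ecoTempo` quantifies that interplay three
ways:

* **Species-time relationships (STR).** Cumulative richness over
  observation windows of length T follows the power law S = c·T^w; the
  exponent w is the temporal scaling rate of richness (higher w = faster
  turnover). Fitted by nonlinear least squares on the geometric-mean
  richness curve, with permutation significance.
* **Colonization-extinction dynamics.** Presence-absence series are
  modelled as independent two-state Markov chains with per-day
  colonization (c) and extinction (e) rates. The interval transition
  probabilities P(0→1) = (c/ρ)(1−e^{−ρΔt}), P(1→0) = (e/ρ)(1−e^{−ρΔt})
  (ρ = c+e) are exact for irregular sampling, so (c, e) are estimated by
  maximum likelihood directly; the characteristic time 1/(c+e) (days)
  summarizes turnover, and a log-link extension
  c = exp(α_c + β_c·z), e = exp(α_e + β_e·z) with z the standardized
  salinity yields the standardized contributions exp(β) − 1 of salinity
  to each rate, plus a likelihood-ratio test against constant rates.
* **Process-model determinism.** A consumer-resource model (Monod uptake
  × Gaussian salinity niche) combined with neutral demographic noise and
  immigration (Wiener-process terms in an SDE) is fitted to the
  relative-abundance series by a pseudo-likelihood; the determinism of
  taxon i over interval k is the deterministic share of the expected
  squared increment, D = 100·(fΔt)²/((fΔt)² + σ²xΔt), aggregated over taxa
  with or without abundance weighting.

A fully seeded synthetic generator (3 estuarine stations, 6 years of
monthly sampling with February skipped, a salinity gradient whose
river-mouth station is far more variable than the marine ones) makes the
whole pipeline testable end to end; `runAll()` orchestrates
simulate/ingest → repeated rarefaction → STR + island-model +
determinism + Hellinger/Bray-Curtis/Mantel/CV-equality statistics.

## Worked example

```r
library(ecoTempo)

design <- stationDesign()                 # 3 stations x 6 years, monthly
env    <- genEnvironment(design, seed = 1)
e1     <- env[env$station == "ST1", ]     # the river-mouth station

# presence-absence dynamics with known salinity-dependent rates
pm <- genPresenceMarkov(trueCEParams(SPool = 2000, c0 = 0.01, e0 = 0.02,
                                     betaC = -0.3, betaE = -0.2),
                        e1$time, env = e1, seed = 1)

fitCE(pm)
#> CEFit: c = 0.0099347/day (se 8.67e-05), e = 0.019894/day (se 0.000172)
#>   characteristic time 33.52 days, equilibrium occupancy 0.333, S_eq 666.1

fitCEEnv(pm)
#> CEFitEnv (salinity): beta_c = -0.2833 (se 0.00936), beta_e = -0.1897 (se 0.00911)
#>   contributions per +1 SD: colonization -0.247, extinction -0.173
#>   LR vs constant rates: 1002.024 (p = 2.59e-218)

strAnalysis(pm, nPerm = 999, seed = 1)
#> STRFit: S = 1256 * T^0.1265  (se_w 0.012, adj R2 0.682)
#>   permutation p = 0.001 (n_perm = 999)
```

Reading the output: the baseline rates (0.01/day colonization, 0.02/day
extinction) are recovered within their standard errors, giving a
characteristic time of ~33 days — a dynamic community. The negative
contributions say that a +1 SD salinity increase slows colonization by
~25% and extinction by ~17%, i.e. higher salinity stabilizes the
community. The STR exponent w ≈ 0.13 with a permutation p of 0.001 says
richness accumulates as a significant power law in time. The full
pipeline over every station and both simulated taxon groups is one call:

```r
res <- runAll(runConfig(seed = 1, outdir = "run1"))
res$summary     # per station x group: w, c, e, t_char, contributions, D
```

Determinism for count data is `determinismAnalysis(cm, topK = 50)`
(one station at a time); see the methods vignette
(`vignettes/temporal-assembly.Rmd`) for the model, the estimator, and —
important for interpretation — the sampling-resolution assumption.

A thin command-line wrapper with subcommands `simulate`, `str`,
`island`, `determinism`, `stats` and `all` is installed at
`inst/cli/ecotempo.R`.

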