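---
title: "Quantifying temporal community assembly: species-time relationships, colonization-extinction dynamics, and determinism"
author: "ecoTempo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoTempo)
```

## The scientific problem

Longitudinal amplicon surveys of microbial communities — ASV count tables
collected monthly for years at several stations along an environmental
gradient — raise a recurring question: how much of the observed turnover is
driven by environmental selection, and how much by dispersal and demographic
chance? `ecoTempo` implements three complementary, quantitative views of
that question:

1. **Species-time relationships (STR).** Cumulative observed richness grows
   with the observation window as a power law, S = c·T^w. The exponent *w*
   measures the temporal scaling rate of richness: higher *w* means faster
   accumulation of "new" taxa, i.e. higher turnover.
2. **Island-biogeography colonization-extinction dynamics.** Each taxon's
   presence-absence series is modelled as a two-state continuous-time Markov
   chain with colonization rate *c* and extinction rate *e* (per day). Under
   taxon independence and equivalence the whole community's dynamics reduce
   to one (c, e) pair, estimable by maximum likelihood even with irregular
   sampling intervals, because the interval transition probabilities have an
   exact closed form. The characteristic time 1/(c+e) (days) summarizes
   turnover: small values mean dynamic communities, large values stable
   ones. A log-link extension c = exp(α_c + β_c z), e = exp(α_e + β_e z)
   with z the standardized salinity quantifies how the gradient shifts both
   processes; exp(β) − 1 is reported as the relative change in a rate per
   +1 SD of salinity.
3. **Process-model determinism.** A consumer-resource model with Monod
   uptake kinetics modulated by Gaussian salinity niches, plus neutral
   demographic noise and immigration as Wiener-process terms in an SDE,
   is fitted to the relative-abundance series; the fitted drift and noise
   are then converted into a per-taxon, per-interval *determinism*
   percentage and community-level (weighted/unweighted) aggregates.

A fully seeded synthetic generator reproduces the statistical structure the
analyses assume — a three-station estuarine survey with monthly sampling
(February skipped), a salinity gradient with station-specific variability,
island-model presence-absence dynamics, and consumer-resource count tables
sampled to fixed sequencing depth — so that every stage of the pipeline is
testable without any external data.

## The island model and its exact interval likelihood

For rates c, e ≥ 0 and an interval of Δt days, with ρ = c + e:

* P(absent → present) = (c/ρ)(1 − e^{−ρΔt})
* P(present → absent) = (e/ρ)(1 − e^{−ρΔt})

These are exact for any Δt, which is what makes irregular sampling grids
unproblematic: the log-likelihood is the sum over consecutive sample pairs
of the tallied state-change counts times the log transition probabilities.
`fitCE()` maximizes it on the (log c, log e) scale (quasi-Newton, three
deterministic starts, convergence tolerance 1e-12 on the relative
likelihood); standard errors come from the inverse observed information
with a delta-method transform back to the rate scale. When one transition
type is never observed, the corresponding rate lies on the likelihood
boundary; the fit is flagged (`boundary = TRUE`) and the SE reported as
infinite rather than fabricating a finite uncertainty. A second degenerate
regime is worth knowing about: when the observed turnover between samples
saturates (the empirical transition fractions approach the theoretical
maximum 1 − e^{−ρΔt} at ρ → ∞), the likelihood has a ridge running to
infinite rates and no finite maximum exists; tiny data sets can land there.

The covariate model evaluates z at each interval's **start** sample — a
piecewise-constant-rate assumption that keeps every interval's transition
matrix exact. Salinity is standardized **per station** by default (the
covariate effect is a within-station quantity along the gradient design);
global standardization is available via `standardize = "global"`. Rates are
per day throughout, so characteristic times are in days. The likelihood
ratio against the constant-rate nested model (df = 2) tests whether
salinity moves the rates at all.

Equilibrium richness S_eq = S_pool · c/(c+e) needs the metacommunity
richness S_pool, which is unobservable; the default is the number of taxa
ever observed in the series (a lower bound), and the argument is exposed.

## The species-time relationship

`strCurve()` computes, for every window length T = 1..n (in sampling
occasions), the geometric mean over all contiguous windows of length T of
the number of taxa present at least once in the window. Windows with zero
richness would make the geometric mean degenerate and are excluded with a
warning. The window unit is the number of consecutive sampling occasions,
which is robust to the irregular month grid; a days-based unit would make
windows of equal T span unequal real time and conflate spacing with
accumulation.

`fitPowerLaw()` fits S = c·T^w by nonlinear least squares on the
untransformed scale (Levenberg-Marquardt), initialized from the log-log
ordinary regression; `se_w` comes from the Jacobian-based covariance and
the adjusted R² is computed on the untransformed scale and clamped to
[0, 1] (an exactly constant curve is a perfect fit of w = 0 and reported
as adjusted R² = 1). Significance is assessed by permutation: the sample
order is permuted uniformly, the full curve + fit recomputed, and
p = (1 + #{adj R²_perm ≥ adj R²_obs})/(n_perm + 1). The adjusted R² is the
primary permutation statistic (a model-significance reading); a w-based
null is reported alongside. Permutations whose nonlinear fit fails are
counted as non-exceeding, which is conservative. Identical samples make
every permutation tie, so p = 1 by construction.

A subtlety worth knowing when sweeping turnover regimes: the packaged
cross-module check correlates fitted w with the characteristic time across
(c, e) settings in which colonization is held fixed and extinction varies,
so that faster turnover co-occurs with lower equilibrium occupancy -- the
pattern of real disturbance gradients, where dynamic sites host more
transient taxa. Under that sweep w falls cleanly with characteristic time.
If instead the equilibrium occupancy is held fixed while both rates scale,
the relationship reverses at desk scale: the accumulation curve of the
island model saturates within a few windows when sampling no longer
resolves the turnover, which flattens the curve's tail and pulls the
(tail-weighted) nonlinear fit of w down for the fastest communities. The
exponent is a property of the whole accumulation curve, and which regime
dominates depends on how occupancy co-varies with turnover.

Whether richness statistics should be computed on one table or averaged
over rarefaction repetitions is left to the caller: `repeatRarefy()`
returns the full list of repetitions (per-repetition seeds derived
deterministically as master seed + repetition index) and the pipeline
averages dissimilarities across them, while occupancy-based analyses (STR
and the island model) default to the unrarefied table because
presence-absence is depth-sensitive and rarefaction only discards
occupancy information; a rarefied mode is a configuration switch.

## The consumer-resource + neutral process model

The generative model for abundances N_i and one shared resource R is

* dN_i = [N_i(μ_i · R/(K+R) · φ_i(s) − m_i) + λp_i] dt + σ_i √N_i dW_i
* dR = [D_R(R_supply − R) − Σ_i q_i μ_i R/(K+R) φ_i(s) N_i] dt

with φ_i(s) = exp(−(s − s_opt,i)²/(2 s_width,i²)) the Gaussian salinity
niche. Simulation is Euler-Maruyama with negative excursions clipped at 0
and salinity linearly interpolated between sampling times. Two numerical
choices matter. First, the resource equation is stiff whenever consumers
are abundant (its relaxation rate includes the total consumption pressure),
so the resource update is semi-implicit — implicit in the linearized
consumption-plus-dilution term — which keeps the integrator stable at the
default step of 0.1 days without resorting to very small steps. Second, a
burn-in (default 365 days at the first sample's salinity) lets the
community reach its stochastic attractor before the first observation.

### Default kinetics and the sampling-resolution assumption

The default `crnModel()` kinetics are deliberately slow: μ_max = 0.12/day,
m = 0.03/day, so that net per-capita rates in relative-abundance space are
a few hundredths per day. Any drift/noise decomposition from discretely
sampled data can only see dynamics that the sampling grid resolves: if
relative abundances re-equilibrate within a sampling interval, the
increments carry almost no information about the drift, and no estimator of
this family can attribute them correctly. With monthly sampling the
practical requirement is per-capita rates comfortably below 1/Δt ≈
0.03/day. This is the single most important assumption of the determinism
module, and it is why the estimator calibration simulations (below) use a
2-day sampling grid: they validate the estimator inside its regime of
validity. On real monthly data determinism estimates should be read as a
*lower bound* — fast, unresolved deterministic dynamics are indistinguishable
from noise at that sampling rate.

### Fitting: pseudo-likelihood with a mean-field closure

Counts are converted to relative abundances x_i and the `topK` most
abundant taxa are fitted (default 50; the remainder are excluded, not
merged, because merging would distort the relative-abundance weights of the
community aggregates). In relative-abundance space the resource coupling
acts as a mean-field term: the per-capita drift is

rate_i(t) = A_i · c(t) · φ_i(s) − m_i − ḡ(t)

where A_i = μ_i R̂/(K+R̂) is the uptake amplitude at the quasi-steady-state
resource, c(t) is the relative excursion of the Monod factor around that
value, and ḡ(t) is the abundance-weighted community-mean per-capita growth
— the replicator-equation form of the model, which keeps simplex dynamics
bounded. The pseudo-likelihood is Δx_i(t_k) ~ Normal(pred_ik, σ_i² x_ik
Δt_k). Because the fitted drift is linear in x within an interval (the rate
is constant given s_k), its within-interval integral has a closed form
(exponential solution), which is used as the pseudo-likelihood mean; it
reduces to the plain Euler mean f·Δt for slow rates and stays numerically
stable at monthly intervals, where a literal Euler step would be unstable.
σ_i is profiled out in closed form. The niche is evaluated at the interval
*midpoint* salinity by default (matching the average within-interval
forcing under the linear salinity interpolation); interval-start evaluation
is available.

The two shared per-interval states (ḡ_k, c_k) are unknown a priori and are
estimated by block coordinate descent: per-taxon parameters given the
shared states, then the shared states profiled per interval given the
parameters, alternating for `nIter` passes (default 3). With few taxa the
multiplicative factor c(t) is weakly identified against the per-taxon
niches and biases them outward, so it is only profiled when at least 10
taxa are fitted (`estimateUptake` overrides). Because the likelihood is
multimodal in s_opt (a niche tail can mimic a monotone salinity response),
each taxon is started from a grid of optima spanning the observed salinity
range. Even so, salinity optima are identified only to a few PSU at
desk-scale series (66-130 samples): within-interval salinity movement
Jensen-flattens the niche, and taxa whose optimum sits near the edge of the
observed salinity range have effectively monotone responses whose optimum
is unidentified. Users should read fitted `sOpt` as niche-scale (± a few
PSU), not point estimates.

### The determinism statistic

The determinism of taxon i over interval k is defined as the share of the
expected squared increment attributable to the fitted deterministic drift:

D_i(t_k) = 100 · (pred_ik)² / [(pred_ik)² + σ_i² x_ik Δt_k]

It is 100 when noise vanishes, 0 when drift vanishes, 50 when the two
expected squared contributions match, and defined as 0 (flagged) when both
vanish. Community aggregates are the per-interval mean over taxa present
(unweighted) and the relative-abundance-weighted mean, plus their time
averages. Note two structural properties: a deterministic system *at rest*
(at equilibrium, including an immigration-decay balance) has zero drift and
hence zero determinism — the statistic measures deterministic *change*, not
deterministic *state* — and rare taxa have low D whenever σ > 0 because
drift scales with x while the noise variance scales with √x. The published
statistic this operationalizes is not specified in equation form in the
literature this package draws on, so the definition above is this package's
own, chosen to be bounded, interpretable, and correct in both limits;
numerical comparability with other implementations should not be assumed.

Calibration (enforced by the test suite): on noiseless consumer-resource
simulations sampled on a 2-day grid the fitted community determinism
exceeds 90 (both aggregates); on driftless noise-only simulations it stays
below 10; and at the default monthly survey scale, strong-niche/low-noise
communities separate from flat-niche/high-noise communities with
non-overlapping determinism distributions across seeds.

## Supporting statistics

* **Hellinger + Bray-Curtis / Sørensen** use vegan's `decostand` and
  `vegdist`; Sørensen is algebraically Bray-Curtis on presence-absence,
  an identity the tests verify on random tables.
* **Mantel** uses Pearson correlation of off-diagonal entries with
  simultaneous row/column permutations (via vegan), one-sided for positive
  association as is standard in ecology; a two-sided p is reported too.
* **CV equality (modified signed-likelihood ratio test).** Unconstrained
  vs common-CV normal likelihoods; given the common CV τ, each group's ML
  mean has a closed form (the positive root of n τ² μ² + (Σx) μ − Σx² = 0),
  so the constrained fit is a fast 1-D profile over τ. For two groups the
  signed root ±√LRT is referred to the standard normal; for k > 2 the LRT
  to χ²_{k−1}. The small-sample modification is delivered as a parametric
  bootstrap under the common-CV fit (default 1000 simulation runs), whose
  p-value is primary; `nSim = 0` reports only the asymptotic p (used in the
  package's own 500-run size calibration, where the bootstrap would add an
  inner loop without changing the conclusion at n = 60).

## The synthetic survey: what it emulates and what it does not

The default `stationDesign()` encodes the survey structure the analyses
assume: 3 stations, 6 years of monthly sampling with February skipped (66
samples per station), sampling-day jitter of ±7 days so intervals are
genuinely irregular, a salinity gradient with means 20/28/30 PSU, and
station salinity SDs of 8/2/1.5 PSU so the river-mouth station is much more
variable than the marine ones (its salinity CV exceeds the marine station's
in ≥95% of seeds). The presence-absence generator defaults to a
metacommunity of 500 taxa with c₀ = 0.01/day, e₀ = 0.02/day (characteristic
time 33 days, equilibrium occupancy 1/3) and salinity effects β_c = −0.3,
β_e = −0.2 on the log scale; counts are multinomial draws of 2000 reads per
sample over lognormal taxon weights. The process-model group uses the
default 40-taxon `crnModel()`. These are desk-scale stand-ins with the
right statistical structure — independence across taxa, exact interval
transitions, fixed-depth compositional sampling — not re-creations of any
particular data set: there is no sequencing error, no compositional bias
beyond multinomial sampling, no taxonomy, and no interaction structure
beyond shared-resource competition. Passing tests therefore demonstrate
the estimators' correctness on data satisfying the models' assumptions,
not the truth of those assumptions in any real system.

## Problem sizes used by the test suite and acceptance script

The packaged checks use: 10⁴ taxa × 66 samples for rate recovery (rates
recovered within 10%); 100 simulations of 600 taxa for the
likelihood-ratio power/size of the covariate model; 200 noisy power-law
curves for STR coverage; 12 turnover regimes spanning characteristic times
5-100 days for the w vs 1/(c+e) correlation; 12-20 taxa × 130 2-day
samples for determinism calibration and 20 seeds per design for
discrimination; 500 runs for the size of the CV and Mantel tests. These
sizes were chosen once as the smallest designs at which the corresponding
asymptotic or distributional arguments are comfortably in force.

## Known limitations

* Determinism at monthly sampling is a lower bound (see above); the
  statistic is about deterministic change, so equilibrium systems score 0.
* Salinity optima from `fitCRN()` carry a few PSU of structural bias at
  desk-scale series.
* The island model assumes taxon independence and equivalence; rate
  estimates on real data are community averages, and detection error
  (false absences at finite sequencing depth) inflates both rates.
* The CE likelihood conditions on the first observed state rather than
  modelling it; with 60+ samples the difference is negligible.
* Boundary and ridge regimes of the CE likelihood (no transitions of one
  kind; saturated turnover) are flagged, not "fixed".
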