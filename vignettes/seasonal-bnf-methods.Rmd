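---
title: "Methods: seasonal BNF curves, phenology de-trending, and the synthetic trial generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal BNF curves, phenology de-trending, and the synthetic trial generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnfcurve)
```

This vignette is the package's own account of its models, the choices
behind them, and what the test suite does and does not establish.

## The ureide proxy and its domain

In ureide-exporting legumes such as soybean, nitrogen fixed in nodules
travels as allantoin and allantoic acid (four N atoms per molecule),
while soil-derived nitrogen travels largely as nitrate. The relative
abundance of ureides in stem tissue,

$$\mathrm{RAU}\,(\%) = 100\cdot\frac{4U}{4U+N},$$

is therefore a proxy for the fraction of plant N derived from fixation.
`compute_rau()` accepts any single consistent concentration unit (the
ratio is scale-invariant), requires non-negative inputs, and refuses the
undefined case $U = N = 0$ rather than returning a placeholder. The
sample taken between full flowering and early pod formation is labelled
R2 throughout; the pipeline does not attempt to distinguish R2 from R3
material.

## Thermal time

Development is tracked in degree-days above a base temperature of 8 °C,
the conventional base for soybean:

$$TT = \sum \max\!\left(0,\ \tfrac{T_{max}+T_{min}}{2} - T_b\right).$$

Two choices deserve note. Daily increments below zero are clamped to
zero — negative degree-day accumulation is biologically meaningless and
clamping is the standard convention — and no upper temperature cutoff is
applied. The clock origin is the V2 stage date, supplied explicitly by
the data (or the generator); the pipeline never infers stage dates.
Missing days inside an accumulation window raise an error listing the
missing dates, because silent gaps bias the clock downward.

## The beta growth function

Seasonal RAU rises sigmoidally, peaks between early and full seed fill,
and declines toward maturity. That shape is captured by the
three-parameter beta growth function

$$\mathrm{RAU}(t) = \mathrm{RAU}_{max}
\left(1+\frac{t_{max}-t}{t_{max}-t_m}\right)
\left(\frac{t}{t_{max}}\right)^{t_{max}/(t_{max}-t_m)},$$

with $\mathrm{RAU}_{max}$ the peak value (%), $t_{max}$ the thermal time
of the peak, and $t_m$ the inflection (thermal time of the maximum
rate). A base of $t/t_{max}$ in the power term is the canonical form of
this growth function and the only choice that satisfies the
self-consistency requirement $\mathrm{RAU}(t_{max}) = \mathrm{RAU}_{max}$
(a variant with $t/t_m$ in that position fails it, and does not
reproduce the derived traits that published parameter sets imply, e.g.
$t_{0.5} = 473$ °Cd for a (90, 397, 1117) curve). At $t_m = 0$, which
real low-BNF fits do reach, all $0^0$ terms are defined as 1 by
continuous limit.

Derived traits:

* `max_rate()` — the closed-form peak of the derivative,
  $\frac{2t_{max}-t_m}{t_{max}(t_{max}-t_m)}
  \left(\frac{t_m}{t_{max}}\right)^{t_m/(t_{max}-t_m)}\mathrm{RAU}_{max}$,
  in % per °Cd. The identity `max_rate == rau_rate(t_m)` is asserted to
  1e-9 in the tests.
* `t_half()` — the unique root of $\mathrm{RAU}(t)=\mathrm{RAU}_{max}/2$
  on $(0, t_{max})$, found with `uniroot` at tolerance 1e-12 (the curve
  is strictly increasing there, so uniqueness is structural).
* `auc_beta()` — the integral of the positive part of the curve from 0
  to the last sampled stage, by composite Simpson quadrature with 2000
  panels (the integrand is cheap; panel count is far past the accuracy
  needed and is cross-checked against adaptive quadrature in the tests).
  Raw AUC is in % · °Cd; the relative AUC divides by the data-set
  maximum so the largest curve scores exactly 1. Both are reported
  because the two conventions are easily conflated and only the relative
  one is comparable across data sets.

### Fitting

`fit_beta()` minimises unweighted SSE with Levenberg–Marquardt iteration
(`minpack.lm::nlsLM`) under box bounds $0 < \mathrm{RAU}_{max} \le 110$,
$0 \le t_m, t_{max} \le 1.5\max(t)$; proposals with $t_m \ge t_{max}$
are repelled by a large finite residual penalty so the optimiser stays
in the valid region without hard failures. Replicate-level observations
enter individually — no pre-averaging — though nothing prevents fitting
stage-level means when replicates are unavailable. Start values are
taken from the data ($\mathrm{RAU}_{max}^0=$ max observed RAU,
$t_{max}^0$ at its thermal time, $t_m^0 = 0.4\,t_{max}^0$), which is
robust for sigmoidal trajectories sampled at four stages. Standard
errors are asymptotic, from the Jacobian at the solution; goodness of
fit is $R^2 = 1-\mathrm{SSE}/\mathrm{SST}$ and the residual SD
$S_{yx} = \sqrt{\mathrm{SSE}/(n-3)}$. Degenerate inputs (all-equal RAU,
fewer than four points, fewer than three distinct thermal times) raise
classed errors — never a silent answer.

The test suite quantifies the fitting machinery two ways: noise-free
data are recovered to 1e-6 (oracle equivalence), and a 200-replicate
Monte-Carlo study at the network's scale (48 points: 4 stages × 12
sites with seasons spread over 900–1500 °Cd, residual SD 12%) checks
that the reported standard errors cover the truth at their nominal
rate.

### Treatment comparison by AICc

Whether a nitrogen treatment changed the seasonal curve is decided by
comparing one shared fit on the pooled observations against separate
fits, with the small-sample Akaike criterion

$$\mathrm{AICc} = n\ln(\mathrm{SSE}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

counting the error variance as a parameter ($k = 4$ shared, $k = 7$
separate), the convention of the curve-fitting software this analysis
style is associated with. Comparisons are run pairwise — control versus
each treatment within a BNF group — not all-subsets. The reported
evidence ratio is $\exp(|\Delta|/2)$.

## Grouping sites by fixation level

Sites are classed by RAU at R6 in the unfertilised control: below the
25th percentile low, above the 75th high, otherwise medium
(interpolation quantiles, type 7). Because field RAU is reported at
finite precision, the cut points are rounded to the data's precision
before classifying, and the boundary rule is deterministic: high iff
$x \ge q_{75}$ and $x > q_{25}$; low iff $x < q_{25}$; ties at $q_{25}$
go to medium (so an all-equal input is all medium). On the bundled
23-site control values this rule puts the $q_{75}$ cut at 88% and
yields a six-site high group. The low/medium boundary is genuinely
ambiguous at integer precision — two sites print the same value yet
published groupings separate them, which is only possible with
unpublished unrounded data — so the package documents its tie-break
rather than chasing an unreproducible split.

## Phenology de-trending and residual regressions

Multi-site networks confound trait responses with season length:
maturity group drives both thermal time to R6 and yield potential. Each
trait (seed yield, HI, oil — biomass and protein are computed too but
flagged as expected non-significant) is first de-trended with a
continuous bilinear model in thermal time to R6:

$$Y = aX+b \ (X<TT_o), \qquad Y = a\,TT_o+b+d\,(X-TT_o) \ (X\ge TT_o).$$

This is the standard four-parameter broken-stick: left slope $a$,
intercept $b$, right slope $d$, breakpoint $TT_o$, continuous by
construction. An alternative three-parameter reading — second segment
proportional through the origin with $d$ derived from continuity — was
considered and rejected: it cannot represent a constant trait (its
second segment is forced through zero), which fails the most basic
sanity requirement of a de-trending model. The breakpoint is profiled
over the observed $x$ values excluding the two extremes at each end;
each candidate reduces to ordinary least squares, and the global SSE
minimiser wins, ties to the smallest candidate. At the network's scale
(~92 site × treatment means) this exhaustive search is deterministic,
reproducible and fast, and sidesteps the convergence fragility of joint
nonlinear breakpoint estimation. De-trending defaults to site ×
treatment means; plot-level de-trending is available by flag
(`use_site_means = FALSE`).

Residuals are then regressed on RAU at R6. The mean regression is OLS
with a two-sided slope test. The boundary regressions minimise the
quantile check loss $\sum_i \rho_\tau(r_i-\alpha-\beta x_i)$ at
$\tau = 0.01$ and $0.99$. Because the optimum of this linear program is
attained at a basic solution — a line through two data points — the
package solves it exactly by enumerating all point pairs with distinct
$x$ and taking the loss minimiser, with deterministic tie-breaking by
sorted pair order. This is quadratic in $n$ but exact and dependency-free
at the relevant scale; no distributional theory is attached to the
boundary slopes (their `p_value` is `NA`), which is why the mean
regression carries the significance statement. Extreme quantiles are
unstable below ~50 points; the function warns there and refuses fewer
than 20.

## The synthetic trial generator

`simulation_spec()` defines the study conditions the package is tested
under: 23 sites, four N treatments (control; 112 kg N/ha at sowing, V4,
or R2–R3), three blocks, stem assays at V4/R2/R6/R8, and agronomic
outcomes at maturity.

**Curves.** Each BNF group carries a control parameter triple — high
(90, 397, 1117), medium (84, 362, 1066), low (71, 0, 931) — matching
published group fits. Treatment effects are additive shifts on the
triple, identical across groups; the defaults are the high-group
control-vs-treatment contrasts (N at R2: −15 on the peak, −140 on
$t_m$, −45 on $t_{max}$ — the strongest and latest-applied effect).
Using one set of shifts across groups is a deliberate simplification:
published per-group effects are not monotone in every group (one low
group fit has a *higher* peak under late N), and a generator used for
directional power checks should inject directionally consistent
effects.

**Phenology.** Thermal time to R6 is uniform on [909, 1733] °Cd, the
observed network range; stages sit at phases 0.15 / 0.48 / 1 / 1.5 of
tt_r6, and site weather is constructed so the thermal clock reproduces
those stage times exactly (constant daily mean within each stage
interval, checked to 1 °Cd in the tests). Sites are allocated to
low/medium/high in quartile proportions (5/12/6 at 23 sites) by a
seeded permutation, independent of season length.

**Season scaling.** Site curves scale $t_m$ and $t_{max}$ with season
length as $(tt_{R6}/1150)^{e}$, default $e = 1$ (fully proportional).
This makes every site's trajectory phase-consistent — RAU at R6 is the
same curve fraction everywhere — so RAU_R6 is independent of season
length within a group. That independence is what lets the de-trending
pathway recover an injected cost slope without confounding, and it is
the property under test in the recovery studies. Its price is
deliberate: pooling sites with a wide season range on the absolute
thermal-time axis spreads the four stage clusters, so pooled
group-curve refits under the full default dispersion carry extra
between-site residual variance beyond the 13% plot noise. Analyses
whose target is the published per-group curve conditions therefore use
a common season (`tt_r6_range = c(1150, 1150)`), where the refit
residual SD equals the plot noise and the refit $R^2$ sits in the
0.62–0.87 band that this class of fits reports. No single configuration
can make RAU_R6 simultaneously near-constant within a group, the season
range span 900–1700 °Cd, *and* one pooled curve fit tight on the
absolute axis — the three constraints are mutually inconsistent for
any curve with a genuine peak — so the generator exposes the scaling
exponent and season range and the package uses the configuration
appropriate to each question.

**Noise and outcomes.** RAU noise is additive Gaussian (SD 13%, the
middle of the reported 11–16% residual band), clipped to [0, 100]; no
published distributional information beyond a residual SD exists, so
Gaussian-with-clipping is the least-structured choice and is
seed-controlled. Assays are emitted as (ureide, nitrate) pairs that
invert the RAU formula exactly (ureide 1, nitrate $4(100-R)/R$), so the
reader→RAU path is covered by a machine-precision round trip. Yield,
HI and oil follow their bilinear phenology trend plus a linear cost in
(RAU_R6 − mean): −13 kg ha⁻¹, −0.0011, and −0.03 g/100 g per %,
respectively; protein carries no injected cost, and biomass is derived
as yield/HI, so its two cost terms approximately cancel — matching the
qualitative expectation that biomass and protein show no residual
association with RAU_R6. A heteroscedasticity toggle widens trait noise
below the phenology trend to exercise the boundary-quantile contrast.

**What the generator does not emulate.** No mixed-model adjustment of
means (block effects are not simulated; simple means stand in for
least-squares means), no soil covariates, no vapour-pressure-deficit or
water-supply structure, no genotype-by-environment interaction beyond
the season-length scaling, and no mechanistic N budget. Passing
recovery tests therefore show that the *estimators* are unbiased and
correctly calibrated under the stated statistical structure — not that
field data obey that structure.

## Problem sizes and runtimes

The Monte-Carlo studies use the scales the analysis itself runs at:
200 replicates for the cost-slope recovery (full 23-site network per
replicate, de-trend on 92 site × treatment means), 200 replicates for
curve-fit coverage (48 points each), 100 replicates for AICc
discrimination power, 200 for breakpoint recovery (92 points). The
whole suite runs in a few minutes on one CPU; the acceptance script in
about one.

## Known limitations

* Mixed-model adjusted means (and their ANOVA) are out of scope; simple
  means are used throughout and documented as such.
* Boundary quantile slopes carry no inference; only the mean regression
  is tested for significance, and no multiplicity correction is applied
  (mirroring the analysis style this package reproduces).
* The published AUC column of the reference parameter table cannot be
  parsed unambiguously (raw vs normalised units), so the bundled table
  stores `NA` there and the package reports both conventions from its
  own fits instead.
* The percent reduction of peak RAU under late fertilisation is
  reported as computed from fitted parameters; the package does not
  assert any particular printed rounding of that ratio.
* Asymptotic standard errors from the curve fit are mildly optimistic
  when the design has few distinct thermal times; the coverage study
  quantifies this at the network's design, not for arbitrary designs.
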