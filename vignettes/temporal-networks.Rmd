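---
title: "Estimating and comparing temporal dynamic networks from EMA and actigraphy data"
author: "emanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing temporal dynamic networks from EMA and actigraphy data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emanet)
```

## The model

`emanet` implements a workflow for intensive longitudinal mental-health
data: participants answer short questionnaires ("beeps") several times a
day while wearing a wrist accelerometer, and the scientific question is how
the variables *drive each other over time* — e.g. whether loneliness at one
beep predicts perceived restriction at the next — and whether that dynamic
structure differs between two independently sampled groups (in the
motivating application, a no-lockdown and a lockdown pandemic stage).

The core object is a directed lag-1 temporal network. Writing
$y_{it} \in \mathbb{R}^p$ for subject $i$'s $p$ variables at beep $t$, the
population model is a multilevel first-order vector autoregression:

$$y_{it} = \mu_i + B_i\, (y_{i,t-1} - \bar y_i) + \varepsilon_{it}, \qquad
\varepsilon_{it} \sim \mathcal N(0, \Sigma), \qquad
B_i = B + U_i ,$$

where $B$ is the group-level coefficient matrix (rows index the outcome at
$t$, columns the predictor at $t-1$), $U_i$ are subject-level random
deviations, and predictors are within-person centered so the edges reflect
within-subject fluctuation rather than stable between-person differences.
$B$ *is* the network: entry $B_{jk}$ is the directed edge
$k \rightarrow j$, the diagonal holds the autoregressive self-loops.

Estimation is nodewise: each variable at $t$ is regressed on all $p$
variables (including itself) at $t-1$ with a random intercept per subject
(`lme4`), optionally with uncorrelated random slopes. With seven nodes, a
fully correlated random-effects VAR is not estimable at realistic sample
sizes, which is why orthogonal random effects are the default
recommendation for larger networks in this model family; we go one step
further and default to random intercepts only, which is the stable choice
at the series lengths the sampling scheme produces (56 beeps). Lag-1 pairs
are formed only between *consecutive beeps within a day*: overnight
intervals violate the roughly-equal-spacing premise of the lag-1 model, so
the last beep of one day is never paired with the first beep of the next.
Variables are z-scaled per group before fitting so coefficients are
comparable across edges; p-values are two-sided Wald tests.

### The two estimation engines

`fit_temporal_network()` has a second engine, `"ols"`, which absorbs the
subject intercepts by within-subject demeaning and fits pooled least
squares. With within-person-centered predictors the two engines estimate
the same fixed effects and agree closely whenever between-subject slope
heterogeneity is modest (a test asserts near-equality on exchangeable
data, and exact equality with a subject-dummy least-squares oracle). The
OLS engine exists because the permutation test refits both group networks
thousands of times; a mixed-model refit per permutation is orders of
magnitude slower for an estimate whose fixed effects are the same. The
permutation test always applies *the same* engine to the observed and the
permuted fits, so the test remains exact regardless of which engine is
chosen.

## From raw acceleration to a network node

Physical activity enters the network as the mean ENMO over the hour before
each beep:

* **ENMO** (Euclidean norm minus one): per sample
  $\sqrt{x^2+y^2+z^2} - 1000$ mg, negative values truncated to zero (the
  metric's usual convention; configurable), averaged in non-overlapping
  5-second epochs.
* **Nonwear scoring**: in sliding 60-minute windows (15-minute steps), an
  axis is flagged when its standard deviation **and** value range are both
  below thresholds (defaults 13 mg and 50 mg); the window score is the
  number of flagged axes, and scores above 1 mark nonwear. The defaults
  are configuration keys: the underlying idea (a worn wrist is never
  metronomically still) fixes the form of the rule, not the thresholds.
* **Pre-beep summary**: mean ENMO over the half-open window
  $[t - 3600\,\mathrm{s}, t)$, using wear epochs only; the value is
  missing when wear coverage is below 50% of the window — a coverage rule
  that prevents one surviving epoch from standing in for an "hour" — and
  in particular whenever the window is entirely nonwear.

## Preprocessing and diagnostics

EMA items are bounded and skewed, so every variable is gaussianized with
the **nonparanormal transformation**: within a group, values are mapped
through the truncated empirical CDF to standard-normal quantiles, with
truncation level $\delta = 1/(4 n^{1/4} \sqrt{\pi \log n})$. The transform
depends on the data only through ranks (any strictly monotone distortion
of a column gives an identical output), ties map to equal outputs, and the
truncation clamps the extreme order statistics — so the map is monotone
but not strictly so at the tails. Missing values pass through untouched;
no imputation is done anywhere (lag pairs with a missing endpoint are
simply dropped).

Two stationarity diagnostics mirror standard practice for this design:

* **Moment-to-moment inertia**: per group and variable, a two-level AR(1)
  (random intercept per subject, day boundaries respected). A fixed-effect
  slope of 1 or more indicates a nonstationary process; EMA items
  typically sit around 0.1–0.4.
* **KPSS battery**: a level-stationarity KPSS test per subject and
  variable (Bartlett long-run variance, automatic lag truncation
  $\lfloor 4 (n/100)^{1/4}\rfloor$, p-values interpolated from the
  published critical values), reporting the proportion of series for which
  stationarity is not rejected at $\alpha = .05$. Constant or short
  series are skipped and counted. No installed package provides KPSS, so
  the statistic is implemented here and cross-checked in the tests against
  a value frozen from an independent implementation.

## Centrality and group comparison

From the fitted $B$:

* **out-strength** of node $k$: $\sum_{j \ne k} |B_{jk}|$ (how strongly
  $k$ drives the rest of the network at the next beep); **in-strength** of
  $j$: $\sum_{k \ne j} |B_{jk}|$. All edges enter, significant or not.
  Absolute values are used because the networks contain negative edges and
  a signed sum would let them cancel; self-loops are excluded because
  strength conventionally measures influence on *other* nodes. Both are
  flags (`signed`, `include_self`), since the literal "sum of edge
  weights" reading is also defensible. Standardized columns are z-scores
  across nodes.
* **overall connectivity**: $\sum_{j,k} |B_{jk}|$, self-loops included by
  default.

Group differences are tested by **subject-label permutation**: whole
subjects are reassigned to groups (sizes preserved), both networks are
refitted with identical estimator options, and each statistic's observed
difference (group 1 − group 2) is referred to its permutation
distribution. The subject is the exchangeable unit — the two stages
sampled independent participants, and permuting beeps would destroy
within-person dependence. Monte-Carlo p-values use the add-one rule
$p = (1 + \#\{|T^\pi| \ge |T^{obs}|\})/(1 + n_{perm})$, which keeps the
test valid at finite $n_{perm}$; with 6 or so subjects per group the
splits can be enumerated exhaustively and the p-value is exact. Raw
(uncorrected) two-sided p-values are reported, matching the convention of
flagging differences at the uncorrected level; an FDR adjustment can be
applied downstream if desired. Failed refits within a permutation are
redrawn and counted, and the run aborts if more than 5% fail.

Person-level averages are compared with Welch t-tests (unequal variances,
Welch–Satterthwaite degrees of freedom) on the raw scales.

## What the synthetic-data generator emulates

No participant data are distributed, so the package ships a generator that
reproduces the study's *structure*:

* two independent groups of subjects (defaults scale down the study's
  ~130 per group), 7 days × 8 beeps randomized within consecutive
  105-minute blocks between 08:00 and 22:00;
* per-subject coefficient matrices $B_i = B + U_i$ with entry-wise
  independent normal random effects (SD 0.05 by default), resampled until
  stationary; diagonal (inertia) entries drawn in 0.10–0.35 and
  off-diagonal edges in ±(0.05–0.15), matching the magnitudes such EMA
  analyses report; the spectral radius is capped at 0.9;
* nonnormal bounded marginals produced by strictly monotone maps of the
  latent gaussian series — a logistic map to 0–100 for the visual-analog
  items, 7-bin quantile discretization for the social-contact Likert item,
  and an exponential map for physical activity — which is exactly the
  situation the nonparanormal transform exists to undo;
* prompts missed completely at random at 17.5% (the study's average),
  capped at 50% per subject (its retention rule); device-measured
  physical activity is not blanked when a prompt is missed;
* raw accelerometry with rest, activity, and nonwear segments: worn rest
  is gravity plus slow posture drift (without it, a perfectly still worn
  device is indistinguishable from nonwear under any std/range rule) and
  sensor noise; activity adds 1–3.5 Hz bursts; nonwear is static with
  small noise, which places it below the detection thresholds by
  construction. The default sampling rate is 10 Hz, the low end of the
  emulated device's 10–100 Hz range, for tractable file sizes.

Missingness is MCAR because only an average missing rate is reported for
the study; real EMA missingness is likely bursty and mildly informative,
and group differences estimated here are robust to MCAR but not
demonstrated robust to informative missingness. Likewise the generator
draws random effects independently per entry; correlated random-effect
structure, measurement reactivity, time-of-day effects and weekend cycles
are *not* emulated, so passing tests certify the estimator and test
machinery, not those aspects of real data.

## Numerical and design choices

* Ties in the gaussianization receive average ranks, hence equal outputs.
* A constant column cannot be gaussianized and raises an error naming the
  variable; constant per-subject series are skipped (and counted) by the
  KPSS battery.
* Singular random-slope fits fall back to random intercepts with a
  warning; a singular intercept-only fit is an error.
* The edge list orders by |weight| descending with ties broken by
  predictor then outcome label, so exports are stable across platforms.
* `group_delta` in the generator perturbs exactly one edge of group 2's
  matrix after the spectral rescaling, so two-group simulations have a
  single known true difference; if the perturbed matrix violates the
  spectral cap the draw is rejected (bounded retries).
* All randomness flows through explicit seeds (`with_seed` restores the
  caller's RNG state), making every artifact bit-reproducible.

## Simulation sizes used by the test suite

The packaged checks run at desk scale, chosen so that each property is
decisive yet the whole suite completes quickly: parameter recovery uses 60
subjects × 56 beeps with zero random-effect SD and innovation SD 0.05;
null calibration of the permutation test uses 200 dataset pairs × 200
permutations on 3-node networks with 15 subjects per group; the power
check injects a 0.15 edge difference at 60 subjects per group across 100
replicates with 200 permutations each (the analysis scripts default to
2,000 permutations, and the statistic registry supports arbitrarily large
counts — the motivating study used 100,000). The Welch and ENMO oracles
run 1,000 random instances each.

## Known limitations

* The estimator reports Wald p-values; for very short series or tiny
  samples these are approximate (the permutation test does not rely on
  them).
* Person-mean centering of the predictors induces the classic O(1/T)
  attenuation of autoregressive coefficients (Nickell bias): at 56 beeps
  per subject the diagonal of $\hat B$ is biased downward by roughly
  $(1+\rho)/T \approx 0.02$. This is a property of all person-mean-centered
  multilevel VAR estimators, not of this implementation; it cancels out of
  two-group *differences*, which is what the permutation test compares.
* "Partial correlation" labels for lag-1 edges are interpreted as
  standardized lagged regression coefficients; exact estimator settings
  behind any particular published coefficient table (random-slope
  structure, standardization scheme) vary across software, so numerical
  agreement with a specific publication is not claimed.
* The contemporaneous and between-subject networks that complete the
  mlVAR triple are outside the reported surface.
* GENEActiv binary parsing and autocalibration are out of scope; raw
  signals are assumed calibrated in milligravity and are exchanged as CSV.

## A minimal run

```{r example, eval = FALSE}
spec <- generate_true_network(
  n_groups = 2, sparsity = 0.3, seed = 1,
  group_delta = list(from = "loneliness", to = "restriction", delta = 0.114))
cfg <- simulation_config(n_subjects_per_group = 40, seed = 2,
                         group_labels = c("no_lockdown", "lockdown"))
ema <- generate_dataset(spec, cfg)
tab <- nonparanormal_transform(assemble_analysis_table(ema))

pick <- function(g) {
  s <- tab[tab$group == g, ]
  attr(s, "node_labels") <- attr(tab, "node_labels"); class(s) <- class(tab); s
}
net <- fit_temporal_network(build_lagged_design(pick("lockdown")))
strength_centrality(net)
permutation_compare(pick("no_lockdown"), pick("lockdown"),
                    n_permutations = 2000, seed = 3, engine = "ols")
```

The numbered scripts under `analysis/` run the same workflow end to end
and leave every table under `results/`.
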