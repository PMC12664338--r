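---
title: "Modeling day-to-day movement-behavior dynamics with actidsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling day-to-day movement-behavior dynamics with actidsem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the preprocessing protocol, the estimation machinery, the
choices we made where the design was genuinely open, and what the test suite
does and does not establish.

## The scientific problem

Hip-worn accelerometers produce, for each participant, a week of
minutes-per-day summaries of sedentary behavior (SB) and physical activity
(PA). Two questions require a within-person, time-ordered analysis: whether
an unusually sedentary or active day carries over into the next day
(autoregression), and whether one behavior's deviation today predicts the
*other* behavior tomorrow (cross-lagged or "bidirectional" effects). Because
people differ both in their typical levels and in their dynamics, and
because person-level symptoms (pain, fatigue, well-being on a 0–10 numeric
rating scale) may moderate those dynamics, the natural framework is a
multilevel dynamic structural equation model (DSEM): a bivariate VAR(1) at
the within-person level whose coefficients are themselves random effects
explained at the between-person level.

## Model

For person $i$ on day $t$:

$$SB_{it} = \mu_{SB,i} + w_{SB,it}, \qquad PA_{it} = \mu_{PA,i} + w_{PA,it}$$

$$
\begin{aligned}
w_{SB,it} &= \phi_{SB,i}\, w_{SB,i,t-1} + \beta_{SB,i}\, w_{PA,i,t-1} + \zeta_{SB,it}\\
w_{PA,it} &= \phi_{PA,i}\, w_{PA,i,t-1} + \beta_{PA,i}\, w_{SB,i,t-1} + \zeta_{PA,it}
\end{aligned}
$$

with independent Gaussian innovations of variances
$\psi_{u,i} = e^{\lambda_{u,i}}$. The naming convention is fixed so that
$\beta_{SB}$ lives in the SB equation (yesterday's activity predicting
today's sitting) and $\beta_{PA}$ in the PA equation. The innovation
covariance is diagonal: no within-day residual covariance between SB and PA
is modeled, because none is reported for this model class; with wear time
roughly fixed, SB and PA minutes are negatively related *between* persons,
which the model carries in the between level instead.

All eight person effects
$u_i = (\mu_{SB}, \mu_{PA}, \phi_{SB}, \phi_{PA}, \beta_{SB}, \beta_{PA},
\lambda_{SB}, \lambda_{PA})_i$ are random. At the between level each is
regressed on one grand-mean-centered person-level predictor $P_i$:

$$u_i \sim N\!\big(\gamma_{0u} + \gamma_{1u}(P_i - \bar P),\ \tau_u\big),$$

mutually independent except for the $(\mu_{SB}, \mu_{PA})$ pair, which
carries the single between-level covariance $\sigma_\mu$ — the one
covariance this literature reports. Missing person-days are
missing-at-random and sampled as latent states.

**Initial condition.** Day-1 deviations follow the person's stationary
distribution, the solution $V_i$ of the discrete Lyapunov equation
$V = A V A^\top + \Psi$ (with $A_i$ the lag matrix). When a posterior draw
is non-stationary the initial density falls back to a diffuse
$N(0, 10^6 I)$. `fit_config(initial = "diffuse")` switches the likelihood to
the diffuse treatment for day 1 throughout — effectively conditioning on
the first observation, which is how the major commercial implementation
behaves. The stationary treatment is the default because it uses the day-1
information; it is the variant exercised by the package's replicate
calibration checks.

## Accelerometer preprocessing

All thresholds are arguments with the standard protocol as defaults:

| parameter | default | meaning |
|---|---|---|
| epoch length | 10 s in, 60 s out | six epochs summed per minute; partial minutes dropped, never zero-padded |
| non-wear window | 60 min | minimum length of a low-count window |
| allowance | 2 min | minutes with counts in (0, 100] tolerated inside a window |
| cut-point | 100 cpm | < 100 sedentary, ≥ 100 active, on worn minutes |
| valid day | 500 min | minimum daily wear time |
| inclusion | 4 days, 1 weekend day | valid days needed per person |

Non-wear semantics: a minute is non-wear iff it lies in *some* window of at
least 60 consecutive minutes whose counts are all ≤ 100 cpm with at most 2
non-zero minutes; any count above 100 terminates every window through it.
The union-of-windows reading matters for streams such as 59 zeros + 3 low
minutes + 59 zeros, where a greedy "maximal run" reading would disagree;
the implementation (a two-pointer sweep) is tested against a brute-force
scanner over all windows. Allowance minutes count toward window length and
are non-wear when inside a detected window. Windows may span midnight; days
are split at local calendar midnight afterwards, weekend = Saturday or
Sunday, and a person's day index runs 1–7 from their first recorded day.

## Estimation

`dsem_fit()` runs independent Metropolis-within-Gibbs chains (C++ core, all
randomness through R's RNG, so a seed fixes every byte of output):

1. person dynamics $(\phi, \beta)$ per equation by conjugate Gaussian
   regression, wrapped in an independence Metropolis–Hastings step whose
   acceptance ratio is the day-1 stationary-density ratio (this makes the
   update exact under the stationary initial condition; under the diffuse
   option the ratio is 1 and the update is the plain conjugate draw);
2. latent means $(\mu_{SB,i}, \mu_{PA,i})$ jointly, bivariate conjugate;
3. $\lambda$'s by adaptive random-walk Metropolis, step tuned to a 0.3–0.5
   acceptance rate during burn-in and frozen afterwards (detailed balance);
4. missing/initial states from their Gaussian full conditionals;
5. between level: conjugate regressions for $(\gamma_0, \gamma_1)$,
   conjugate updates for $\tau_u$ and the 2×2 $\mu$-covariance block.

Defaults mirror the field: 50,000 iterations, thin 10, 2 chains, first half
burn-in. Convergence is summarized by the potential scale reduction in the
$\sqrt{(W+B)/W}$ convention (identical chains give exactly 1); a single
chain falls back to split-chain PSR with a warning.

**Hyperprior scaling (important).** "Diffuse by default" must be read on the
data's scale. Minutes-per-day outcomes give $\psi \approx e^9$ and a
latent-mean spread of order $10^4$ min². Textbook "diffuse" choices —
IG(0.001, 0.001) for variances and an identity-scale inverse-Wishart for
the $\mu$ covariance block — are *not* diffuse here: the unit-scale
Wishart concentrates the covariance block near 1 min², and the joint
posterior acquires a quasi-absorbing degenerate mode in which the person
means collapse onto the between-level regression line while the freed
person-level offsets masquerade as autoregression (we traced
$\tau_{\mu,SB}$ from ~16,000 to ~1 over a few hundred sweeps, with
$\phi_{SB}$ inflating to 0.4–0.6). The package therefore defaults to the
flat variance priors of the standard commercial implementation: uniform on
each $\tau_u$ (IG(−1, 0)) and the flat improper inverse-Wishart
(IW(0, −(p+1))) on the covariance block, with $N(0, 10^6)$ on regression
coefficients and $N(0, 10^8)$ on the min/day-scaled intercepts. The
conjugate-ε settings remain available through `fit_config()`; with very few
persons the flat priors are improper and the fit demands either more
persons or proper hyperpriors (the error message says so). The sampler
kernel itself was verified exact with a successive-conditional (Geweke)
self-test, which reproduces prior moments to Monte-Carlo error.

**Stationarity is not enforced** on person-effect draws: reported
person-level coefficients may fall outside (−1, 1). Standardization simply
marks non-stationary draw/person combinations undefined and excludes them
from that draw's across-person average, reporting the exclusion rate
(typically well below 1%).

## Reporting

Point estimates are posterior medians (means also reported), intervals are
equal-tail 95% credibility intervals, the one-tailed posterior $p$ is
$\min(\Pr(\theta<0), \Pr(\theta>0))$, and "significant" means the interval
excludes zero — all matching this literature's conventions.

Within-person standardization uses model-implied stationary moments rather
than sample moments of seven noisy days: with $V_i$ from the Lyapunov
equation, $\phi$ is its own standardized value (same variable at both
lags), $\beta_{SB}$ is rescaled by $\sqrt{V_{PA}/V_{SB}}$ (and conversely),
the standardized residual is the innovation share $\psi_u / V_u$, and the
within $R^2$ is its complement. These are averaged across persons per draw
and then summarized over draws. One boundary subtlety: stationarity of the
bivariate system does not mathematically force $|\phi| < 1$ (a negative
cross-lag product can stabilize $|\phi|$ slightly above 1), so the familiar
bound holds for essentially all, but not provably all, stationary draws.

Between-person standardization divides $\gamma_{1u}\,\mathrm{SD}(P)$ by the
total between-level SD $\sqrt{\gamma_{1u}^2 \mathrm{Var}(P) + \tau_u}$; the
standardized $\sigma_\mu$ uses the same total-SD convention (with a null
predictor slope this is the plain residual correlation), and the
between-level $R^2$ is the predictor's variance share. The day-wise
descriptives report the SB share of wear both as the mean of person-level
ratios and as the ratio of day means, since the two conventions differ and
published percentages do not identify which was used; Spearman correlations
use average ranks with the two-sided t approximation.

The DIC is *conditional*: the deviance is minus twice the within-level
observed-data log density given person effects and latent states, $pD =
\bar D - D(\hat\theta)$ at posterior means, $DIC = \bar D + pD$. Conditional
DIC values are comparable across runs of this package but not across
software using marginal or differently-conditioned deviances.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are a stated
world, not a dial. Epoch streams: six 10 s epochs per minute, counts drawn
Poisson around level/6 within wear bouts (non-negative integers with
realistic dispersion), exact zeros outside, with per-minute wear ground
truth. Panels: person effects drawn from the between model
(rejection-sampling non-stationary draws, with a logged rejection count),
day-1 deviations from the person's stationary distribution, then the within
equations; simulated minutes are real-valued and deliberately *not* clamped
to [0, 1440] by default, since truncation would bias recovery tests (an
optional clamp exists). Default between-level truths sit at the magnitudes
published for hip-worn accelerometry in a sedentary-dominant adult cohort:
latent means ≈ 460/245 min per day of SB/PA with variances ≈ 13,900/10,850
and covariance ≈ −6,870 (a −0.56 correlation), weak positive autoregression
(0.18/0.05), near-zero cross-lags, log innovation variances 9.10/8.12 with
spreads 0.19/1.03, predictor slopes zero, and a pain-like predictor
(1.9 ± 2.4 on the 0–10 scale, truncated by resampling). The generator does
*not* emulate device-specific artifacts (spurious spikes, axis cross-talk,
day-boundary wear), integer-valued minute totals, or any real wear-time
distribution; a green recovery test therefore establishes correctness of
the estimation machinery under the stated model, not fidelity of that model
to any particular cohort.

## What the tests establish

The suite verifies, among others: exact agreement of non-wear detection
with a brute-force window scanner on random streams; Lyapunov residuals at
numerical precision and agreement with long simulated series; posterior
dynamics within ±0.02 of conditional least squares on a single subject with
2,000 days; pooled 95%-interval coverage of the eight fixed effects of at
least 85% over 20 study-scale replicates with PSR < 1.1 throughout; scale
invariance of every standardized quantity under rescaling the raw minutes;
and bit-for-bit determinism of the whole pipeline given a seed. In the
null-calibration check (predictor slopes truly zero), seven of the eight
ON-predictor intervals cover zero in at least 90% of the fixed-seed
replicates; the one exception falls a single replicate short there, a count
binomially consistent with nominal coverage rather than evidence of
miscalibration — the replicate block is deliberately not re-seeded to make
that check pass.

## Known limitations

- Lag-1 dynamics only; no measurement-error layer; exactly two outcome
  series; time-invariant predictors, one at a time (fit three models for
  three predictors, as the applied literature does).
- Day-level missingness only (a day is observed for both series or
  neither).
- The conditional DIC is not comparable to marginal-deviance DICs.
- Seven days per person identify dynamics mostly through pooling; the
  person-level coefficient ranges that the reports expose are
  shrinkage-dominated at that length.
- With fewer than ~5–6 persons the default flat hyperpriors are improper;
  supply proper ones or use the single-subject mode.
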