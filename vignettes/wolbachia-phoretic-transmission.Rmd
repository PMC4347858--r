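---
title: "Modelling endosymbiont spread with parasitoid-vectored horizontal transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling endosymbiont spread with parasitoid-vectored horizontal transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbdyn)
```

## The problem

*Wolbachia* and similar facultative endosymbionts are inherited from
mother to offspring, usually imperfectly. On vertical transmission alone a
strain with no fitness effect and no reproductive manipulation is doomed:
a fraction $\mu$ of each infected female's ova are uninfected, so
prevalence decays geometrically. Aphelinid parasitoids change the
arithmetic. When a wasp probes or feeds on an infected whitefly nymph its
mouthparts and ovipositor pick the bacterium up, and a subsequent
non-lethal probe of an uninfected nymph can establish a new, heritable
infection — the wasp acts as a phoretic ("dirty needle") vector. This
package implements the population-dynamic consequences of that mechanism
and the statistical machinery for the laboratory experiments that
characterise it.

## The prevalence recursion

With discrete generations and prevalence $p_t$ among adults, vertical
transmission, relative fecundity $F$ ($s_f = 1-F$) and cytoplasmic
incompatibility with relative hatch $H$ ($s_h = 1-H$) give the offspring
prevalence

$$k \;=\; \frac{p_t\,(1-\mu)(1-s_f)}
{1 - s_f p_t - s_h p_t (1-p_t) - \mu s_h p_t^2 (1-s_f)},$$

after which each infected host generates $w$ new horizontal cases among
the uninfected fraction:

$$p_{t+1} = k + w\,k(1-k).$$

$w$ is the number of new cases generated by one infected host in an
otherwise uninfected population, discounted by any reduction in vertical
transmission among hosts infected this way. Males and females are not
tracked separately: both sexes are assumed equally likely to be probed
and to transmit, so a single prevalence suffices.

Assumptions worth keeping in view: random mating; the visit rate of
vectors is constant across generations; wasps probe hosts independently
of infection status; horizontally infected females express fecundity and
CI exactly as stably infected ones.

### Parameters

| parameter | meaning | range | typical value here |
|---|---|---|---|
| $\mu$ | fraction of uninfected ova from infected mothers | $[0,1)$ | 0.03 |
| $F$ | relative fecundity of infected females | $>0$ | 1 or 1.05 |
| $H$ | relative hatch rate of incompatible crosses | $[0,1]$ | 1 or 0.1 |
| $w$ | horizontal cases per infected host per generation | $\ge 0$ | 0–0.06 |

`model_params()` stores $F$ and $H$ and derives $s_f,s_h$ on
construction, so a beneficial symbiont ($F>1$, negative $s_f$) needs no
special handling.

## Equilibria and invasion

Linearising at $p=0$ gives the invasion growth factor
$\lambda=(1+w)(1-\mu)F$; CI contributes only at second order, so the
threshold for invasion *from rare* never depends on $H$. For $w=0$ and
$s_h>0$, cancelling $p$ in $k(p)=p$ leaves the quadratic
$$s_h\,[1-\mu(1-s_f)]\,p^2-(s_f+s_h)\,p+1-(1-\mu)(1-s_f)=0,$$
whose smaller root is the classical CI invasion threshold
(`ci_threshold()`; 0.0345 at $\mu=0.03$, $H=0.1$). In general,
`fixed_points()` clears the recursion's denominator to a quintic in $p$
(with $p=0$ always a factor), takes the real `polyroot()` solutions in
$[0,1]$, Newton-polishes them, and cross-checks with a bisection scan
over $10^4$ grid points so ill-conditioned coefficient sets cannot drop a
root; roots closer than $10^{-8}$ are merged and each must satisfy
$|{\rm step}(p)-p|<10^{-10}$. Stability is classified from the map's
derivative, computed by central finite differences with step $10^{-6}$
(one-sided at the boundaries); $|{\rm d}p_{t+1}/{\rm d}p_t|$ within
$10^{-6}$ of 1 is reported as neutral. The identity map
($\mu=0,F=1,H=1,w=0$) is flagged degenerate rather than enumerated.

Three canonical scenarios (all $\mu=0.03$, $p_0=0.01$, contrasting
$w\in\{0,0.01,0.06\}$) are bundled as `scenario_trajectories()`: a
neutral strain (lost unless $\lambda>1$, i.e. $w>\mu/(1-\mu)\approx
0.031$; interior equilibrium $p^\*=(1-\frac{\mu}{w(1-\mu)})/(1-\mu)
\approx 0.4995$ at $w=0.06$), a CI strain ($H=0.1$; bistable at $w=0$,
near fixation at $w=0.06$), and a mutualist ($F=1.05$; equilibrium
$0.37$ at $w=0$, higher and reached faster with the vector). The default
horizon is 1000 generations — long enough for every regime here to reach
its attractor visually — and configurable. A trajectory is declared
converged when successive iterates differ by less than $10^{-10}$ and
lost below prevalence $10^{-6}$. For large $w$ the horizontal step can
formally exceed 1; it is clipped to 1 with a warning rather than an
error so sweeps over $w$ stay robust.

## The individual-based vector mechanism

`simulate_abm()` resolves the mechanism at the level of hosts. Each
generation: (1) reproduction — the number of infected offspring among
$n$ hosts is drawn $\mathrm{Binomial}(n, k)$ around the deterministic
vertical expectation (the discrete-generation framing leaves demographic
stochasticity open; binomial sampling is the minimal choice); (2) a
transmission phase — each host is probed with probability $v$ in a
random order by an effective wasp; probing an infected host contaminates
the wasp, and the contamination can infect the next uninfected host
probed with probability $\tau\sigma$ ($\tau$ = infection given survival,
$\sigma$ = survival of probing; by default the vector never kills its
host and $\sigma$ simply discounts infections that would not survive to
reproduce). The census is taken at the adult stage after vector
exposure, which makes generation $t$ of the ABM directly comparable with
the recursion $p_{t+1}=k+wk(1-k)$, whose horizontal step likewise acts
on the new generation. Contamination lasts one probe by default
(`infectious_visits`, configurable upward to mimic longer-lived
contamination), and a `kill_hosts` mode removes probed non-survivors
before reproduction instead.

Because every host is probed at most once per phase, infections created
during a phase cannot feed back into it, and the number of infection
opportunities is exactly the number of uninfected probes immediately
preceded by an infected probe — in expectation $n v\,k(1-k)$. Each
succeeds with probability $\tau\sigma$, which is why the aggregate
recursion with $w = v\tau\sigma$ summarises the mechanism, and why
`estimate_w()` (one infected host seeded in an otherwise uninfected
population, one phase, count the new cases) recovers
$v\tau\sigma(1-\tfrac{1}{nv})$ up to Monte-Carlo error. With the
behavioural values used throughout ($v=0.3$, $\tau=0.938$,
$\sigma=0.302$) this gives $w\approx 0.085$ — below the parasitism rate
but not dramatically so (`plausibility_band_for_w()`).

When the package validates the ABM against the recursion it compares the
mean trajectory (30 replicates of $10^4$ hosts over 40 generations) with
the recursion run at the *estimated* $w$, inside a band that combines
replicate noise with the uncertainty of $\hat w$ propagated through the
trajectory's sensitivity $\partial p_t/\partial w$ (finite differences).
Omitting that second term would treat a noisy $\hat w$ as exact and
reject structurally correct agreement.

## The statistics pipeline

The experiment analyses mirror standard practice for such data:

* **Proportions** (`outcome_proportions()`): percentages to one decimal,
  95% intervals computed on the logit scale
  ($\mathrm{logit}\,\hat p \pm 1.96\sqrt{1/x+1/(n-x)}$) and
  back-transformed — asymmetric on the proportion scale; boundary counts
  use the exact binomial interval instead. `logit_prevalence_fit()` does
  the same per group after pooling replicates, via intercept-only
  binomial GLMs (the saturated group model), so a single group
  back-transforms exactly to the raw proportion.
* **Heterogeneity** (`lrt_heterogeneity()`): twice the log-likelihood
  difference between per-group and common-probability binomial models,
  $\chi^2$ with (groups − 1) df — df 4 for a five-generation design.
  With replicated designs both models carry a replicate random intercept
  integrated by adaptive Gauss–Hermite quadrature (15 nodes,
  `lme4::glmer`); when the variance estimate collapses to zero (as it
  should under a well-behaved null) the test reduces to the fixed-effects
  GLM, which is the exact binomial likelihood-ratio test. The returned
  `note` records which likelihood was used.
* **Trend** (`logistic_trend()`): binomial regression of counts on time
  by IRLS (relative deviance tolerance $10^{-12}$), Wald $z$ on the
  slope; complete separation is detected from degenerate fitted
  probabilities and flagged rather than silently reported.
* **Fitness** (`fitness_compare()`): Gaussian traits are reduced to
  replicate (cage) means and tested by a pooled two-sample t — in the
  balanced $r+r$ design this is likelihood-equivalent to the linear
  mixed model with a replicate random effect and yields $2r-2$ df (6 for
  4 + 4 cages), which is what pins the analysis to the design rather
  than to any mixed-model engine. Ratio traits are per-pair counts fitted
  by a quasi-binomial GLM, the over-dispersion scale estimated from the
  Pearson statistic. Longevity uses the Cox partial likelihood
  stratified by replicate (Breslow ties, no censoring assumed) — a
  deliberate simplification of a shared-frailty model that preserves the
  arm contrast without estimating a frailty variance. Ratio traits carry
  an explicit `trials` column, since over-dispersion is unidentifiable
  from Bernoulli rows.

Tests are two-sided at the 95% level throughout.

## The synthetic generators

Each generator emulates one experiment's sampling structure, seeded and
deterministic (`withr::with_seed`; the global RNG is untouched):

* `gen_transmission()`: 106 visited nymphs split multinomially
  (0.358/0.340/0.302 died / parasitoid / whitefly), infection binomial at
  0.938 among survivors.
* `gen_persistence()`: 5 generations × 4 replicate lineages × 10 tested,
  binomial at a constant prevalence of 0.875 — the midpoint of the
  85–90% band such experiments report; the per-generation values are not
  tabulated anywhere, so a constant is the neutral choice and doubles as
  the null for calibrating the heterogeneity test.
* `gen_decay()`: 24/48/72/96 h × 4 replicates × 10 hosts, logit-linear
  decline anchored at 0.9 (24 h) and 0.1 (96 h) — the quantitative
  reading of "transmissible for the first 48 h".
* `gen_fitness()`: 4 cages × 10 pairs per arm; development time and
  fecundity Normal with cage random effects, longevity exponential with
  an infected hazard ratio of 0.5, survival and sex ratio over-dispersed
  binomial via logit-scale jitter. Effect sizes are realistic
  placeholders for this system, not measured values, and are documented
  as such.

What the generators deliberately do **not** emulate: real experiments
have non-binomial measurement error, possible temporal drift in
prevalence, censored longevities and correlated traits within pairs.
Passing the calibration suite therefore demonstrates that the estimators
are correct for their assumed sampling models, not that those models
exhaust real data.

## Validation choices and problem sizes

The test suite checks, among others: exact reproduction of worked
proportion/likelihood arithmetic; agreement of `fixed_points()` with the
$w=0$ quadratic across a $(\mu,H)$ grid to $10^{-10}$; invasion from
$p_0=10^{-4}$ iff $\lambda>1$ over a random parameter grid (cases with
$|\lambda-1|<5\times10^{-3}$ are skipped as numerically neutral over the
3000-generation horizon); IRLS against an independent Newton
maximisation of the binomial likelihood to $10^{-6}$; type-I error of
the heterogeneity LRT within $5\%\pm2\%$ over 2000 null persistence
datasets; trend-slope recovery bias below 5% over 500 decay datasets;
and 95%-interval coverage of a 1.5-day development-time effect of at
least 93% over 500 fitness datasets. These problem sizes keep the full
suite to a few minutes while leaving Monte-Carlo error well inside the
asserted margins.

## Known limitations

One effective wasp per generation (no wasp population dynamics or
host-instar preferences); no interspecific transmission; no sex
structure; the frailty longevity model is approximated by
stratification; the GLMM route of the heterogeneity test relies on
`lme4` and falls back to fixed effects whenever the replicate variance
is estimated at zero, so datasets with weak replicate signal are tested
slightly conservatively.
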