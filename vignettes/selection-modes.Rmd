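---
title: "Inferring selection modes from mutation-frequency trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selection modes from mutation-frequency trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotraj)
```

## The statistical problem

Time-resolved pool sequencing of an evolving, asexual microbial
population yields, for every de novo mutation, a frequency trajectory
sampled on a sparse grid of days. This package asks a single question of
a *family* of such trajectories: which mode of selection dominates the
dynamics — periodic selective sweeps, clonal interference, or
diversifying (negative frequency-dependent) selection between ecotypes?

The test rests on two nonparametric curve statistics over the
*established* trajectories, those that crossed a low threshold
$x_0 = 0.01$ and thereby escaped immediate stochastic loss:

* the frequency propagator $G(x)$, the fraction of established
  trajectories whose maximum ever reaches frequency $x$; and
* the sojourn-time spectrum $T(x)$, the mean time from origination at
  $x_0$ to the first occurrence at $x$, over trajectories reaching $x$.

These are summarised at an intermediate frequency $x_m = 0.3$ and a
near-fixation frequency $x_f = 0.95$:

$$p = \frac{G(x_f)}{G(x_m)}, \qquad \tau = \frac{T(x_f)}{T(x_m)}.$$

$p$ estimates the probability that a mutation established at
intermediate frequency goes on to (near-)fix; $\tau$ compares the time
scales of the late and early legs of the ascent. A deterministic
logistic sweep at any constant selection coefficient $s$ has
$T(x) = \log[x(1-x_0)/((1-x)x_0)]/s$, so the coefficient cancels in the
ratio and `logistic_sojourn_ratio(0.01, 0.3, 0.95)` $= 2.01$ is the
parameter-free reference for independent sweeps. Under clonal
interference only some established mutations outrun their competitors
($p<1$, roughly exponential propagator $G(x)\sim e^{-\lambda x}$,
`fit_propagator_decay()`), while passage times compress ($\tau \lesssim
2$). Under ecotype-structured, negative frequency-dependent selection,
conditionally beneficial mutations reach intermediate frequencies on the
time scale of their within-ecotype selection coefficients, but
cross-ecotype selection pins ecotype frequencies and suppresses
fixation: $p \ll 1$ and $\tau \gg 1$; with no fixation at all, $\tau$ is
reported as the end-of-observation lower bound
$(\text{end} - \overline{t_{\text{orig}}})/T(x_m)$ and flagged
`tau_is_lower_bound`.

The classification rule in `classify_mode()` is deliberately simple and
fully exposed (`mode_thresholds()`): diversifying if $p<0.5$ and $\tau$
(or its lower bound) exceeds 3; periodic sweeps if $p \ge 0.9$ and
$|\tau - 2| \le 0.5$; clonal interference if $0.2 \le p < 0.9$ and
$\tau \le 2.5$; anything else — including every fit on an observation
span shorter than 2000 generations (`confident = FALSE`) and every
boundary tie — resolves to `undetermined`. The descriptive ranges in the
literature overlap; fixed, documented cutoffs seemed preferable to
hidden judgment, and users can override them.

## Estimating origination and passage times from censored, sparse data

Pool-seq observation censors the data twice: frequencies are binomial
draws at finite depth (about 300× here), and calls below a detection
floor (5%) are reported as 0. Sampling is sparse relative to a sweep
(every 100 generations against a ~150-generation ascent from 1% to 95%
at $s=0.05$). Three numerical choices deal with this; all were
validated against matched simulations observed on a 10× finer,
noise-free grid, and both alternatives remain available as arguments.

**Crossing times** (`interpolation`, default `"logit"`). The first
occurrence of a level $x$ is interpolated between the straddling
samples on the logit scale, which is exact for logistic trajectories.
The frequency-linear chord (`"linear"`) lies below a sigmoid near
saturation and systematically delays the $x_f$-crossing at sparse
sampling — enough to inflate $\tau$ by ~0.4–0.5 at the study design
above, an estimator artefact, not dynamics. Frequencies are clamped to
$[10^{-4}, 1-10^{-4}]$ before the logit (a sample reading exactly 1.0 at
depth 300 constrains the true frequency only to $\gtrsim 0.99$);
segments starting at a censored 0 fall back to linear interpolation.

**Origination** (`method`, default `"backcast"`). Because $x_0 = 0.01$
sits below the 5% floor, the crossing of $x_0$ is never observed and
typically predates the last zero sample. The default backward-extrapolates
the first observed segment (the line through the first two detected
points) down to $x_0$, clipped to $[0,\ \text{first detected day}]$.
The alternative `"interior"` rule interpolates the chord from the last
zero sample, taking the 0 at face value; it under-reconstructs the
censored early segment, shortening all sojourn times by a constant and
biasing $\tau$ upward. Both rules coincide when only one detected point
exists or when observed points straddle $x_0$.

**Rare-type advantage** (`rare_advantage()`, default censored-binomial
maximum likelihood when the depth is known). The least-squares slope of
$\mathrm{logit}(x)$ over detected rare-range samples is the natural
estimator, but at depth 300 with a 5% floor the detected points just
above the floor are upward-selected noise, and the slope is biased low
by tens of percent — well outside the 20% recovery this estimator is
meant to deliver for effects of order 0.4% per generation. The ML fit
models read counts as binomial around a logistic mean path and treats
zero samples as left-censored at the floor; in the same validation it is
unbiased to a few percent. `method = "ls"` retains the simple slope.

## What the simulators emulate — and what they do not

`simulate_directional()` is a standard Wright–Fisher beneficial-mutation
process: multinomial resampling of genotype counts weighted by
$1+s_{\text{genotype}}$ (additive effects within a genotype),
$\mathrm{Poisson}(NU)$ new mutations per generation, full asexual
linkage via an explicit genotype genealogy, so hitchhiking and
interference emerge naturally. $N\,U$ sets the regime: $NU = 0.01$
(with fixed $s=0.05$) gives non-overlapping sweeps, $NU = 1$ (with
exponential $s$, mean 0.03) gives pervasive interference.

`simulate_resource_competition()` generates diversifying selection
mechanistically rather than by an imposed frequency-dependence: each
genotype allocates consumption over $R$ substitutable resources and its
resource payoff is $\sum_r \text{supply}_r\,\alpha_{gr}/\bar\alpha_r$
(`resource_fitness()`), so types feeding on underused resources gain
automatically and ecotype frequencies are attracted to supply
proportions. Mutations perturb the allocation vector (truncated
Gaussian, sd `alloc_mut_sd`, renormalised) *and* carry a direct
within-ecotype benefit (exponential, mean `s_mean`, default 0.03). The
direct component is a deliberate design choice: allocation perturbations
alone are selectively neutral in their marginal effect at the
consumer-resource equilibrium, so at $N = 10^5$ no marker would reach
intermediate frequency within 8000 generations by drift — whereas the
two-regime structure being emulated requires fast within-ecotype sweeps
under suppressed global fixation. The default initial condition seeds
$R$ pure specialists at supply-proportional frequencies (the
stable-ecotype regime); `init = "generalist"` starts from a single
generalist and lets ecotypes form or not.

Observation is layered on the exact dynamics by `subsample()`: binomial
reads at the scheme's depth, zeroing below the detection threshold, with
mutations never observed above the floor dropped — mirroring how variant
tables are actually filtered. Everything is reproducible from a single
integer seed, with the caller's RNG state untouched.

Desk-scale defaults are $N = 10^5$ and horizons of at most $10^4$
generations; in-vivo populations of $10^7$–$10^8$ are emulated by this
smaller $N$ because the regime is governed by the products $Ns$ and
$NU$, not by $N$ alone. Features of real data the generators do *not*
reproduce: horizontal gene transfer (HGT trajectories must be analysed
as ordinary trajectories), mutators, deleterious or neutral passengers
as an explicit class (passengers arise only as hitchhikers on beneficial
backgrounds), demographic bottlenecks, and measurement artefacts beyond
binomial depth noise. Passing the simulation-based checks therefore
demonstrates internal consistency of the estimators under each regime's
idealised dynamics, not agreement with any particular in-vivo dataset.

## Supporting statistics

* `detect_sweeps()`: a sweep is a trajectory whose interpolated maximum
  exceeds 95% and whose every later sample stays at or above the
  maintenance floor (default = the threshold; `strict = TRUE` forbids
  dips, since "kept high frequency" is qualitative in origin).
* `mutation_accumulation()`: $M(t)$ is the plain sum of allele
  frequencies per sampled day; its per-generation rate is the
  free-intercept least-squares slope (the first sample may postdate
  colonization). Fixed mutations keep contributing 1.
* `dn_ds()`: a raw count ratio, not site-normalised — site counts would
  require the genome annotation, which is out of scope; treat elevated
  values comparatively, not as a formal rate ratio.
* `parallelism()` counts hosts per mutated target (set semantics); the
  loss-of-function flag is the heuristic "hit by at least one indel or
  IS insertion".
* `freq_change_correlation()`: Pearson correlation between frequency and
  the subsequent change over consecutive *detected* samples (zeros are
  censored values and break pair formation), requiring at least four
  detected time points; a per-generation-rate variant is a flag.
* `assign_lineages()` makes the manual Muller-plot nesting rule
  deterministic: process mutations by descending maximum frequency
  (ties: earlier origination, then id); attach each to the deepest
  placed lineage that dominates it within `eps = 0.05` at every sampled
  day and whose trajectory it positively tracks over shared detected
  days (the correlation check passes vacuously below three shared
  detected days or for constant trajectories, e.g. a fixed parent);
  otherwise attach to the root, flagging low-frequency placements as
  low-confidence. `muller_table()` emits exclusive abundances, rescaling
  child overshoot within `eps` (with a warning) and raising an error
  naming the day and nodes beyond it; per day the abundances sum to 1.
* `max_growth_rate()` / `induction_rate()`: maximum sliding-window
  least-squares slope of $\ln(\mathrm{OD})$, respectively of the
  mitomycin-normalised $\ln$ ratio (reported as a positive per-hour
  rate). The window is 4 points (1.5 h at 30-min readings) by default;
  `window_points = 2` reduces to pairwise differences.

## Known limitations

* $T(x)$ averages over a different subset of trajectories at each $x$,
  so monotonicity of $T$ and $\tau \ge 1$ are guaranteed per trajectory
  and for homogeneous families, not for arbitrary mixtures.
* The propagator denominator counts each mutation trajectory once;
  linked cohorts are not collapsed, so a sweeping cohort of $k$
  mutations contributes $k$ identical trajectories.
* Lineage placement of low-frequency mutations from frequencies alone is
  intrinsically unreliable; the flag marks it rather than resolving it.
* The consumer-resource model is one concrete generator of negative
  frequency-dependent selection, chosen for mechanistic transparency;
  other ecological models (cross-feeding, phage predation) would produce
  the same test signature through different parameters.

## Problem sizes used in the checks

The packaged tests and `scripts/acceptance.R` use 20 replicate hosts per
regime at $N = 10^5$ and 8000 generations with depth-300 sampling every
100 generations; the fixation-probability check uses 2000 single-copy
replicates at $N = 10^4$; the neutrality moment check uses 2000
one-generation replicates at $N = 100$. These sizes give Monte-Carlo
errors comfortably inside the assertion margins while keeping a full run
in the tens of seconds on one CPU.
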