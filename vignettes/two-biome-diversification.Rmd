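---
title: "Two-biome geographic state-dependent diversification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-biome geographic state-dependent diversification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the numerical and design choices made where
conventions were genuinely open, and what the validation experiments do
and do not establish.

## The model

Every lineage on a dated phylogeny occupies one of three geographic
states: endemic to the **temperate** biome, endemic to the **tropical**
biome, or **widespread** (present in both). Seven rates, all in
events/lineage/Myr, govern the process:

* $\lambda_{Temp}, \lambda_{Trop}$ — within-biome speciation. An endemic
  speciates into two endemic daughters; a widespread lineage speciating
  *within* a biome leaves one endemic daughter in that biome plus one
  widespread daughter.
* $\lambda_{TempTrop}$ — speciation by biome divergence: a widespread
  lineage splits into one temperate and one tropical endemic.
* $\mu_{Temp}, \mu_{Trop}$ — extinction of endemics; the same rates act
  as range contraction of widespread lineages (a widespread lineage that
  "goes extinct in" one biome becomes endemic to the other). Widespread
  lineages therefore never die in one event.
* $d_{Temp}, d_{Trop}$ — range expansion into the widespread state.
  **Naming is source-labelled**: $d_{Temp}$ is the rate at which a
  *temperate* endemic expands into the tropics, $d_{Trop}$ the rate at
  which a *tropical* endemic expands into temperate regions. The
  meaning of the ratio $d_{Temp}/d_{Trop}$ in the robustness sweep flips
  if this is misread: values above 1 mean range expansion is more
  frequent *from temperate regions into the tropics*.

Net diversification within a biome is $r = \lambda - \mu$, the quantity
whose between-biome difference the whole analysis targets.

Tips are assigned states from latitudinal ranges against the tropic
lines at $\pm 23.4^\circ$: tropical if the range lies within them,
temperate if entirely poleward, widespread otherwise. The boundary is
measure-zero and the convention for ranges ending exactly on a line is
ours: a range touching a line from inside stays tropical; a range
*starting* exactly at a line is temperate.

## Likelihood

The log-likelihood is computed by the standard pruning scheme for
state-dependent birth–death models: for each lineage and state $i$,
$D_i(t)$ is the probability density of the observed subtree given the
lineage is in state $i$ at age $t$, and $E_i(t)$ the probability that a
lineage in state $i$ at age $t$ leaves no sampled descendant at the
present. Time is measured in Myr from the present into the past. Along
each branch the six coupled ODEs are integrated backward in time; the
extinction equations are, writing $T$, $R$, $W$ for
temperate/tropical/widespread,

$$\dot E_T = \mu_T - (\lambda_T + d_T + \mu_T) E_T + d_T E_W + \lambda_T E_T^2$$
$$\dot E_W = -(\lambda_T + \lambda_R + \lambda_{TR} + \mu_T + \mu_R) E_W
  + \mu_T E_R + \mu_R E_T + \lambda_T E_T E_W + \lambda_R E_R E_W
  + \lambda_{TR} E_T E_R$$

(and symmetrically for $E_R$); the $D$ equations carry the matching
linear loss, gain and re-speciation terms. At an internal node of age
$t_n$ the daughters combine as

$$D_T \leftarrow \lambda_T(t_n)\, D_T^{(l)} D_T^{(r)}, \qquad
D_W \leftarrow \tfrac12 \sum_{\text{modes}} \lambda_{\text{mode}}(t_n)
  \left( D^{(l)} D^{(r)} + D^{(l)} \leftrightarrow D^{(r)} \right),$$

where the widespread sum runs over the three cladogenetic modes
(within-temperate, within-tropical, biome divergence), each symmetrized
over the left/right daughter assignment with a factor $\tfrac12$ — and
no $\tfrac12$ on the endemic combinations. This factor convention is
fixed; since the forward simulator realizes exactly the same event set,
the simulator-vs-likelihood recovery experiments in the test suite are
the binding check that the two sides agree.

**Incomplete sampling.** State-specific sampling fractions
$f_T, f_R, f_W$ enter only through the tip conditions: $D_{\text{obs}} =
f_{\text{obs}}$, other $D = 0$, and $E_i = 1 - f_i$ for every state.
They are estimated as (tips in state)/(described species in state),
with described totals optionally extrapolated from trait-database
proportions times a described-species grand total (rounded half-up).

**Root treatment.** The data do not determine how the three root-state
values are combined. The default weights each state by its relative
$D$ value and conditions on survival — dividing by
$\sum_i w_i \lambda_i (1 - E_i)^2$ with $\lambda_W = \lambda_T +
\lambda_R + \lambda_{TR}$ — matching the convention of widely used
state-dependent diversification software; equal weights and a fixed
root state are available. One non-obvious consequence, worth knowing
when benchmarking: even with both dispersal rates at zero, the
*widespread* state keeps a nonzero subtree density (a lineage observed
as endemic may have been widespread and contracted), so the
likelihood-weighted root leaks weight onto it and the model does **not**
collapse exactly to a one-region birth–death model. The collapse is
exact under a fixed root state, which is how the birth–death oracle
checks are run.

**Time variation.** Within-biome speciation rates may vary linearly,
$\lambda(t) = \lambda_0 + r\,t$ with $\lambda_0$ the rate at the
present; extinction, dispersal, and biome-divergence speciation stay
constant. Because $t$ increases into the past, *negative* slopes mean
speciation increasing through time toward the present (the regime the
bundled `time_increasing` scenario emulates). Rates are evaluated at
absolute ages, including at node combinations. Parameter sets with
$\lambda(t) < 0$ anywhere on $[0, \text{tree height}]$ get
log-likelihood $-\infty$ rather than being clamped: positivity over the
clade's history is treated as a hard constraint.

**Numerics.** Each branch is integrated with an adaptive Dormand–Prince
5(4) scheme at relative tolerance $10^{-8}$ and absolute $10^{-10}$
(the test suite verifies that halving the tolerances moves a 100-tip
log-likelihood by less than $10^{-6}$). After each branch the $D$
vector is rescaled to unit sum and the log factor accumulated, which
prevents underflow on trees of thousands of tips. During
maximum-likelihood fitting and MCMC the analysis drivers relax the
tolerances to $10^{-7}/10^{-9}$; the objective changes far below the
scale that model selection or posterior summaries resolve.

## Model space and inference

The scenario space crosses (i) biome-divergence speciation present or
fixed to zero, (ii) equal or free dispersal, and (iii) the four
equality patterns of $\lambda$ and $\mu$ — 16 models, of which the 8
dispersal-equal ones form the reduced space for small phylogenies. The
fully free model has 7 parameters.

ML fits run on the log-rate scale (lower bound $10^{-10}$, avoiding
boundary pathologies of rates at zero) with L-BFGS-B, slopes on the
natural scale since they may be negative. Starting points come from the
character-independent (equal-rates, 3-parameter) fit, jittered
multiplicatively by $U(0.5, 2)$ per rate; across a nested model set the
fits are warm-started from the best already-fitted model, which also
enforces the expected lnL monotonicity across nested pairs in practice.
Models are ranked by AIC ($2k - 2\ln L$), ties broken toward fewer
parameters, and the selected model is checked against each model nested
within it by likelihood-ratio tests with $\chi^2_{\Delta k}$ reference.
Time-varying refits deserve a caution: the zero-slope point (the
time-constant optimum embedded in the richer model) can be
near-stationary even when time dependence is supported, so
`fit_time_varying()` starts the optimizer deterministically at zero
slopes and at slopes of $\pm 0.3\,\lambda_0/\text{height}$ and keeps
the best optimum.

**Priors and MCMC.** All free rates share an exponential prior whose
mean is twice the character-independent net-diversification estimate
($\text{rate} = 1/(2\hat r)$); when $\hat r \le 0$ the mean falls back
to the character-independent speciation rate. The exact prior
parameterization behind this convention is not published; this rule is
our informed default and is recorded in the output metadata. Sampling
is univariate slice sampling with linear stepping-out (width = prior
mean, unlimited steps) and shrinkage, truncated to positive support; we
chose stepping-out over interval doubling because doubling requires an
extra acceptance test for correctness while unlimited stepping-out is
valid with plain shrinkage. The default chain is 20,000 sweeps after a
500-sweep burnin; the chain mixes within a few sweeps on the problems
here, so tests and drivers use shorter chains. MCMC covers
time-constant models only — the exponential prior has no meaning for
sign-free slopes — and a single seeded chain is used, with the lnL
trace retained for stability inspection. Significance of the
net-diversification difference is read off the equal-tailed 95%
credibility interval of the draw-wise $r_{Trop} - r_{Temp}$: the
difference is called significant when the interval excludes 0.

## Dispersal-ratio sweep

The published grid specification — "150 values from 0 to $+\infty$" —
leaves the spacing open. We place the grid uniformly in
$u = \rho/(1+\rho) \in [0,1]$, which is symmetric under
$\rho \leftrightarrow 1/\rho$, maps the endpoints to literal one-way
dispersal submodels ($d_{Temp} = 0$, resp. $d_{Trop} = 0$), and forces
$u = 0.5$ ($\rho = 1$) onto the grid by snapping the nearest point
(for even grid sizes this single snapped point is the only departure
from exact reciprocal symmetry — a parity constraint, since a symmetric
grid containing the self-symmetric point $\rho = 1$ must have odd
size). Each grid fit constrains
$d_{Temp} = \rho\, d_{Trop}$ with one free dispersal scale and is
warm-started from its neighbour, sweeping outward from $\rho = 1$
(profile-likelihood continuity). The reported interval is the largest
contiguous grid run around $\rho = 1$ on which the sign of
$\hat r_{Trop} - \hat r_{Temp}$ matches the baseline sign.

## The forward simulator

The simulator realizes exactly the events the likelihood models, by
next-event (Gillespie) sampling with per-state rate bookkeeping; for
time-varying speciation the waiting times are drawn against an upper
rate bound and thinned. It emulates the kind of data the real analysis
consumes — a dated, ultrametric, nearly complete species-level tree
with biome states and known sampling fractions — with defaults chosen
to be mammal-like: rates of order $0.05$–$0.4$ events/lineage/Myr, tree
heights of 15–40 Myr giving ~500 sampled tips, sampling fractions
$(0.84, 0.83, 0.85)$, and a tropical root state for the
tropical-origin scenarios.

Two conditioning choices matter when interpreting results. Runs that
die out (or, with a target size, miss the acceptance band) are retried
up to a cap, with the retry count recorded: this conditions the output
on survival, matching the likelihood's default conditioning, and the
size band (simulate to fixed time, reject sizes outside the band) is a
simplicity-over-exactness choice that mildly favours typical-sized
outcomes over the generalized sampling approach.

What passing the recovery tests does *not* show about real data: the
generator has no among-lineage rate variation within a biome, no
nonlinear time dependence, no spatial structure beyond the two biomes,
no phylogenetic or dating error, and biome states are known without
error. Results on real supertrees inherit all of those complications.

## Validation experiments and their problem sizes

The test suite and the acceptance script rerun, at fixed seeds:

* exact oracles — closed-form birth–death reduction (fixed-state root),
  pure-death extinction probabilities, zero-slope degeneracy of the
  time-varying likelihood;
* simulator moment checks — mean Yule tip count $e^{\lambda T}$ and
  binomial sampling thinning, each within 3 Monte-Carlo SE at 1,000
  replicates;
* parameter recovery — 50 replicates of ~500-tip out-of-tropics data
  (the standalone validation script runs 40 and records its replicate
  counts alongside each value),
  checking the sign of $\lambda_{Trop} - \lambda_{Temp}$ and
  $\mu_{Temp} - \mu_{Trop}$ and the per-rate median *signed* relative
  error (a bias measure: ML point estimates of the weakly identified
  rates — extinction above all — scatter widely at this size, so their
  median *absolute* relative error is large even for a correct
  implementation, while their median signed error stays near zero);
* model-selection calibration — 50 replicates per regime at ~200 tips
  over the 8 dispersal-constrained models: equal-rates data should
  select the equal-rates model most of the time, out-of-tropics data a
  model with unequal $\lambda$ or $\mu$ in a large majority;
* MCMC sanity — seeded determinism, posterior-mean/ML agreement within
  2 posterior SD on a ~500-tip fixture, and recovery of the exponential
  prior by the slice sampler under a flat likelihood.

These sizes keep the full suite within a practical runtime on one CPU;
they are stated here so the experiments are reproducible as specified.

## Known limitations

Extinction rates (and with them absolute net diversification) are
weakly identified from extant-only phylogenies; treat the *difference
in trends* between biomes, not the absolute $\mu$ values, as the robust
output. Only two regions are modelled; the likelihood conditions on a
known, binary, ultrametric tree (no fossils, no polytomies, no dating
error); per-lineage rate heterogeneity and diversity dependence are out
of scope. The per-order batch mode simply extracts MRCA clades and
reruns the pipeline, which ignores dispersal into and out of the focal
clade.
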