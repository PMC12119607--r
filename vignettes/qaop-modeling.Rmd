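---
title: "Bayesian-network qAOP modeling: methods and design notes"
author: "qaopbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian-network qAOP modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qaopbn)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open.

## The AOP and its graph

The adverse outcome pathway (AOP) is a knowledge-driven causal chain for
smoke-induced mucus hypersecretion in bronchial epithelium. Its measured
nodes are ROS generation and GSH depletion (molecular initiating events),
AREG secretion (a modulating factor feeding EGFR signaling), EGFR
activation (KE1), SP1 activation (KE2), mucin MUC5AC production (KE3),
goblet-cell metaplasia/hyperplasia (KE4) and mucus hypersecretion (the
adverse outcome, AO). We encode it as a directed acyclic graph with the
dose — the nicotine concentration of the whole-smoke exposure, in µg/mL —
as a parentless continuous root node:

```{r}
default_aop()
```

Two structural decisions were open and are worth recording:

* **KE2 is excluded by default.** Its in vitro readout is too variable to
  regress on; `default_aop(include_ke2 = TRUE)` restores it, and the
  synthetic generator still produces KE2 data either way (with inflated
  noise), so the exclusion is an analysis choice, not a data-format one.
* **Dose feeds only the upstream assays** (ROS, GSH, AREG). The
  alternative wiring — dose as a direct parent of every node — is a
  legitimate reading of a dose-rooted AOP; it is available by building a
  custom `aop_graph()`, which the whole pipeline accepts. We default to
  the parsimonious chain because it preserves the AOP's mediation logic:
  downstream probabilities respond to dose only through their upstream
  key events. A practical consequence, visible in the examples below, is
  that dose–response signal attenuates through each regression stage, so
  late-node dose curves are flatter than the raw data's.

## The synthetic-data generator

The laboratory dataset the analysis was designed around is not publicly
deposited, so the package treats a generator as first-class: it emulates
the *statistical structure* that the pipeline assumes, with known ground
truth. It is explicitly not a mechanistic simulation of smoke chemistry
or cell biology.

Per replicate, the fold change is lognormal:

$$\mathrm{FC}_{n,e,d,v,r} = \exp\!\big(\underbrace{a_n\, \rho_{nv}\, E_v\,
H_v(d)\, T_v(e)}_{\text{signal}} + \underbrace{\delta_v (e-1)}_{\text{drift}}
+ \varepsilon\big),\qquad \varepsilon \sim N(0, \tau_v^2)$$

* $H_v(d) = d^{h}/(\mathrm{EC50}^{h} + d^{h})$ is a Hill saturation in
  dose, zero at the air control;
* $T_v(e)$ is an asymmetric Gaussian bump over exposure repetitions —
  early nodes (ROS, GSH, AREG, KE1) peak at exposure 1–2 and decay slowly
  (decay widths 3.5–4), so their dose response fades gradually but never
  vanishes; late nodes (KE3, KE4, AO) peak at exposure 5–6;
* $a_n = \exp N(0, 0.3^2)$ is a donor amplitude; each donor also shifts
  the late-node peak backward by $|\,\mathrm{round}\,N(0,1.5^2)|$
  exposures (capped), reproducing the observed spread of donors peaking
  at exposure 3–4 versus 6;
* $\rho_{nv}$ implements the responder mixture: with probability 0.5 a
  donor is a responder; non-responders have their late-node signal
  multiplied by 0.15, which makes pooled late-exposure, high-dose
  distributions bimodal;
* $\delta_v = 0.04$ per exposure for the mucin endpoints encodes the slow
  upward creep of mucin readouts even under air control — the ingredient
  that later gives the odds-ratio control arm nonzero odds;
* maximal effects $E_v$ are set so the AO and KE4 reach roughly 10–20
  fold at the top dose (goblet-cell fractions bound the plausible dynamic
  range), with smaller maxima upstream.

Defaults mirror the study conditions: 6 donors × 3 replicates, doses
{0, 510, 1620, 4490} µg/mL, 6 exposure repetitions, replicate noise SD
0.25 (natural-log scale; 0.8 for the fragile KE2). All of it is
config-exposed through `generator_config()`, and `simulate_invitro()`
returns the realized expectation surface, donor effects and responder
flags as ground truth for recovery tests.

What passing tests on this generator show — and what they do not: the
pipeline provably recovers known parameters, respects its closed-form
oracles and reproduces the qualitative dose/exposure/threshold patterns
*under the generator's assumptions* (lognormal noise, Hill × temporal
separability, linear-Gaussian-compatible dependence). Real cultures can
violate all of these (heteroscedastic assays, saturating histology,
donor-by-dose interactions), so numerical probabilities from synthetic
data are not estimates of the laboratory system's probabilities.

## Resampling

`resample_dataset()` implements moment-matched lognormal resampling.
For each cell and node, $\mu = \ln(\bar f^2/\sqrt{\bar f^2 + s^2})$ and
$\sigma^2 = \ln(1 + s^2/\bar f^2)$ are the exact lognormal
location/scale for a distribution with mean $\bar f$ and SD $s$. The
covariance couples nodes through a correlation matrix pooled **per
exposure** across all (donor, dose) cells — computed on per-cell mean log
fold changes — because per-cell correlation is not estimable from three
replicates. Numerical details:

* Pooled correlations with per-cell variances can produce an indefinite
  covariance; `repair_psd()` clips negative eigenvalues at zero and
  restores the original diagonal by a congruence rescaling (which cannot
  break positive semi-definiteness). Repairs are silent but logged in the
  object's `repairs` attribute and in the provenance sidecar.
* Sampling uses an eigendecomposition square root, so PSD-singular
  covariances (post-repair) are handled without a Cholesky failure.
* Draw $i$ of a (donor, dose) cell reuses one standard-normal block
  across all exposures. Marginally per exposure the draws are exactly
  $MN(\mu, O)$; jointly they form coherent trajectories, which is what
  the dynamic model's transition regressions require. Draws are aligned
  by (donor, dose, draw index) and `fit_dbn()` verifies that alignment.
* One master seed; each cell derives an independent substream, so partial
  regeneration is stable. M defaults to 1,000 draws per datapoint;
  property tests use larger M.
* Everything internal is natural-log; thresholds arrive as FC, log2FC or
  log10FC and pass through `threshold_to_log()` exactly once. No implicit
  scale anywhere — a configuration threshold without a declared scale is
  an error.

## Static model

`fit_gbn()` fits, per exposure slice and per non-root node, an OLS
regression of the node on its graph parents over the pooled resampled
draws of all donors and doses, with the dose column appended as the root
value. Predictors are standardized internally (doses span 0–4,490 while
log fold changes are order 1) and coefficients returned on the original
scale; exact collinearity fails fast naming the offending parents rather
than silently pseudo-inverting. Residual variance uses denominator
$n - p$.

Inference is forward (ancestral) sampling with the dose fixed as an
interventional root assignment — the standard reading of querying a
dose-rooted Gaussian BN. $P(\mathrm{KE} > \Delta \mid d)$ is the
exceedance fraction over `M` samples (default 10,000, binomial SE always
reported). A dose window $[d \pm \epsilon]$ is available
(`epsilon > 0` draws each sample's dose uniformly in the window) but
defaults to 0: with forward sampling the window exists only for
compatibility with the windowed formulation, not because estimation needs
it. Doses outside the fitted range warn (extrapolation) but proceed,
since OR grids deliberately extend to 5,000 µg/mL.

Goodness of fit is the squared correlation between the model's
conditional means (given observed parents) and observed values, per node
— for OLS on the training slice this is the regression $R^2$; on other
slices it is a transfer diagnostic.

## Dynamic model

`fit_dbn()` regresses each node at exposure $e$ on its own value and its
graph parents at $e-1$, pooling aligned draws over donors and doses, with
dose as an additional covariate. Open choices, resolved as follows:

* the lag is fixed at $\tau = 1$ (the Markov formulation); a longer lag
  would need a different pooling scheme and is out of scope;
* dose is included in the transition regression as an **unpenalized**
  covariate (rather than stratifying by dose), keeping one model per
  transition; a stratified analysis can be emulated by filtering the
  resamples before fitting;
* ridge penalties come from a 50-point log-spaced grid on
  $[10^{-3}, 10^{3}]$; the intercept is never penalized and predictors
  are standardized inside the solver;
* the penalty is selected by exact leave-one-out cross-validation using
  the closed-form identity $e_i^{\mathrm{loo}} = (y_i - \hat y_i)/(1 -
  h_{ii})$ for the fixed linear smoother, with ties broken toward the
  larger penalty. For efficiency the selection runs on a random
  subsample of at most 2,000 rows (the identity stays exact on the
  subsample; the final fit uses all rows). A constant response is
  degenerate and returns the grid maximum with a warning. Worth noting:
  exact LOOCV is itself noisy — on pure-noise problems it picks the grid
  maximum in roughly 60–80% of replications, not always, which is a
  property of LOOCV rather than of the implementation.

Transition probabilities use likelihood weighting. The evidence node
(e.g. KE4 at $e-1$) is proposed uniformly on a range whose default is
$[\Delta,\ 2 \times \text{marginal mean}]$ — the cutoff is taken equal to
the activation threshold, and "mean" is the fitted marginal mean of the
evidence node at the queried dose and previous exposure (linearly
interpolated between fitted doses). Particles are weighted by the
Gaussian marginal density of the evidence; remaining previous-exposure
regressors are drawn from their marginals; the target is sampled from the
fitted transition; the estimate is the weighted exceedance fraction, with
effective sample size and a weighted standard error reported. When the
range is degenerate ($2\times$mean $\le$ cutoff, typical at early
exposures or low doses where the evidence node is not yet activated) the
query errors; batch drivers (`run_pipeline()`,
`donor_subset_distribution()`) catch this per query and record `NA` with
a warning instead of failing the run.

`donor_subset_distribution()` reruns resample → fit → query on every
$\binom{N}{k}$ donor subset (20 for 3 of 6) and returns five-number
summaries — the donor-variability band around each transition
probability.

## Odds ratios

`or_vs_dose()` re-expresses every fold change relative to the matched
donor's exposure-1 air-control mean, so the control condition at later
exposures retains its drift; the control arm's probability at dose 0 is
then genuinely nonzero and the odds ratio

$$\mathrm{OR}(d) = \frac{P(d)/(1-P(d))}{P(0)/(1-P(0))}$$

is finite. The event is KE4 (GCM/H) exceeding a 10-fold change — chosen
because mucin concentrations are roughly 10-fold elevated in severe
disease — evaluated from the late-exposure (default 6) static model over
a 500–5,000 µg/mL grid. The control arm uses the *same late-exposure*
model at dose 0 (drift included); using the exposure-1 control instead
would fold the aging effect into the exposure arm, and is available by
fitting `exposure = 1`. Degenerate arms (probability 0 or 1) are flagged
per row, never dropped; an optional continuity correction is off by
default and recorded when used.

## Dosimetry bridge

The reverse-dosimetry module is deliberately plain arithmetic:
`per_area_dose()` converts an insert concentration to
µg/cigarette/cm²/day via the collection volume (110 µL) and insert area
(0.33 cm²), reported at 2 decimals by convention with full precision
available; `tb_surface_area()` sums per-generation airway surface areas
over generations 0–6 (the goblet-cell-bearing region);
`deposition_concentration()` divides a deposited mass by a region area.
Aerosol deposition physics is out of scope: the deposited mass per
cigarette is an input, and the published input parameter tables of the
deposition model ship only as a documented YAML fixture. The packaged
airway geometry is computed from the public Weibel model "A" morphometry
(cylindrical areas, $\pi d \ell \cdot 2^g$) and is a synthetic stand-in:
its generation 0–6 total (~252 cm²) is not the morphometry total any
specific study used, and no test asserts agreement with one.

## Problem sizes and determinism

Default analysis sizes are chosen as a deliberate accuracy/cost point:
1,000 resampled draws per datapoint (matching the resampling design the
analysis assumes), 10,000–20,000 forward samples per probability (SE
≤ 0.005), 50,000–100,000 particles where an oracle comparison needs
tight Monte-Carlo error, and 100–300 draws per cell inside the 20-fold
donor-subset loop. Every stochastic function takes an explicit seed;
substream seeds are derived with a small multiplicative hash kept below
$2^{31}$. `run_pipeline()` writes a manifest with the config hash and
per-file checksums, and identical configs reproduce byte-identical CSVs.

## Known limitations

* All conditionals are linear-Gaussian; saturating or threshold-like
  node relationships are approximated by their pooled linear projection,
  which attenuates dose signal through long mediation chains.
* The per-exposure pooling of the correlation matrix assumes one
  response–response correlation structure across donors and doses.
* The dynamic model's evidence-range rule and likelihood weighting are
  one concrete reading of a loosely specified inference scheme; the
  range, threshold and particle count are all exposed.
* Synthetic-data results validate machinery, not biology: no claim is
  made that probabilities or odds ratios computed here match those of
  any laboratory dataset.
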