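---
title: "Hybrid process-informed neural networks: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid process-informed neural networks: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ecopinn combines mechanistic simulators ("process models", PMs) with
multi-layer perceptrons into process-informed neural networks (PINNs) and
evaluates them end to end on two self-contained study systems: a
predator–prey benchmark whose every input is printed in the package, and a
synthetic multi-site forest carbon-flux problem. This vignette is the
package's account of the science: the models, their assumptions, the
tunable parameters, the numerical choices, and what the synthetic testbed
can and cannot show.

## The two process models

### Predator–prey dynamics

The data-generating model is a Lotka–Volterra system with a sigmoidal
(type III) functional response,

$$\frac{dx}{dt} = r x - \frac{b x^2 y}{1 + s x^2}, \qquad
  \frac{dy}{dt} = \frac{b x^2 y}{1 + s x^2} - m y,$$

with prey growth rate $r = 0.1$, feeding rate $b = 0.02$, predator
mortality $m = 0.04$ and prey searching time $s = 0.025$, simulated from
densities $(x_0, y_0) = (10, 10)$ over 130 time units on a grid of step
0.5. The deliberately mis-specified process model replaces the sigmoidal
by a linear (type I) feeding term $b x y$ and assumes initial densities
$(12, 10)$; those initial conditions are part of the model configuration,
not estimated. Three benchmark scenarios share nine prey observations at
random grid times: (i) sparsity only (the PM is structurally correct),
(ii) sparsity plus the structural error, (iii) additionally Gaussian
observation noise with standard deviation 0.5.

**Integration.** Both systems are integrated with a classical fixed-step
4th-order Runge–Kutta scheme at internal step 0.05, subsampled to the
output grid. No scheme is canonical here; RK4 was chosen because it is
simple, its order is verifiable (halving the step shrinks the error
$\ge 8\times$ in the tests), and it is smooth in the parameters, so exact
forward sensitivities can be propagated alongside the state. The type I
system's conserved quantity $H = b x + b y - m \ln x - r \ln y$ is used
as an independent accuracy probe.

**Differentiability.** R has no automatic-differentiation substrate, so
the gradient contract is met analytically: the sensitivity equations
$S' = A(u)\,S + B(u)$ (with $A = \partial f/\partial u$,
$B = \partial f/\partial \tau$) are integrated with the same RK4 scheme,
yielding exact gradients of every grid point with respect to
$(r, b, m, s, x_0, y_0)$. The test suite verifies them against central
finite differences at relative tolerance $10^{-4}$.

### A miniature light-use-efficiency flux model

The flux PM maps daily drivers
$X = (T, D, \phi, R, \mathrm{faPPFD}, \mathrm{CO_2}, d)$ — air
temperature (°C), vapour pressure deficit (kPa), photosynthetically
active radiation (mol m⁻² day⁻¹), precipitation (mm day⁻¹), absorbed PAR
fraction, CO₂ (ppm) and day of year — to
$Y = (P, E, \theta)$: gross primary productivity (g C m⁻² day⁻¹),
evapotranspiration (mm day⁻¹) and stored water (mm). Its daily core is a
light-use-efficiency model,

$$P_k = \beta\, \phi_k\, \mathrm{faPPFD}_k \prod_i f_{i,k},$$

with multiplicative modifiers in $[0, 1]$. Full ecosystem models of this
family specify many empirical modifier forms; this package instead
*defines* a documented mini-model that preserves the structure — the
$\theta \to P$ coupling through a soil-water modifier $f_{W,P}$ and the
$P,\theta \to E$ coupling through $f_{W,E}$ — with the fewest free
parameters. It is a stand-in, not a port, of any published
parameterisation, and is also the data-generating "truth" (plus
controlled perturbations) for the synthetic experiments:

* $f_T = \mathrm{logistic}(k_T (\tilde T - T_0))$, where $\tilde T$ is an
  exponential moving average of temperature with e-folding time
  $t_{acc}$ (seasonal acclimation);
* $f_D = \exp(-\kappa D)$;
* $f_{W,P} = f_{W,E} = \mathrm{clamp}\!\big((w - w_{wilt})/(w_{sat} -
  w_{wilt}),\,0,\,1\big)$ with $w = \theta_{soil}/\textrm{capacity}$,
  evaluated at the previous day's soil water (the two ramps share their
  break points to keep the parameter count near ten);
* $E = \alpha P D^{\nu} f_{W,E}$;
* water balance: precipitation falls as snow below 0 °C or through a
  surface pool that drains to the soil the same day; snow melts at a
  degree-day rate; $E$ is limited by available water; drainage caps the
  soil pool at capacity. The balance
  $\theta_k - \theta_{k-1} = R_k - E_k - \mathrm{drainage}_k$ closes to
  $10^{-9}$ mm in the tests.

The 11 parameters with their defaults and prior bounds are in
`flux_param_table()`. CO₂ is accepted as an input but unused by the
default modifiers (the functional role of CO₂ is left open in this model
family); day of year never enters the PM directly. Initial pools are
soil at 0.7 × capacity and empty snow/surface unless configured.

Parameter Jacobians of $P$, $E$ and $\theta$ are propagated day by day by
the chain rule through the recursion (`run_flux_pm(sensitivities =
TRUE)`), using the active branch's derivative at the piecewise-linear
kinks. At generic parameter values these Jacobians match central finite
differences to $10^{-4}$ relative; exactly at a ramp break point the
one-sided derivatives differ, which is inherent to the model form.

## The model variants

`model_variant()` configures seven models. With $\hat y^{NN}$ the network
output and $\hat y^{PHY}$ the PM prediction:

| kind               | prediction                  | training loss |
|--------------------|-----------------------------|---------------|
| `pm`               | $\hat y^{PHY}$              | (calibration) |
| `naive`            | $\hat y^{NN}(X)$            | $\mathrm{MSE}(y, \hat y^{NN})$ |
| `bias_correction`  | $\hat y^{NN}(\hat y^{PHY})$ | $\mathrm{MSE}(y, \hat y^{NN})$ |
| `parallel_physics` | $\hat y^{NN} + \hat y^{PHY}$| $\mathrm{MSE}(y, \hat y^{NN} + \hat y^{PHY})$ |
| `regularisation`   | $\hat y^{NN}(X)$            | $\mathrm{MSE}(y, \hat y^{NN}) + \lambda\, \mathrm{MSE}(\hat y^{PHY}, \hat y^{NN})$ |
| `domain_adaptation`| $\hat y^{NN}(X)$            | two-phase (below) |
| `embedding`        | bias-net output             | $\mathrm{MSE}(y, \hat y^{NN}) + \lambda\, \mathrm{MSE}(y, \hat y^{PHY})$ |

The regularisation weight $\lambda \in [0, 1]$: the larger it is, the
more strongly predictions are tied to the PM. For the embedding it
defaults to 1 (a value treated as fixed rather than tuned, since the
embedding's flexibility is already constrained by the averaging described
next). Networks are plain MLPs (ReLU or tanh hidden layers, linear output
— a regression under a normality assumption), trained full-batch by Adam
unless a batch size is given. Features are z-scored with training-fold
statistics; day of year is encoded as a (sin, cos) pair by default
(`cyclic_doy` flag), a choice made to remove the artificial discontinuity
at year boundaries when the integer day is fed directly.

**Physics embedding.** A parameter network maps the covariates of a
contiguous daily series to per-day raw parameter outputs; these are
averaged over data points (and output nodes), *then* squashed through a
scaled sigmoid into the prior bounds, giving one parameter vector per
series — so the embedded PM receives a single calibration, like the
stand-alone PM, and the evaluation batch is the full series. Averaging
before squashing guarantees valid PM inputs and keeps the average
meaningful. The PM runs inside the forward pass; a bias-correction
network maps its standardised $(P, E, \theta)$ to the target. Gradients
reach the parameter network through the PM's analytic Jacobians — the
package's replacement for a tensor-library autodiff pass — and the
backward route is verified against finite differences in the tests.

**Domain adaptation.** Phase 1 pre-trains on purely artificial data: for
each of $n$ Latin-hypercube draws from the parameter priors, a covariate
surrogate simulates drivers and the PM simulates GPP; the pooled
simulations yield an emulator. Phase 2 fine-tunes on observations. The
surrogate fits harmonic (Fourier) regressions of each covariate on day of
year (3 annual harmonics) with bootstrap residuals — a smooth-seasonal
surrogate chosen over spline-based smoothers for its transparency; the
precipitation series is resampled from observed days to preserve
dry-day structure. Phase 1 never reads observed targets: the pretraining
table is assembled from surrogate output only, and the test suite proves
it by showing the emulator is bit-identical when the observed targets are
replaced by arbitrary values.

## Calibration

The stand-alone PM is calibrated either by MCMC or by gradient descent.

*MCMC*: adaptive random-walk Metropolis within uniform prior bounds, a
Gaussian likelihood with the model prediction as mean and standard
deviation fixed at 1 (configurable; estimating it is out of scope). The
proposal starts at $2.4^2/d$ times a tenth of each prior width and a
global scale adapts towards 23.4 % acceptance during burn-in (the first
half, discarded from summaries); proposals outside the bounds are
rejected, so a flat likelihood returns the uniform prior — a property the
tests check by Kolmogorov–Smirnov on thinned draws. The MAP estimate is
the highest-posterior draw after burn-in. A sampler with richer
adaptation (ensemble or differential-evolution samplers) would be a
drop-in replacement; the sampler is a vehicle here, not a contribution.

*Gradient descent*: Adam or plain descent on the mean squared error,
with gradients from the analytic sensitivities and parameters clipped to
bounds after each step. Both routes coexist because both are sensible
defaults in different regimes (sharp likelihoods vs. cheap exploration).
The predator-prey benchmark calibrates its PM by *plain* descent at the
printed learning rate of $10^{-5}$: trajectory sensitivities over 130
time units are large, so raw-gradient steps traverse the prior box in a
few thousand iterations, whereas Adam's normalised steps at that rate
could move each parameter by at most (steps × learning rate) and would
never leave the neighbourhood of the starting point. Networks always use
Adam.

Prior bounds for the predator-prey rates (`lv_bounds()`) are weakly
informative positive boxes rather than intervals centred on the
generating values. This matters for the mis-specified scenarios: the best
type I approximation to the sigmoidal-feeding truth lies at rate
combinations far from the generating parameters (high mortality, low
growth), and truth-centred priors would forbid exactly the compensation
that makes a structurally wrong model still useful.

## Protocols

* `sparsify_weekly()` keeps days 1, 8, 15, … — one data point per week,
  systematically selected.
* `make_cv_plan()` builds blocked cross-validation: whole validation
  years (temporal), whole sites (spatial), or whole sites of a restricted
  year set (spatio-temporal), with the test year/site excluded from every
  fold.
* `random_search()` draws architectures and optimisation parameters
  jointly and scores each candidate by mean validation MSE across folds.
* The PM used inside process-aware variants is calibrated per fold (an
  open choice; per-fold calibration was preferred so that no fold ever
  sees validation-block information through the PM).

## The synthetic multi-site testbed

Real eddy-covariance data cannot ship with the package, so
`gen_flux_dataset()` builds five synthetic forest sites (boreal evergreen
— the transfer target —, temperate deciduous, mountain evergreen,
mediterranean winter-wet deciduous, oceanic evergreen) with 4–7 years of
daily data each, all containing calendar years 2005 and 2008. Climate
generation: seasonal sinusoid + AR(1) temperature; radiation from a
clear-sky curve damped by an AR(1) cloudiness index deliberately only
weakly coupled to the wet-day process, so radiation carries day-to-day
information that no other covariate proxies; VPD grows exponentially with
temperature and dips on wet days; precipitation is a seasonal
occurrence/intensity process; faPPFD follows an evergreen or deciduous
phenology curve held constant within 8-day blocks (satellite-product
resolution converted to daily by constancy); CO₂ is constant per site.
The calendar has no leap days.

Observed GPP is generated by the same flux model *plus structural
perturbations the PM does not contain*: a radiation saturation
$\phi \mapsto \phi_{sat}(1 - e^{-\phi/\phi_{sat}})$ with
$\phi_{sat} = 25$ mol m⁻² day⁻¹ on all sites, and a site-varying exponent
$\gamma \in [0.7, 1.5]$ on the soil-water modifier. Heteroscedastic
Gaussian noise ($\mathrm{sd} = 0.3 + 0.15\sqrt{P}$) approximates the
magnitude-dependent scatter of flux measurements while staying close to
the Gaussian likelihood assumed in calibration. The saturation scale and
the cloudiness decoupling were fixed together at generator-design time so
that the planted process is genuinely recoverable from one site-year of
data — a calibrated PM absorbs much of the mid-range curvature through
the correlated VPD pathway, and with a weaker or fully confounded signal
the testbed could not discriminate inference methods at all. The
noise-free truth is recorded in `P_true` for oracle tests.

What passing on this testbed shows: that the architectures, losses,
protocols and inference machinery behave as designed when the true
data-generating process is a known structural perturbation of the PM.
What it cannot show: robustness to instrument drift, gap-filling
artefacts, non-Gaussian error, phenology shifts or any real-data pathology
— conclusions about real forests require real forcing data.

## Inference: ICE variable importance

`ice()` computes individual conditional expectations over four 2-week
windows (days 1–14 of March, June, September, December of the evaluation
year): one covariate is varied over 25 grid points spanning its observed
range extended by 10 % (clamped to physical limits), all other covariates
stay at observed values, and per-day prediction curves are averaged over
each window. Whether to average covariates first or curves after is
ambiguous in general; per-day curves averaged afterwards is the default
and both orders are exposed (`average_first`).

For the process model (and the PM inside parallel physics and bias
correction), ICE uses a *one-step* recomputation: the modified covariate
enters the day's modifiers and GPP with the water and acclimation states
held at their reference-run values. This isolates the same-day partial
effect — it is what makes the PM's radiation curve exactly linear (a
structural check in the tests) — and deliberately does not propagate
multi-day storage effects, so the PM's precipitation curve is flat by
construction. For the embedding, the full series with the modified window
is pushed through the forward pass (the series-averaged parameters shift
slightly; this is the honest forward semantics of that architecture).

`ice_departure()` ranks covariates by the RMS difference between a
model's and the PM's window-averaged curves, normalised by the standard
deviation of observed GPP — the planted-mismatch detector used in the
acceptance checks.

## Numerical and budget choices

Problem sizes used by the test suite and the acceptance script were
chosen as the smallest at which the qualitative claims are stable: the
predator-prey benchmark runs its printed configuration with budgets
scaled to 6 000 PM steps and 20 000 network epochs at the printed
learning rates, 5 seeds, leave-one-out folds; flux experiments use 1 200
MCMC iterations × 3 chains per fold, 800 network epochs, an 8-candidate
random search per network variant (scored on the validation folds only),
and 3 seeds for medians. The search is not an optional nicety: with
architectures fixed by hand the network variants either memorise the
sparse noisy training rows or extrapolate wildly at a transfer target,
and the comparison against the process model degenerates into a
comparison against a badly-sized network.

In the predator-prey benchmark the networks are trained on consecutive
observation *pairs* — the first observation has no predecessor and forms
no pair — and evaluated by autoregressive rollout from the known initial
density (each step conditioned on the model's own previous prediction),
which is how a one-step-ahead model produces a full trajectory. These two
choices carry the benchmark's scientific content: the networks never see
the unobserved initial transient, so the purely correlative model misses
it in rollout, while the process model reproduces it from structure alone
and the residual-learning PINN inherits it. An anchored evaluation mode
(conditioning every grid point on the nearest training observation) is
also available and behaves very differently — it turns the network into
an interpolator of the training set rather than a dynamical model, and
flatters it accordingly. The benchmark's PM calibration first screens a
dense Latin hypercube over the prior box (forward runs only) and then
descends from the best start at the printed learning rate: with nine
observations of a mostly-flat trajectory the loss surface has
observation-fitting local basins that are wrong on the full trajectory,
and pure local descent from an arbitrary start tends to stay in one.

Degenerate inputs: densities must be non-negative (noisy *observations*
may go negative and are accepted as features); non-finite states abort
integration with the failure time; empty series, mismatched lengths and
out-of-bounds λ raise immediately; constant series make rank correlations
`NA` rather than an error.

## Known limitations

* The flux mini-model is a structural stand-in; its parameter values are
  not transferable to any real ecosystem model.
* Sensitivities use the active branch at piecewise-linear kinks; an
  optimiser step landing exactly on a break point sees a subgradient.
* The observation-error standard deviation is fixed, not estimated.
* No uncertainty quantification beyond cross-validation spread; no
  recurrent architectures; single-output targets (GPP or prey density).
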