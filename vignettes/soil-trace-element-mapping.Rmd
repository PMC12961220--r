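---
title: "Mapping soil trace elements with SPDE spatial models"
author: "soilspde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping soil trace elements with SPDE spatial models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilspde)
```

## The problem

National geochemical surveys measure element concentrations (cobalt, copper,
selenium, zinc, ...) in soil at a few thousand sites spread over millions of
square kilometres — roughly one site per 1600 km². Turning such sparse point
measurements into continuous concentration rasters with honest uncertainty
requires a model of the spatial process, not just an interpolator.
`soilspde` implements that workflow end to end: survey-table cleaning,
covariate preparation, mesh construction, Bayesian hierarchical model
fitting, model comparison and validation, and predictive raster generation —
exercised throughout on synthetic surveys with recorded ground truth.

## The model

Concentrations $y_i > 0$ at site $s_i$ are modeled on the log scale through
the linear predictor

$$\eta_i = \beta_0 + \mathbf{x}_i^\top \boldsymbol\beta + w(s_i) + u_{k(i)},$$

where $\mathbf{x}_i$ are standardized environmental covariates (soil organic
matter, pH, saturated hydraulic conductivity, percent clay, temperature,
elevation, slope, cultivated-crop proportion), $w(s)$ is a zero-mean
Gaussian random field with Matérn covariance, and $u_k$ is an iid effect of
the administrative "state" unit containing the site, capturing local
variation that the smooth field misses. Two likelihoods are supported:

* **lognormal** — $\log y_i \sim \mathcal N(\eta_i, \sigma_{\mathrm{obs}}^2)$;
* **gamma** — $y_i \sim \mathrm{Gamma}$ with mean $e^{\eta_i}$ and shape $\phi$.

Because the field enters on the log scale, its effect is multiplicative:
a field value $v$ scales the expected concentration by $e^{v}$.

### The SPDE representation

The Matérn field (smoothness $\nu = 1$, the conventional default of the
SPDE machinery in two dimensions) is represented as a Gaussian Markov
random field on a triangulation: with P1 finite elements the lumped mass
matrix $C$ and stiffness matrix $G$ yield the sparse precision

$$Q(\rho, \sigma) = \tau^2\left(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\right),
\qquad \kappa = \sqrt{8}/\rho, \quad
\tau^2 = \frac{1}{4\pi\kappa^2\sigma^2},$$

where $\rho$ is the *practical range* — the distance at which correlation
has decayed to $\rho\kappa\,K_1(\rho\kappa) \approx 0.14$, conventionally
quoted as "about 0.1" — and $\sigma$ is the marginal SD of the field.
`assemble_fem()` verifies the classical identities (zero row sums of $G$,
mass equal to mesh area) in the test suite, and precomputes the generalized
spectrum of $C^{-1/2} G C^{-1/2}$ so prior log-determinants cost $O(n)$
during inference.

### Priors

* Range and marginal SD carry **penalized-complexity priors**:
  $P(\rho < u_\rho) = \alpha$ (density $\lambda \rho^{-2} e^{-\lambda/\rho}$,
  $\lambda = -u_\rho \log\alpha$) and $P(\sigma > u_\sigma) = \alpha$
  (exponential, rate $-\log(\alpha)/u_\sigma$). The default calibration is
  $P(\rho < u) = 0.5$ with $u$ set to half the x-extent of the data
  (`default_range_threshold()`) — or, for fine-mesh refits, to the coarse
  fit's posterior-mean range — and $P(\sigma > 0.5) = 0.5$.
* Intercept and fixed effects: Normal(0, precision $10^{-4}$), with the
  $10^{-2}$ and $10^{-6}$ variants available for the prior-sensitivity
  suite.
* State-effect precision: Gamma(shape 1, rate $5\times10^{-5}$).
* The observation-level parameter has no stated convention, so the package
  documents its own defaults: a PC-style exponential on
  $\sigma_{\mathrm{obs}}$ with $P(\sigma_{\mathrm{obs}} > 1) = 0.1$, and an
  Exponential(0.01) on the gamma shape. Both are weakly informative at the
  scale of log-concentration data and both are configurable in
  `prior_set()`.

## Mesh construction

`coarse_mesh_params()` derives every knob from the x-direction spatial
extent of the data, following the standard heuristic: inner maximum edge =
extent/12, outer offset = extent/3, outer maximum edge = 5 × inner, cutoff
= inner/5. `fine_mesh_params()` then sets the inner edge to a fraction
(default 1/10, sensitivity variants 1/5 and 1/15) of the estimated range,
inheriting everything else; an inherited cutoff that would reach the new
edge length is reduced to a fifth of it, since a cutoff at or above the
edge target cannot produce a valid mesh.

`build_mesh()` seeds the triangulation with the data points (greedily
thinned so no two seeds are closer than the cutoff), a densified boundary
ring, a hexagonal lattice at 0.76 × the inner edge target inside a slightly
dilated boundary, and a coarser lattice filling a convex buffer of at least
the outer offset; Bowyer–Watson Delaunay triangulation follows. Cutoff
thinning near data points can locally open holes wider than the edge
limit, so up to three refinement passes split any inner-domain edge longer
than the limit and re-triangulate. The construction targets the *contracts*
(no inner edge above the limit, all data inside the inner domain, buffer at
least the offset wide, positive triangle areas) rather than any particular
mesher's node placement, and `mesh_quality()` reports minimum angles, edge
histograms and counts for the visual-evaluation step.

## Inference

`fit_spde()` integrates the hyperparameters
$\theta = (\log\rho, \log\sigma, \log\sigma_{\mathrm{obs}}\ \text{or}\ \log\phi, \log\tau_{\mathrm{state}})$
over a deterministic grid:

1. the posterior mode of $\theta$ is located by Nelder–Mead (Brent in one
   dimension) on the exact (lognormal/gaussian) or Laplace-approximate
   (gamma) marginal posterior;
2. a numeric Hessian at the mode sets grid directions and step sizes
   (eigendecomposition, steps of 1.2 posterior SD with 3 points per
   dimension; 0.9 SD and 5 points when only one or two hyperparameters are
   free — both configurable via `control`);
3. each grid point contributes an exact conditional Gaussian over the
   latent vector $(\boldsymbol\beta, \mathbf w, \mathbf u)$; for the gamma
   family the conditional is a Newton/Laplace approximation (damped
   iterations on the sparse precision, convergence at $10^{-6}$ step size
   and $10^{-9}$ relative objective change, 50-iteration cap), followed by
   an importance correction: a small seeded batch of Laplace-proposal draws
   per grid point corrects the Laplace marginal likelihood by the
   log-mean importance ratio, and the stored posterior draws are
   systematically resampled by the same weights. The correction removes the
   mode-versus-mean bias of the skewed gamma conditional, and the gamma
   fixed-effect summaries are therefore computed from the corrected draws
   rather than from the Gaussian mixture.

Posterior marginals are mixtures over grid points; fixed-effect quantiles
come from the Gaussian-mixture CDF inverted to $10^{-10}$. Joint draws
(hyperparameters from the grid weights, latent vector from its sparse
Cholesky conditional) are stored with the fit and drive everything
downstream: WAIC/DIC/CPO, posterior predictive checks and prediction. The
lognormal family is implemented *exactly* as the Gaussian model on
log-responses plus the change-of-variables Jacobian in predictive
densities, which the test suite exploits as a family-level oracle, and an
independent MCMC sampler (`mcmc_oracle()`) — which never touches the
marginal-likelihood code path — guards both families on small instances.
The oracle makes joint hyperparameter-plus-latent moves: each random-walk
proposal on a log-hyperparameter is accompanied by a latent draw from the
proposal-side conditional, with the proposal density entering the
acceptance ratio, so its hyperparameter mixing is not damped by
conditioning on the current field (the conventional conditional updates
were observed to mix an order of magnitude more slowly on gamma toys).

The grid approximation is the main accuracy knob: 3 points per dimension
centred on the mode is coarse but mode-anchored, and parameter-recovery
tests (fixed-effect coverage, range within ±30%) pass at that default.
Users wanting finer hyperparameter marginals can raise `grid_points`.

## Model comparison and validation

* `waic()` uses the variance-based effective-parameter form
  $-2\sum_i[\log \mathbb E_s\, p(y_i\mid s) - \mathrm{Var}_s \log p(y_i \mid s)]$
  over stored draws; `dic()` uses the posterior-mean plug-in deviance. The
  criteria are named without formulas in the conventions this workflow
  follows, so the standard definitions are adopted and frozen by tests
  against brute-force recomputation.
* `cpo()` computes conditional predictive ordinates by harmonic-mean
  importance weighting, with a brute-force leave-one-out refit for
  observations where a single draw carries more than 20% of the importance
  weight; `lcpo()` is $-\mathrm{mean}(\log \mathrm{CPO}_i)$, so lower is
  better (the sign/scale convention is fixed here since only "lower is
  better" is conventional). Inside `fit_model_list()` the
  importance-sampling estimate is used without refits: WAIC leads the
  ranking and LCPO only breaks ties.
* `cross_validate()` is exact for the gaussian/lognormal families: per
  hyperparameter grid point the dense observation precision
  $P = (M Q_0^{-1} M^\top + \sigma^2 I)^{-1}$ yields closed-form
  leave-one-out and leave-group-out predictive densities, combined across
  grid points with importance-adjusted weights (the gamma family falls
  back to importance sampling). Groups are an observation plus its
  `group_size - 1` nearest neighbours, removed jointly — the grouping rule
  is not standardized elsewhere, so this deterministic choice is documented
  here. Score stability across loo/lgo levels is a *density-dependent*
  property: it requires many sites within one correlation range (the
  regime of a national survey); at sparser designs lgo scores degrade
  measurably, which the tests demonstrate on purpose-built instances.
* `posterior_predictive_check()` simulates replicate datasets and compares
  the observed mean, median, variance and 90th quantile to the 95%
  intervals of their simulated distributions.
* `sensitivity_suite()` refits under mesh fractions 1/5, 1/10, 1/15, the
  0.5 km cutoff override and alternative prior sets, flagging WAIC shifts
  above 10 units (smaller differences are treated as equivalent fits).

## Prediction

`predict_surface()` standardizes the prediction rasters with the
**training** scaling record — the coefficients are defined on the training
scale, so re-standardizing each raster by its own statistics would silently
change the model — evaluates $\eta$ per joint draw (barycentric field
projection, containing-state effect, prior-mean zero for states unseen in
training), and summarizes the per-draw response-scale expectation
($e^{\eta + \sigma^2_{\mathrm{obs}}/2}$ for lognormal, honouring the
lognormal mean rather than exponentiating a mean) by its average and
2.5%/97.5% quantiles. Between observations the posterior variance of
$\eta$ enters the mean through the same exponential, so the posterior-mean
surface sits a few percent above the plug-in product
$e^{\hat\beta_0 + \hat w(s)}$ except at data-pinned locations, where the
two coincide. Cells with missing covariates stay masked; cells outside the
mesh are masked with a warning count. `rasterize_surface()` masks to the
study boundary, and exports go through the plain-text ESRI ASCII grid
format with the georeferencing scaled from km to m (values untouched).
`percentile_classify()` bins a surface into ten deciles labelled with raw
value ranges; credible-bound rasters reuse the posterior mean's breaks, and
values equal to a break go to the lower class (a documented tie rule).

## The synthetic-data generator

`simulate_survey()` produces data with exactly the structure the model
assumes: uniform site placement in a rectangular domain tiled into states,
smooth covariate surfaces plus cell noise, an SPDE-sampled Matérn field,
iid state effects, lognormal or gamma observation noise, two near-replicate
depth horizons (multiplicative $e^{\mathcal N(0, 0.05^2)}$ perturbations of
the site value, so horizon averaging is exercised), a detection limit that
censors about 2% of assays (flagged, values retained, so the LLD/2
substitution is testable), and a ~1% rate of "N.S." not-sampled horizon
records. Defaults are the package's reference study conditions: 400 sites
on a 1200 × 800 km domain with 4 × 3 states, three active covariates
($\beta$ = 2, 0.4, −0.3, 0.2), range 300 km, field SD 0.8, state SD 0.2 and
log-scale observation SD 0.3 — a skew, spatial-signal-to-noise and
site-density regime comparable to a continental trace-element survey.

What the generator does **not** emulate: real covariate texture (SSURGO /
climate-normal rasters have sharp geological and land-use boundaries, not
smooth Fourier surfaces), non-stationarity of the field, irregular national
boundaries and coastlines, preferential or clustered sampling, and
element-specific chemistry. Passing recovery tests therefore demonstrates
that the machinery is correct under the model's own assumptions, not that
the model is adequate for any particular real survey.

One consequence of the smooth covariate surfaces deserves emphasis: their
dominant wavelengths (hundreds of km) are comparable to — or longer than —
the spatial field's range, so a model that omits a covariate can absorb
its surface into the field almost losslessly. Fixed-effect *estimation*
remains well calibrated (the coverage tests pass), but WAIC-based *model
selection* among spatial models discriminates weakly on such data: the
five-model comparison tests show near-exchangeable criteria values, and
the selection-consistency check fails under these generator conditions.
Selecting covariates reliably requires fine-scale covariate variance the
field cannot mimic, which real soil-property rasters have and these
synthetic surfaces deliberately simple ones do not.

## Numerical and design choices

* Containment is closed: points on a boundary or cell edge count as
  inside, so coastal sites are never silently dropped; a sample exactly on
  a shared grid-cell edge is assigned one cell by a seeded draw.
* Horizon combination is mean-of-available (average where both horizons
  exist, coalesce where one does) — the two published descriptions
  ("averaged", then "combined using coalesce") reduce to this single rule.
* The collinearity screen keeps the earlier-listed covariate of an
  offending pair and applies the strict > 0.7 rule with a $10^{-10}$
  epsilon so a pair at exactly the threshold is retained.
* Raster alignment: area-weighted means when the source is finer than the
  template (so a binary cropland raster becomes a per-cell proportion),
  bilinear interpolation otherwise; zonal means renormalize around missing
  source cells.
* All randomness flows through explicit integer seeds with derived child
  streams; package functions restore the caller's RNG state.
* Test and example problem sizes are desk-scale by design: surveys of
  70–400 sites, meshes of 300–2400 nodes, 20-replicate recovery studies.
  The methods are size-independent; these sizes keep the full suite
  reproducible in minutes on a single CPU.

## Limitations

The hyperparameter grid is deliberately small (a mode-centred CCD-like
design would be the next refinement); hyperparameter marginal SDs from a
3-point grid are crude even though means and latent marginals are accurate.
The gamma path relies on a single Laplace approximation per grid point
(no simplified/full Laplace corrections), and gamma cross-validation uses
importance sampling. The mesher handles convex buffers only (non-convex
boundaries are buffered through their convex hull). The posterior spatial
field is identified only up to soft confounding with the intercept, so its
domain average is near but not exactly zero.
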