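---
title: "Models and methods behind tunnelvis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tunnelvis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunnelvis)
```

## The assay and its measurements

`tunnelvis` analyses free-flight bioassays in which cohorts of ~50
mosquitoes are released into a low-speed wind tunnel (224 x 61 x 61 cm
working section, 40 cm/s laminar flow) and tracked in 3D at 60 Hz while
pairs of visual stimuli — a test stimulus (a narrowband LED channel between
390 and 743 nm, or an achromatic gray, or an unilluminated black tulle
target) and a mid-gray control — are projected onto the tunnel floor,
optionally together with a CO2 plume and an odor. The package's coordinate
convention puts the origin at the centre of the working-section floor, +x
downwind, +y cross-wind, +z up, all in cm; the two stimuli sit
symmetrically about y = 0. The tracker cannot hold individual identities
for long, so the unit of observation is the *trajectory*, and
non-independence of trajectories within a run is handled by the mixed
models below.

Three behavioral metrics are computed from trajectories of at least 90
frames (1.5 s):

* **activation** — the number of trajectories recorded during a stimulus
  period, a proxy for the propensity to fly;
* **recruitment** — the proportion of those trajectories that enter either
  *response volume*, a fictive vertical cylinder (diameter 14 cm, height
  4 cm, base on the floor) centred over each stimulus;
* **preference index** — per trajectory,
  `pi = (t_test - t_control) / (t_test + t_control)`, where `t_*` are
  dwell times inside the two volumes.

Dwell time is the count of in-volume samples divided by the frame rate; no
sub-frame interpolation is attempted, because 60 Hz is the native
resolution of the tracker. Volume membership is boundary-inclusive so the
metric is deterministic. Period windows are half-open, `[t_start, t_end)`,
and a trajectory spanning several periods contributes its in-period frames
to each. A trajectory that enters neither volume has an undefined index:
it propagates as `NA` and carries zero weight downstream, never as a fake
zero. Occupancy maps are 2D histograms of all sample positions (top or
side projection) normalised to percent residency; the default bin is
0.3 cm^2 in *area* (side ~0.55 cm) — the published description is
ambiguous between side and area, the choice only rescales the map, and it
is exposed as a parameter.

## Quality control

Runs are excluded wholesale on three independent criteria: responses to
the visual stimuli during the clean-air periods (odor contamination),
generally low responses (delivery or animal problems), and a strong
imbalance between the two halves of the stimulus series (the run missed
the activity peak). The criteria are qualitative in their published form;
`qc_thresholds()` commits to numbers — clean-air recruitment above 2%,
fewer than 5 recruited trajectories per run, a half-to-half recruited
ratio above 3 (computed as `(larger + 1)/(smaller + 1)` so empty halves
compare cleanly) — and the thresholds used are echoed in every report.
Loosening any threshold can only keep more runs, which the test suite
checks as a monotonicity property.

## The beta-binomial mixed model

Preference is analysed at the trajectory level as successes/trials counts:
successes are frames in the test volume, trials are frames in either
volume. Using the raw frame counts implements the published time-weighting
exactly — a trajectory that dwelt longer contributes more information —
without fractional trials. Counts are overdispersed relative to a binomial
(individual mosquitoes differ), so the model is a beta-binomial with mean
`mu` and precision `phi` (`alpha = mu * phi`, `beta = (1 - mu) * phi`; the
binomial is the `phi -> Inf` limit), with a logit link:

`logit(mu_ij) = x_ij' b + u_j,  u_j ~ N(0, sigma^2)`

For preference models the random intercept `u_j` is drawn per run x
stimulus-pair presentation; for activation and recruitment (period-level
counts) a single intercept per run is used. The marginal likelihood
integrates each cluster's intercept by *adaptive* Gauss–Hermite
quadrature: the conditional posterior mode and curvature are found by a
vectorised Newton ascent (tolerance 1e-10), the 20 default nodes are
centred and scaled there, and one node gives the Laplace approximation
when speed matters. `sigma` and `phi` are optimised on the log scale by a
quasi-Newton method (`nlminb`, relative tolerance 1e-10) with
finite-difference derivatives — analytic gradients through the adaptive
recentring are not tractable in a form worth maintaining. Standard errors
come from the numerical Hessian at the optimum. When a variance parameter
drifts to its boundary (e.g. no overdispersion, `phi` at its upper bound)
the optimizer may report "false convergence"; the fit is accepted if the
scaled gradient in the interior directions is negligible, and genuinely
non-converged fits are refused by all downstream summaries.

Effects of stimulus factors are tested by likelihood-ratio tests between
nested fits. Group means are formed on the link scale with
data-proportional weighting over non-grouping factors, with Wald intervals
back-transformed to the response scale (equivalent to the quantiles of a
Gaussian parametric bootstrap of the linear predictor, which is how the
tests check them); preference-scale results use `pi = 2p - 1`. Post hoc
contrast families are Sidak-adjusted (`1 - (1 - p)^m`, `m` = the contrasts
requested in one call); a priori contrasts bypass adjustment. Per-run
predictions — the individual points plotted beside group means — are the
empirical-Bayes modes of the cluster intercepts combined with the cell's
fixed effects.

The test suite verifies the implementation against independent routes: the
pinned-variance fit reproduces `glm(..., family = binomial)` coefficients
to 1e-4; the free fit agrees with an independent TMB-based beta-binomial
mixed model on the same records; EB modes match per-cluster 1D numerical
maximisation to 1e-6; and a 300-replicate null simulation holds the LRT's
5% size within binomial Monte-Carlo error.

## Intensity curves and relative potency

The relationship between preference and stimulus intensity is a
four-parameter log-logistic,

`f(x) = c + (d - c) / (1 + exp(b * (log x - log e)))`,

with lower/upper asymptotes `c`, `d` on the preference-index scale, the
inflection at relative intensity `e` (where `f(e) = (c + d)/2`), and
steepness `b`. Intensities are measured relative to the unilluminated
black tulle target, and are strictly positive because of ambient light
(the generator adds a 0.08 ambient offset for the same reason).

Estimation is two-stage, mirroring the published procedure: stage 1 fits
the beta-binomial mixed model with intensity as a factor and produces
run-level preference predictions; stage 2 fits the sigmoid to those
predictions by least squares in `(b, log e)` coordinates, starting from a
logit-linearisation of the scaled response plus a 5 x 5 multistart grid
around it (optimizer relative tolerance 1e-14 on the objective). The
asymptotes are estimated once, from the achromatic gray ramp, because it
spans the widest relative-intensity range — an explicit span guard (at
least 5-fold) refuses ramps that cannot pin both asymptotes — and `c`, `d`
are then frozen for every wavelength x odor curve. Flat data are flagged:
`c = d` as degenerate in stage 1, `|b| < 0.05` as `e`-unidentifiable in
stage 2. A `two_stage` option estimates per-run `(b, e)` and pools them by
inverse-variance weighting, a deliberate approximation to a full nonlinear
mixed fit (which of `b`, `e` were random in the published fits is not
stated; both-random is the default here).

Curves are compared by *relative potency*: a delta-method z-test on
`log(e1) - log(e2)` using the `(b, log e)` covariances of the two fits
(both sharing the frozen asymptotes). Identical fits give ratio 1 and
p = 1; the test suite checks the p-value against a parametric bootstrap of
the log-ratio and the scale-equivariance of `e` under rescaling of x.

## Photometry

Stimuli of different wavelengths are equated on photon flux rather than
radiant power, because photoreceptor catch counts photons. Photon flux is
the trapezoidal integral of `E(lambda) * lambda / (h c)` over the band of
a measured irradiance spectrum (W cm^-2 nm^-1 on an ascending nm grid),
and the isoquantal scale for a channel is `target / flux` — LED output via
PWM is assumed proportional to duty cycle, so a single multiplicative
scale suffices; non-linearity correction is out of scope. The default
target is 3.5e11 photons cm^-2 s^-1, the level used for all monochromatic
stimuli at relative intensity 1.0. The measurement geometry is assumed to
be cosine-corrected irradiance at the tunnel floor.

## The synthetic generator

No animal data ship with the package; `simulate_run()` generates runs with
the statistical structure the analysis assumes, so every pipeline stage is
testable and parameter recovery can be demonstrated. A run is a schedule —
a clean-air period, a main series (17-channel spectral sweep at isoquantal
intensity, or an intensity ramp over nominal 0–3), and a closing clean-air
period, 90 s per main period and 120 s per clean-air period — plus
trajectories laid down as fixed-speed (50 cm/s) correlated random walks
with wrapped-normal turning (SD 0.35 rad/frame) and reflecting walls.
Wind advection is deliberately omitted: tracking-level realism is not what
the downstream statistics consume.

The behavioral layer factorises the dwell-split probability on the logit
scale: `logit(p) = base(lambda) + odor_shift + run effect`, with
`base(lambda)` an inverted Gaussian centred near 525 nm (ceiling 0.85,
depth 1.25, width 60 nm) — preference is lowest in the green band and
rises toward the spectrum's ends — and achromatic or ramp stimuli
following the four-parameter log-logistic (defaults b = 2, c = -0.6,
d = 0.5, e = 0.8). Floral and oviposition odors add a hard green-band
(475–575 nm) boost of 0.8 and 0.6 logits; host odor adds a uniform 0.4.
Activation is Poisson (10 trajectories per period in clean air, x2.5 with
CO2); each trajectory is recruited with a logistic probability whose
baseline (0.004) and CO2 gain (+2.6 logits) reproduce the qualitative
study conditions: well under 1% recruitment without CO2 and a
7–17-fold CO2 increase. Recruited trajectories draw a total dwell (>= 30
frames, ~1.5 s mean) split beta-binomially (precision phi = 8) between the
volumes; run random intercepts (SD 0.5 for preference per stimulus pair,
0.4 for recruitment per run) and a 15% fraction of sub-90-frame track
fragments complete the structure. All of these defaults are the package's
committed study conditions; none is derived from published parameter
values beyond the qualitative statements above.

Two constructional choices matter for testability. First, recruited
trajectories enter and leave the response volumes through vertical
descents and ascents with transit between volumes at an altitude above the
cylinder tops, so the number of in-volume samples equals the drawn dwell
counts *exactly* — the metrics layer can be tested to recover the
generator's books frame-for-frame. On wall reflections and entry/exit
manoeuvres the chord between consecutive samples is shorter than the free
flight step, never longer. Second, within a simulated run, trajectories
not engaged with a target cruise above the response cylinders. Without
this, chance floor-level passes of long wandering tracks contributed ~20%
of preference records and a spurious ~4% "recruitment" without CO2,
contradicting the intended near-zero baseline; approach to the volumes is
what the recruitment process models. The free-wander primitive
(`simulate_trajectory(mode = "wander")`) retains the full section height,
so chance-passage physics remains available and is itself tested against
the geometric volume fraction.

What passing recovery tests on these simulations does **not** show: real
trajectories have wind-structured kinematics (casting, surging), identity
fragmentation correlated with position, tracker noise, and preference
surfaces that need not factorise additively on the logit scale. The
simulations validate the *estimators* under the model's assumptions, not
the biology.

## Problem sizes and numerical choices

The shipped tests use desk-scale designs chosen to make the statistical
checks sharp at interactive runtimes: parameter recovery on 200 simulated
clusters; LRT size on 300 null replicates of a 2 x 30-cluster design with
8 quadrature nodes; end-to-end odor-shift recovery on 12 + 12-run cohorts
and null calibration on 20 replicate 6 + 6-run cohorts. Determinism is
part of the contract: a run is a pure function of (configuration, seed),
cohort seeds are derived arithmetically from the cohort seed, and
re-running any analysis with the same inputs reproduces tables
bit-for-bit.

Known limitations: the fixed-effect language covers the factorial designs
this pipeline needs, not arbitrary formulas; no Bayesian posterior
sampling; the two-stage dose-response is an approximation to a full
nonlinear mixed fit; stimulus-order/period covariates are not included in
the preference models by default (the published analysis alternated
stimulus order between runs instead).
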