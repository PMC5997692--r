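---
title: "Models and methods behind channelflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind channelflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelflux)
```

channelflux infers water-transport and selectivity properties of artificial
water channels from four kinds of evidence: vesicle swelling kinetics,
fluorescence counting, molecular trajectories, and filtration records. This
vignette states each model, its assumptions, the tunable parameters with
their defaults and units, and the numerical choices made where the design
was genuinely open. Nothing here asserts an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Units and constants

All internal computation is SI; unit tags apply only at the boundary.
Membrane permeability is a velocity under an osmotic gradient (μm s⁻¹),
interconvertible with the pressure-normalised flux used for industrial
membranes through the van 't Hoff factor:

$$L_p = P_f \frac{V_w}{R T},$$

re-expressed in L m⁻² h⁻¹ bar⁻¹ (LMH/bar). The default temperature is
**283.15 K** — the stopped-flow assay temperature — which makes
1 μm s⁻¹ ≡ 2.75×10⁻³ LMH/bar; at 298 K the factor would be 2.61×10⁻³, so
temperature is always an explicit argument. Single-channel permeability is
a volumetric rate (cm³ s⁻¹) or a molecular rate; the two differ by the
molecular volume of water $v_w = V_w/N_A = 2.99\times10^{-23}$ cm³, so
3×10⁻¹⁴ cm³ s⁻¹ ≡ 10⁹ molecules s⁻¹. Membrane-scale and single-channel
units form two deliberately disconnected conversion families: crossing
them requires vesicle geometry and a channel count, which is the job of
`single_channel_permeability()`, not of a unit tag.

## Stopped-flow swelling kinetics

Vesicles exposed to a hypotonic gradient swell, and at 90° scattering the
intensity decays approximately exponentially. The model is
$I(t) = b + A e^{-kt}$ with

$$k = P_f \frac{3}{r} V_w \,\Delta C,$$

$3/r$ the sphere surface-to-volume ratio and $\Delta C$ the gradient in
mol m⁻³ (numerically mOsm). Design choices:

* **Single exponential by default.** A two-exponential option exists for
  traces with fast mixing artifacts and reports the largest-amplitude
  rate. Standard stopped-flow practice; the fit model is otherwise
  unconstrained by the assay description.
* **Deterministic initializer, no random restarts**: baseline from the
  mean of the final 5% of points, then a log-linear regression on the
  baseline-subtracted first half of the decay.
* **The radius is the user-supplied hydrodynamic (DLS) radius**; no
  shrink/swell geometry correction during the transient, matching the
  initial-size convention for reported permeabilities.
* Traces that are constant or trend upward are refused rather than fitted.

Uncertainty is first-order (delta-method) propagation of the fit's rate
standard error; when triplicate traces are supplied the replicate mean is
reported with the propagated standard error of that mean, and quoted
intervals use the expanded-uncertainty factor k = 2.

## FCS counting

The autocorrelation of fluorescence from a 3D Gaussian focal volume with
two freely diffusing species is

$$G(\tau) = \frac{1}{N}\sum_{i=1}^{2} f_i
  \left(1+\frac{\tau}{\tau_i}\right)^{-1}
  \left(1+\frac{\tau}{S^2\tau_i}\right)^{-1/2},$$

with $N G(0) = 1$. Before solubilization the slow species is the vesicle;
after, the labeled channel micelle; channels per vesicle is the
slow-species ratio $N_\mathrm{mic}/N_\mathrm{ves}$, which is invariant to
the (shared) focal-volume calibration. Choices:

* **Structure parameter S fixed (default 5).** Floating S alongside two
  species is ill-conditioned; it is user-overridable, never fitted.
* **Triplet/photophysics terms omitted**; lags below 10 μs are excluded by
  default instead.
* **Weights 1/G²**, consistent with multiplicative detector noise.
* **Free-dye correction is an explicit user-supplied fraction** applied to
  the micelle count; automatic species reassignment would silently move
  counts between populations.

## FRAP

Recovery is modelled as two mobile exponential components,
$F(t) = f_1(1-e^{-t/\tau_1}) + f_2(1-e^{-t/\tau_2})$, immobile fraction
$1-f_1-f_2$, and $D_i = w^2/(4\tau_i)$ for spot radius $w$. This is the
two-regime approximation (one diffusion coefficient per regime) rather
than the exact Bessel-function spot solution. A single-exponential model
is fitted alongside; if the second component fails to reduce the RMSE by
more than 2%, or the two recovery times agree within 10%, the
single-component result is returned flagged — a two-way split of one
kinetic component is otherwise arbitrary.

## Trajectory observables

Coordinates are nm, time ns, z the membrane normal. Wrapped coordinates
are never guessed at: analyses refuse input whose per-frame jumps exceed
half the box and direct the user to `unwrap_trajectory()` (per-axis
minimum-image accumulation).

* **MSD** uses blocked (fragmented) time-origin averaging, default
  fragment 20 ns, and the Einstein relation $D = \mathrm{slope}/(2d)$
  over a default fit window of 10–50% of the fragment — below the
  statistics-poor tail, above short-lag regimes. Fits with $r^2 < 0.9$
  are flagged unreliable.
* **RMSD** superposes each frame on the reference by centroid translation
  plus the Kabsch rotation before computing deviations, so rigid-body
  motion is invisible and only conformational change remains.
* **Tilt** takes the channel axis as the normal of the best-fit plane of
  the ring atoms (smallest principal component), robust to ring
  puckering, and folds angles into [0°, 90°] since the observable is
  head–tail symmetric: 0° is transmembrane-upright, 90° lies in-plane.
* **Collective diffusion.** For single-file transport the dimensionless
  coordinate accumulates $dn = \sum_i \Delta z_i / L$ over waters in the
  channel slab; $\langle n^2(t)\rangle = 2 D_n t$ and $p_f = v_w D_n$.
  Membership uses the **both-frames rule**: a water contributes to a frame
  pair only if it is inside the slab in both frames. The rule is
  deterministic and its omitted entry/exit contributions are bounded by
  one per-frame step, which vanishes at fine sampling. Displacements are
  taken minimum-image with period L; if more than 1% of in-slab steps
  exceed L/4, the sampling is too coarse to disambiguate wrap events and
  the analysis refuses to proceed. The Einstein fit for $D_n$ uses the
  first 20 lags, where time-origin statistics are densest.

For N independent waters of axial diffusivity D in a channel of length L,
$D_n = N D / L^2$ exactly — the analytic oracle used throughout the tests.

## Steered pulling and the PMF

Replicate constant-velocity force traces are linearly resampled onto a
common 0.1 Å grid restricted to the intersection of their ranges,
averaged pointwise, and the mean force is integrated by cumulative
trapezoid with $G(z_\mathrm{start}) = 0$ — average-then-integrate, the
estimator matching the experimental protocol, not Jarzynski exponential
averaging. This estimator carries a friction-work bias of $\gamma v$ per
unit distance that inflates barriers at fast pulling; the synthetic
generator's defaults (friction 0.05 kcal mol⁻¹ ns Å⁻², pulling at the
protocol speed of 10 Å ns⁻¹ with a 1000 kcal mol⁻¹ Å⁻² spring over a
±6 Å window around a 2 Å-wide Gaussian barrier) put that bias near 6% at
the barrier, within the 15% recovery tolerance the tests assert. The
generator integrates overdamped Langevin dynamics (Euler–Maruyama,
dt = 5×10⁻⁶ ns, refused when $k_s\,dt/\gamma > 0.1$) because the
estimator under test is the averaging-and-integration chain, not inertial
dynamics; recorded forces are block means along the restraint coordinate.
Barriers below the pass threshold (default 100 kcal/mol) classify a
solute permeant, above the block threshold (default 1500 kcal/mol)
excluded, between them indeterminate.

## Filtration membranes

Hydraulic permeability is the zero-intercept slope of flux against
pressure (test pressures 50/60/70 psi convert at 0.0689476 bar/psi).
Observed rejections $R_o = 1 - C_p/C_f$ are corrected for concentration
polarization with the stagnant-film model

$$R_t = \left[1 + \frac{1-R_o}{R_o}\, e^{-J_v/k}\right]^{-1},$$

which exactly inverts the generator's forward model. The mass-transfer
coefficient is a required input per record; a Sherwood-correlation helper
for stirred cells exists but is never applied implicitly. The rejection
curve is fitted as a logistic $R(M) = R_\mathrm{max}/(1+e^{-(M-\mu)/s})$
with $R_\mathrm{max}$ free but bounded at 1 (small solutes plateau below
full rejection); the **MWCO is the 90%-rejection crossing** (industry
convention, exposed as a parameter), $\sigma = \pi s/\sqrt 3$ from the
logistic density's closed form, and sharpness is $\sigma/\mathrm{MWCO}$.
The derivative of the fitted curve, normalised on a grid spanning
$\mu \pm 12 s$, is the pore-size probability density; a narrower grid
truncates the logistic's exponential tails enough to bias the numerical
standard deviation by several percent, so grids not covering
$\mu \pm 5s$ are refused.

## Synthetic data: what it does and does not show

Every generator is a pure function of its arguments including the seed,
and writes its truth parameters into the output. The noise models are the
simplest ones consistent with each instrument: additive Gaussian
proportional to the decay amplitude for scattering traces, multiplicative
Gaussian for FCS, additive truncated Gaussian for rejections, thermal
Langevin noise for pulling. Defaults are the study conditions:
100 nm vesicle radius, 100 mOsm gradients, 2% trace noise, 1% FCS and
rejection noise, a 4 nm channel slab, a 450 Da cutoff with
$\sigma/\mathrm{MWCO} = 0.29$, and a representative 300–1100 Da solute
grid (25 Da spacing, chosen once for a well-conditioned three-parameter
logistic fit).

Passing recovery tests on these systems demonstrates that the estimators
are unbiased and correctly propagated **under the stated forward models**.
It does not demonstrate robustness to what real instruments add —
mixing-dead-time artifacts, detector afterpulsing and triplet blinking,
vesicle polydispersity, membrane fouling, or correlated MD force-field
errors. Quantities whose published values depend on the original
instrument records or the 200 ns all-atom trajectories (measured vesicle
permeabilities, FRAP constants, per-dye rejections, simulated channel
permeabilities) are therefore validated here by parameter recovery and
analytic oracles at desk-scale problem sizes (e.g. 40 waters × 20 000
frames for the collective-diffusion recovery, 10 pulling replicates,
20-seed rejection studies), not by numeric reproduction.

## Known limitations

* Ideal van 't Hoff osmotic pressure; no activity corrections.
* No solute (glycerol/urea) permeability or hypertonic-shrinkage
  geometry.
* FCS: no photon-stream correlation, cross-correlation, or anomalous
  diffusion.
* Trajectories: XYZ + YAML sidecar is the contract; binary MD formats
  should be converted upstream.
* PMF: no umbrella sampling/WHAM, no Jarzynski/Crooks estimators.
* Filtration: no Donnan/charge-exclusion modelling; the logistic form is
  descriptive, not a pore-level transport model.
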