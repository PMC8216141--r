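---
title: "Methods: cyclic tensile characterization of single trabeculae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cyclic tensile characterization of single trabeculae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabmech)
```

## The material model

Single trabecular struts loaded in tension are neither linearly elastic nor
rate-independent. `trabmech` models one trabecula as the parallel coupling
of two rheological layers:

* a **Prandtl layer** — a spring of modulus $E_{pr}$ in series with a
  plastic slider. The slider's yield stress hardens with accumulated
  plastic strain $\kappa$ following a Voce saturation law
  $$\sigma_Y(\kappa) = \sigma_u - (\sigma_u - \sigma_y)\,e^{-p\kappa},$$
  i.e. it starts at the initial yield stress $\sigma_y$, hardens
  exponentially with exponent $p$, and plateaus at the ultimate stress
  $\sigma_u$. The hardening reserve is $R = \sigma_u - \sigma_y$.
* a **Maxwell layer** — a spring $E_{mx}$ in series with a dashpot
  $\eta$, contributing stress relaxation with time constant
  $\tau = \eta / E_{mx}$.

$E_{pr}$ is the quasistatic (long-term) modulus $E_\infty$;
$E_{pr} + E_{mx}$ is the instantaneous modulus $E_0$; any apparent
stiffness at a finite strain rate lies between the two. In the pre-yield
linear regime the loss tangent at angular frequency $\omega$ is available
in closed form,
$$\tan\delta = \frac{E_{mx}\,\omega\tau/(1+\omega^2\tau^2)}
{E_{pr} + E_{mx}\,\omega^2\tau^2/(1+\omega^2\tau^2)},$$
evaluated by convention at 1 Hz (approximate gait frequency).

### Numerical integration

The literature describing this model names the layers but not the update
equations, so the integrator is this package's own choice and is treated
as part of the model definition:

* Maxwell layer: backward Euler,
  $\sigma_{mx}^{n+1} = (\sigma_{mx}^{n} + E_{mx}\Delta\varepsilon) /
  (1 + E_{mx}\Delta t / \eta)$ — unconditionally stable, first order.
* Prandtl layer: elastic predictor / radial-return corrector. The
  plastic increment solves
  $|\sigma^{tr}| - E_{pr}\,\Delta\gamma = \sigma_Y(\kappa + \Delta\gamma)$,
  which has a unique root (left side strictly decreasing, right side
  non-decreasing); it is found by safeguarded Newton iteration. The
  internal variable is the *accumulated* plastic strain
  $\kappa \mathrel{+}= |\Delta\gamma|$, so yield is tension/compression
  symmetric. Whether the original model hardens on accumulated or signed
  plastic strain is not documented; only tensile histories are exercised
  here, where the two coincide until unloading-induced reverse yield,
  which the protocol never reaches.

Each sampling interval is divided into `substeps` (default 4)
integration sub-steps. Halving the step changes the stress of the default
protocol by well under 0.1 % (tested); an optional tolerance mode doubles
the sub-step count until two refinements agree, and errors at a cap rather
than returning an unconverged result. Internal units are MPa, seconds and
dimensionless strain; GPa and GPa·s are converted at the interface because
published parameter tables mix both.

## The loading protocol

The displacement-controlled cyclic protocol ramps at 0.01 mm/s to a peak
that grows by 0.025 mm per cycle, holds, unloads to the previous cycle's
peak (to zero in cycle 1), and holds again. The first two holds last 60 s
to allow complete relaxation; all later holds last 10 s. The signal is
sampled at 10 Hz, mirroring the optical strain camera. Two details are not
printed anywhere and are package choices: the first peak equals one
increment (0.025 mm, configurable), and the final cycle completes its
unload/hold like any other.

## Curve analytics

Records are segmented into loading / hold / unloading / hold phases by
classifying the displacement rate against a tolerance (half the nominal
ramp rate), with a widened central difference so per-sample noise does not
flip the classification; runs shorter than `min_run` samples are absorbed
into their predecessor. Each loading phase is fitted with
$f(x) = a(1 - e^{x/b}) + c$ and each unloading phase with
$f(x) = (a/b)(e^{bx} - 1)$ in phase-local coordinates; the tensile modulus
of a cycle is the analytic derivative of the fit, evaluated by default at
the first sample of the phase (the initial part of the cycle). Fits use
multi-start Nelder-Mead least squares; non-convergence marks the value
missing rather than failing a whole record.

The **envelope** is the strict running maximum over loading-phase strain —
hold-phase relaxation never enters it. On the envelope, apparent stiffness
$\hat E$ is the slope of the linear regression (with intercept, not forced
through the origin) over the initial segment whose end point maximizes
$R^2$; that end point is the apparent yield strain $\hat\varepsilon_y$.
Ties in $R^2$ resolve to the largest end index, so exactly linear data
yields the full linear region. The minimum regression window is 10 samples
(an $R^2$ scan on smaller windows is degenerate); both choices are
configurable because the source procedure does not state them. Elastic
work $\hat W_{el}$ and postyield work $\hat W_{py}$ are trapezoidal areas
under the envelope polyline before and after yield, in MJ/m³.

Two quantitative caveats, both visible in the tests: at the printed
protocol rate with typical viscosity ($\tau \approx 2$ s) the cycle-1
loading tangent sits near $E_0$, not $E_\infty$ — the quasistatic reading
requires rate·$\tau$ to be small; and the envelope of a cyclic record
tracks an uninterrupted ramp only *on average* (within 5 % here), because
the Maxwell stress has relaxed right after each hold and rebuilds over
$\sim\tau$.

## Inverse identification

`identify()` minimizes the stress RMSE between simulation and measurement
with the downhill simplex (Nelder-Mead, the only optimizer used by
design), over the log-transformed vector
$(E_{pr}, E_{mx}, \sigma_y, R, p, \eta)$ — the $R \ge 0$ parametrization
encodes $\sigma_u \ge \sigma_y$ for free, and log-space encodes
positivity. Soft box bounds ($E$ in [0.1, 30] GPa, stresses in
[1, 500] MPa, $p$ in [1, 500], $\eta$ in [10⁻³, 100] GPa·s) act through a
multiplicative quadratic penalty. The lower $\eta$ bound is deliberately
far below physiological values: with $\eta$ capped at ~0.05 GPa·s, an
effectively inviscid (purely elasto-plastic) specimen would be forced into
a lossy regime with $\tan\delta \approx 0.06$ at 1 Hz; the wide bound lets
the fit express "no viscosity" honestly.

Starts are data-driven and deterministic (no RNG): $E_{pr}$ from the
cycle-1 loading tangent, $\sigma_y$ from the envelope yield point,
$\sigma_u$ from 1.1× the peak envelope stress, $\eta$ from the 1/e decay
time of the first hold, $p = 50$; plus fixed multiplicative restarts and a
low-viscosity corner start that serves records whose holds show no
relaxation. Convergence tolerance is 10⁻⁶ relative with at most 5000
evaluations per start. The RMSE spans the full record (loading, holds,
unloading) up to failure; the source procedure does not say whether holds
were included, and including them is what makes $\eta$ identifiable.

On noiseless self-generated 7-cycle records the fit recovers $E_{pr}$ and
$\sigma_u$ to a few percent and $\eta$ to ~10 %; $p$ and $\sigma_y$ trade
off against each other along the hardening curve and are individually
softer (~20 % for $p$), which matches the much larger reported
between-specimen scatter of the hardening exponent.

### Quality control

`qc_filter()` applies three sequential rules: (1) drop records whose RMSE
is an IQR outlier of the pooled RMSE distribution; (2) drop records with
fewer than `min_cycles` complete cycles (default 3; a stricter 4-cycle
regime is one argument away — the source description is ambiguous between
the two); (3) flag per-variable IQR outliers and blank the value, not the
record. Quartiles are type-7 (linear interpolation) with 1.5×IQR fences,
both configurable; flags are documented as convention-dependent.

## TMD analytics

Volumes are calibrated density grids (mg HA/cm³). Segmentation smooths
with an isotropic Gaussian ($\sigma$ = 1 voxel, zero-padded — background
is fluid at zero density) and thresholds at a single level, default
490 mg HA/cm³. Histograms are normalized by the count of nonzero masked
voxels. Intensity profiles run along the two orthogonal in-plane axes
through the cross-section's mass centroid, each normalized by the mask
chord through the centroid, then averaged; the source procedure says
"axes" without stating their number or orientation, and the two-axis
average is this package's convention (verified invariant under 90°
rotations). Zone statistics report mean ± SD for the whole strut, the
fracture zone and the non-fracture remainder, plus paired differences for
signed-rank testing. No partial-volume correction is applied to the
surface shell; the lower surface TMD is reported as-is. Mean
cross-sectional area is masked volume divided by axial length.

## The synthetic cohort

The generator emulates the study design: 20 donors (10 control, 10
fracture) × 10 trabeculae. All positive quantities are log-normal with
moments matched to the reported group mean ± SD (material parameters,
failure strain, morphometry, geometry); age, BMI and T-score are normal;
sex and orientation are balanced alternating assignments. Total variance
splits 60 % between donors / 40 % within donors on the log scale —
the direction (interdonor dominance) is the study's own finding; the exact
split is unreported and 60/40 is the package's single fixed choice. A
shared latent factor couples the within-donor deviations of TMD and
$E_{pr}$ at rank correlation ≈ 0.3, matching the reported pooled
TMD-stiffness correlation.

Curves add Gaussian noise of constant *absolute* SD to strain (default
10⁻⁴) and stress (default 0.5 MPa), so relative noise is larger at small
strains, as in optical strain tracking; records truncate at the first
sample whose noiseless strain exceeds the specimen's failure strain. TMD
volumes are digital cylinders with the record's mean area, a linear
surface-deficit ramp over the outer three voxels, an axial fracture band
with an additional deficit (default 7 mg/cm³, the reported whole-minus-
fracture-zone gap), and i.i.d. voxel noise.

What a green test does *not* establish: the generator has no imaging
physics (beam hardening, partial volume beyond the surface ramp), no
real DIC error structure, no within-record parameter drift, and cylinders
instead of real strut geometry. Green means the algorithms recover what
the stated world contains — not that they would behave identically on
scanner data.

## Statistics

Two-sided nonparametric tests throughout: Mann-Whitney U (exact by
enumeration for combined n ≤ 12 without ties, otherwise normal
approximation with tie and continuity correction), Kruskal-Wallis
(tie-corrected H, χ² p), Wilcoxon signed-rank (zeros dropped, exact for
n ≤ 15), Spearman correlation (t approximation), Bonferroni correction,
and a two-sample power formula
$n = (Z_{\alpha/2} + Z_{1-\beta})^2\,2\sigma^2/(\mu_1-\mu_2)^2$ with
dropout inflation $N = \lceil 2n/(1-d)\rceil$. The "general linear model"
is deliberately a single-covariate ANCOVA (group + age, partial F for the
group term); inter- vs intradonor variability runs both one-way ANOVA and
Kruskal-Wallis on the donor grouping, a belt-and-braces pairing used
because the data deviate from normality but not grossly. Degenerate
designs (zero within-donor variance) report a capped/flagged F rather
than NaN.

## Known limitations

* The constitutive law is scalar and uniaxial; no 3D embedding, no
  temperature or hydration dependence.
* $\sigma_y$ and $p$ are jointly soft in the inverse problem; compare
  them across cohorts, not per specimen.
* The backward-Euler Maxwell update is first order; sinusoidal
  steady-state tests need sub-stepping at $\Delta t \gtrsim \tau/20$, and
  the simulator exposes that control.
* NRRD support is intentionally minimal (3D, raw little-endian or ascii).
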