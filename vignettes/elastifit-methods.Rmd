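---
title: "Methods: hyperelastic characterization of soft-tissue tension tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperelastic characterization of soft-tissue tension tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastifit)
```

## The measurement problem

elastifit analyses uniaxial tension tests on squat soft-tissue cylinders
(here: infant cerebellum cores, 9 mm diameter x 5 mm height) glued between
two platens and pulled at a constant grip velocity to 30% grip strain. The
machine records time (s), grip displacement (mm) and force (N). Three
nominal strain rates are studied — 2, 20 and 100 s⁻¹, i.e. grip velocities
of 10, 100 and 500 mm/s over the 5 mm height — with at least six replicate
specimens per rate. The tissue is modelled as isotropic, incompressible
and hyperelastic; rate dependence enters only through fitting each rate
separately, not through an explicit viscoelastic law.

## Kinematics

With grip strain $e = \Delta h / H$, a glued squat cylinder does not
deform homogeneously: the lateral faces are constrained at the platens and
the mid-plane stretches more than the grip separation suggests. The
effective axial stretch is taken as the linear correction

$$\lambda = 1 + K\,e, \qquad K = 1.583,$$

valid for grip elongation ratios $h/H \in [1.0, 1.3]$. The package
enforces this window as a *warning*, not an error, so that the endpoint
$h/H = 1.3$ (grip strain 0.3, hence $\lambda = 1.4749$) is always legal.
"30% strain" throughout means grip strain $e = 0.3$; the corrected end
stretch is therefore 1.4749, not 1.3. This reading makes the published
exponential stress laws numerically consistent with the published end
stresses (at $\lambda = 1.4749$ the slow-rate law gives ~359 Pa against a
~394 Pa measured mean, whereas at $\lambda = 1.3$ it would give only ~194
Pa).

Stress uses the Lagrange (nominal) convention $S_{11} = F/A$ with $A$ the
*undeformed* cross-section ($\pi d^2/4$); no area update or machine
compliance correction is applied. Incompressibility gives principal
stretches $(\lambda, \lambda^{-1/2}, \lambda^{-1/2})$ and invariants
$I_1 = \lambda^2 + 2/\lambda$, $I_2 = \lambda^{-2} + 2\lambda$, $I_3 = 1$.

Units are SI internally (m, s, N, Pa); millimetres are accepted at the I/O
boundary and converted exactly once, inside `record_to_curve()`.

Records showing a sustained run of negative stress (five or more
consecutive points below −10 Pa, both configurable) are rejected as
adhesion failures: the glue bond let go, so the tail of the record does
not measure tissue. The thresholds are package choices; the underlying
exclusion rule is qualitative.

## Constitutive families

Four families are available; $\mu$ is the infinitesimal shear modulus and
for all three energy-based families the small-strain uniaxial slope is
$dS_{11}/d\lambda|_{\lambda=1} = 3\mu$ (incompressible Young's modulus):

* **Fung** $W = \frac{\mu}{2b}\left(e^{b(I_1-3)} - 1\right)$,
  $S_{11} = \mu e^{b(I_1-3)}(\lambda - \lambda^{-2})$ — strain-stiffening,
  parameters $\mu > 0$ (Pa), $b > 0$.
* **Gent** $W = -\frac{\mu}{2} J_m \ln\!\left(1 - \frac{I_1-3}{J_m}\right)$,
  $S_{11} = \frac{\mu J_m}{J_m - (I_1-3)}(\lambda - \lambda^{-2})$ —
  limiting chain extensibility with locking parameter $J_m > 0$. The
  locking singularity is guarded: evaluation errors once
  $I_1 - 3 \ge 0.999\,J_m$, well before overflow.
* **Ogden (one term)**
  $W = \frac{2\mu}{\alpha^2}\left(\lambda_1^\alpha + \lambda_2^\alpha +
  \lambda_3^\alpha - 3\right)$,
  $S_{11} = \frac{2\mu}{\alpha}\left(\lambda^{\alpha-1} -
  \lambda^{-\alpha/2-1}\right)$, any $\alpha \ne 0$. The energy prefactor
  is $2\mu/\alpha^2$ so that $dW/d\lambda$ reproduces the stress form
  exactly. $\alpha$ is deliberately unrestricted in sign: matching the
  published slow-rate end stress with the published slow-rate $\mu$
  *requires* $\alpha < 0$ (strain softening), and one-term Ogden is
  standard with either sign. $\alpha = 2$ recovers neo-Hookean
  behaviour, as do Fung with $b \to 0^+$ and Gent with $J_m \to \infty$ —
  a cross-family reduction the test suite asserts.
* **Exponential** $S_{11} = -A\,e^{-\lambda/B} + C$ — defined at stress
  level only, with no strain-energy function ($A \ge 0$ Pa, $B > 0$,
  $C$ Pa). Its value at $\lambda = 1$ is generally nonzero and is kept as
  defined, not shifted; `strain_energy()` and `small_strain_modulus()`
  refuse this family.

The closed-form stresses are verified internally against a central finite
difference of the strain energy (`stress_from_energy()`, default
half-step 1e-6); agreement to 1e-6 relative away from $\lambda = 1$ is a
standing property test.

## Fitting

`fit_model()` minimizes the *unweighted* sum of squared stress residuals
(no weighting is defensible without a stated error model) with bounded
Levenberg–Marquardt, restarted from a deterministic grid:
$\mu \in \{10^2, 10^3, 10^4\}$ Pa crossed with $b \in \{0.1, 1, 5\}$,
$J_m \in \{0.2, 1, 10\}$ (clipped to the locking-feasibility bound
$J_m > (I_{1,\max}-3)/0.999$), $\alpha \in \{-4, -1, 2, 6, 12\}$. The
exponential family instead seeds itself from a log-linear heuristic: for
trial offsets $C_0$ above the data, $\log(C_0 - S)$ is regressed on
$\lambda$, giving $B = -1/\text{slope}$ and $A = e^{\text{intercept}}$.
Default bounds are generous physical ranges
($\mu \le 10^6$ Pa, $b \le 50$, $J_m \le 10^4$, $|\alpha| \le 20$,
$A \le 10^7$ Pa, $B \le 10$, $C$ free); convergence tolerance is 1e-10 on
the relative objective reduction, and `converged` is reported from the
optimizer's own ftol/xtol/gradient criteria. Goodness of fit is the plain
coefficient of determination about the observed mean; no weighting, no
adjustment.

Degenerate inputs (fewer than 4 points, all-nonpositive or constant
stress) raise typed errors rather than returning nonsense;
`fit_all_models()` converts per-family errors into failed rows so one
family's failure never hides another's fit. Ranking is by descending R²,
ties broken by fewer parameters then family name.

Both fitting modes of the study design are supported: per-replicate fits
(whose across-replicate mean ± SD corresponds to reported modulus
tables) and a fit of the across-replicate average curve; `run_pipeline()`
computes both, since published tables of this kind rarely state which was
used.

## Summary statistics

All summaries interpolate linearly in grip strain, through one shared
routine (`curve_stress_at()`), and use the $n-1$ sample SD:

* **End stress** — per-curve stress interpolated at exactly $e = 0.3$;
  curves stopping more than 1e-3 short are incomplete tests and error.
* **Coefficient of variation** — across-replicate SD/mean on a default
  grid of 26 strains in $[0.05, 0.30]$. Below 0.05 the mean stress is
  near zero and the ratio diverges, which is why the grid starts at 0.05;
  grid points with non-positive mean are dropped with a warning.
* **Secant moduli** — chord slopes $(S(b)-S(a))/(b-a)$ over the strain
  decades (0–0.1, 0.1–0.2, 0.2–0.3) on the *grip-strain* axis. A chord
  (not a regression over interior points) is the simplest definition
  consistent with "slope over a range", and is exactly testable against an
  independent interpolation oracle.
* **Rate comparison** — Welch's two-sided t-test per rate pair, flagged at
  p < 0.05, reported raw (three pairwise tests, no multiplicity
  adjustment). Welch rather than pooled-variance because the published
  end-stress SDs differ several-fold across rates. Two zero-variance
  groups compare to p = 1 when their means agree, p = 0 otherwise.

## The synthetic-data generator

The generator exists so the full pipeline — file I/O, kinematics,
fitting, summaries — runs and is testable with no laboratory data. Its
defaults encode the study conditions, and they are fixed, not tuning
knobs:

* 3 rates (2, 20, 100 s⁻¹) × 6 replicates × 200 samples per ramp, 9 mm ×
  5 mm geometry, loading to exactly 30% grip strain.
* Ground truth per rate is a **one-term Ogden law**, with $\mu$ set to the
  published per-rate Ogden shear moduli (560.9, 1110.8, 1239.6 Pa) and
  $\alpha$ solved by root finding so the end stress at $\lambda = 1.4749$
  equals the published mean end stresses (393.7, 928.3, 2582.4 Pa),
  giving $\alpha \approx -1.59, +0.53, +5.66$. Ogden is used rather than
  the published exponential laws because the exponential laws undershoot
  the published end-stress means by 9–12% at $\lambda = 1.4749$, whereas
  Ogden can satisfy both anchors at once — and it exercises the headline
  fitting path. Note the $\alpha \mapsto S_{11}$ map at fixed $\mu$ is
  U-shaped (minimum near $\alpha \approx -4$ at this end stretch); the
  solver works on the increasing branch right of the minimum, where the
  root is unique.
* Noise is one multiplicative factor per replicate,
  $c_i \sim N(1, \text{sd})$ truncated to (0.2, 1.8), with per-rate sd
  equal to the published end-stress SD/mean (0.214, 0.061, 0.109), plus
  i.i.d. additive jitter of 5 Pa emulating load-cell noise. This
  reproduces the observed pattern of roughly strain-uniform CoV whose
  magnitude sits inside the published per-rate CoV ranges and below the
  0.5 ceiling. The truncation prevents non-physical negative-stiffness
  replicates.
* Determinism: each record's RNG stream is seeded by
  `master_seed + rate_index*1000 + replicate_index` (mod 2³¹−1), so the
  whole dataset is a pure function of the configuration and seed. When
  averaging over *several* master seeds (as the calibration checks do),
  seeds should be spaced by more than the offset range — the package's
  own checks use a spacing of 10007 — otherwise datasets share record
  streams and averaging gains no precision.

What the generator does **not** emulate: within-test noise colour
(the true sensor spectrum is unknowable from published summaries),
machine compliance, inertial ringing at the fastest rate, glue-failure
events, temperature or post-mortem-time effects, and any genuine
viscoelasticity. Passing tests therefore show the pipeline is
self-consistent and correctly calibrated to the published summary
statistics — not that it would reproduce raw laboratory curves.

## Problem sizes and numerical choices

The standing test suite fits on curves of 40–120 points and averages over
20 master seeds for calibration checks and 10 for the scatter ceiling;
these sizes put every Monte-Carlo assertion several standard errors away
from its threshold while keeping the suite quick. Interpolation is linear
throughout; root finding and optimization use tolerances of 1e-12 and
1e-10 respectively; the finite-difference oracle uses a 1e-6 half-step.
Ties in model ranking are broken deterministically (fewer parameters,
then family name) so reports are byte-stable across runs.

## Known limitations

* Per-range secant moduli reported by the original study cannot be used
  as calibration anchors: summing its printed range-slopes times range
  widths falls far short of its printed end stresses, so the exact
  procedure behind that table (stress measure, strain axis, averaging
  order) is not inferable. The package computes chord moduli with a
  single documented convention instead.
* Experimental R² ranges depend on raw specimen curves that were never
  deposited and are not reproducible here.
* The exponential family's nonzero stress at $\lambda = 1$ means it
  should not be extrapolated below the fitted range.
* Only tension is supported; compression (grip ratios below 1) is a
  domain error by design.
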