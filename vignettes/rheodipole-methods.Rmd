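---
title: "Methods: the finite-dipole rheotaxis model and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the finite-dipole rheotaxis model and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheodipole)
```

## The model and its assumptions

`rheodipole` treats an adult zebrafish as a self-propelled finite
dipole: two point vortices of strengths $\Gamma_l(t), \Gamma_r(t)$
[cm$^2$/s] a fixed distance $l$ apart, swimming in two dimensions in a
steady uniaxial channel flow $U(y)$. The assumptions worth keeping in
mind are:

* **Two-dimensional, inviscid kinematics.** The swimmer moves in the
  horizontal plane; diving is outside the model. The background flow is
  a fixed parabola $U(y) = q\,y^2 + U_0$ (defaults $q = -0.036$
  1/(cm·s), $U_0 = 1.584$ cm/s); the fish does not perturb it.
* **First-order (reduced) dynamics.** The flow is Taylor-expanded at
  the two vortex positions about the centroid; for a parabolic profile
  the turn-rate equation is *exact* under this reduction and the axial
  speed differs only by the constant remainder $q\,(l/2)^2\cos^2\theta$
  (both facts are asserted to machine precision in the test suite, and
  the exact two-point form is retained in `exact_derivatives()` as an
  oracle).
* **Control through the vortex strengths only.** All sensing — lateral
  line, vision, touch — acts by modulating $\Gamma_l, \Gamma_r$, which
  follow coupled Cox–Ingersoll–Ross (CIR) processes with a shared
  differential input $u(t)$ (positive into the left vortex, negative
  into the right; the single exception is the repulsive outlet rule,
  which boosts both).
* **Hydromechanical sensing = local circulation.** The lateral-line cue
  is the line integral of $U$ around a circle of radius $r$
  approximating the fish perimeter, $L_c = -\pi r^2 U'(y)$. A two-state
  Markov switch $K(t)$ gates whether the cue is used. In a uniaxial
  flow this feedback is exactly gradient-following, which is what makes
  the upstream heading an attractor of the coupled $(y, \theta)$
  dynamics: a fish tilted slightly upstream-and-up rises into the upper
  half-channel, where the combined passive vorticity and hydro torque
  rotate it counterclockwise back through the upstream heading, and
  symmetrically below the centerline.

## Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| $\alpha$ | 1/s | 1.0 | decay rate of the vortex strengths |
| $\beta$ | cm²/s | 10 (Bright), 16 (Dark) | baseline strength; $\beta/(2\pi l)$ is the noise-free relative speed |
| $\sigma$ | cm/s | 1.5 | CIR noise intensity (Feller: $\sigma^2 < 2\alpha\beta$) |
| $\kappa$ | 1/s | 2.0 | coupling; how fast straight swimming resumes |
| $K_R$ | 1/s | 5.0 | hydrodynamic feedback gain |
| $\lambda_1, \lambda_2$ | 1/s | 0.3, 0.3 | switch-on / switch-off rates of $K(t)$ |
| $K_W$ | cm²/s² | 38.224 (0 in Dark) | visual wall-turn intensity |
| $C$ | 1/cm | 2.236 | spatial decay of the wall effect |
| $\eta$ | cm²/s² | 10 | tactile turn rate at contact |
| $\epsilon$ | cm | 0.001 | wall-contact tolerance |
| $l$ | cm | 0.5 | dipole width (fish thickness ~5 mm) |
| $r$ | cm | 1.8 | sensing radius, half a body length |
| BL | cm | 3.6 | body length; wall-interaction range and mask |

$K_W$, $C$, $\eta$, $\epsilon$, the flow coefficients, the arena
(30 cm × 13.8 cm, 1 cm² corner squares), the 30 Hz sampling and the
burn-in protocol (keep the last 300 s of 6 × 300 s) are study
constants. The body length deserves a note: the literature value is
printed once as 3.6 *mm*, which is inconsistent with a 5 mm fish
thickness and with a "1 BL" grid of ~3 cm cells; we read it as 3.6 cm
and expose it in the configuration.

The remaining control constants ($\alpha, \beta, \sigma, \kappa, K_R,
\lambda_{1,2}$) have no published numeric values (they are reported
only graphically), so the package defaults were chosen once, as the
values a behavioral modeler would call realistic, and then frozen:
relative swim speeds $\beta/(2\pi l)$ of 3.2 cm/s (Bright) and 5.1 cm/s
(Dark) — fish in the dark swim faster relative to the flow, which is
exactly what weakens their rheotaxis — a turn-rate standard deviation
near 2 rad/s, switch dwell times of a few seconds, and a feedback gain
strong enough that the hydro torque beats the turning noise in the
outer half-channel. One candidate set considered early on (weaker
coupling, stronger noise) produced an unphysical absorbing state — the
fish orbiting indefinitely inside a corner square under the frozen
visual torque — and was rejected on that ground; the retained defaults
produce sustained exploration with clear upstream bias.

## What the synthetic generator emulates — and what it does not

`run_trial()` reproduces the experimental protocol: Euler–Maruyama at
$dt = 1/30$ s, five trial-lengths of burn-in, exactly 9,000 retained
samples, arena confinement, corner freezing of the wall encounter, and
the recorded turn rate defined as the realised per-step heading
increment over $dt$ (what a tracker measures).
`sample_population_params()` draws per-trial parameter sets from
Gaussian population statistics, pooled across conditions except
$\beta$, with Dark forcing $K_W = 0$; draws are rejected until positive
and Feller-feasible. `run_experiment()` assembles the 12 + 12 design.

Simulated trajectories do **not** contain: tracking noise or identity
swaps, burst-and-coast gait structure (the CIR noise is continuous),
three-dimensional excursions, or any fish-induced modification of the
flow. Passing recovery tests on this generator therefore demonstrates
internal consistency of the estimation pipeline, not robustness to
real tracking artifacts.

## Numerical choices

* **Positivity of the discrete CIR chain**: full truncation (clip
  inside the square root and after the step). Under the default
  parameters fewer than $10^{-3}$ of steps clip.
* **Switch transitions** use exact exponential probabilities
  $1 - e^{-\lambda dt}$ rather than Bernoulli $\lambda\,dt$.
* **Quadrature oracle** for the circulation: composite trapezoid on the
  periodic integrand, 512 nodes (spectrally accurate; exact to
  $10^{-10}$ for parabolas, $O(r^4)$ otherwise).
* **Wall geometry**: the encounter is the first boundary crossed by the
  heading ray ("projected" distance); the collision angle is signed by
  which side of the body faces the wall, with $\mathrm{sign}(0) := 0$
  in the wall feedback so a perfectly aligned fish receives no lateral
  bias. Position is clamped to the boundary after each step (the
  simplest confinement consistent with collisions being modelled
  through the strengths); inside the four 1 cm² corner squares the
  encounter is frozen at its entry value.
* **Inverse kinematics** uses forward differences over one sample, the
  same first-order scheme as the forward model, so on synthetic data
  the strength estimates are exact away from walls up to the $O(l^2)$
  flow-sampling remainder (~$10^{-2}$ cm²/s here).
* **Flow-profile inversion** uses only frames with
  $|\sin\theta| > 0.1$ (the bare requirement $\sin\theta \ne 0$ lets
  the cotangent term amplify noise without bound) and, optionally,
  drops frames clamped onto the boundary.
* **Likelihood**: the Euler residuals standardised by
  $K_0\sqrt{\Gamma}$ ($K_0 := 1$, so the reported $\sigma$ is directly
  comparable) give a Gaussian likelihood in
  $(\alpha, \beta, \sigma/K_0, \kappa, K_R)$; the Feller constraint is
  enforced by the reparameterisation
  $\sigma^2 = 2\alpha\beta\,\mathrm{logistic}(s)$, keeping every
  iterate strictly feasible, and fits reaching the boundary are
  flagged. Optimisation is BFGS from five deterministic starts around a
  weighted-least-squares solution of the (linear) drift — the WLS step
  is itself almost the exact MLE, which is why convergence is fast and
  reproducible.
* **Switch labelling**: both series normalised by their global maximum
  absolute value; the turn signal smoothed by a 15-sample (0.5 s)
  centered moving average; error threshold 0.35 over a 2 s continuous
  window.
* **Wall calibration**: the 5% smoothing span is floored at 10 points
  (it only binds below 200 retained points); the smoothed magnitudes
  are regressed on the collision distance $d$ at the retained points;
  fewer than 20 retained points leaves the decay $C$ undefined and
  takes $K_W$ from the maximum-strength correction alone, matching how
  sparse trials are reported in the published per-trial table.
* **$\lambda$ counting** is normalised by occupancy time (the CTMC
  maximum-likelihood rates); a state never visited yields a missing
  rate, not zero.

## Problem sizes

The test suite and `scripts/acceptance.R` use trials of 9,000–54,000
samples; the recovery harness calibrates 10 replicate 1800 s trials
(~17,000–26,000 masked step pairs each after the 1-BL wall mask);
long-run SDE properties use $10^5$ steps. These sizes were chosen so
every stochastic assertion sits several standard errors inside its
tolerance.

## Known limitations

* **Switch-proxy attenuation.** The latent switch $K(t)$ is observable
  only through behavioral synchrony. On synthetic data, where the truth
  is known, the labelling rule misclassifies a substantial fraction of
  frames: near the centerline the cue is ~0 and "following" vs
  "ignoring" is genuinely unidentifiable, and the normalisation by the
  global maximum (which includes wall-turn spikes) compresses the
  informative mid-channel signal. The downstream effect, quantified by
  `recover_parameters()`, is systematic: $\alpha, \beta, \sigma,
  \lambda_1$ recover to within a few percent, while $\kappa$, $K_R$ and
  $\lambda_2$ are biased low (errors-in-variables attenuation and
  dwell-time stretching). Feeding the same likelihood the *true* switch
  series recovers all five SDE parameters within a few percent, so the
  bias belongs to the labelling stage, not the estimator. Calibrations
  of real data inherit the same caveat, invisibly.
* **Wall-mask sensitivity.** Widening the away-from-wall mask to 1.2 or
  1.4 BL leaves $\alpha, \beta, \sigma$ within 10% but moves the
  proxy-identified $\kappa, K_R$ more, for the same reason.
* The model is two-dimensional, single-fish, with a frozen background
  flow; vestibular and olfactory channels are absent.
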