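---
title: "Rolling-regulated sperm navigation: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rolling-regulated sperm navigation: models, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollnav)
```

# Overview

Mammalian sperm beat their flagella asymmetrically: the midpiece bends more
to one side, which in a planar swimmer produces a torque and hence circular
paths. Progressive swimmers escape this trap not by beating symmetrically
but by *rolling* — rapid, discontinuous rotations about the longitudinal
axis that flip the direction of the asymmetry. `rollnav` implements this
picture as a set of small coupled models:

* a **waveform** module describing the beat as a Fourier series with a
  zeroth (asymmetry) harmonic and multiplicative Gaussian noise;
* a **kinematics** module mapping the beat to planar motion through
  resistive force theory (RFT);
* a **rolling** module for the stochastic switching process $\Pi(t)$;
* a **rheotaxis** module (Adler phase-locking under shear);
* a **hydrodynamics** module (far-field Stokeslet swimmer–wall coupling);
* a **wall-dynamics** module (near-field contact mechanics, the S1–S4
  interaction taxonomy, and the reservoir state machine);
* a **track-analysis** module (circle fits, center diffusion, curvature
  SNR, wall-detention metrics, thermal bounds);
* a **synthetic-data** module generating every input with ground truth.

All lengths are µm, times s, angles rad (counter-clockwise positive),
viscosities Pa·s, forces pN, torques pN·µm. In these units Pa·s equals
pN·s/µm², so no hidden conversion factors appear anywhere.

# The beat and its asymmetry

The planar deflection is
$$ y(x,t) = \sum_{n=0}^{N} \Pi(t)\, a_n(t) \cos(n\omega t - kx), \qquad
   k = 2\pi/\lambda,\ \lambda \approx L, $$
with asymmetry index $\sigma = (a_1 - a_0)/a_1$: $\sigma = 1$ is a
symmetric beat, smaller values are more asymmetric. Amplitudes and the
frequency carry delta-correlated multiplicative Gaussian noise,
$a_n = \tilde a_n (1 + \eta_n)$, realised per time step as independent
Gaussians of standard deviation $\sqrt{D/\Delta t}$ (the Euler–Maruyama
convention), so statistics converge in distribution as $\Delta t \to 0$.
The default keeps $N = 2$ harmonics — the zeroth, first and second lines
dominate measured midpiece spectra — and warns when any $|a_n|/L \ge 0.2$,
the edge of the small-amplitude regime the RFT mapping assumes.

## Construction of an asymmetric beat from the opening angle

`build_asymmetric_beat(phi0)` generates a one-parameter family of beats:
one half-beat is the sine arc $\sin u$ traversed over $u \in [0, \phi_0]$
with $\phi_0 \in (\pi, 2\pi]$; even extension about the turning point and
periodic continuation give a waveform of period $2\phi_0$ in phase. The
choice of where to close the arc is the design decision that fixes the
whole family, and we took the one that reproduces the anchor properties of
the asymmetry parameterisation exactly:

* $\phi_0 = 2\pi$ closes the arc on a full sine cycle, so the DC Fourier
  coefficient $a_0 = (1 - \cos\phi_0)/\phi_0$ vanishes and $\sigma = 1$
  (symmetric beat);
* $\phi_0 < 2\pi$ leaves an unbalanced lobe, $a_0 > 0$ and $\sigma < 1$;
* $\sigma$ is monotonically increasing in $\phi_0$ on $(\pi, 2\pi]$
  (verified as a property test).

Alternative readings of "a sine restricted to an interval, evenly
extended" — even reflection about the interval midpoint or endpoints —
preserve the segment mean $-2\cos\phi_0/(2\phi_0-\pi)$, which does *not*
vanish at $\phi_0 = 2\pi$; they cannot represent a symmetric beat at the
symmetric end of the family, so we rejected them. The Fourier amplitudes
are computed by adaptive quadrature (and checked against a dense-grid
trapezoid oracle in the tests); magnitudes populate the returned
`beat_spec`, scaled so the first harmonic has a physical amplitude
(default 4 µm, a typical midpiece deflection).

## Measuring the zeroth harmonic

The simple estimator implemented by `measure_zeroth_harmonic()` is the
midrange rule $a_0 = |y_L - y_R|/2$ with $y_L = \max(y - c)$ and
$y_R = -\min(y - c)$ for centerline $c$. Two estimator caveats are worth
stating because they shape the tests:

* **The centerline must be the straight flagellar axis, not the time
  mean.** The time mean of the series *is* the zeroth harmonic; removing
  it before measuring forces the estimate to zero. The synthesizer emits
  series referenced to the straight axis, so the default is $c = 0$;
  series from other sources must be referenced accordingly.
* **Even AC harmonics bias the midrange.** For $y = a_0 + a_1\cos\theta +
  a_2\cos 2\theta$ the estimator returns $a_0 + a_2$ (the midrange of the
  AC part is $a_2$, not 0). The estimator is exact exactly when the AC
  part has half-wave symmetry — in practice, when the first harmonic
  dominates. Recovery tests therefore use the first-harmonic
  representation of constructed beats; with realistic $a_2/a_0$ ratios the
  bias is the estimator's, not the synthesis's.

When time stamps are supplied and at least three beat periods are covered,
the implementation averages per-beat maxima and minima instead of taking
global extremes. For noise-free beats this is identical to the plain
midrange; under symmetric amplitude noise the per-side extreme-value
biases cancel in the difference, which is what lets a 0.5-µm zeroth
harmonic be recovered within 10% from ten noisy beats.

# Resistive-force-theory kinematics

With Gray–Hancock drag
$\xi_T = 2\pi\mu / (\ln(2\lambda/d) - 1/2)$, $\xi_N = 2\xi_T$ (flagellum
diameter $d = 0.4$ µm; all overridable), the torque of the asymmetric beat
is
$$ \tau_f = (\xi_N - \xi_T)\,\omega k L\, a_0 \sum_n n \tilde a_n^2 , $$
linear in $a_0$ and vanishing for isotropic drag. The force/torque balance
closure is documented rather than fitted: thrust
$(\xi_N - \xi_T)\langle \dot y\, y'\rangle$ balanced against tangential
body drag gives
$V_P = (\xi_N/\xi_T - 1)(\omega k/2)\sum_{n\ge1} n a_n^2$, and the torque
balanced against rotational drag about the flagellum midpoint
($\xi_N L^3/12$) gives
$$ \Omega = 24\,\frac{\xi_T}{\xi_N}\,\frac{a_0}{L^2}\,V_P . $$
The *proportionality* $\Omega \propto (\xi_T/\xi_N)(a_0/L^2)V_P$ is the
substantive physical statement (tested: the $(a_0/L,\ L\Omega/V_P)$ sweep
fits a line through the origin with $R^2 > 0.99$); the constant 24 depends
on the rotation-point convention and is exposed for what it is. One
consequence inherited by everything downstream: noise in $a_0$ perturbs
$\Omega$ and $\kappa$ linearly but leaves $V_P$ untouched, whereas noise
in higher harmonics perturbs $V_P$ but not the curvature — this is why the
trajectory integrator models center diffusion with a single multiplicative
noise $\Omega(t) = \tilde\Omega(1 + \eta_0(t))$.

A deliberate non-goal: the torque formula above is taken as the model's
definition and is *not* re-derived here by integrating the local RFT drag
along the flagellum. The leading-order torque cross term of such a line
integral is proportional to $a_0\cos kx$ and integrates to zero over
exactly one wavelength with $\lambda = L$; recovering the closed form
requires the length-preservation closure of the full derivation, which the
package does not reproduce. Tests assert the formula's arithmetic and its
stated scalings instead of a line-integral equality.

## Rolling and the progressive speed

The heading obeys $\dot\theta = \Pi(t)\Omega(1+\eta_0)$. For switching at
mean interval $T_{SR}$ the triangular heading sweep averages to the net
drift
$$ \bar V = V_P\left|\frac{2\sin(\Omega T_{SR}/2)}{\Omega T_{SR}}\right|,
$$
with $\bar V \to V_P$ for frequent rolling and $\bar V = 0$ for the
non-rolling limit. The Monte-Carlo check measures event-to-event
displacement over one switching period (two intervals): this estimator is
unbiased through second order in the interval noise, whereas long-window
net displacement decoheres (any $\sigma_{SR} > 0$ makes the direction of
drift a random walk, so the *asymptotic* mean velocity is zero — the
closure describes the speed of the slowly wandering mean path, not a
long-time drift). Tests accept the closure when it falls within the 95%
Monte-Carlo confidence interval plus a fixed 1% of $V_P$ numerical floor
for integrator discretisation, a floor set a priori from the Euler step
sizes used.

Rolling intervals are sampled from a zero-truncated Gaussian by inverse
CDF (deterministic per seed; a gamma alternative with the same moments is
available). At the default interval statistics (mean 0.11 s, sd 0.02 s)
the truncation is 5.5 standard deviations away and its bias is
negligible; a warning marks heavier truncation. After $n_{SR}$ events the
progressive direction disperses as $\sqrt{n_{SR}}\,\sigma_{SR}|\Omega|$:
the interval errors accumulate as a random walk, so the square-root law is
the physically correct reading, and the Monte-Carlo in the test suite
confirms it while excluding the linear-in-$n$ alternative by more than ten
standard errors.

HLI (head light intensity) pulse trains are segmented by an Otsu two-class
threshold with a hysteresis band of 10% of the dynamic range; positive
edges are rolling events. Because the between-class variance is flat
across the empty gap between the two intensity classes, the threshold is
taken at the middle of the flat maximum — at either edge the hysteresis
band would sit inside one class and edges would be missed.

# Rheotaxis

Upstream orientation follows the Adler equation
$\dot\theta = -A\gamma\sin\theta + \Pi(t)\Omega$. The shear-response
product defaults to $A\gamma = 10$ rad/s at shear rate
$\gamma = 0.6\ \mathrm{s^{-1}}$ (the low-shear regime in which sperm
rheotaxis operates); $A$ alone is not separately identified by anything
the package computes, and every ordering prediction tested is independent
of its value. The perpendicular speed $V_N$ defaults to 0 — it enters only
the quadratic upstream-velocity correction and is not otherwise
quantified.

The lock angle is $\theta_{UP} = \arcsin(\Omega/A\gamma)$ when
$|\Omega| \le A\gamma$ (beyond that the package returns an explicit
"no upstream lock" result, and the integrator shows unbounded winding).
Rolling contracts the average lock angle to
$\tilde\theta_{UP} = \tilde\Pi\,\theta_{UP}$. Two systematic effects bound
the accuracy of that closed form and set the test tolerances: averaging
the $\arcsin$ is not the $\arcsin$ of the average (≈5% at
$\Omega/A\gamma = 0.5$, duty 0.1), and at finite switching frequency the
triangular ripple of $\theta(t)$ has an asymmetric-dwell offset that
decays like one over the switching frequency. At switching ≥ 20× faster
than $A\gamma$ both effects together sit inside the 10% band the tests
use. The upstream velocities
$$ \tilde V_{UP} = V_P\cos\tilde\theta_{UP} - V_F
   \quad\text{and}\quad
   V_P - V_F - \Bigl(V_N\tfrac{\Omega}{A\gamma}
   + \tfrac12 V_P\bigl(\tfrac{\Omega}{A\gamma}\bigr)^2\Bigr) $$
are both returned; their difference is bounded by
$(\Omega/A\gamma)^4 V_P$, and rolling strictly improves the upstream
velocity whenever $\Omega \ne 0$.

# Far-field hydrodynamics

The swimmer is three regularized point forces on the fluid: the drag
reaction at the head, the opposing propulsive force at the flagellum
center ($L/2$ behind), and a perpendicular pair encoding the beat torque.
Calibration: $|f| = \xi_T L V_P$ so the free swimmer's RFT speed is
$V_P$; the beat-asymmetry angle $\Delta\tilde\theta$ (the angle swept per
beat) tilts the propulsion axis and implies
$\Omega = \Delta\tilde\theta\,\omega/2\pi$, whose torque
$\Omega \xi_N L^3/12$ is supplied jointly by the tilted pair and the
perpendicular couple. Forces are Gaussian-regularized Stokeslets (Cortez
blobs, width 1 µm; the point-force limit is available), evaluated in the
swimming plane of a 3-D Stokes flow — the quasi-2D plane assumption of the
chamber. The velocity field is exactly divergence-free in 3-D; note that
an in-plane slice of a 3-D field has nonzero *2-D* divergence, so the
incompressibility test differentiates all three components.

No-slip boundaries are imposed by an image-system construction: image
Stokeslets placed behind the wall (a ring outside the circular reservoir,
a line behind the plane wall, offset several collocation spacings), with
strengths solved by least-squares collocation so the velocity vanishes on
the wall. This replaces a finite-element solve with an analytic
superposition at desk scale; the residual on the wall is returned with
every field and held below $10^{-3}$ of the field scale in the tests
(with the chosen source offset it is typically near machine precision).
The far field of the force-free swimmer decays at least as $1/r^2$
(dipole), and the wall-induced drift decays at least as $h^{-2}$ in the
wall distance.

The drift law
$U_w = U_{wp}\bigl(1 - \tfrac32\sin 2\Delta\tilde\theta\bigr)$ is taken as
the model's closed form, with $U_{wp}$ — whose absolute magnitude depends
on dipole strength and height conventions — computed numerically as the
drift of the $\Delta\tilde\theta = 0$ swimmer at the same pose. Rolling
averages the instantaneous drift exactly to
$U_{wp}(1 - \tfrac32\tilde\Pi\sin 2\Delta\tilde\theta)$, restoring the
full symmetric-swimmer attraction as $\tilde\Pi \to 0$. The
orbit-averaged drift magnitude for the calibrated swimmer (80 µm/s, tilt
up to 15°) circling 40 µm from the center of the 500-µm reservoir comes
out two orders of magnitude below the swimming speed — distant walls do
not steer circular swimmers; asymmetry and diffusivity do.

# Near-field wall dynamics

Contact force balance: with propulsive force $F_T$ and perpendicular force
$F_N$, the normal surface force is $N = F_T\sin\beta \mp F_N\cos\beta$
(away/toward-wall perpendicular force), with the no-contact threshold at
$\beta_{th} = \arctan(F_N/F_T)$.

The post-contact angle dynamics are $\dot\beta = g(\beta) + \Pi(t)\Omega$.
The lubrication computation that produces $g$ involves a pressure profile
and a fitting scale not reproducible here, so the package uses a two-slope
surrogate family
$$ g(\beta) = -g_0'\sin\beta\cos\beta - (g_\pi' - g_0')\sin^3\beta\cos\beta,
$$
odd in $\beta$, vanishing at $0$ and $\pi/2$, with $g'(0) = -g_0'$
(stable alignment) and $g'(\pi/2) = g_\pi'$ (instability); both slopes are
free parameters of the family. Stable angles are found by bracketed root
finding on the stable branch, checked against a dense-grid scan; with
rolling, $\tilde\beta_S^* = \tilde\Pi\,\beta_S$, and near the stable point
$\beta(t)$ is a triangular wave of peak-to-peak $\Omega T_{SR}$.

The S3→S4 transition threshold
$$ \Omega_{th} = \frac{\pi}{2}\,
   \frac{|g'(0)|\,g'(\pi/2)}{g'(\pi/2) - |g'(0)|}
   \;\approx\; \frac{\pi}{2}|g'(0)| $$
follows from the linearized detachment/return rule: the sperm detaches at
$\beta_s \approx \Omega/|g'(0)|$, returns at the same incidence (the
detachment angle is independent of the incidence angle — a property the
integrator confirms across an incidence sweep), and locks into tilted wall
swimming when $\beta_s$ exceeds the unstable angle
$\beta_u \approx \pi/2 + \Omega/g'(\pi/2)$. The event-driven simulation in
`first_s4_omega()` iterates exactly these contact cycles, so it reproduces
the formula by construction of the same linearization; with the surrogate
family's *exact* roots the stable and unstable branches only merge at the
saddle-node, which for the default slopes lies well above $\Omega_{th}$ —
the formula's small-angle character should be kept in mind when comparing
against measured thresholds.

The reservoir state machine classifies by the overlap variable
$s = \tfrac12(R^2 + R'^2 - d^2)$: rolling → S1; $s > RR'$ → S2 (no
contact); $0 < s \le RR'$ → S3; $s \le 0$ → S4. Boundary ties ($s = RR'$
to S3, $s = 0$ to S4) are an arbitrary, documented convention. The center
separation $d(t)$ diffuses as a **1-D** Brownian motion (matching the mean
first transition time $\langle T\rangle = (R - R')^2/2D$; a 2-D radial
alternative would not), reflected at 0 and at $R$. Frequent rolling
($\Omega T_{SR} < 2\pi$, the rolling-sperm criterion) makes the first wall
contact absorbing into S1; a non-rolling sperm's first contact pins S3 or
S4 through the detachment-angle rule; infrequent rolling adds ballistic
center relocations (speed $V_r$, uniformly random direction) that reset
the contact memory and make S2↔S3↔S4 transitions reversible. The
relocation speed is a free generator parameter (defaulting to the path
speed), as is the relocation duration.

Intermittent search: coverage of a diffusing disc grows like
$\sqrt{t}$, so $n$ relocation-separated phases sweep
$\propto \sum_i\sqrt{T_i} \ge \sqrt{\sum_i T_i}$; a grid-coverage
Monte-Carlo (distinct cells visited) accompanies the proxies.

# Track analysis

* **Circle fit**: the algebraic Kåsa linearization — deterministic, exact
  on noiseless circles, equivariant under rigid motions; windowed refits
  produce $\kappa(t)$ and the center series.
* **Center MSD**: 2-D convention $\mathrm{MSD} = 4D\tau$, fitted through
  the origin over the first 10% of lags (ballistic contamination grows
  with lag); the log-log slope over the same range flags ballistic versus
  diffusive scaling.
* **Curvature SNR**: $\tilde\kappa^2/(\langle\kappa^2\rangle -
  \tilde\kappa^2)$; zero variance is an explicit infinite-SNR result. The
  per-step turning-angle curvature ($\Delta\theta_i/\Delta s_i$) recovers
  frame-rate multiplicative curvature noise directly, which is what makes
  the generator's SNR recoverable within 20% and the normalized mean step
  $\delta^2\kappa^2 \propto \mathrm{SNR}^{-1}$ testable with a log-log
  slope of $-1 \pm 0.15$.
* **Wall metrics**: detention is the first contiguous episode within 5 µm
  (half a head-to-midpiece scale; configurable) of the wall; $T_D$ its
  duration, $V^*$ the on-wall speed over the speed in the second before
  contact, $\rho^*$ the on-wall path length over the total path length
  from first contact onward — wall-followers sit near 1, touch-and-detach
  events well below.
* **Thermal bound**: rigid-rod rotational diffusion with the
  Tirado–García de la Torre end correction
  ($\delta_r = -0.662 + 0.917/p - 0.050/p^2$, $p = L/d$), at TALP
  viscosity 3.2 mPa·s and 310 K. For $L = 80$ µm, $d = 5$ µm this is
  $5.4\times10^{-6}\ \mathrm{s^{-1}}$. The implied curvature SNR
  accumulates the thermal heading variance over one orbit,
  $\mathrm{SNR}_{th} = \pi\kappa V_P/D_r \approx 2\times10^5$ at
  $\kappa = 5\times10^{-3}$ µm⁻¹ — the package asserts only this
  conservative lower bound ($>10^4$), since sharper published figures
  depend on an averaging window that is not identified here.

# The synthetic-data generator

The generator defines the study conditions and is not a tuning knob. The
presets are: TALP (path speed 70 µm/s, rolling at 0.11 ± 0.02 s, frame
interval 0.08 s), 4% PVP (45 µm/s, rolling suppressed, 0.16 s frames) and
1% PAM (70 µm/s, rolling suppressed, 0.08 s frames). Modes: progressive
(rolling trajectory integrated at a fine internal step, subsampled to the
frame rate), circular (per-frame multiplicative curvature noise with
$\mathrm{sd} = 1/\sqrt{\mathrm{SNR}}$), intermittent (circular with
ballistic relocations and a CW/CCW flip at each sparse rolling event), and
medium-switch (instantaneous progressive→circular transition at the
boundary between two presets, on a common frame interval). An HLI channel
carries one pulse per rolling event (width one frame), and every track has
a ground-truth attribute.

What the generator emulates: the first-order statistics the analysis stack
assumes — speeds, interval laws, curvature noise, pulse trains, state
phenomenology. What it does not: hydrodynamic coupling between cells,
three-dimensional excursions, imaging noise and segmentation artefacts,
tail-resolved flagellar shapes, or any mechanism for *why* viscosity and
viscoelasticity suppress rolling (the presets encode the phenomenon, not
its cause). Passing closed-loop tests therefore certifies the estimators
against the stated statistical model of the data, not against everything a
microscope can produce.

# Numerical choices and problem sizes

Heading and wall-angle dynamics integrate with fixed-step Euler–Maruyama
(stochastic) or classical RK4 (deterministic switching), with steps at
most $0.01/\max(|\Omega|, \omega_{SR})$. Switching times are evaluated
exactly on the grid (the flip applies at the first grid point at or after
the event); tests that need the duty cycle resolved exactly choose steps
commensurate with the interval lengths, since an incommensurate step
systematically stretches one phase of the duty cycle. First-passage
Monte-Carlos use steps small enough that the Euler boundary-overshoot bias
(of order $a\sqrt{D\,\Delta t}/D$) is buried in the Monte-Carlo error.
Simulation sizes in the test suite — 150–200 seeds for the progressive
speed closure, 200-s trajectories for center MSD, 400-s circular tracks
for the SNR scaling, 500–800 walkers for first-passage — were chosen so
the whole suite runs in well under a minute on one core while keeping
every Monte-Carlo comparison inside its stated confidence band.

# Known limitations

* The RFT closure constant (24) and the drag ratio $\xi_N/\xi_T = 2$ are
  conventions; only ratios and proportionalities are asserted against
  independent oracles.
* The viscoelastic slope change of the curvature–asymmetry relation (PAM
  media) is out of scope: no constitutive model is implemented; the PAM
  preset differs from TALP only phenomenologically.
* The surrogate phase-curve family stands in for the lubrication solve;
  its slopes are free parameters, so absolute wall angles are not
  predictions, only their structure and orderings.
* $U_{wp}$'s absolute magnitude depends on the dipole-strength and height
  conventions of the force calibration; the tested statements are the
  closed-form shape in $\Delta\tilde\theta$, the decay laws, and the
  sub-µm/s orbit-averaged bound.
* The white-noise floor of measured beat spectra mixes flagellar and
  measurement noise; the spectrum reports the floor but does not decompose
  it.
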