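---
title: "Quenching a mood swing: model, controllers, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quenching a mood swing: model, controllers, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodswing)
```

## The model

`moodswing` treats Bipolar II mood dynamics as a second-order Liénard
oscillator. With $x_1$ the emotional mood and $x_2 = \dot x_1$ its change
rate, the plant is

$$\dot x_1 = x_2, \qquad
  \dot x_2 = -c\,x_1 + b\,a\,x_2 - b\,x_1^2 x_2 + u,$$

a van der Pol oscillator with restoring stiffness $c$, damping gain $b$ and
damping threshold $a$: small-amplitude mood ($x_1^2 < a$) is anti-damped
(pushed away from rest), large-amplitude mood is damped. The balance of the
two produces the clinical picture the model is meant to capture — any
nonzero initial mood grows into a sustained fixed-amplitude oscillation
between hypomanic and depressive phases, while the neutral state
$(0,0)$ is the unique equilibrium of the unforced system. The input $u$
represents treatment (medication plus therapy) entering the rate equation.

Assumptions worth making explicit:

* **Sign convention.** The package implements the state-space form above
  verbatim. The equivalent scalar form is $\ddot x - b(a - x^2)\dot x +
  c\,x = u$, i.e. *negative* linear damping near the origin — the form
  that actually sustains an oscillation from $x(0) = 0.5$ and that is
  consistent with the regressor/parameter factorization below. Writing
  the nonlinear damping with the opposite sign would make the origin
  attracting and leave nothing to treat.
* **All quantities are dimensionless**, including time. The model is a
  qualitative description; nothing in the package calibrates $a, b, c$ or
  the time axis against clinical data.
* **Both states are measurable.** No observer is provided; state
  estimation from physiological indicators is out of scope.
* **Parameters are positive.** The constructors reject $a, b, c \le 0$:
  every meaningful parameterization of the oscillator interpretation is
  positive, and positivity is what the control proofs use.

The drift of $\dot x_2$ is linear in the parameters,
$W(x)\,\theta$ with $W = (-x_1,\; x_2,\; -x_1^2 x_2)$ and
$\theta = (c,\; ba,\; b)$. The reference patient
($a=1, b=2, c=9$) therefore has $\theta = (9, 2, 2)$.

## The two treatment laws

Backstepping introduces the virtual control $x_{2d} = -k_1 x_1$ for the
mood equation and the error variable $h = x_2 - x_{2d} = x_2 + k_1 x_1$,
with positive gains $k_1$ (mood loop) and $k_2$ ($h$ loop).

**Exact model knowledge (EMK).** Differentiating $h$ along the plant gives
$\dot h = W\theta + u - k_1^2 x_1 + k_1 h$ (note: differentiating
$x_{2d} = -k_1 x_1$ along $\dot x_1 = -k_1 x_1 + h$ contributes
$+k_1^2 x_1 - k_1 h$ to $\dot h$ with these signs, which fixes the sign
pattern of the law). The package's default law is therefore

$$u = -W\theta + k_1^2 x_1 - k_1 h - x_1 - k_2 h,$$

which produces *exactly* the linear closed loop
$\dot x_1 = -k_1 x_1 + h$, $\dot h = -k_2 h - x_1$, and makes
$V = \tfrac12 x_1^2 + \tfrac12 h^2$ decay as
$\dot V = -k_1 x_1^2 - k_2 h^2$. A variant with the $k_1^2 x_1$ and
$k_1 h$ terms sign-flipped is available as `law = "as-printed"`; it does
not achieve the exact cancellation, but at the reference gains it still
yields a stable linear loop (both eigenvalues in the open left half
plane), which the test suite verifies by numerical linearization. The
corrected law is the default because it is the one for which the
closed-loop identities and the Lyapunov argument hold exactly — the
property tests check them to machine precision.

**Adaptive.** With $\theta$ unknown, the law substitutes a running
estimate $\hat\theta$ and adds the gradient update
$\dot{\hat\theta} = \Gamma W^\top h$, $\Gamma$ symmetric positive
definite. The imperfect cancellation leaves
$\dot h = -k_2 h - x_1 + W\tilde\theta$ with
$\tilde\theta = \theta - \hat\theta$; the update law is exactly the choice
that cancels the $h W \tilde\theta$ cross term against
$-\tilde\theta^\top \Gamma^{-1}\dot{\hat\theta}$ in
$V = \tfrac12 x_1^2 + \tfrac12 h^2 +
\tfrac12\tilde\theta^\top\Gamma^{-1}\tilde\theta$, so again
$\dot V = -k_1 x_1^2 - k_2 h^2$. The orientation bookkeeping ($W$ stored
as a triple, $\Gamma W^\top h$ meaning matrix · vector · scalar) is purely
notational. Either sign choice for the $W\tilde\theta$ term would work if
paired with the matching update sign; the package fixes the internally
consistent pair above.

Two consequences deserve emphasis:

* $\dot V$ contains no $\tilde\theta$ term, so the estimate is only
  guaranteed to be *bounded and settling*, not convergent to $\theta$.
  Identification would require persistent excitation, and a successfully
  quenched trajectory is the opposite of persistently exciting. The
  package therefore *reports* final estimates and never asserts their
  closeness to the truth. In the bundled adaptive scenario the estimate
  moves from $(6, 2.5, 5)$ by less than $10^{-2}$ before the error signal
  dies out.
* Initializing the adaptive loop at the true parameters does **not**
  reproduce the EMK loop exactly: while $h \ne 0$ the update law keeps
  adapting, so $\hat\theta$ leaves $\theta$ during the transient and the
  two closed loops differ at the $10^{-5}$ level (measured on the
  reference scenario). What is exactly true — and tested — is that the
  control *law* coincides with the EMK law pointwise when
  $\hat\theta = \theta$.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $a, b, c$ | patient model | 1, 2, 9 | reference patient used by all presets |
| $x(0)$ | initial mood/rate | (0.5, 0) | standard perturbed start |
| $k_1, k_2$ | backstepping gains | 1.1/1.22, 10 | EMK/adaptive reference gains |
| $\Gamma$ | adaptation gain | $0.1\,I_3$ | reference choice; any symmetric PD matrix is accepted since that is all the stability argument needs |
| $\hat\theta(0)$ | initial estimate | (6, 2.5, 5) | the one printed re-initialization (corresponding to a guess $a=0.5, b=5, c=6$); configurable per scenario |
| step | RK4 step | $10^{-3}$ | resolves the fastest closed-loop mode ($\lambda \approx -10$) with $|\lambda| h = 10^{-2}$ |
| duration | horizon | 40 untreated / 10 treated / 30 re-estimation | several limit-cycle periods, resp. full decay with wide margin |

All quantities are dimensionless (see above), so "time units" are model
time, not days.

## Numerical choices

* **Integrator.** Classical fixed-step RK4: deterministic, order 4, no
  hidden adaptivity — identical configurations produce bit-identical
  trajectories, which the test suite asserts. An `adaptive-stepper`
  backend (lsoda at `rtol 1e-10`) exists purely as a cross-check; the two
  agree to well below 1e-6 on the reference runs. The observed RK4
  convergence order on the untreated run exceeds 3.5.
* **Continuous-time control.** The law is evaluated inside every RK4
  stage, i.e. treatment is modelled as a continuous signal, not a
  sampled-and-held dose.
* **Blow-up guard.** Any state component exceeding $10^6$ in magnitude
  aborts integration with an error naming the time — relevant only for
  pathological configurations; the untreated reference model never
  approaches it from moderate initial moods.
* **Steady-state window.** Metrics that describe "the end" of a run
  (amplitude, estimate drift) use the final 25% of the horizon by
  default.
* **Zero crossings.** A mood change is a strict sign change between
  consecutive samples; a sample exactly at zero does not count. This
  makes "no mood change during treatment" a sharp, checkable claim.
* **Estimate settling.** "Converged to a constant" is operationalized as
  per-component total variation below `1e-4` over the final window —
  a criterion that is invariant to the output thinning factor in the
  settled regime.
* **Envelope rate.** The exponential certificate uses
  $\beta = 2\min(k_1, k_2)$, the sharp constant implied by
  $\dot V \le -2\min(k_1,k_2) V$; existence of *some* positive rate is
  what the theory gives, and this is the tightest one it supports.

## What the scenarios do and do not show

The bundled scenarios are synthetic study conditions: one reference
patient, noise-free dynamics, perfectly measurable states, continuous
dosing. Passing tests therefore demonstrate that the *algorithms* do what
the theory claims under the model's assumptions — they say nothing about
parameter values of real patients, measurement noise, medication dynamics
or dosing constraints, none of which the model represents. The problem
sizes (horizons 10–40 time units at step $10^{-3}$, with a step/10
refinement as amplitude oracle) were chosen so every claim is checked well
inside the asymptotic regime of the integrator.

## Known limitations

* No state observer; both states are assumed measured.
* No input saturation, no dosage mapping for $u$, no disturbance inputs.
* The adaptive law has no projection or leakage modification; estimates
  are bounded by the Lyapunov argument but unconstrained in sign.
* Mood-state convergence of the adaptive loop is verified numerically;
  the package does not attempt the Barbalat-style argument needed to turn
  boundedness of $\dot V$ into a formal asymptotic-convergence proof.
* Bipolar I (fast-swing) dynamics and stochastic mood components are out
  of scope.

## Session info

```{r}
sessionInfo()
```
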