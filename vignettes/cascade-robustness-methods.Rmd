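---
title: "Models and methods: duration robustness of signaling cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: duration robustness of signaling cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durobust)
```

## The protocol and the quantities measured

All three model tiers share one protocol. For $t < 0$ a constant input
enzyme $E_0$ (concentration `e0_init`) drives the first layer; the cascade
settles into a stimulated steady state in which layer $i$ carries a
phosphorylated fraction $g_i \in (0,1)$. At $t = 0$ the stimulus is
removed and the output — the phosphorylated substrate of the last layer —
relaxes toward zero. We measure:

* the **half-life** $\vartheta$: the smallest $t > 0$ at which the output
  has fallen to half its pre-stimulus value;
* the **logarithmic gain** of $\vartheta$ with respect to a rate
  parameter: the slope of $\vartheta$ against the parameter on a log–log
  plot, estimated by a central difference with half-step $0.05$ in
  $\log_{10}$. A magnitude of 1 corresponds to plain inverse
  proportionality (single-exponential relaxation); magnitudes below the
  threshold $0.3$ are counted as *duration robustness*. The threshold is
  deliberately loose — any value clearly below 1 gives the same
  qualitative picture;
* the **consecutive-profile similarity**: for two output profiles sampled
  on the same $\tau = \log_{10} t$ grid and separated by a parameter step
  $\Delta\log_{10}\beta$,
  $\frac{1}{|\Delta\log_{10}\beta|}\sqrt{\int_a^b |y_1(\tau) -
  y_2(\tau)|^2\, d\tau}$, integrated by the trapezoid rule over
  $[a, b] = [-2,\, 4 + \log_{10} 6]$. Values below 0.3 indicate
  *dynamics robustness* — the entire temporal profile, not just the
  half-life, barely moves.

On the similarity measure we made one interpretive choice: the
conventional $L^2$ norm includes the square root, while the un-rooted
integral of the squared difference is sometimes displayed in this
context. The norm (`use_sqrt = TRUE`) is the default because it is the
measure actually named; the literal un-rooted form is available by
switch, and the two never disagree about *which* regions are robust for
the profiles produced here, only about the scale of the curve. Profiles
are compared raw by default; `profile_normalized = TRUE` divides each by
its pre-stimulus value, which is useful when comparing across models
whose output scales differ.

## The Heinrich cascade and its steady state

The nonlinear model keeps only the essentials of a phosphorylation
cascade: each layer's phosphorylated form $M\!p_i$ is produced
bimolecularly by the layer above and removed first-order,

$$\dot{M\!p}_0 = -\beta_0 M\!p_0, \qquad
\dot{M\!p}_i = \bar\alpha_i\, M\!p_{i-1} (M^{tot}_i - M\!p_i)
 - \beta_i M\!p_i,$$

with substrate conservation $M_i + M\!p_i = M^{tot}_i$ built in. The
assumptions behind this reduction — negligible enzyme–substrate
complexes, irreversible catalysis, constant active phosphatase — are
exactly what the Huang–Ferrell tier relaxes. Effective first-order kinase
activities are $\alpha_0 = \bar\alpha_0\, E_0^{init}$ and $\alpha_i =
\bar\alpha_i M^{tot}_{i-1}$. Under stimulus the phosphorylated fractions
obey the recursion

$$g_0 = \frac{1}{1 + \beta_0/\alpha_0}, \qquad
g_i = \frac{1}{1 + (\beta_i/\alpha_i)/g_{i-1}},$$

implemented in `steady_state_gains()` and verified in the tests against
long-time integration of the stimulated ODEs. The recursion makes the
upstream-shielding structure transparent: $g_i$ depends only on layers
$\le i$, so downstream parameters never move upstream steady states,
while $1/g_N$ is *affine* in any single $\beta_i$ — which is why the
activation bound $\beta_i^{\max}$ (the largest $\beta_i$ keeping
$g_N > 0.5$) has a closed form, with a log-bisection route kept purely as
a cross-check. Note that $\beta_i^{\max}$ is exactly proportional to
$\alpha_i$, and that changing an upstream kinase moves it only through
the (nearly saturated) factor $g_{i-1}$ — approximate, not exact,
invariance.

Activation itself is the strict criterion $g_N > 0.5$. The boundary value
is conventional; the analysis is insensitive to reasonable alternatives,
and the threshold is exposed as an argument throughout.

## The linearized tier

Linearizing the normalized cascade ($m_i = M\!p_i/\tilde M_i$, all
$m_i(0) = 1$) about the deactivated state gives a lower-triangular chain
whose output is a linear combination of exponentials
$\sum_i c_i e^{-\beta_i t}$ with $\sum_i c_i = 1$ — the classic
decay-chain form. `linearized_solution()` builds the coefficients by the
chain recursion; when two rates coincide within a relative tolerance of
$10^{-9}$ the confluent branch is taken, producing polynomial-in-$t$
prefactors *exactly* rather than perturbing the rates. (The default
fast-slow-fast base set actually hits this branch: its two fast
phosphatase rates are equal.) The closed form is tested against direct
ODE integration of the linearized system at $10^{-8}$ relative accuracy.

When the smallest rate $\beta_k$ is well separated, the half-life obeys
$\vartheta \approx \log(2 c_k)/\beta_k$ (`duration_approx()`), whence the
duration gain with respect to a non-minimal $\beta_i$ is
$\frac{1}{\log 2 + \log c_k}\,\partial \log c_k / \partial \log \beta_i$
(`gain_from_coefficients()`, with the partial taken by central
differences). The two routes to the gain — this formula versus
differencing $\vartheta$ itself — agree to discretization error, which
the tests check at a $10^{-3}$ differencing step. If $c_k < 1/2$ the
slow mode never carries half the output, the log turns negative, and the
approximation is reported as invalid rather than returned.

The linearized output is *unsaturated*: its coefficients can be large and
the profile can far exceed 1 before decaying. The half-life is therefore
defined as the first downward crossing of $1/2$.

## The Huang–Ferrell tier

The mass-action model keeps every species: 8 free substrate forms, 4 free
enzymes and 10 enzyme–substrate complexes (22 states), with each of the
10 enzymatic steps a Michaelis scheme $E + S \rightleftharpoons C \to
E + P$. Layers 1 and 2 require double phosphorylation, the source of
ultrasensitivity. Phosphatases are explicit, so a layer's
dephosphorylation activity is proportional to its total phosphatase
concentration $P^{tot}_i$ — sweeps over `p_tot.i` are the HF counterpart
of the Heinrich $\beta_i$ sweeps. Conservation of every substrate and
enzyme pool holds by construction of the right-hand side and is asserted
along trajectories in the tests.

Two choices here were genuinely open:

* **Stimulus removal.** "Removing the stimulus" at $t=0$ is ambiguous
  when the input enzyme sits partly in complexes. The default (`hard`)
  deletes free $E_0$ *and* the $E_0$-substrate complex, returning the
  sequestered substrate to its free unphosphorylated pool — every trace
  of the input disappears while substrate conservation is preserved. The
  alternative (`free_only`) zeroes only free $E_0$ and lets existing
  complexes turn over. For the generated base sets the complexed input is
  a tiny fraction, and the two options give indistinguishable relaxation.
* **What counts as output.** The doubly phosphorylated terminal substrate
  exists free and phosphatase-bound. The default output (and $g_2$) is
  the free form; `output_include_bound = TRUE` adds the bound form. Both
  are exposed because neither convention is canonical.

The stimulated steady state is found by integrating the stimulated system
over doubling horizons until the maximum relative state change per
doubling falls below $10^{-9}$ (capped at a configurable horizon, with
the residual reported on failure).

## Numerics

* **Integrator**: BDF (`deSolve`, adaptive implicit) at `rtol = 1e-8`,
  `atol = 1e-12`. The post-stimulus cascade is stiff from $t = 0$
  whenever kinases are fast; a stiffness-switching method can stall on
  the densely log-spaced output grids used here, so the implicit method
  is used unconditionally. Halving the tolerances moves sampled profiles
  by less than $10^{-6}$ (tested).
* **Sampling**: profiles are sampled at 600 uniform $\tau$ points over
  $[-2, 4 + \log_{10} 6]$ by default, enough that doubling the density
  changes the similarity integral by less than $10^{-4}$ (tested); many
  tests use sparser grids for speed.
* **Half-life**: bracketed on a log-dense sample of the trajectory, then
  refined by `uniroot` to $10^{-8}$ relative, re-integrating from the
  stored bracket-left state. If the output has not crossed one half by
  the default horizon $6\times10^4$, the search window extends up to
  $100\times$ before reporting failure. Solver undershoots below zero at
  the `atol` scale are clamped in trajectories; larger negativity warns.
* **Sweep gains**: computed two ways — central differences of
  $\log_{10}\vartheta$ on the sweep grid itself (step 0.2, one-sided at
  the ends), and a per-point refined re-evaluation at step 0.05 so that
  robust-interval edges do not depend on the sweep grid coarseness. The
  refined gain is the default for interval detection and is switched off
  only for the expensive HF sweeps.
* **Condition 3 cutoff**: "$\beta_k \ll \alpha_k$" is operationalized as
  $\beta_k/\alpha_k < 0.1$, configurable; no canonical cutoff exists.

## The synthetic parameter generator

The measured kinetic tables this analysis was designed around are not
redistributable here, so `heinrich_base()` and `hf_base()` generate
*emulated* sets that encode only the stated organization: phosphatase
rates fast–slow–fast across the three layers ($\beta = (1, 0.01, 1)$,
i.e. a hundredfold timescale separation), unit substrate totals, and
kinase activities fast relative to the slow phosphatase
(`kinase_speed_factor`, default $10^5$, times the slow rate — effective
activities of $10^3$), with the stimulus raised until the output
activation clears `activation_floor` (default 0.9). The HF base uses one
Michaelis scale for all ten steps ($a = d = k = 1$, $K_m = 2$), substrate
totals of 100, and $P^{tot} = (1, 0.01, 1)$. Units are arbitrary but
consistent; every derived quantity is reported in input units.

These sets reproduce the *qualitative* robustness structure — the slow
middle layer is rate-limiting and not robust at its base value, the outer
layers are robust over decades, fast downstream kinases shield upstream
perturbations — and that is all the tests claim. They do not reproduce
any measured system's numbers, and passing tests say nothing about
absolute durations in real pathways. `random_ensemble()` supplies
log-uniform parameter sets (default range $[10^{-4}, 10^4]$, filtered for
activation and distinct rates) for property-style tests; the ensemble
seed is isolated from the caller's RNG state.

One point where the generated conditions sharpen intuition: with *all*
kinases very fast, a formal duration-robust interval exists even for the
slow layer's phosphatase once it is raised far enough to stop being
rate-limiting — exactly what the robustness conditions predict. The
scientifically meaningful statement, which the tests assert, is about the
*base* organization: the rate-limiting layer is not robust where it sits
(its gain is $\approx -1$), while the outer layers are.

## Problem sizes and limitations

The shipped tests integrate 3-state cascades on grids of 60–300 $\tau$
points and the 22-state HF model on grids of up to 120 points, with
sweeps of 9–15 points; the full suite runs in well under a minute on one
CPU. The acceptance script's headline sweep uses 11 grid points with
three half-life evaluations each.

Known limitations: no feedback, crosstalk, or transcription-layer
dynamics; no stochastic (Gillespie) kinetics; no Michaelis–Menten
reduction of the HF tier; no dose–response analysis (the stimulus is
binary on/off); the similarity measure is the $L^2$ family only. The
$N$-stage generalization of the Heinrich/linearized tiers follows the
same layer pattern and is fully supported; the HF implementation is fixed
to the canonical 3-layer, 10-step architecture.
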