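---
title: "Dual-number tangent linear and adjoint models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-number tangent linear and adjoint models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualvar)
```

## Dual arithmetic

A dual number $d = x + y\varepsilon$ with $\varepsilon^2 = 0$ obeys
$f(x + y\varepsilon) = f(x) + f'(x)\,y\,\varepsilon$ for any differentiable
$f$, which a Taylor expansion shows directly: every term of order
$\varepsilon^2$ and higher vanishes. The package stores dual objects as a
real vector plus an $m \times s$ matrix of dual coefficients; $s = 1$ is
the classic dual number and $s > 1$ carries $s$ mutually annihilating
parts ($\varepsilon_i \varepsilon_j = 0$), so one evaluation propagates
$s$ directional derivatives while computing the shared real part once.
With $s = 1$ the multi-part arithmetic reduces to single-part arithmetic
identically — the same floating-point operation sequence per component,
which the tests assert with `expect_identical()`.

Design choices where the algebra alone does not decide:

* **Comparisons act on real parts only.** Control flow in overloaded model
  code (branches, `max`/`min`) therefore follows the nonlinear trajectory;
  the propagated derivative is that of the branch actually taken. This is
  the usual piecewise-linearization semantics of operator-overloading AD.
* **`abs` at zero** takes derivative 0 (the symmetric subgradient,
  `sign(0) = 0`); `dpmax`/`dpmin` break exact real-part ties in favor of
  the **first argument**, matching a left-to-right hand-written
  conditional. Both conventions are deterministic and tested.
* **`0^p` with `p < 1`** raises an error rather than returning an infinite
  dual part: the derivative does not exist and silent infinities corrupt
  an entire adjoint sweep. Similarly `log`/`sqrt` of non-positive real
  parts fail loudly, naming the function and offending value.
* **Plain numerics promote** to duals with zero dual part, so model code
  runs unchanged on floats, duals, or a mix.
* Dual coefficients are stored **dense**; sparsity is exploited at the
  segment level (below), not inside the scalar type, which keeps the
  arithmetic vectorizable.

## From dual numbers to TLM and adjoint

For a nonlinear step $M_{NL}: \mathbb{R}^n \to \mathbb{R}^n$, evaluating
$M_{NL}(x_{NL} + x_{TL}\varepsilon)$ returns the nonlinear solution in the
real part — bitwise identical to the plain evaluation, an invariant the
suite checks — and the tangent-linear product $\mathbf{M}(x_{NL}) x_{TL}$
in the dual part (`evaluate_tlm()`). The adjoint product cannot be read
off a single dual evaluation; it is assembled column by column,
$\mathbf{M}^T x_{AD} = \sum_i e_i (\mathbf{M} e_i)^T x_{AD}$:

* `adjoint_bruteforce()` performs the $n$ unit-seeded evaluations
  literally ($n$ evaluator calls, the instrumented counters confirm);
* `adjoint_multidual()` batches all $n$ seeds into one evaluation with $n$
  independent dual parts. Each output coefficient is accumulated in the
  same order as the brute-force path, so the two agree bitwise. A
  `chunk` knob trades calls for memory when $n$ seeds at once would be
  too large; the default is one full-width call.
* `adjoint_segmented()` exploits model structure, below.

## The segmented adjoint

Biogeochemical models decompose naturally into process segments, and two
observations shrink the adjoint cost. First, a segment reads few
variables: grazing depends on the five plankton variables but not on the
nutrients, so five seeds suffice for its Jacobian block regardless of the
state size. Second, most segments are pointwise — outputs in a grid cell
depend only on inputs in that cell — so a single multi-dual evaluation
seeded per *variable* (not per variable-and-cell) recovers every per-cell
block simultaneously.

Segments here are declared as **identity-plus-transfer** maps:
$y_i = x_i$ outside the write set and $y_i = x_i + u_i(x_{\text{reads}})$
inside it, so the Jacobian is $I + U$ with $U$ supported on
(writes × reads), and the adjoint of a composed step
$S_k \circ \dots \circ S_1$ is $S_1^T \cdots S_k^T$ applied in reverse
order, each linearized about the state *input* to that segment along the
stored nonlinear trajectory (checkpointing granularity is one segment).
A written variable whose transfer depends on its own value must appear in
the read set; footprints may over-declare (correct, slower) but never
under-declare. `check_footprints()` probes this at tolerance zero: seeding
all out-of-footprint variables must return the seed matrix itself, bitwise,
as the dual response.

Three segments get special treatment, mirroring how host ocean models keep
pre-existing tangent/adjoint code for generic operators:

* **transport** (vertical diffusion) and **sinking** (upwind advection)
  are linear; their hand-coded TLM is the operator itself and their
  adjoint its transpose;
* **light attenuation** couples cells vertically through the optical path.
  The biology update is pointwise *given* irradiance, so the
  photosynthesis adjoint seeds five read variables plus one irradiance
  direction (six seeds) per cell and closes the column coupling with the
  analytic attenuation adjoint
  $\partial I_k / \partial P_j = -\kappa_c \, \Delta z_j I_k$ for layers
  $j \le k$ (half-thickness at $j = k$, midpoint integration).

Setting `hand_coded = FALSE` in `nemuro_model()` routes all three through
the generic dual-number machinery instead, giving an independent
cross-check; the suite requires the two paths to agree to $10^{-12}$
relative. `adjoint_segmented()` also verifies on entry that the declared
segments compose to the monolithic step at the linearization state.

Verification is two-pronged everywhere: the **dot-product identity**
$\langle \mathbf{M}u, w\rangle = \langle u, \mathbf{M}^T w\rangle$ over
seeded random pairs (pass threshold $10^{-12}$ relative), and a
**finite-difference oracle** (central differences, step
$10^{-6}(1 + |x_i|)$, agreement to $10^{-6}$ relative) that is independent
of the dual-number path entirely.

## The ecosystem column model

The differentiation target is an 11-variable plankton ecosystem of the
NEMURO family — two phytoplankton (PS, PL), three zooplankton (ZS, ZL,
ZP), NO3, NH4, DON, PON, Si(OH)4, and Opal — on a vertical column (5
layers of 5 m and a 3600 s step by default). Nitrogen units are
mmol N m$^{-3}$, silicon mmol Si m$^{-3}$, rates per day. The process set
is the standard one: Michaelis–Menten nutrient uptake with
ammonium-inhibited nitrate uptake ($e^{-\psi \cdot \mathrm{NH4}}$,
$\psi = 1.5$), silicate limitation of PL (multiplicative, to keep the step
smooth), saturating light limitation $I/(I + k_I)$, Ivlev grazing
$g_{\max}(1 - e^{-\lambda(P - P^*)})$ (thresholds $P^*$ default to 0 so
the default step is smooth; positive thresholds exercise the
piecewise-smooth `max(0, ·)` path), linear plus quadratic mortalities,
egestion/excretion split by assimilation and growth efficiencies
($\alpha = 0.7$, $\beta = 0.3$), decomposition PON→DON→NH4, nitrification,
and opal dissolution. Default rate constants are in the range of published
NEMURO configurations for a productive eastern-boundary column; they are
deliberately round, overridable, and carry no claim of matching any
specific operational parameter file.

Two structural decisions matter more than any particular rate value:

* **Conservation by construction.** Every biological term is an explicit
  transfer between compartments, so each biology segment conserves total
  nitrogen per cell exactly, and total silicon
  ($\mathrm{Si(OH)_4} + r_{Si:N}\,\mathrm{PL} + \mathrm{Opal}$) within the
  silicon sub-cycle: silicon bound in grazed or dying PL is routed to
  Opal, and PL takes up silicate in proportion to its *net* nitrogen
  gain. The tests assert conservation to $10^{-12}$ relative, a strong
  independent check on the implementation because a misplaced term breaks
  it immediately.
* **No positivity clipping inside differentiated code.** Clipping destroys
  TLM/adjoint consistency; stability is the time step's job instead. The
  grid constructor enforces an explicit-diffusion stability number
  $\le 0.5$, sinking enforces a CFL number $\le 1$, and negative input
  concentrations raise an error naming the cell and variable rather than
  being silently repaired.

One model step composes transport → photosynthesis (with light) → grazing
→ mortality → remineralization → sinking, the same fixed order in the
nonlinear, tangent linear, and adjoint paths (the adjoint applies the
reverse). Chlorophyll a is diagnosed as
$\mathrm{chl} = c_{chl:N}(\mathrm{PS} + \mathrm{PL})$ with
$c_{chl:N} = 1.59$ mg chl (mmol N)$^{-1}$; being linear, its tangent and
adjoint are the factor and its transpose.

## Incremental strong-constraint 4D-Var

The cost of an initial-condition increment $\delta x$ is
$$ J(\delta x) = \tfrac12\,\delta x^T B^{-1} \delta x +
   \tfrac12 \sum_k (H_k(x_k) - y_k)^T R^{-1} (H_k(x_k) - y_k), $$
with the trajectory launched from background $+$ increment and the model
treated as error-free. $B$ and $R$ are diagonal — a transparency choice at
column scale, and a divergence from operational systems whose background
covariances carry spatial and cross-variable structure. The gradient comes
from one reverse-time adjoint sweep that injects
$H^T R^{-1}(Hx - y)$ at each observation time.

The minimization is the classic incremental form: innovations are fixed
within an outer loop, the inner loop minimizes the resulting quadratic by
conjugate gradients in control space $v = B^{-1/2}\delta x$ (the
control-variable transform, on by default, which makes 10 inner iterations
meaningful; without it the identity block of the Hessian is replaced by
$B^{-1}$ and conditioning suffers), and each Hessian application costs one
TLM sweep plus one adjoint sweep. Defaults are 10 inner iterations and 2
outer loops. CG stops early at a relative residual of $10^{-10}$,
secondary to the iteration cap; a non-positive curvature direction raises
an error pointing at `dot_product_test()`, since it can only arise from an
inconsistent TLM/adjoint pair. Observation times snap to the nearest model
step with ties rounding down. The quadratic cost per CG iterate is
recovered from the tracked $A x$ product (no extra sweeps) and must be
non-increasing.

Gradient correctness is established two ways: finite-difference
directional derivatives (agreement to $10^{-5}$ relative) and the Taylor
remainder test, whose log–log slope must be at least 1.9 (an exact
gradient gives 2; a 1% gradient error collapses the slope to 1, the
negative control). The remainder floor is set at
$10^3 \epsilon (|J| + 1)$ to exclude rounding-dominated points from the
slope fit.

## The twin laboratory

The synthetic-observation generator emulates the *structure* of a coastal
observing system, not its physics: one surface variable observed densely
and gaplessly (surface NO3 here — the physical circulation model whose
temperature would play this role is out of scope), and surface chlorophyll
observed sparsely, with a contiguous block of time slots removed as a
cloud-cover analog (block-contiguous rather than i.i.d., because real
cloud masks remove regions, not random samples). Noise is Gaussian with
exactly the error standard deviations used in $R$ — perfectly specified
errors, isolating machinery correctness from misspecification effects.
The truth is the background with a multiplicative lognormal perturbation
(scale 0.2), which preserves positivity.

The default window is 96 steps of 3600 s — a 4-day assimilation cycle,
the cycle length typical of operational coastal systems — on the 5-layer
column, observed every 6 steps. These are desk-scale study conditions
chosen once; the test suite uses shorter windows (8–24 steps) and 1–5
layers for the properties that do not need the full cycle, and the stated
problem sizes appear in each test.

What passing twin tests does and does not show: they demonstrate that the
derived TLM/adjoint pair is exact for this model, that the minimization
behaves as the theory predicts (monotone quadratic costs, zero-innovation
fixed point, truth recovery under full observability as the background
constraint loosens, improvement at the observation locations), and that
the whole pipeline is a pure function of configuration and seed. They do
not demonstrate skill on real observations, with misspecified error
statistics, or in the presence of model error — all explicitly out of
scope.

## Numerical choices and limitations

* Finite-difference oracle: central, step $10^{-6}(1 + |x_i|)$, tolerance
  $10^{-6}$ — the standard truncation/rounding compromise.
* Dot-product discrepancies are normalized by
  $|\langle \mathbf{M}u, w\rangle| + 10^{-30}$; the tiny guard only
  matters for degenerate zero products.
* Text serialization uses the shortest decimal representation that
  round-trips to the identical double, so the determinism claims survive
  a write/read cycle.
* The dense Jacobian builder refuses states above a configurable cap
  (default 5000): materializing $\mathbf{M}$ defeats the purpose at
  realistic sizes, and the error message points to the matrix-free paths.
* Known limitations: forward-mode AD costs one model evaluation per seed,
  so the adjoint remains more expensive than a hand-coded reverse sweep —
  the segmented construction reduces, but does not remove, this gap;
  second derivatives are out of scope (no hyper-dual numbers); the column
  physics is a deliberately minimal stand-in for a circulation model; and
  diagonal $B$ ignores the balance constraints an operational system would
  impose.
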