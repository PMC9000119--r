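---
title: "Pacemaking two-variable cell models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pacemaking two-variable cell models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacecell)
```

## The models and their assumptions

`pacecell` simulates two minimal phenomenological descriptions of
excitable cells together with their pacemaking (self-oscillatory)
variants.

**Aliev–Panfilov family.** The excitable AP model drives a normalized
potential $u$ with a cubic source $k\,u(u-a)(1-u)$ and a slow recovery
variable $v$ whose rate $\varepsilon(u,v) = \varepsilon_0 + \mu_1
v/(u+\mu_2)$ shapes restitution; $c_t = 1/12.9$ maps model time to
milliseconds. The pacemaking variant (pAP) replaces $-a$ in the
*potential equation only* by an independent control parameter $b$
(`ap_params(b = )`); the recovery equation keeps $a$, because the
published parameter tables list both. With $b>0$ the cubic nullcline's
left branch crosses into $u<0$, a positive-$u$ equilibrium appears at the
intersection with the recovery nullcline, and the cell leaves rest
through a Hopf bifurcation into a stable limit cycle whose rate grows
almost linearly with $b$.

**Corrado / Mitchell–Schaeffer family.** The potential carries separate
inward ($\tau_{in}$) and outward ($\tau_{out}$) current scales gated by
$h$; the pacemaking variant (pCN) smooths the original Heaviside gate
into the Boltzmann sigmoid $h_\infty(u) = [1-\tanh((u-u_{gate})/u_s)]/2$
with slope factor $u_s$ and, as in pAP, shifts the cubic by an
independent $b$. The gate relaxes over
$\tau(u) = \tau_{open}\tau_{close} / [\tau_{open} -
h_\infty(\tau_{close}-\tau_{open})]$. This interpolation is implemented
exactly as published even though its limits are asymmetric
($\tau(h_\infty{=}0)=\tau_{close}$ but
$\tau(h_\infty{=}1)\ne\tau_{open}$ for the tabulated constants);
`cn_params(tau_scheme = "convex")` selects the plain convex blend
instead, and both choices give indistinguishable behavior in every
experiment we ran. In the $(u,h)$ plane the pCN cycle runs clockwise
(the gate closes while the potential is high), whereas the pAP cycle in
$(u,v)$ runs counterclockwise — `orbit_orientation()` checks the signed
loop area.

Tissue is monodomain-style: $I_{ext} = \nabla\!\cdot\!(D\nabla u)$
discretized to a sparse conservative operator (zero row sums under
no-flux and periodic boundaries). Passive, non-regenerative tissue obeys
$du/dt = -c_t S u + I_{ext}$ with $S = 26$.

## Parameters that matter

* `b` (dimensionless, both families): excitability/pacemaking control.
  Isolated-cell defaults: pAP oscillates for $0 < b \lesssim 0.07$
  (quiescent at $b \le 0$ — the Hopf onset), pCN for roughly
  $0.07 \lesssim b \lesssim 0.5$ with the 0D constants.
* AP family: $k{=}8$, $a{=}0.13$, $\varepsilon_0{=}0.002$, $\mu_1{=}0.2$,
  $\mu_2{=}0.3$ (0D/1D) or $0.5$ (SAN) — `cell_preset()` lists every
  tissue preset. Larger $\mu_2$ slows recovery and lowers the rate.
* CN family: $\tau_{in},\tau_{out},\tau_{open},\tau_{close}$ in ms set
  the upstroke, repolarization and gate recovery scales; the intestinal
  ICC preset is two orders slower ($16/200/1500/1800$ ms) than the
  cardiac 0D set ($0.3/6/120/150$ ms), giving slow waves at tens of
  cycles per minute.
* Coupling: `d = D/dx^2` (1/ms) for strands; diffusion tensors in
  mm²/ms for sheets (SAN type 1 anisotropy $D_y{:}D_x = 1{:}0.208$);
  interlayer conductance $d^{IM} = 6\times10^{-3}$/ms in the intestine.

Some published tissue-parameter rows print only the entries that differ
from the row above; the presets adopt that inherit-from-row-above
reading (`?cell_preset` documents each) and every field can be
overridden.

## Numerics

Forward Euler (FE) is used for exploration and everywhere the stability
criterion $D\Delta t/\Delta x^2 < 1/(2N)$ holds (`stability_check()`;
the internal guard uses the equivalent Gershgorin bound
$\Delta t\,\max_i |W_{ii}| < 1$, which reduces to the textbook form on
isotropic grids). Backward Euler (BE) solves
$x - x_t - \Delta t\,\mathrm{RHS}(x) = 0$ with a damped Newton iteration
on each node's analytic $2\times2$ reaction Jacobian, wrapped in a
fixed-point sweep over the coupling current for tissues; both iterate to
an absolute tolerance of $10^{-7}$ within at most 20 inner iterations,
and exceeding the cap raises an error rather than clamping. The time
base is a 64-bit step counter times $\Delta t$, so 60-s runs at
$\Delta t = 10^{-4}$ ms accumulate no additive drift.

`error_norms()` quantifies FE-vs-BE accuracy as relative $L_2$ and
$L_\infty$ norms over one cycle plus a relative frequency error over the
whole run. Two design points deserve note. First, the single cycle
compared is the **first** complete cycle from the shared initial state,
with the test trace aligned at its own mid-level crossing: later cycles
are dominated by the accumulated phase drift between step sizes, which
would swamp the waveform error by two orders of magnitude and is already
captured — cleanly — by the frequency error. Second, traces on different
grids are aligned by linear interpolation onto the reference grid.
Representative 10-s values at $\Delta t = 0.1$ ms against a BE
$\Delta t = 10^{-4}$ ms reference: pAP ($b{=}0.03$) 0.14% / 0.85% /
0.19%; pCN ($b{=}0.2$) 0.38% / 2.7% / 0.16%; each norm falls roughly
tenfold per decade of $\Delta t$ (first-order convergence).

Cycle features (`extract_features()`) are delimited by upward crossings
of the mid-amplitude level, computed iteratively (global extrema first,
then the level implied by averaged per-cycle extrema); crossing times
are refined by linear interpolation. Fewer than three complete cycles
after the settling time (default 30 s) is reported as *quiescent*, a
result, not an error. APD90 is time spent above
$POP - 0.9\,(POP - MDP)$ per cycle; $DI = CL - APD90$ by construction.

Equilibria (`find_equilibria()`) come from dense multi-start damped
Newton iteration on a $50\times50$ grid over the search box, merging
duplicates within $10^{-6}$ and requiring residual norms below
$10^{-10}$; for the CN family the gate is confined to $[0,1]$. This
replaces formal continuation software: it finds the points, while
stability is probed dynamically (simulation from the equilibrium) where
a test needs it.

## Synchronization protocols

A pacemaker loaded by $n$ cables of 20 excitable cells is built by
`build_star()`. Integer loads are explicit strands (and remain bitwise
identical forever if started identically — a test asserts this);
fractional loads use one representative strand whose current into the
pacemaker is scaled by $n$, exactly equivalent for synchronized integer
loads and continuous down to $n = 0.5$. `measure_sync()` counts
mid-level upcrossings of the pacemaker and of strand cell 16 (away from
the sealed end) and declares 1:1 entrainment when the count ratio
differs from one by less than one part in the cycles counted — the
published criterion is verbal, so this count-based rule is our
operational definition. `scan_sync_limits()` brackets the 1:1 region(s)
in $b$ per coupling value with a coarse scan plus bisection
(tolerances $10^{-4}$–$10^{-3}$ matching the families' $b$ scales), and
`sync_vs_coupling()` implements the fixed-$b$ protocol with state
carried between coupling values so hysteresis can be probed in both
scan directions. A noteworthy model property: the loaded pAP pacemaker
is suppressed outright over much of the $(d, b)$ plane, so its 1:1
regions are islands rather than bands.

## The tissue experiments

**SAN (2D).** A 10 mm × 10 mm sheet, 200×200 nodes at
$\Delta x = 0.05$ mm, atrial AP cells everywhere except a central
ellipse of pAP cells (half-axes 3 and 1 mm, long axis 30° off the fiber
$y$ axis; the anisotropy tensor stays grid-aligned). Type 1 is bare and
anisotropic; type 2 is isotropic with a 0.25-mm passive ring pierced by
four 1-mm exit pathways centered on the ellipse axes (geometry
under-specified in print, so configurable). Heterogeneous interfaces
take the arithmetic mean of the two nodes' diffusion coefficients,
keeping the operator symmetric. Runs start from $u=v=0.01$, count
per-node threshold crossings over the last 2 s of a 4–5 s run (no
duration is published; 4 s yields ≥3 atrial beats), and map the first
propagated beat as the activation sequence — a later window would
assign different beats to different nodes. At $D_y = 0.090$ mm²/ms the
sheet entrains 1:1 (identical counts at every node) at ≈100 cycles/min;
at $D_y = 0.048$ the atrium follows 2:5. A 1.5×-coarsened mesh
(133×133, $\Delta x = 0.075$ mm, $\Delta t$ scaled by $1.5^2$ to keep
the stability margin) reproduces both regimes and the rate to ~1% and is
what the acceptance script and tests run; 2×-coarsening starts to break
wavefronts and is not used for regime calls.

**Intestine (3D as dual-layer sheet).** A 1200-mm tube of circumference
44 mm, cut and unrolled: two stacked 176×4800 grids at
$\Delta x = 0.25$ mm (ICC and SMC layers), each internally diffusive
($D^I = 5\times10^{-5}$, $D^M = 8\times10^{-4}$ mm²/ms), coupled
pointwise by $d^{IM}$. The cut seam is periodic along the circumference;
the published text says periodic "along $y$", but the unrolled-tube
geometry implies the circumferential axis, so that is the default with
`periodic = "y"` available. The ICC excitability falls exponentially
with distance from the duodenum, $b_{CN}(i) = 0.4 + 1.3\,
e^{-i\Delta x/680}$ (`bcn_gradient()`), spanning 1.70 down to 0.62 over
the simulated half. A transient conduction block (state reset to
$u = 0.001$, $h = 0.5$ for one step over a 22 mm × 40 mm rectangle at
$y_0 = 580$ mm) triggers dysrhythmia; the published block time appears
as both 8100 s and 5100 s in different sections, so 8100 s is the
default and both are configurable. Full-horizon runs (11,600 s over
1.7 M nodes) are cluster-scale, so the package's default experiment
divides lengths and the gradient decay by 10 (16×480 nodes) — this
preserves the intrinsic-frequency span (the $b$ range is identical) and
the entrainment phenomenology, and a 1500-s run shows the formation of
constant-frequency plateaus; the tests assert the plateau structure on a
further-halved domain (4×240 nodes, `scale = 20`), which reproduces the
same plateau at the same rate, with the full geometry available via
`intestine_experiment(scale = 1)`.

## Known limitations

* **High-excitability quiescence.** With the tabulated constants, both
  pacemaking families lose their limit cycle at the top of the printed
  control ranges in this implementation: the isolated pAP cell is
  quiescent by $b \approx 0.08$, and the coupled ICC–SMC pair's cycle
  folds (leaving a stable focus that captures the standard initial
  state) near $b_{CN} \approx 1.35$–$1.65$ — below the duodenal
  endpoint $b_{CN}(0) = 1.70$. The distal intrinsic frequencies match
  published values closely (10.2 cpm at $b = 0.62$; ~7.5–8 cpm at the
  full-length end), and the cycle frequency just below the fold is
  16–18 cpm, bracketing the published 17.5 cpm proximal value, so the
  gradient-to-frequency map is right where the cycle exists; but the
  proximal end itself rests. Consequently the proximal zone of the
  intestine sheet stays quiescent and the entrained plateau profile
  covers only the distal part. We verified the behavior is insensitive
  to scheme (FE/BE), step size (2.5 → 0.1 ms), the gate-τ interpolation,
  a logistic versus tanh gate, and initial conditions; we have not found
  a reading of the published constants that removes it.
* The SAN sheet entrains at ≈100 cpm against a published "about 120";
  the atrial parameter row is ambiguous in print and the measurement
  window unstated, either of which could account for the gap. The
  regime dichotomy (1:1 vs 2:5 exit block) is exact.
* The synthetic experiments emulate idealized geometry — no diffusion
  gradients or cellular heterogeneity inside the SAN, a regular
  cylinder for the gut — so passing tests demonstrate the models'
  collective dynamics, not fidelity to any animal's anatomy.
* Electromechanical and thermodynamic coupling, formal bifurcation-type
  classification, and adaptive or higher-order time stepping are out of
  scope.
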