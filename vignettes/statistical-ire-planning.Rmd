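---
title: "Statistical treatment planning for irreversible electroporation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical treatment planning for irreversible electroporation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(ireplan)
```

## The problem

Irreversible electroporation (IRE) ablates tissue by delivering trains of
short, high-amplitude electric pulses between needle electrodes: above a
critical local field strength the cell membrane is permanently
permeabilized and the cell dies, without the thermal damage of
radiofrequency or cryo ablation.  Classical treatment-planning models are
*deterministic*: they draw a single iso-field contour (a demarcation line)
and declare everything inside it dead.  Real tissue — especially tumor
tissue — is a heterogeneous population of cells of different sizes,
stages and orientations, so the probability of death rises *smoothly*
with the local field.  A statistical cell-death law predicts, around the
fully ablated core, a rim of partially damaged tissue that the
single-threshold model cannot represent at all.  Knowing the extent of
that transition rim is exactly what a planner needs when the goal is to
kill every tumor cell while sparing surrounding structures.

`ireplan` implements this statistical planning workflow end to end:

1. fit a Peleg–Fermi survival model with pulse-number-dependent
   parameters to survival-versus-field data (`fit_protocol()`);
2. solve the dimensionless 2-D steady-state field equation for a
   two-needle electrode configuration (`solve_potential()`);
3. compose the two into a spatial map of cell-survival probability and
   kill/transition/survive zone metrics (`survival_map()`,
   `ablation_metrics()`, `parametric_sweep()`).

## The survival model

The core dose–response law is a Fermi (logistic) curve in the local field
magnitude $E$:

$$ S(E; n) = \frac{1}{1 + \exp\!\big[(E - E_c(n))/A(n)\big]} $$

where $S$ is the surviving fraction $N/N_0$, $E_c(n)$ is the field at
which half of the population is killed after $n$ pulses, and $A(n)$ sets
the width of the live-to-dead transition.  Both parameters decay
exponentially with the number of pulses,

$$ E_c(n) = E_{co}\, e^{-k_1 n}, \qquad A(n) = A_o\, e^{-k_2 n}, $$

with intercepts $E_{co}$, $A_o$ (the extrapolation to $n = 0$) and
per-pulse rates $k_1, k_2 \ge 0$.  The non-negativity of the rates
encodes the physical requirement that extra pulses can only increase
damage at a fixed supra-threshold field.  The exponential form for
$A(n)$ mirrors the one for $E_c(n)$; the literature describes only its
"typical behavior", and the mirrored decay is the simplest form with the
right intercept and monotonicity.  Pulse length is handled by fitting a
separate parameter set per pulse length — there is no interpolation
across pulse lengths, and `parametric_sweep()` refuses to guess one.

A catalog of the older one-dimensional inactivation laws (first-order
kinetics, the two Hülsheger forms, Weibull) is available through
`classical_survival()` for comparison; none of them carries the pulse
number as an explicit parameter, which is why the Peleg–Fermi form is
the planning default.

### Fitting

`fit_protocol()` is a two-stage estimator:

* **Stage 1** fits $(E_c, A)$ independently for each pulse-number group
  by Levenberg–Marquardt nonlinear least squares *on the survival scale*
  (residuals $\hat S - S$), with analytic Jacobians.  Survival
  observations are bounded in $[0,1]$, so their errors are bounded too;
  a logit-scale fit would blow up the influence of saturated wells.
  Starting values are data-driven and deterministic: $E_c^{(0)}$ is the
  field whose observed survival is nearest 0.5, $A^{(0)}$ a quarter of
  the field span.  A group is rejected as unidentifiable when it has
  fewer than 4 records, fewer than 3 distinct fields, or all survivals
  on one side of the transition (above 0.95 or below 0.05) — such data
  carry no information about $E_c$.
* **Stage 2** fits the exponential decays to the per-$n$ series of
  $\hat E_c$ and $\hat A$, initialized by log-linear regression and
  refined by least squares on the parameter scale, and reports the
  $n = 0$ intercepts.  A fitted rate that comes out slightly negative
  (|rate| < `clamp_tol` = 1e-3 per pulse) is treated as sampling noise,
  clamped to zero and recorded in the model's provenance; a larger
  negative rate aborts with a data-quality error rather than silently
  producing a survival law that worsens with fewer pulses.

### Uncertainty

Parameter uncertainty comes from a nonparametric bootstrap: records are
resampled with replacement within each pulse-number group and the whole
two-stage pipeline is refit (default 200 replicates, fixed seed,
caller's RNG stream untouched).  The reported 95% intervals are
normal-theory intervals, estimate $\pm\, 1.96 \times$ bootstrap SE,
truncated at the parameter-space bound 0.  With only a dozen records
per group, raw percentile intervals of the resampling distribution are
systematically too short for these smooth estimators; the symmetric
normal-theory construction is the better-calibrated default at this
sample size, and the package's acceptance suite verifies its calibration
directly (each parameter's interval covers the generating truth in at
least 90% of 100 simulated replicate datasets).

## The field model

During a pulse the tissue is resistive and the potential obeys
$\nabla\cdot(\sigma\nabla\phi) = 0$; with homogeneous, isotropic
conductivity this is the Laplace equation, and $\sigma$ cancels
entirely.  Pulse lengths (tens of microseconds and up) are long against
the ~1 µs membrane charging time, so a steady-state DC solve per pulse
is appropriate.  Lengths are scaled by the electrode separation $L$ and
fields by the reference $E_{co}$, giving the single dimensionless
control parameter

$$ C = \frac{V}{E_{co}\, L}, $$

the applied voltage in units of the voltage that would put the average
field at the $n=0$ kill threshold.  The electrodes are gauged
antisymmetrically at $\pm C/2$ (only the difference is physical, and
antisymmetry makes the midplane potential exactly zero — a free
correctness check).  The outer rectangle is insulating (homogeneous
Neumann), the physical condition for a tissue block with no other
current path.

### Numerics

The solver is a 5-point finite-difference scheme on a uniform
node-centered grid (default $h = 0.01$, i.e. 100 nodes per electrode
separation; tolerance $10^{-8}$ on the relative residual).  Nodes whose
centers fall inside or on an electrode circle are Dirichlet nodes;
interior nodes adjacent to a circle use Shortley–Weller fractional arms
to the exact circle intersection.  This last choice matters: imposing
the electrode potential on the staircase set alone costs an order of
accuracy at the curved boundary, while the fractional-arm correction
restores second-order convergence globally (arm fractions are floored at
$10^{-6}$ to keep the system well scaled).  The linear system is solved
by a sparse direct factorization with one step of iterative refinement
if needed; the contract is the residual, which lands near machine
precision.  Field magnitudes are central differences at interior nodes
and one-sided differences next to electrodes and domain edges;
electrode-interior nodes are not tissue and carry no field.

### Validation against an exact solution

Two parallel cylinders at $\pm C/2$ in an *unbounded* medium have a
closed-form potential by the classical two-wire image construction:
line charges at $(\pm a, 0)$, $a = \sqrt{1/4 - r^2}$, make both circles
exact equipotentials, and

$$ \phi^*(x,y) = \frac{C/2}{\cosh^{-1}(1/2r)}\,
   \ln\frac{\rho_-}{\rho_+}. $$

`analytic_two_cylinder()` exposes this solution and its analytic
gradient.  One subtlety: the oracle lives in an unbounded medium, while
the production solver's insulating box confines the current, and the two
genuinely differ far from the electrodes — that difference is domain
truncation, not solver error.  The validation mode
`solve_potential(..., outer_bc = "analytic")` therefore imposes the
oracle's trace on the outer rectangle, making the discrete and exact
problems identical up to discretization.  In that configuration the
acceptance suite verifies sub-1% relative $L_2$ agreement at the default
grid, approximately quadratic error decay over the refinement ladder
$h = 0.02, 0.01, 0.005$, and sub-2% field-magnitude error outside a
$2h$ collar around the electrode surfaces, where the staircase error
concentrates and metrics are excluded.

## Composing the two: survival maps and zone metrics

Because survival is scale-invariant in the field ($S$ depends only on
$E/E_{co}$, $n$), the dimensionless field solution feeds the
dimensionless survival law directly:
$S(\text{node}) = \mathrm{fermi}(E^*(\text{node});\, e^{-k_1 n},\,
(A_o/E_{co})\, e^{-k_2 n})$.
`ablation_metrics()` partitions the tissue nodes into three zones:

* **kill**: $S \le s_\text{kill}$ (default 0.05),
* **transition**: $s_\text{kill} < S < s_\text{live}$,
* **survive**: $S \ge s_\text{live}$ (default 0.95),

with areas in units of $L^2$ (node count × $h^2$; electrode interiors
excluded).  The 5%/95% defaults are the conventional symmetric bounds
for "complete" kill and "unaffected" tissue; both are configurable and
always echoed in the output, since no canonical values exist.  The three
areas partition the tissue domain exactly — every node is classified
once — and the deterministic single-threshold area at $E_c^*(n)$ always
lies between the kill area and kill + transition.  Indeed the
deterministic demarcation set *is* the $S \le 0.5$ region of the
statistical map, node-exactly, because $S = 0.5$ exactly at
$E^* = E_c^*$ and the logistic is strictly monotone; what the
deterministic model misses is not the contour but everything the
transition zone says about partial damage around it.

`parametric_sweep()` evaluates a protocol grid $(n, C, t)$ for one
geometry.  The field equation is linear, so the geometry is solved once
at $C = 1$ and rescaled — the package asserts that rescaled and directly
solved metrics agree to solver tolerance.  On the reference two-needle
geometry the sweep reproduces the expected qualitative orderings: kill
area grows strictly with $n$ and with $C$, the transition area grows
with $C$, and a strictly positive transition rim exists for every finite
$A^*$ — the structural feature absent from every deterministic model.

**Domain size.**  Areas are only measurable if the domain contains the
region being measured.  The solver default is a 4L × 4L box, ample for
the kill zone; at the largest voltage in the reference sweep
($C = 2.5$, $n = 50$) the *outer* boundary of the transition rim
(the $S = s_\text{live}$ contour) leaves that box and the transition
area is clipped.  The package's sweep validation therefore uses an
8L × 8L domain, on which the rim is contained (the survive zone stays
strictly positive across the whole voltage sweep) and halving $h$ moves
the areas by well under a percent.  Users studying high-$C$ protocols
should size the domain so the survive zone remains visible; the metrics
report makes this easy to check.

## The synthetic data generator

No raw survival table is available in the source literature, so the
package ships a generator (`generate_dataset()`) that emulates the
*shape* of the published single-cell prostate (DU-145) experiments: 12
field levels spanning 0.1–3.3 kV/cm, pulse counts $\{1, 2, 4, 10\}$,
one record per (field, $n$) cell, with a known Peleg–Fermi truth behind
it.  The default noise model is binomial counting noise with 200 cells
per assay well — survival assays count cells, so the binomial is the
natural error model, with variance $S(1-S)/N$ vanishing at the
extremes; a clipped-Gaussian alternative exists for robustness testing.
The seed expands into an independent substream per (field, $n$) cell,
so extending the design does not perturb existing draws.
`default_illustrative_model()` provides fixed parameter sets (one per
pulse length, thresholds inside the experimental envelope, longer
pulses given lower thresholds and faster decay) used by documentation
and tests; they are illustrative, not measurements.

What the generator does **not** emulate bounds what passing tests can
claim: real assays have between-well and between-day variation, dose
spacing chosen by the experimenter rather than an even grid, possible
deviations from the Fermi shape itself, and — most importantly — single
cells in suspension are not cells in tissue.  Parameter-recovery results
here demonstrate that the estimator is correct and calibrated *under the
stated model*, not that the illustrative parameters describe any real
tissue.  For clinical use, per-tissue parameters must be fitted to real
data; the caveat travels with every fitted-model file via its
provenance block.

## Degenerate inputs and tie-breaks

* Logistic exponents are clamped at ±745, so extreme fields saturate
  cleanly to $S = 0$ or 1 without overflow.
* A node exactly on an electrode circle counts as electrode
  (inside-or-on classification).
* $S = 0.5$ exactly (a node exactly on the demarcation contour) counts
  as killed in the deterministic map and in the $S \le 0.5$ region —
  the same inclusive convention on both sides, which is what makes the
  node-exact equivalence hold.
* Zone thresholds are inclusive on the outer classes
  ($S \le s_\text{kill}$, $S \ge s_\text{live}$).
* `n` is a non-negative real in the decay curves (the fitted model can
  be extrapolated continuously, and $n = 0$ reads off the intercepts),
  but datasets require integer $n \ge 1$.
* An electrode disk must cover at least 4 grid nodes or the solve
  refuses to run ("under-resolved"); at the default $h$ the reference
  geometry has ~10 nodes per radius.

## Problem sizes

The shipped test-suite and validation runs use: 41×41 to 81×81 grids
for unit checks of map algebra and geometry; the refinement ladder
$h = 0.02, 0.01, 0.005$ on the 4L × 4L domain (201² to 801² nodes) for
the solver-oracle comparison; a 401² grid on the 8L × 8L domain for the
reference protocol sweep; and 100 replicate datasets × 200 bootstrap
replicates for the calibration study.  These sizes were chosen so the
full validation runs comfortably on a laptop-class single core while
keeping discretization effects well below the tolerances being
asserted.

## Known limitations

* Homogeneous, isotropic conductivity only; the field equation supports
  spatially varying $\sigma$, but the solver does not expose it.
* 2-D cross-sections of long parallel needles; no 3-D solver.
* No Joule-heating/thermal-damage coupling — pulse protocols near the
  thermal limit need a coupled model this package deliberately omits.
* No reversible-electroporation or transient membrane-charging
  modeling (steady-state DC per pulse).
* Pulse length selects a fitted model; nothing is interpolated between
  pulse lengths.
* The illustrative parameter values are for demonstration only.
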