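---
title: "Wave-arc delivery modelling: trajectories, timing, complexity and gamma QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-arc delivery modelling: trajectories, timing, complexity and gamma QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavearc)
```

## The delivery technique being modelled

O-ring linacs carry two rotation axes: the gantry and the ring. Rotating
both during beam-on yields a *wave arc* — a noncoplanar arc that sweeps
through (gantry, ring) angle space without any couch motion, combined with
dynamic MLC modulation. `wavearc` models the computational core of this
technique at desk scale: trajectory geometry and discretization, delivery
timing under machine constraints, MLC plan complexity, and diode-array-style
gamma verification. It deliberately contains no clinical dose engine; the
bundled dose model is a labelled toy.

## Trajectory model

A trajectory is an ordered list of *manipulation points* (MPs) in
(gantry, ring) space; clinical practice uses 5–8. Only the ring may reverse
direction, and only at MPs; the gantry is monotone. Each *sub-arc* (segment
between consecutive MPs) must satisfy, per the vendor rule set encoded in
`trajectory_rules()`:

* the **dominant angle** — the axis with the larger absolute span, gantry
  winning ties — spans a multiple of 4°, and at least 24°;
* the ring rotates at most 1° per gantry degree (ratio cap 1);
* an optional list of forbidden rectangles in (gantry, ring) space stands in
  for the vendor's unpublished ring–table collision map.

The tie-break and the interpretation of "multiple of 4°" as applying to the
*span* (not absolute MP coordinates) are fixed, documented conventions.

Discretization spaces beams along the **Euclidean norm**
$\sqrt{\Delta g^2 + \Delta r^2}$ of the path, not along the gantry alone —
the defining difference from coplanar VMAT spacing. Per sub-arc of norm $L$
the segment count is $n = \max(1, \mathrm{round}(L/24))$ with half-up
rounding (a fixed convention — R's default round-half-even would make the
beam count depend on parity), giving uniform spacing $L/n$; MPs are always
beams. Each beam then receives exactly two control points at $\pm\tfrac14$
of the adjacent inter-beam norm, clamped at the trajectory ends. The
$\pm\tfrac14$ offset realises "two CPs per beam, equally distributed
between neighbours" with a testable rule; with uniform spacing $s$ it
produces the pattern $\{0, s/4, 3s/4, 5s/4, \dots\}$. When the ring is
constant the whole construction collapses to a plain VMAT angular grid,
which the tests exploit as an independent oracle.

## Delivery-time models

Two solvers share one constraint set (`machine_constraints()`): gantry
0.1–6 °/s, ring 0.1–2.5 °/s, MLC leaves ≤ 4 cm/s at isocenter, and a
discrete dose-rate table within 150–400 MU/min. The true table entries are
not public; the default is a 50 MU/min grid and is configuration, not a
claim.

**Planner model** (`tps_time_estimate()`): one constant gantry speed and one
constant dose rate over the whole arc (preserving constant MU per CP), ring
speed modulated per sub-arc through the fixed span ratio. The fastest
constant gantry speed is capped jointly by the gantry maximum and by
$v_{ring}^{max} \cdot g_k / r_k$ over sub-arcs; the required dose rate is
snapped *up* to the nearest table entry and the time re-evaluated as
$\max(T_{motion}, \mathrm{MU} \cdot 60 / DR)$. This closed form is the fixed
point a bisection-plus-snap search would return, and it is verified against
an exhaustive search over the dose-rate table × a 0.001 °/s speed grid.

**Controller model** (`controller_simulate()`): the machine re-optimises at
every MP, so each sub-arc independently takes
$t_k = \max(g_k/v_g^{max},\; r_k/v_r^{max},\; \mathrm{MU}_k \cdot 60 / DR^{max})$,
the highest dose rate being selected by default and reduced to the table
entry giving a simultaneous finish when axis speed is limiting. Between
sub-arcs the axes stop for 0.1 s while the dose rate dips to ~100 MU/min;
the MU delivered during the dip is debited from the following sub-arc, so
cumulative MU is conserved (well inside the 0.5 MU bookkeeping tolerance).
Traces are emitted at 100 Hz with piecewise-constant speeds — no
acceleration modelling, as no acceleration limits are published. Within a
sub-arc the *trace* carries the exact constant rate $\mathrm{MU}_k/t_k$
(which may fall between table entries) so that MU bookkeeping is exact; the
discrete table entry chosen by the selection rule is reported separately in
`dose_rates`.

Two numerical notes. First, on heavily dose-rate-limited sub-arcs the axes
travel at their slowest in-range speeds and then hold at exactly zero while
the beam finishes, keeping every sample either in-range or zero. Second,
per-sub-arc optimisation is *not* uniformly bounded by the single-dose-rate
planner: a plan mixing motion-limited and dose-rate-limited sub-arcs sums
per-sub-arc maxima, which can exceed the planner's maximum of sums. The
conservatism inequality (controller ≤ planner) is a theorem for single
sub-arcs and for homogeneous multi-sub-arc regimes, and that is exactly
what the test suite asserts.

## Modulation complexity score

For each control point, with $p_i$ the positions of the $N$ open leaves of
one bank and $p_{max} = \max p - \min p$:

$$\mathrm{LSV}_{bank} = \frac{\sum_{i=1}^{N-1}\big(p_{max} - |p_{i+1}-p_i|\big)}{(N-1)\,p_{max}},
\qquad \mathrm{LSV} = \mathrm{LSV}_{left}\cdot\mathrm{LSV}_{right}$$

$$\mathrm{AAV} = \frac{\sum_{j\,\in\,open}(r_j-l_j)\,w_j}{\sum_{j\,open\,anywhere}\big(\max_{cp} r_j - \min_{cp} l_j\big)\,w_j}$$

$$\mathrm{MCS} = \sum_i \frac{\mathrm{AAV}_i+\mathrm{AAV}_{i+1}}{2}\cdot
\frac{\mathrm{LSV}_i+\mathrm{LSV}_{i+1}}{2}\cdot\frac{\mathrm{MU}_i}{\mathrm{MU}_{total}}$$

MCS is 1 for an unmodulated arc and decreases with modulation. Conventions
frozen here: a bank with fewer than two open leaves or zero spread scores 1;
closed pairs are excluded from position sets and carry no area; disjoint
open runs are concatenated in leaf-index order; MU weighting is per CP
*gap*; and in `mcs_arc()` an all-closed CP contributes a zero term (AAV 0,
degenerate LSV 1) while `lsv()` alone on such an aperture is an error. The
implementation is pinned to an independently coded straight-from-formula
oracle on 100 seeded arcs to 1e-12.

## Minimum 3D gamma index

Measurements live on two orthogonal diode planes; the reference is the full
3D planned grid. Per diode above the low-dose threshold (20 % of the
planned-grid maximum, applied to the *measured* diode dose — the planned
maximum is used as "maximum expected dose" because measured maxima are
noisy):

$$\gamma = \min_{r}\sqrt{\Big(\frac{D_m - D_p(r)}{0.03\,D_{max}}\Big)^2 +
\Big(\frac{\lVert r - r_{diode}\rVert}{3\,\mathrm{mm}}\Big)^2}$$

with global normalization and trilinear interpolation of the planned dose.
The candidate set is frozen as: the diode position, a fine local lattice of
step $\mathrm{DTA}/10$ within radius $\min(\gamma_0, 3)\cdot\mathrm{DTA}$
(where $\gamma_0$ is the dose-only gamma at the diode — beyond that radius
the distance term alone exceeds $\gamma_0$, and a gamma above 3 is far past
the pass threshold), and every voxel center. The optimized search prunes
candidates whose distance term alone exceeds the running best; this is
mathematically identical to exhaustively evaluating the same set, which the
tests confirm to 1e-9 on grids up to $41^3$. $\gamma \le 1$ counts as a
pass. Dose pulses are binned to CPs by planned cumulative MU with pro-rata
splitting at boundaries; angular correction factors are pluggable
(identity by default plus an illustrative cosine falloff — real detector
factors are proprietary, which is also why published clinical passing rates
are out of reach of this toolkit).

## Plan metrics

Coverage is the PTV fraction at or above prescription (closed threshold);
low-dose spillage is the whole-grid volume at ≥ 50 % of prescription over
the PTV volume (the PTV itself is included — the convention is documented
because the source definition does not state it). $D_{x\%}$ uses the
near-maximum convention: the dose to the hottest $x\%$ of the structure,
interpolated on the descending sorted voxel-dose curve. Voxels are uniform
rectilinear with no partial-volume weighting (a documented limitation).
Technique comparisons use the classical paired two-tailed t-test
(`stats::t.test` with a zero-variance guard) and half-up integer rounding
of percent changes at report level only.

## Synthetic generators and what they do (not) show

`generate_plan()` draws rules-conformant trajectories: gantry spans are
multiples of 4° in [24°, 48°]; ring spans are 0 or a multiple of 4° of at
least half the gantry span (shallow nonzero tilts would drive the coupled
ring speed below its 0.1 °/s minimum on dose-rate-limited arcs, and deep
tilts match the observation that only a minority of CPs carry large ring
rotation), alternating direction at MPs within ±60°. MU defaults to 300
split equally per CP (the planner's constant-MU-per-CP assumption);
aperture modulation is a smooth seeded perturbation scaled by a
`complexity` knob in [0, 1], with `complexity = 0` giving an identical
aperture everywhere and hence MCS exactly 1. All generators are pure
functions of their seed and restore the caller's RNG state.

`toy_dose_engine()` projects apertures along the beam direction with a
Gaussian penumbra and exponential depth attenuation. It is linear in MU and
rotates with the plan — enough to exercise the QA chain — but it is not a
dose calculation: no scatter, no heterogeneity, no output factors. Passing
gamma tests on its output demonstrates the *verification machinery*, not
clinical accuracy, and the published per-site dose statistics cannot be and
are not reproduced here.

Test problem sizes (chosen so the full suite runs in seconds on one core):
dose grids of $11^3$–$21^3$ voxels at 4–10 mm spacing, tens of diodes per
plane, plans of 1–4 sub-arcs, 100–200 seeded repetitions for the
property suites. The exhaustive-search cross-checks use the same sizes.

## Known limitations

* No acceleration or servo dynamics in traces; speeds are
  piecewise-constant.
* Dose-rate table contents, MP ramp shape, detector angular factors, diode
  layout and collision maps are proprietary: all are configuration with
  documented defaults, not claims about the vendor systems.
* The DICOM-RT reader supports explicit-VR little-endian files only and
  maps the ring angle from a configurable tag (no standard attribute
  exists).
* Sub-arcs may not cross the 0°/360° gantry seam; split them beforehand.
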