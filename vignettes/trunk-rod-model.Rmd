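---
title: "A rod-network model of the elephant trunk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rod-network model of the elephant trunk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trunkdyn)
```

## The model

`trunkdyn` treats the elephant trunk as a muscular hydrostat discretized
into ten elliptical cross-sections of five lumped point masses each — a
center node `O` and four outer nodes (dorsal `P`, ventral `Q`, laterals
`B`, `A`) — giving 50 nodes and 150 translational degrees of freedom. The
nine regions between consecutive sections are the *segments*; each is a
truncated pyramid with non-parallel rectangular bases. Nodes are connected
by rods that sustain only axial load:

* **longitudinal** rods join same-role nodes of adjacent sections (the
  muscle analogue of the longitudinal musculature; the center `O–O` chain
  is included, since without it the backbone centers would have no
  first-order axial support — radial rods are perpendicular to the
  backbone);
* **radial** rods join each section's center to its four outer nodes
  (the radial/transverse musculature: their contraction narrows the
  cross-section);
* **connective** rods close the perimeter of each section between
  adjacent outer nodes (passive connective tissue).

At rest the trunk hangs vertically, tip down, as the animal rests: the
backbone tangent points along $-Z$, the dorsal axis along $+X$, gravity is
$-Z$, and planar reaching unfolds in the $X$–$Z$ plane. This orientation is
not cosmetic: with a horizontal rest backbone, no rod crossing a section
gap has a vertical component, so the truss could not carry gravity at
first order. Hanging, the longitudinal rods carry the weight in tension,
which also stabilizes the shear-soft inter-section modes geometrically.

Each rod's elastic behavior is the axial tension
$\tau = k\,(\ell - \ell_0)$ with $k = EA/\ell_0$, applied along the rod's
*current* direction — the elastic term of the governing equation is
configuration dependent ($K(q)$), i.e. a geometrically nonlinear truss.
This matters: with a linearized passive term (stiffness matrix frozen at
rest), any sustained pushing (negative) longitudinal force is laterally
unstable, because the active forces do follow the deformed geometry while
the passive ones would carry no stabilizing geometric tension. Elongation
and bending trials then diverge with an e-folding time of tens of
milliseconds. The assembled rest-configuration matrices (global stiffness
$150\times150$, lumped diagonal mass) are still built exactly as the
element formalism prescribes — local $6\times6$ axial elements, rotated by
direction cosines and scatter-added — and serve as the linearization for
the estimation machinery below.

The equation of motion is
$M\ddot q = F_{ext} + F_{int}(q, f) - C\dot q$, integrated with an
adaptive Dormand–Prince Runge–Kutta (4/5) scheme. Two optional damping
terms are provided, both default-on and both set to zero for conservation
audits:

* mass-proportional $C = c\,M$ with $c = 2\,\mathrm{s^{-1}}$, damping slow
  gross motion;
* a Kelvin–Voigt axial term per rod, $\beta k \,\dot\ell$ with
  $\beta = 0.005\,\mathrm{s}$, damping the 20–40 Hz ringing of the stiff
  axial and radial modes that piecewise-constant force input would
  otherwise excite (mass-proportional damping cannot reach those modes:
  its modal damping ratio falls as $c/2\omega$).

## Physical parameters

| parameter | default | unit | note |
|---|---|---|---|
| total mass | 100 | kg | allocated to sections by truncated-cone volume, then equally to each section's five nodes |
| backbone length | 1.85 | m | spans the nine modelled segments (~0.2056 m each); the anatomical tip beyond the last section is excluded |
| base / tip radius | 0.15 / 0.05 | m | linear taper; tip value matches the trunk tip's physical radius |
| Young's modulus | 1e6 | N/m² | apparent modulus, constant by default; a proximal/middle/distal profile (3 segments each) is configurable |
| rod area fractions | 0.15 / 0.10 / 0.05 | – | longitudinal / radial / connective share of the local section area $\pi a b$; an apparent modulus alone does not fix per-rod stiffness, so areas must be chosen to make $k$ finite |
| classification thresholds | 20, 0.02 | deg/m, m | bending and elongation thresholds; 0.02 m is 10% of a resting segment |
| sampling rate | 100 | Hz | trials and controller |
| force bound | ±5000 | N | box bound on estimated active forces |

All defaults live in `default_config()`; the YAML/JSON loader validates
strictly (unknown keys are errors — a typo in a physical constant must not
silently become a default).

The pipeline examples and the acceptance script use the decreasing
stiffness profile $E = (10, 6, 3)\times10^5$ N/m² for
proximal/middle/distal regions: sensitivity analysis of this model family
found decreasing distal stiffness improves trajectory prediction, and it
also reduces the ventral-rod compression that large distal bends induce.

## Kinematics

A cross-section is eight parameters: center, intrinsic Z-Y-X Euler angles,
and semi-axes $(a, b)$, $a \ge b$. The local frame convention is: local
$x$ = ellipse-plane normal (backbone tangent), local $y$ = lateral
in-plane axis, local $z$ = dorsal in-plane axis. Segment length is the
Euclidean distance between consecutive centers. The bend angles
$(\alpha, \beta)$ are the components of the axis–angle vector of the
relative rotation between consecutive section frames, projected on
section $i$'s dorsal and lateral axes respectively (exact for planar
motion, continuous for small rotations; the tangent component — torsion —
is discarded, as twisting movements are out of scope). Curvature
components are $K_\alpha = \alpha/L$, $K_\beta = \beta/L$ (deg/m) and
$K = \sqrt{K_\alpha^2 + K_\beta^2}$. Positive curvature bends toward the
dorsal side, so that curvature correlates positively with the
dorsal-minus-ventral force difference.

Ellipse fitting from marker points is a two-stage fit — total-least-squares
plane, then the Halir–Flusser stabilized direct algebraic ellipse fit
in-plane. Dorsal-only marker arcs are accepted down to 5 points, with a
conditioning warning below 120° of arc coverage.

A movement is classified **B** (bending) when maximum curvature exceeds
20 deg/m anywhere while no segment lengthens by more than 0.02 m over its
first-sample value, **BE** when both thresholds are exceeded, and
**OTHER** otherwise (twisting classes are detected only as OTHER).

## Inverse dynamics

Per timestep, the active rod forces are the solution of a bounded
nonlinear least-squares problem: integrate the dynamics over one sampling
interval with candidate forces held constant and minimize the squared
discrepancy between simulated and observed node displacements. The
unknowns are 3 per segment — dorsal and ventral longitudinal forces and a
radial force split equally over the distal section's four radial rods
(27 for the full trunk). The lateral and center longitudinal rods carry
the mirrored mean force $F_{m_L} = (F_{L,dorsal} + F_{L,ventral})/2$:
longitudinal musculature surrounds the whole cross-section, and without
this axial drive commanded elongations are unrealizable (the passive rods
resist, the ring warps, and the centers cannot move axially at first
order).

Tracked degrees of freedom default to all three coordinates of every free
node. Three observations force this choice: the radial force has no
first-order effect on the centers (so the ring must be tracked for
identifiability); the lateral ring nodes move in $Y$ whenever the section
narrows, even in planar movements (with $Y$ untracked the optimizer can
crush the ring invisibly); and the actively driven center chain must be
observed or it drifts unchecked. Error *metrics*, in contrast, remain 2D
(X, Z), as planar trajectory errors are conventionally reported.

Two stabilizing terms augment the per-step objective, both configurable:

* a dt-scaled terminal-velocity mismatch (weight 1): matching only
  displacements leaves the step's final velocity free, which destabilizes
  sequential tracking;
* a small fixed least-effort penalty ($10^{-6}$ per newton): the
  underactuated per-step problem (27 unknowns against ~300 residuals) has
  near-null co-contraction directions along which forces otherwise
  random-walk to the bounds. The penalty selects the minimal-effort
  solution, the standard resolution of muscle redundancy.

The solver exploits the structure of the model: everything is linear
except the active-force direction matrix $B(x)$. Phase 1 iterates linear
least-squares solves against the exact matrix-exponential step response
(no ODE integration), refreshing $B$ at the linearly predicted mid-step
geometry. Phase 2 runs Levenberg–Marquardt on true integrated residuals
with that analytic Jacobian; phase 3 re-linearizes $B$ at the true
mid-step geometry while it pays off. On model-generated trajectories the
whole scheme recovers generating force histories essentially exactly
(relative RMS well below 1%).

Sequential estimation over a trial has two modes. For model-generated
trajectories (`"data"`), each step starts from the data-synchronized
state, which keeps the per-step problems decoupled — the right mode for
parameter recovery. For measured/kinematic trials (`"simulation"`), each
step starts from the evolving simulation and targets the next observed
sample with a fractional gain (0.1) on the accumulated error: the
estimation then acts as a per-step tracking controller. A full one-step
correction would be deadbeat $1/\mathrm{dt}$ feedback — it saturates the
force bounds and destabilizes; the fractional gain recovers drift over a
few samples. The velocity target carries the matching closing rate,
since demanding the data velocity while also demanding a position
correction is contradictory within one sample.

The per-step problem is underactuated, so part of each observed step is
simply not achievable; those components accumulate into a tracking lag
that grows toward the tip — the simulated tip tracks observed tips to
about 4–5% of trunk length under the default conditions, with distal
curvature errors considerably larger than proximal ones. This
proximal-to-distal degradation is characteristic of per-step myopic
force scheduling in lumped trunk models generally, not of the optimizer: exhaustive per-step optimization
cannot reduce it (multi-step corrections would require transiently
counterproductive motion that a one-step objective never chooses).

## Stereotypical laws and reaching

Per segment, three ordinary-least-squares laws are fitted on aligned
shape and force series: curvature and length each on
$(\Delta F_L, F_R, F_{m_L})$, and the radial force on
$(\Delta F_L, F_{m_L})$. Units are deg/m, m and N; adjusted $R^2$ uses
the standard $(n-1)/(n-p-1)$ correction. Laws are fitted per movement
class (pooling across that class's trials); no multiple-testing
correction is applied to coefficient inference, which is reported as-is.
The three laws form a determined $3\times3$ linear system mapping a
desired $(K, L)$ to $(\Delta F_L, F_R, F_{m_L})$; solving and
substituting back reproduces the inputs to numerical precision, and the
system errors out when its condition number exceeds $10^{12}$.

The reaching controller interpolates commanded curvature and length as
time-convex combinations of initial and final values at 100 Hz, solves
the law system at each sample, distributes the forces to rods
(`FmL ± dFL/2` on the dorsal/ventral longitudinal rods, mirrored `FmL`
on lateral and center rods, `FR/4` on each radial rod of the segment's
distal section), and integrates forward holding each force piecewise
constant. The schedule has exactly $T f_s$ pieces; the strict index range
never evaluates $t = T$, so the final commanded shape is the last sample
— an `include_endpoint` flag appends the exact target. The loop is open:
no simulated shape is fed back.

Driven by laws fitted on three bending trials, the controller reaches a
commanded final shape with a tip error of about 7% of trunk length; the
closed loop reproduces the inverse-dynamics simulation it was fitted on
to sub-millimeter accuracy, so almost all of that error is the tracking
lag inherited from the inverse stage.

When computing a *target tip position* for a commanded shape, use the
forward-kinematic reconstruction of the command
(`backbone_from_shape()`). Reconstructing a tip from *measured* shape
series instead carries a chord-composition bias (the measured per-segment
rotations need not bisect the actual chords) that compounds to ~0.18 m
over nine segments — an artifact of the reconstruction convention, not of
control quality.

## The synthetic generator

`generate_reaching_trial()` emulates the structure of a mocap-derived
dataset: 10 section rows at 100 Hz, resting segments of ~0.2 m, planar
bending of tens of deg/m, elongation up to 30%, optional Gaussian center
noise, all randomness through an explicit seed. Shapes ramp from rest to
peak with a minimum-jerk time profile. Curvature is distally weighted by
default (`curvature_profile = "front"`, tip-segment weight 1 so the
classification boundary in peak curvature is unchanged): real reaching
movements concentrate curvature toward the tip, and holding a large
*uniform* bend would put the whole ventral rod chain into compression
beyond the available gravity tension — a laterally unstable configuration
the symmetric per-segment actuation cannot stabilize, and one real trunks
avoid. For BE trials every section radius scales as
$\sqrt{L_{rest}/L(t)}$, which preserves the elliptic-frustum volume
analytically (uniform elongation across segments).

What the generator does **not** emulate: mocap artifacts (marker
occlusion, gap-filling), non-planar twisting classes, trunk-specific
kinematic statistics beyond the distal curvature weighting, and any
force-level ground truth for kinematic trials (dynamically consistent
ground truth comes from `generate_ground_truth_forces()`, which
forward-simulates seeded smooth force histories). Tests passing on
synthetic trials therefore validate the machinery and its internal
consistency, not fidelity to any particular animal's data.

## Numerical choices

* Integration: `deSolve::ode(method = "ode45")`; trial-level tolerances
  default to `rtol 1e-6 / atol 1e-9`; estimation residuals use
  `1e-9 / 1e-12` for recovery oracles so that force errors cannot hide
  below the integrator noise floor, and `1e-6 / 1e-9` in tracking mode
  where the residual floor is set by model–data mismatch instead.
* The matrix-exponential step propagator is computed once per
  structure/step-size at dt/2 (full-step matrices follow by squaring) and
  reused across all steps.
* Ellipse fits reject collinear inputs; rotation-vector extraction is
  continuous at the identity and handles angles near π via the diagonal.
* Hexahedral segment volumes decompose into six tetrahedra sharing the
  body diagonal from corner 1 to corner 7 — a fixed convention, so
  volumes are bit-reproducible.
* Problem sizes: parameter-recovery oracles run on a 3-section, 0.4 m,
  10 kg trunk; pipeline and acceptance runs use the full 10-section trunk
  with 2 s trials at 100 Hz.

## Known limitations

* No oblique rods, torsion, or non-planar movement classes; no contact or
  self-collision; no muscle physiology (activation dynamics, force–length
  curves).
* The per-step myopic estimation cannot plan multi-step corrections;
  distal tracking degrades accordingly.
* The base section is rigidly fixed, so commanded base-ring deformations
  (e.g. the base's share of a BE narrowing) are unreachable by
  construction.
* Real-data layouts for the deposited dataset are mapped by
  `load_deposited_trial()` against a documented synthetic fixture; first
  contact with the actual deposit may require adjusting the loader.
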