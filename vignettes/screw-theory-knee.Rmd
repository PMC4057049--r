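---
title: "Screw-theoretic analysis of the knee: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screw-theoretic analysis of the knee}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screwgait)
library(dplyr)
```

## The model

`screwgait` treats the knee during the stance phase of gait as a joint with
one instantaneous degree of freedom. Both the motion of the joint and the
forces acting on it are represented by *screws*: lines in space with an
associated pitch, written in Plücker coordinates $(\mathbf d, \mathbf m)$
with direction $\mathbf d$ and moment $\mathbf m$. An instantaneous motion
is a *twist* (screw + amplitude, rad/s); a force system is a *wrench*
(screw + intensity, N). The central pairing is the **virtual coefficient**
of two screws,

$$R(p,q) = (h + h')\cos\theta - a\sin\theta
         = \mathbf d_p \cdot \mathbf m_q + \mathbf d_q \cdot \mathbf m_p,$$

with $h, h'$ the pitches, $\theta$ the angle and $a$ the common-perpendicular
offset between the axes. It measures the rate of work a unit wrench on one
screw does through a unit twist about the other. Two screws with
$R(p,q) = 0$ are *reciprocal*: a force along a reciprocal line cannot
disturb motion about the screw. The package uses the full mutual-moment
convention (no factor $\tfrac12$); Ball's classical virtual coefficient is
half this value. Because $\theta \in [0,\pi]$ with $a \ge 0$ cannot carry
the sign of the mutual moment, the geometric form is evaluated internally
with the *signed* perpendicular offset along
$\mathbf d_p \times \mathbf d_q$; the coordinate form is authoritative and
the geometric form is retained as a cross-check
(`virtual_coefficient(p, q, geometric = TRUE)`).

A body free to twist about a single screw is constrained by the
five-dimensional system of screws reciprocal to it. For the knee this
reciprocal manifold is modelled by six zero-pitch lines — ACL, PCL, MCL,
LCL and the medial/lateral tibiofemoral contact normals P1, P2 — each
reciprocal to the instantaneous axes of the knee (IAK). A ground-reaction
wrench lying in the span of those lines is neutralized by constraint
reactions while doing no work on motion about the IAK; solving

$$\textstyle\sum_i x_i S_i + W = 0$$

for the reaction intensities $x_i$ yields the medial and lateral contact
forces as the intensities on P1 and P2 (`decompose_wrench()`).

### The cylindroid

All screws linearly dependent on two given screws form a two-system whose
axes sweep a cubic ruled surface, Ball's cylindroid (Plücker's conoid). Its
two *principal screws* intersect orthogonally, carry the extremal pitches
$h_\alpha, h_\beta$ of the system, and give the canonical frame in which a
screw at direction angle $\phi$ has pitch
$h_\alpha\cos^2\phi + h_\beta\sin^2\phi$ and crosses the nodal line at
$z = (h_\beta - h_\alpha)\sin\phi\cos\phi$, so every axis satisfies
$z(x^2 + y^2) = (h_\beta - h_\alpha)\,x y$. `build_cylindroid()` derives the
principal screws from first principles: the pitch of a combination
$c_1 p_1 + c_2 p_2$ is the Rayleigh quotient of the $2\times2$
mutual-moment matrix against the direction Gram matrix, so the principal
screws are the eigenvectors of that generalized eigenproblem. (Published
closed-form coordinates for the principal screws of this construction are
sometimes typeset inconsistently; for zero-pitch generators the
first-principles result is $h_\alpha = -b\tan\sigma$ and
$h_\beta = +b\cot\sigma$, with $b$ half the common-perpendicular distance
and $\sigma$ half the angle between the generators, and the package tests
pin exactly that.)

The IAK itself arises on a cylindroid: the relative twist of the thigh with
respect to the shank is the 6-coordinate difference of the two segment
twists, hence a screw of the two-system spanned by the segment ISAs
(`relative_twist()`). The composition convention is worth stating: for two
twists applied to one body, `compose_twists()` returns the *replacing*
single twist $dv_1 p_1 + dv_2 p_2$; the closure form in which the three
twists sum to zero holds with the equilibrating twist being this resultant
with negated amplitude. Axis and pitch are identical either way; only the
amplitude sign differs, and the orientation of an instantaneous axis is a
convention, not an observable.

### The perception–action policy

Choosing which line to lean on is cast as a finite Markov decision process
over screw states: the stage cost of choosing screw $q$ in state $p$ is
$|R(p,q)|$ — the energy a unit wrench on $q$ spends through a unit twist
about $p$ — and the optimal return satisfies the Bellman recursion
$f(p) = \min_q\{R(p,q) + \gamma f(T(p,q))\}$ (`value_iteration()`). The
classical statement of this recursion carries no discount or horizon; the
package implements absorbing terminal states with an optional discount
$\gamma \in (0,1]$ (default 1 with terminals) and documents this as its own
completion of the formulation. Ties break toward the lowest action index
and are recorded. The frame-by-frame specialization is the
reciprocity-seeking stance policy (`stance_policy()`): among candidate
lines, pick the one most nearly reciprocal to the current IAK, i.e. the
line along which a force disturbs the joint least.

A companion diagnostic, `special_config_ratios()`, flags the special
configuration of a one-DOF system in which actuators lose control of the
end-effector freedom: the twist-amplitude ratio collapses to 0 while the
wrench-intensity ratio diverges.

## Estimating the IAK from markers

Per-frame segment poses come from an orthogonal Procrustes fit of each
marker cluster against its reference frame (`rigid_fit()`, `fit_poses()`);
clusters must have at least three non-collinear markers. The per-frame
twist is the finite-displacement screw of the relative pose between frames
$i - s$ and $i + s$, reduced by the matrix logarithm (`twist_from_poses()`
with span $s$, one-sided at the ends). For noiseless sampling of a constant
screw motion this is exact at any span, which is what makes the synthetic
closures in the test-suite meaningful.

Two numerical gates matter:

* **Low-velocity gate.** Frames whose rotation increment is below 0.1° are
  reported as translation-dominated (infinite pitch, axis point undefined)
  and excluded from cylindroid construction and the policy trace. The
  direction of a finite helical axis is undefined at zero rotation, so any
  threshold is a judgement call; 0.1° keeps machine-precision recovery on
  clean data while refusing to report meaningless axes.
* **Span under noise.** With marker noise the axis-direction error of a
  finite helical axis scales inversely with the rotation increment, so the
  estimator's span should be chosen to give increments of roughly 15–20°.
  At the default study conditions (60° sweep over 1 s sampled at 100 Hz,
  eight markers on a 0.3 m cluster, 1 mm isotropic noise) a span of 25
  frames gives a median axis error of about 0.3°. An optional centred
  moving average (`smooth_markers()`) is the only filtering the package
  does.

## The synthetic study conditions

`gen_stance_trial()` forward-constructs everything the pipeline estimates,
so ground truth is exact by construction rather than simulated dynamics:

* **Geometry** (`gen_constraint_geometry()`): six zero-pitch lines in the
  tibia frame (x lateral, y anterior, z up, origin at the joint centre),
  contact points 25 mm either side of the centre, ligament attachments at
  adult-knee dimensions, 2 mm seeded jitter. Six independently drawn lines
  would span the whole screw space; the rank-5 constraint manifold of a
  one-DOF joint is a geometric condition, so the generator draws a
  physiological flexion axis first (mediolateral, small pitch) and tilts
  each nominal line minimally into its reciprocal plane. The set's
  one-dimensional reciprocal system then *is* that axis, which doubles as
  the trial's IAK.
* **Kinematics**: the shank cluster is stationary (the foot is planted in
  stance) and the thigh cluster rotates about the IAK with a smooth 15°
  flexion profile; 100 Hz sampling, 0.6 s stance with 0.1 s swing padding.
  With a stationary shank the relative twist equals the thigh twist, so
  the noiseless marker replay recovers the IAK to machine precision — the
  honest closure for a desk-scale validation.
* **Loads**: per-frame constraint intensities follow the classic
  double-hump vertical profile at 1.2 body weight peak for a 70 kg
  subject, split 65/35 medial/lateral, with 10–40 N constant ligament
  tone; the GRF wrench of each frame is $W = -\sum_i g_i S_i$ with
  $g_i \ge 0$, reduced to force-plate form (force, centre of pressure on
  the $z=0$ plate, free vertical moment) exactly. Contact-line directions
  point downward, so recovered compressive contact intensities are
  positive and the vertical GRF is upward-positive. Frames whose vertical
  force falls below the 20 N stance-detection threshold are zeroed so a
  written-and-reread trial reproduces the same stance mask and truth.

One consequence of six lines of rank 5 deserves emphasis: the reaction
intensities are statically indeterminate along a one-dimensional gauge
(any $g + c\nu$ with $\sum_i \nu_i S_i = 0$ produces the same wrench).
`decompose_wrench()` resolves this by minimum-norm least squares, reporting
the rank so that a user supplying five independent lines gets the unique
solution; the generator correspondingly stores the minimum-norm
representative of its applied combination as the recovery truth and keeps
the raw nonnegative loads alongside (`truth$applied`). Physically the gauge
freedom lives mostly in ligament tone — contact forces are far better
determined — and negative intensities (tension at a contact) are reported
and flagged rather than clamped.

What the synthetic trials do *not* emulate: soft-tissue artifact (markers
are rigid), muscle dynamics and co-contraction (muscle lines enter only
through `replace_wrench()`), ligament elasticity, multi-DOF knee motion,
and measured instrumented-implant loads. Passing the recovery tests
therefore demonstrates correctness of the geometry and algebra under the
stated model, not accuracy on real gait data.

## Numerical choices

* Rank and nullspace cutoffs: singular values below $10^{-10}$ of the
  largest are zero (`reciprocal_system()`, `decompose_wrench()`,
  `rigid_fit()` degeneracy checks).
* Reciprocity tolerance: $10^{-9}$ in SI metres (`is_reciprocal()`).
* Normalization: screws are stored with $|\mathbf d| = 1$, or
  $\mathbf d = 0, |\mathbf m| = 1$ for infinite pitch; a linear combination
  with $|\mathbf d| \le 10^{-12}$ becomes an infinite-pitch screw, and a
  fully vanishing combination a flagged null twist/wrench.
* The wrench-feasibility check in `decompose_wrench()` rejects a wrench
  whose virtual work on the IAK exceeds `tol` (relative to wrench
  magnitude): such a wrench would move the joint and no constraint
  reaction can balance it.
* Value iteration converges in sup norm to `tol = 1e-10` from an all-zero
  start; for nonnegative costs the sweeps are monotone, which the tests
  assert.
* Transmission ratios on the cylindroid are parameterized as
  $\lambda_\alpha/\lambda_\beta$ with $\lambda_\beta = 1$; the default
  sampling band 0.3–2.5 is the physiologically feasible range of
  thigh-versus-shank velocity ratios.

## A worked pass through the pipeline

```{r pipeline}
trial <- gen_stance_trial(seed = 42)
results <- run_pipeline(trial$markers, trial$grf, trial$geometry)
results

results$forces |>
  filter(stance) |>
  select(time, medial_N, lateral_N, residual) |>
  slice(c(1, 15, 30))

max(abs(results$forces$medial_N - trial$truth$intensities$P1))
```

The residual column is the 6-coordinate norm of the unbalanced wrench and
sits at roundoff for consistent inputs; the recovery error against the
stored truth is likewise numerical zero. `autoplot(results$forces)` draws
the medial/lateral curves, `autoplot()` on a `conoid_samples()` tibble the
ruled surface in plan view.

## Known limitations

* The IAK estimator is a finite-displacement method; it reports the
  average screw over the span, which biases curved axis paths at large
  spans. Choose the span to balance noise against path curvature.
* The equilibrium model is quasi-static: inertial terms of the shank/foot
  are ignored, as is load sharing with structures outside the six-line
  manifold.
* TRC input is supported in its common tab-delimited form (mm or m); C3D
  binary capture files are out of scope — export to TRC first.
* The decision-process module is deliberately small (finite states,
  deterministic transitions); it formalizes the policy notion rather than
  providing a general dynamic-programming toolkit.
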