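---
title: "Methods: active elastic solids and velocity-field topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active elastic solids and velocity-field topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(defectflow)
```

## The model

`defectflow` studies how an epithelial monolayer, released from quiescence,
self-organizes into long-range polar order. The monolayer is modeled as an
*active elastic solid* (AES): cells are beads permanently connected by
springs, each self-propelled along a unit polarity vector that turns toward
its own velocity. In the overdamped limit,

$$\dot{\mathbf R}_i = V_c \mathbf P_i + \frac{1}{\zeta}\mathbf F_i,
\qquad
\dot{\mathbf P}_i = \gamma\,(\mathbf P_i \times \dot{\mathbf R}_i)\times \mathbf P_i,$$

where $V_c$ is the propulsion speed (35 µm/h by default), $\zeta$ the
substrate friction (set to 1, defining the force unit), $\mathbf F_i$ the
elastic force, and $\gamma$ the turning rate. For unit $\mathbf P$ the double
cross product equals $\dot{\mathbf R} - (\mathbf P\!\cdot\!\dot{\mathbf R})\mathbf P$,
which is how it is evaluated. Springs store

$$U(r_{ij}) = \tfrac{K}{2}(d_{ij}-r_{ij})^2 + B\,(d_{ij}-r_{ij})^4,$$

with rest lengths $d_{ij}$ drawn from the packed geometry and confined to
$[0.8d, 1.2d]$ around the mean cell spacing $d = 22.5$ µm. The quartic term
suppresses compressional instabilities and over-stretching at large strain.

Two dimensionless groups control the physics: the rigidity
$\tilde K = K d/(\zeta V_c)$ (defaults to 40; values of order 10–50 keep
deformations moderate) and the turning rate $\tilde\gamma$ (defaults to 1.5;
polar order requires roughly $\tilde\gamma \gtrsim 1$).

### Nondimensionalization of the turning rate

$\gamma$ carries units of 1/µm (it multiplies a velocity to give a rotation
rate). The package measures time in units of $d/V_c$, making
$\tilde\gamma = \gamma d$ the unique dimensionless turning-rate group: at
$\tilde\gamma = 1.5$ the alignment rate is
$\tilde\gamma V_c/d \approx 2.3\,\mathrm{h^{-1}}$. This choice reproduces the
phenomenology the model is meant to capture — ordering over a ~10 h window
through a defect-rich intermediate. Treating the printed value 1.5 as
$\gamma$ in 1/µm directly would give an alignment rate of
$\gamma V_c \approx 52\,\mathrm{h^{-1}}$, which locks the monolayer into a
rigid flock within minutes and never shows the defect-mediated coarsening
stage; we therefore read it as the $\gamma d$ group.

### The quartic coefficient

No numeric value for $B$ is fixed by the physics above; the package sets
$\tilde B = B d^3/(\zeta V_c) = \tilde K/4$, which makes the quartic term
equal the harmonic one at 50% strain and negligible below 20% strain, i.e.
inert in the moderate-deformation regime and active exactly where it is
needed. It is exposed as `b_tilde` in `sim_params()`.

### Boundary conditions

Confinement is a circular domain of radius $R$. Particles beyond $R$ feel a
linear inward spring (`boundary_stiffness`, default equal to $K$). Within a
strip of width `boundary_turn_zone` (default $d/2$) the polarity is rotated
*away from the outward normal* at rate
`boundary_turn_rate` $\times \sin(\text{angle to the normal})$, but only
while it has an outward component: tangential and inward orientations are
torque-free. This rectified form lets cells stream along the wall — the wall
condition of the vortex state — while still preventing escape. The turning
law's strength (default 5 h⁻¹) and functional form are modeling choices; the
qualitative behavior (boundary-guided confinement, inward early migration,
late swirl) is robust to them, the quantitative core position is not.

### Integration and stability

Explicit Euler with the polarity renormalized to unit length after every
step. The default time step is derived from the stiffest rate present:
spring relaxation ($\approx 6K/\zeta$ per particle at coordination six),
polarity turning ($\gamma \times$ typical speed), boundary stiffness, and the
advective limit $V_c\,\mathrm{d}t \le 0.05\,d$. At the default parameters
this gives $\mathrm{d}t \approx 0.0013$ h; `run()` aborts with a diagnostic
if any particle moves more than $0.5d$ in one step. Halving the step changes
the final polar order by well under 2% (tested). Because rest-length
clamping leaves a little residual stress in the as-built lattice, runs begin
with 0.25 h of propulsion-free relaxation so that $t=0$ is a mechanical
equilibrium and the initial speed equals $V_c$.

## The lattice

Disordered, globally isotropic networks are built in two stages.
`pack_disks()` inserts differently sized repulsive disks (radius factors
uniform in $[0.8, 1.2]$) at 60% of target size and grows them iteratively,
alternating deterministic overlap relaxation with zero-temperature
Metropolis kick moves. `build_network()` connects Voronoi-adjacent pairs
(Delaunay edges, via `deldir`), prunes hull slivers longer than $1.5d$
(restoring any edge whose removal would disconnect the graph), and assigns
each spring the rest length of its initial extension clamped to
$[0.8d, 1.2d]$ — a stress-free start wherever no clamping occurs.

The builder's default domain radius gives every cell $0.932\,d^2$ of area,
calibrated once so that the mean spring rest length equals $d$ to within a
fraction of a percent across seeds; at a fixed externally imposed radius the
mean scales with the imposed density instead. Packings show no hexatic order
($\langle|\psi_6|\rangle < 0.45$ versus 1 for a crystal) and statistically
isotropic edge directions.

## Velocity-field topology

Analysis operates on PIV-like gridded velocity fields.
`grid_particle_velocities()` mirrors the interrogation-window sampling: a
165 µm square window centered on each node of a 66 µm grid (99 µm overlap
between consecutive windows), each node reporting the mean velocity of the
particles it contains; empty windows are masked.

`winding_number()` implements the eight-neighbor algorithm: the velocity
directions $\theta_k = \operatorname{atan2}(v_k, u_k)$ of the eight
neighbors, traversed anticlockwise from the top-left in mathematical axes
(x right, y up — the winding sign depends on this convention, which is why
it is fixed package-wide), are lifted to $[0, 2\pi)$, consecutive
differences are range-adjusted to $(-\pi, \pi]$, and their sum over the loop
divided by $2\pi$ is the charge: +1 for a vortex of either spin, −1 for a
saddle, 0 elsewhere. Charges of magnitude above one are reported verbatim.

`detect_frame()` merges same-charge detections closer than 165 µm by
single-linkage clustering (one defect per cluster, at the member centroid).
Merging is restricted to like charges: merging opposite charges would erase
exactly the pairs about to annihilate. `filter_persistent()` keeps a
detection only if it belongs to a chain of same-charge detections in
consecutive frames (each within the link radius of the previous) at least
two frames long.

## Tracks and pair events

`link_defect_tracks()` links detections between successive frames by greedy
mutual-nearest-neighbor matching within the link radius, same charge only;
gap closing is disabled because the persistence filter already removes
single-frame flicker. `track_velocities()` reports, for stable tracks of at
least 25 time points, the Euclidean path length divided by the number of
time points, converted by the frame interval.

`call_events()` calls an annihilation for a (+1, −1) track pair whose
deaths coincide within one frame and 165 µm, and a proliferation for the
symmetric condition on births. Three safeguards matter at analysis scale:

* tracks ending in the last frame (or starting in the first) are not deaths
  (births), and endpoints within one interrogation window of the field
  border are excluded — leaving the field of view is not annihilation;
* annihilating pairs must have *approached*: the pair coexists for at least
  three frames with shrinking separation (mutual attraction is what defines
  the event; newborn pairs must recede symmetrically);
* for the reversal analysis, `annihilation_reversals()` additionally
  requires the dipole signature. Superposing an ideal $\pm 1$ pair,
  $\theta = \phi_+ - \phi_- + \psi$, gives direction $\psi - \pi$ between
  the defects versus $\psi$ far away, *for any spin phase*: the corridor is
  always anti-parallel to the surrounding flow. Detections whose corridor is
  not anti-aligned (> 90°) with the ambient annulus are winding hits inside
  unresolved turbulent texture, not dipole pairs, and are dropped.

`reversal_angle()` then measures the circular-mean flow direction in the
rectangle between the pair's final positions at the death frame and one
frame after disappearance, returning the absolute change. For genuine
dipoles this is the corridor adopting the ambient direction — the ~180°
reversal that accompanies "instantaneous" polar ordering.

## Order metrics

`mean_speed()` is the mean velocity magnitude. `correlation_function()`
implements the cos-weighted spatial correlation exactly as defined for this
analysis: for integer lags $r$ along the x grid axis,

$$C(r) = \frac{1}{N_x N_y (N_x - r)} \sum_{x+r<N_x}\sum_y
\left[\delta u\,\delta u' + \delta v\,\delta v'\right]
\cos(\theta - \theta'),$$

with fluctuations about the frame's spatial mean velocity (the reference for
"fluctuation" is a package choice; a temporal mean would need multiple
frames). Lags run along +x only and are averaged over rows, as the
$(N_x - r)$ normalizer implies; the estimator is isotropic in expectation
(tested by 90° field rotation). `correlation_length()` normalizes by
$C(0)$, fits $a\,e^{-r/b}$ by profiled least squares over lags $r \ge 1$
(the amplitude is solved analytically on a log-spaced grid of decay scales,
then polished; plain Gauss–Newton stalls on noisy late-time curves), and
reports $\xi$ where the *fitted* curve crosses 0.5, i.e.
$\xi = b\ln(2a)$. If the fitted curve never reaches 0.5 in range, $\xi$ is
right-censored at the maximum lag and flagged; a spatially constant field
has zero fluctuations and is reported as maximally correlated (normalized
correlation 1, censored $\xi$).

`vorticity_field()` is $\omega = \partial v/\partial x - \partial u/\partial y$
with central differences inside and one-sided differences at the edges
(rigid rotation at rate $\Omega$ gives $2\Omega$; positive =
counterclockwise). `region_direction()` is the per-frame circular mean of
flow directions in a rectangle, flagged undefined when the resultant
vanishes.

## Kinematics

`relative_motility()` registers all trajectories by subtracting the anchor
cell's displacement (pure translation — no rotation component, matching the
effect of image registration on a small field of view) and reports each
other cell's summed per-frame step length divided by the window duration:
101 frames at 4-min intervals span 6.7 h by default. The anchor itself is
excluded from the output. `pair_msd()` selects track pairs closer than
23 µm in the first analyzed frame, requires both tracks complete over the
window, and fits an ordinary least-squares line to the mean squared
pair distance versus time; the slope (µm²/h) is reported without any
solid/liquid categorical call — independent 2D random walks of per-frame
step SD $\sigma$ give slope $4\sigma^2$ per frame.

## Synthetic data: what it does and does not emulate

`compose_defect_field()` builds exact point-defect configurations by angle
superposition — ground truth for position, charge, spin, and loop winding.
`correlated_noise_field()` perturbs a uniform flow direction with a Gaussian
field whose autocorrelation is $\approx e^{-r/\lambda}$, generated by
spectral filtering with the exponential kernel's 2D spectral density
$S(k) \propto (1+k^2\lambda^2)^{-3/2}$ on an enlarged periodic domain (exact
target correlation in expectation, $O(N\log N)$). The default perturbation
amplitude is $\sigma = 0.2$ rad: in this small-angle regime the direction
correlation transfers linearly to the velocity correlation, whereas larger
$\sigma$ adds a cosine-weighting baseline of order $\sigma^2$ at long range
(for full-circle random directions the cos-weighted estimator has a
structural baseline of one half — a property of the estimator, not a bug of
the generator). `synth_trajectories()` provides rigid, diffusive, and mixed
relative-motion regimes with known parameters.

These fixtures validate every analysis operation against exact ground
truth. They do not emulate PIV estimation noise, uneven cell density,
division/extrusion, or image artifacts; passing on them shows the
*analysis* is correct, not that PIV upstream of it would be.

## Validation problem sizes and what desk scale shows

The package's end-to-end checks run confined monolayers of N = 2,500 cells
(domain radius ≈ 600 µm) at $\tilde K = 40$, $\tilde\gamma = 1.5$, observed
every 4 min for 6 h, across at least five seeds — sizes chosen so the whole
cycle of disorder → defect-rich coarsening → single surviving vortex
completes well inside the observation window. Reference-scale geometry
(N = 100,000, R ≈ 3.5 mm) is supported by the same code path.

Desk scale reproduces: charge-balanced defect populations, coarsening by
pair annihilation to a modal final count of one +1 defect, anticorrelation
of defect count with both mean speed and correlation length, and ~180°
corridor reversal across isolated dipole annihilations. Two finite-size
caveats are documented rather than hidden. First, the surviving vortex core
wanders: with the domain only ~3.5 correlation lengths across, the core
explores a substantial fraction of the disk instead of sitting pinned at
the center, and on multi-day timescales the vortex can destabilize into a
collective sloshing mode that expels the core entirely — at reference scale
the core stays central. Second, most called annihilations happen early, while the background is
still ordering, and many of them are tight pairs that drop below the 66-µm
detection resolution while their flow structure persists — detection
deaths rather than completed annihilations, whose measured "reversal" is
near zero because the field hardly changes across them. The
dipole-signature filter above isolates the events for which corridor
reversal is defined (those reverse by 160–180°), but such validated events
are rare at this domain size, so population averages over all called
events sit well below 180° and fluctuate strongly between seeds.

## Known limitations

* The model has no cell shape, division, death, or biochemical signaling,
  and no noise terms in the equations of motion; determinism given a seed
  is exact.
* Half-integer (nematic) defects are out of scope; the winding analysis is
  polar.
* The correlation estimator inherits finite-domain bias from subtracting
  the frame's spatial mean (about −12% on a 64×64 grid spanning ~10
  correlation lengths, independent of $\lambda$); single-frame $\xi$
  estimates are right-skewed, so medians over frames or seeds are the
  robust summary.
* The tracker is a transparent mutual-nearest-neighbor linker; it is not a
  general-purpose multiple-hypothesis tracker and will split tracks under
  large inter-frame motion relative to the link radius.
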