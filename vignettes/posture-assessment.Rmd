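---
title: "Upper-limb posture measurement and rehabilitation assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upper-limb posture measurement and rehabilitation assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armassess)
```

# Scope

`armassess` implements a complete desk-testable pipeline for marker-less
upper-limb motion analysis in rehabilitation: two synchronized depth-camera
skeleton streams are calibrated and fused, denoised, fitted with a
rigid-body model of both arms by crossbreed particle swarm optimization
(CBPSO), and summarized two ways — geometrically, as the reachable-workspace
relative surface area on a shoulder-centered unit sphere, and by a learned
movement-quality score from a spatial–temporal graph convolutional network
(STGCN) extended with ConvLSTM-derived self-attention. Because clinical
recordings cannot ship with a package, a synthetic motion and sensor
simulator generates all inputs, with known ground truth, under a documented
impairment model.

This vignette records the science and every design decision that was
genuinely open.

# The rigid-body model

The upper limbs are modeled as two 9-degree-of-freedom (DOF) serial chains
hanging from a torso base frame fixed at the neck: 2 DOF at the
sternoclavicular (SC) joint, 3 at the glenohumeral joint, 1 at the elbow, 2
at the wrist and 1 at the hand. Ten rigid segments connect 11 markers (the
neck plus shoulder, elbow, wrist, palm and hand tip of each arm), so every
reconstructed pose satisfies bone-length conservation exactly — the model's
core biological-feasibility guarantee, asserted to 1e-9 relative error in
the tests.

Conventions (the source of most sign pitfalls, so stated explicitly):

* world/torso frame: x to the subject's right, y up, z anterior; meters.
* rest pose: arms hanging, segment axes along −y; shoulder offsets along ±x.
* x-axis joint rotations are flexion-positive (a positive angle moves the
  segment anteriorly); the left chain mirrors the right by sign-flipping
  rotations about y and z. Mirror symmetry is a tested invariant.
* angles are radians internally; the rhythm regression below is in degrees
  and converted at the boundary.

At the SC joint the transform is a product of a z-rotation and a
y-rotation. With the shoulder offset along x and y up, it is the z-factor
that elevates the girdle, so the elevation/depression angle (`sc_ud`) drives
the z-rotation and the protraction/retraction angle (`sc_fb`) the
y-rotation. (Assigning them the other way round — which a literal reading of
the printed product order suggests — swings the arm ~15 cm posterior at
high elevation, which is anatomically wrong and triggers spurious
self-occlusion in the simulator.)

## Scapulohumeral rhythm

Girdle motion is coupled to the arm lift angle β (degrees) by the
piecewise-linear regression

* θ_fb = −0.35 β (β<0); 0 (0≤β≤70); −0.22 β + 15.4 (β>70)
* θ_ud = −0.3 β (β<0); 0 (0≤β≤30); 0.36 β − 10.8 (β>30)

Both branches meet continuously at the breakpoints (tested by ε-sweep). The
rhythm enters the solver as a *soft prior*, not a hard constraint, because
the regression was fitted on healthy subjects and hemiplegic patients
deviate from it; the prior weight (1e-4, squared-radian units on the meters²
fitness scale) is small enough never to dominate observed markers.

The lift angle is identified with the glenohumeral elevation slot `sh_z`.
Since the package expresses full 0–180° protocol elevation in that slot
(the scapular share of elevation is absorbed there rather than split out),
its default limit reaches 180°, and the SC elevation limit reaches 60°
(the regression itself prescribes 54° at β = 180°). All limits are
config-overridable, per-angle box bounds from standard range-of-motion
tables.

# Inverse kinematics by crossbreed PSO

Per frame and per arm, IK is posed as bound-constrained minimization of

    fitness(x) = Σ_j w_j ‖y_j − F(x)_j‖²  +  w_r · rhythm deviation
                 + w_s · ‖x − warm start‖²

over the 9 joint angles, where `y_j` are the observed arm markers in the
torso frame, `w_j` their confidences (occluded markers are excluded — this
is how occlusion is *repaired* rather than interpolated), and `F` the
forward-kinematics map. The solver is classical PSO (inertia ω = 0.72,
learning factors c1 = c2 = 1.49, 60 particles, 300 iterations, per-particle
per-dimension uniform random factors) extended with a crossbreed operator:
each iteration a random 20 % pool is paired, and each pair is replaced by
children whose positions are the Pc-blend (Pc = 0.6) of the parents and
whose velocity is the normalized parent-velocity sum rescaled to the first
parent's speed; children inherit the replaced parent's personal-best memory.
With the operator disabled the solver reduces bit-exactly to classical PSO
(a regression test). Positions are clamped at the bounds with the velocity
zeroed on clamped dimensions; the global-best fitness is non-increasing by
construction and asserted every step.

Numerical choices that mattered:

* **Warm starts.** Frame *t* seeds one particle at frame *t−1*'s solution.
* **Analytic seeding.** Each frame additionally seeds a small deterministic
  bank of particles from geometric estimates: the shoulder→elbow direction
  (girdle-compensated through the rhythm regression) solved in two Euler
  families (twist+elevation and flexion+abduction), with elbow and wrist
  flexion from marker angles. The bank places the swarm in the correct
  basin of attraction; the stochastic search then polishes, and the
  tolerance stop usually fires well before the iteration budget.
* **Temporal-continuity prior.** `w_s = 1e-6` pulls toward the warm start.
  It is negligible wherever markers constrain the pose, but it anchors DOFs
  the current frame leaves unobservable (wrist/hand angles while the distal
  markers are occluded); without it the swarm fills those DOFs with
  arbitrary in-bounds values and occluded-tip reconstruction degrades from
  millimeters to decimeters.
* **Redundancy.** With a straight arm the three shoulder Euler angles have a
  one-parameter family of equivalent solutions; angle-recovery assertions
  are therefore made on flexed-elbow poses (identifiable DOFs) and
  marker-space accuracy is asserted everywhere. For the same reason a
  stationary target yields marker-steady, not angle-frozen, solutions.
* **Torso pose.** Translation is the neck marker; rotation is estimated from
  the pelvis line and spine axis when a full-body frame is available, and is
  taken as world-aligned for 11-marker streams (the capture protocol seats
  the subject facing the rig; estimating torso yaw from the shoulder line
  would alias girdle rotation into torso rotation).
* The per-frame fitness kernel (forward kinematics over a 60-particle
  batch) is implemented in C++ (Rcpp); the C++ and R chains are asserted
  equal to 1e-12 in the tests.

# Two-camera fusion and preprocessing

Extrinsics come from Kabsch/SVD rigid registration of 3-D point
correspondences (reflections excluded, collinear sets rejected); on
noise-free correspondences the recovered transform is exact to 1e-9 over
1000 random motions. Frames are paired by nearest timestamp (5 ms default
tolerance — hardware synchronization is assumed, not implemented). Fusion
is per joint: confidence-weighted averaging, verbatim takeover when only one
camera sees the joint, confidence 0 and the master sentinel when neither
does; fused confidence is the max. The fused position provably lies on the
segment between its sources.

Denoising follows the median-then-Butterworth order: a running median
(window 5 samples, reflected edges) kills isolated occlusion spikes, then a
6th-order zero-phase (forward–backward) Butterworth low-pass. A 30 Hz
cutoff is kept as the configuration default for high-rate capture, but it
is unattainable below 60 Hz sampling, so the effective default is
`min(30, 0.45 · rate)` Hz. Zero-phase filtering uses odd-reflection padding
so start/end transients stay out of the data. Confidence-0 samples are
bridged linearly *for filtering only* — the sentinel position (0,0,0) would
otherwise leak through the filter into neighboring valid samples — but
their confidence marks are preserved, so the model fit still treats them as
unobserved: reconstruction, not interpolation, remains the repair
mechanism.

Signal-to-noise ratio is defined per joint-axis channel as
`10·log10(var(reference)/var(raw − reference))` with a documented reference
(the processed signal in field use; the simulator ground truth in tests,
where the direction processed ≥ raw is asserted on ≥90 % of moving
channels).

# Reachable workspace

Hand-tip trajectories are shoulder-centered, arm-length-normalized and
radially projected to the unit sphere (frames with the hand below 20 % of
arm length are dropped as non-extended). The envelope boundary is the
alpha shape in an azimuth–elevation chart (seam placed behind the back),
computed by the classical empty-disk edge criterion; the default disk
radius is `max(1.5 × median nearest-neighbor distance, 0.15 × chart
diagonal)` — the first term suits uniform covers, the second keeps sparse
sweep traces from disintegrating into per-curve tubes. An interior-point
prefilter and deterministic thinning keep the quadratic scan tractable.
The boundary is smoothed with a closed centripetal Catmull–Rom spline
(interpolating every vertex, re-projected to the sphere), split by the
horizontal and sagittal planes through the shoulder, and each piece's
spherical area is computed by geodesic polygon area on the unit sphere.
Relative surface area (RSA) is normalized by the full sphere 4π
(configurable in interpretation; the quadrant convention is Q1 inner-above,
Q2 inner-below, Q3 outer-above, Q4 outer-below). Quadrant additivity holds
to 1e-9 and cap regions match the closed form 2π(1−cos θ)/4π to 1 %.

# The assessment network

Input is the 11-node skeleton sequence, centered at the neck marker and
divided by arm length. The architecture:

1. **Temporal lift.** The raw sequence is concatenated channel-wise with its
   learned temporal convolution (kernel 9), doubling the channels (3→6).
2. **Three STGCN blocks.** Per partition k ∈ {identity, adjacency} the
   block projects its input to an 8-channel query, runs a ConvLSTM over
   time (gates are 1×1 channel maps applied per node), and projects the
   hidden state to an 11×11 attention map S = 1 + tanh(H·P): entries live
   in (0, 2) around the neutral value 1, so attention *modulates* the fixed
   degree-normalized partition adjacency D^(−1/2)(A_k + I)D^(−1/2) through
   an elementwise product. The modulated graph convolution (ReLU, summed
   over partitions, 12 channels) feeds three parallel temporal convolutions
   (kernels 3/5/7, 4 channels each, concatenated) plus a residual
   projection. Permutation equivariance of the attention-GCN is verified on
   random tensors.
3. **Head.** Node-mean pooling, four stacked LSTM layers (output dims
   80/40/40/80, dropout 0.25 between layers during training), then a fully
   connected scalar read from the *time-mean* of the last LSTM layer.

Training minimizes mean squared error on the 0–100 score scale with Adam
and global gradient-norm clipping (clip 10). Seeded runs are bit
reproducible.

Design decisions that were genuinely open, and why they fell this way:

* The lift's two operators are read as channel concatenation and temporal
  convolution of the raw sequence.
* Attention maps are produced by a learned linear projection of the
  ConvLSTM hidden state, tanh-squashed and re-centered at 1. Centering at 1
  makes the untrained network behave like a plain STGCN (neutral
  attention), and makes "freeze attention at 1" a meaningful ablation.
* Readout uses the time-mean of the last LSTM layer, with zero forget-gate
  bias. The conventional last-time-step readout saturates at these sequence
  lengths (the final hidden state approaches an input-insensitive fixed
  point, and sample-to-sample output spread collapses to ~0.1 score points);
  the time-mean preserves input sensitivity and trains reliably.
* The configuration default keeps the conventional optimizer setting for
  this architecture (learning rate 0.1, batch 4), but training helpers
  default to 0.005: 0.1 diverges for this loss scale, and divergence is
  surfaced by an explicit loss-is-finite check rather than silently hidden.
* Joint importance is the *temporal modulation* of a node's outgoing
  attention row — the time-averaged absolute deviation of the row from its
  temporal mean, averaged over blocks, partitions and sequences, min–max
  scaled across the 11 nodes. A plain time-average of |S| is dominated by
  the static component of the learned maps and does not discriminate
  moving from resting limbs; modulation is zero for motionless nodes by
  construction, which matches the clinical reading (which joints
  participate in this movement).

# The simulator and its impairment model

The simulator defines the study conditions. The 16-action protocol is: four
vertical-plane sweeps (azimuth 0/45/90/135°, elevation traversing 0–180°
with a smooth sin² out-and-back profile, arm straight), four horizontal
sweeps (elevation 45/90/135/180°, azimuth traversing 0–135°), and eight
proximal reaches (side, lumbar spine, stomach, contralateral and
ipsilateral shoulder, nose, ear, head top) implemented as minimum-jerk
out-and-back interpolations to per-landmark joint-angle configurations
stored as config constants. Durations are 4 s (sweeps) and 3 s (reaches);
the girdle follows the rhythm regression exactly, so generator and solver
share one convention.

Impairment has three documented dials: `rom_scale` multiplies joint-angle
amplitude; `tremor_amp` adds band-limited (4–8 Hz) noise *in joint-angle
space* (so corrupted motion stays biologically connected, RMS-scaled in
degrees); `slowness` dilates time. The ground-truth label is the explicit
formula `score = clamp(100·rom_scale − 4·tremor_amp, 0, 100)` — strictly
increasing in range of motion, strictly decreasing in tremor. No claim is
made that this matches any clinical scale; it exists so that score
regression has a defined target, and the network benchmarks test
*direction* (full model beats ablation and mean predictor), never clinical
values.

Rendering places two cameras 2 m apart subtending 90° at the subject, fills
the 21 non-upper-limb device joints from a static standing template (format
completeness only), and applies three corruptions: additive Gaussian
position noise; i.i.d. per-joint-frame dropouts; and geometric occlusion —
a marker more than 10 cm behind the torso's frontal plane, on the far side
from the camera, is reported with confidence 0 and a sentinel position.
With corruption disabled, rendering is exactly the rigid camera transform
and is invertible to numerical precision (tested).

What the simulator does *not* emulate — and hence what green tests do not
show about real data: soft-tissue and clothing artifacts, systematic
tracker biases (device skeletons are not rigid), correlated multi-joint
dropouts, true torso motion, left-arm involvement, inter-subject
anthropometric variation beyond segment lengths, and any clinically
validated score semantics.

# Problem sizes used by the test suite

Chosen as the smallest sizes at which each property is meaningfully
exercised: the FK→IK round trip solves ~48 noise-free frames spanning all
16 actions at the full swarm setting (60 particles, 300 iterations); the
occlusion-repair check runs one full 30 fps sweep with 20 % per-camera
dropout; the network capacity check trains on 8 labelled sequences (stop at
MSE < 1); the comparison benchmark uses 200 synthetic sequences at 6 fps,
an 80/20 split and 3 seeds, comparing test MAD of the full model, the
attention-frozen ablation and the mean predictor, averaged over seeds.

# Known limitations

* The azimuth–elevation chart distorts near the poles; alpha-shape
  extraction is chart-based (areas themselves are computed on the sphere).
  Boundaries through the zenith (full overhead sweeps) are handled but the
  chart seam must stay behind the subject.
* Euler-angle redundancy makes some joint angles unidentifiable from
  markers alone (straight arm, occluded hand); the package reports
  marker-space accuracy and constrains angles only softly.
* The assessment network is intentionally compact (a few thousand
  sequences would saturate it); it is a faithful, testable implementation
  of the architecture, not a tuned clinical model.
* Scores, importance maps and workspace areas are comparable *within* this
  package's conventions; absolute values depend on normalization choices
  (RSA/4π, score formula) that are documented rather than canonical.
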