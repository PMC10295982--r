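---
title: "Predicting wrist rotations from proximal arm kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting wrist rotations from proximal arm kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristcast)
```

## The problem

Most upper-limb prostheses ship with a fixed or passively adjustable wrist.
Users compensate with shoulder and trunk movements that are uncomfortable and,
over time, harmful. If the wrist rotation needed for a task can be predicted
from the kinematics of the more proximal joints — elbow and shoulder — a
motorized wrist could orient itself automatically, without adding channels to
the human-machine interface.

`wristcast` implements that idea for shelf-to-shelf object transports
(pick-and-place): the three wrist-related rotations — wrist flexion/extension
(F/E), wrist abduction/adduction (A/A) and forearm pronation/supination (P/S)
— are regressed on the five proximal angles (elbow F/E and A/A; shoulder F/E,
A/A and P/S) with shallow neural networks, against a linear baseline. Because
the subject recordings such studies rest on are not publicly deposited, the
package ships a synthetic motion-capture generator with exact ground truth, so
every pipeline stage is verifiable at desk scale.

## The synthetic study

The generator emulates a five-subject protocol: each subject transports two
standardized SHAP objects (a 50 mm power-grip cylinder and a 70 mm sphere)
between the 12 ordered pairs of four shelf slots (UL, UR, DL, DR), three
consecutive repetitions each — 360 trials, each starting and ending in the
anatomical position and lasting about 5 s.

Trials are built in joint space. A posture keyframe (9 angles) is authored for
every (slot, object, phase in grasp/release) combination, plus the anatomical
rest posture; the trajectory passes anatomical → grasp(origin) → carry →
release(destination) → anatomical along minimum-jerk segments (zero endpoint
velocity and acceleration), the carry posture being a retracted midpoint of
grasp and release that reproduces the arc the hand describes away from the
shelf between pick and place. Joint-space keyframing was chosen over
task-space inverse kinematics because it yields exact ground-truth angles for
round-trip testing.

Two authored properties deserve note:

* **Event geometry.** The transmitter sits on the shelf with its y-axis
  pointing at the subject, so the hand is nearest the shelf (minimum y) at
  grasp and release. Because forward reach is a sum of sines of the shoulder
  and shoulder+elbow flexions, a posture with total flexion near 90° sits at
  maximum reach, and paths through it would poke past the shelf plane
  mid-transport. All shelf keyframes therefore keep total flexion below
  ~90°, and the carry posture retracts monotonically in both flexion sums;
  hand depth is then monotone on every trajectory segment and its minima
  fall exactly at the protocol events. This is what makes the "minimum of the
  hand-sensor Y coordinate" detection rule literally true in the simulator.
* **Object and subject structure.** The cylinder is grasped from the side
  with a strongly pronated forearm (P/S −70°), the sphere from above with a
  supinated forearm (+45°) and a distinct wrist F/E pattern; proximal-joint
  differences between the objects are small (a few degrees at the elbow).
  Wrist postures therefore depend on the object much more than the network
  inputs do, which is exactly what makes object information valuable to the
  predictors. Per-subject style is modelled by perturbing every grasp/release
  keyframe angle once per subject (sd 3°, the scale of inter-subject
  sensor-placement differences); since the perturbations are
  keyframe-specific they survive per-subject mean-centering and create a
  genuine benefit for subject-specific training.

Sensor poses follow by forward kinematics through a rigid chain (upper arm
30 cm, forearm 26 cm, hand 9 cm) with fixed mounting frames per sensor (hand,
forearm, arm, trunk), plus i.i.d. Gaussian noise: sd 0.1 cm on positions and
0.5° on the wrapped orientation angles — the magnitude class of an
electromagnetic tracker. Segment durations get ±10% uniform jitter per
repetition. The raw rate is 60 Hz (the normalized grid, below, is what the
analysis actually sees; 60 Hz × 5 s comfortably oversamples it). Everything
is reproducible from one master seed.

What the generator does *not* emulate: soft-tissue artifact, tracker
distortion near metal, drift, marker dropout, trunk motion, or biomechanical
couplings beyond the authored keyframes. Passing tests on synthetic data
therefore validate the *pipeline machinery* — angle extraction, alignment,
filtering, event detection, training — not the real-data effect sizes.

## From sensor poses to joint angles

Each sensor reports position and intrinsic Z-Y'-X'' Euler angles (azimuth,
elevation, roll) wrapped to [−180°, +180°]. Rotation matrices are rebuilt from
the wrapped angles (matrices are wrap-invariant), mounting frames are removed,
and the relative rotation across each joint — forearm→hand (wrist),
arm→forearm (elbow + forearm P/S), trunk→arm (shoulder) — is decomposed in
the fixed anatomical order F/E first, then A/A, then P/S. The axes are F/E
about z, A/A about y and P/S about the distal long axis x, so axial rotation
is the final rotation about the segment it rotates — the standard convention
for pronation/supination; the middle (A/A) angle lives in [−90°, 90°] and
gimbal lock at |A/A| = 90° is flagged rather than thrown (authored keyframes
stay far from it). Output channels are unwrapped to continuous series; the
wrist-pair P/S residual is computed and stored but excluded from modelling
(anatomically negligible).

## Preprocessing

1. **Repetition synchronization.** The three repetitions of a transport are
   aligned by dynamic time warping on the 3-D hand-position trajectory
   (repetition 1 is the reference; query samples mapped to one reference
   instant are averaged). The DTW dynamic program uses the step set
   {(1,1),(1,0),(0,1)} with ties preferring the diagonal; it is checked
   against an exhaustive-path oracle in the tests. The hand position is used
   as the alignment signal because the pick/place events are defined on it.
2. **Filtering.** A third-order Butterworth low-pass, applied
   forward-backward (zero phase) by default so event timing is unbiased;
   single-pass is available. The cutoff is configurable with a 5 Hz default,
   standard for reach kinematics. Edges are handled by odd reflection padding
   with steady-state initial conditions, giving exactly unit DC gain. The
   filter runs on the extracted angle and hand-position series: extraction
   itself is exact algebra on rotation matrices, and filtering after it
   avoids touching wrapped orientation channels near discontinuities.
3. **Time normalization.** Linear interpolation onto 101 points (normalized
   time 0.00–1.00, step 0.01 ≈ 50 ms for a 5 s trial), endpoints preserved
   exactly.
4. **Centering.** Every angle channel is re-expressed per subject as the
   difference from that subject's mean over all their samples, absorbing
   sensor-placement offsets; the offsets are kept for the inverse transform,
   and errors are always reported in degrees on the un-centered scale.

## Event detection and case assembly

Pick (PK) is the minimum of hand y over normalized indices 0–50, place (PL)
the minimum over 51–100; the halves are a natural segmentation because the
normalized trial is symmetric (rest → pick → place → rest), and ties take the
earliest index. A flat y trace (range < 0.1 cm) is a detection error.

The instant-wise (FFNN) dataset takes two cases per trial: inputs are the
five proximal angles sampled an *anticipation* before the event (0.5 s ≈ 10
steps or 0.75 s ≈ 15 steps — the time a motorized wrist would need to turn),
targets are the three wrist angles at the event. Optional one-hot input
extensions encode the object (1 unit), the subject (one per subject) and the
task PK/PL (1 unit). The default study yields 5 × 2 × 12 × 3 × 2 = 720 cases;
15% are held out at random for testing.

The time-delay (TDNN) dataset predicts the wrist angles at *every* instant
from a tapped delay line of the five input channels: delays 1:10 (≈ 0.5 s of
history), 1:15, 1:2, or 11:12 (a 0.1 s window anticipated 0.5 s). Trials are
split at trial level (15%, stratified half cylinder / half sphere), each group
is multiplied by a Tukey window whose cosine ramps span the first and last 5
of the 101 samples (the rest transitions; ratio 2·5/100 = 0.1) and
concatenated in a seeded recorded order; only the first max(delay) samples of
the concatenation are masked, trial boundaries being handled by the taper.

## The network and its trainers

One shallow architecture serves both datasets: tanh hidden layer (5–20
units), linear output, min-max scaling of inputs and targets to [−1, 1]
fitted on training data and frozen (the toolbox-default recipe for shallow
regression nets). Initialization is seeded Nguyen-Widrow. The FFNN maps 5(+)
inputs to 3 outputs; the TDNN uses one network per wrist angle (5·|delays|
inputs, 1 output), three per configuration.

The default trainer is Bayesian-regularized Levenberg-Marquardt. With
E_D = Σe² the sum of squared scaled errors and E_W = ½Σw², each step solves

    (β JᵀJ + (α + μ) I) Δw = −(β Jᵀe + α w)

with the Jacobian J computed by exact backpropagation, and μ adapted ×0.1 on
acceptance, ×10 on rejection (μ ∈ [10⁻¹⁰, 10¹⁰]). The objective this step
descends — and against which acceptance is tested — is F = β E_D + 2α E_W;
its fixed point for a linear network is the ridge solution
(XᵀX + (α/β) I)⁻¹ Xᵀy, which the tests verify to 10⁻⁶ against the closed
form. After each accepted step the evidence framework re-estimates the
effective number of parameters γ = Σ βλᵢ/(βλᵢ + α) over the eigenvalues λᵢ of
JᵀJ — a form that keeps γ within [0, N_w] by construction — then α ← γ/(2E_W)
and β ← (M − γ)/(2E_D). Training stops on the epoch cap, μ overflow, or a
relative loss change below 10⁻⁹. No validation set is carved: the
regularization replaces early stopping. Plain Levenberg-Marquardt (α ≡ 0) and
Møller's scaled conjugate gradient are provided as comparison trainers; both
stop early on a 15% validation split with patience 6 (set `val_fraction = 0`
to disable).

The linear baseline stacks every normalized instant of every trial into one
matrix and fits ordinary least squares per target angle on the five
predictors, reporting MAE and per-angle Pearson correlation; rank-deficient
predictor sets are flagged and solved in minimum norm.

## Evaluation harness

Errors are MAE (instant-wise predictor) or RMSE (time-delay predictor) in
degrees; correlation is pooled Pearson over the three outputs for the FFNN
and the mean of per-angle correlations for the per-angle TDNNs — the paper
convention for each table family. Whether correlation is computed on centered
or un-centered angles is genuinely open; the harness computes it on the
centered scale (the scale the networks see), and both modes are exposed
through `correlation()`. Every grid cell is averaged over 5 training sessions
with derived seeds, reported mean ± SD.

Problem sizes are chosen for desk-scale reproducibility: the harness trains
TDNNs on every 2nd sample of the training concatenation (the 101-point series
oversample the 5 Hz-filtered movement) for at most 40 epochs — the loss curves
stabilize well before that — and FFNNs for at most 120 epochs. On the default
360-trial study the full comparison (both architectures, two hidden widths,
two delay windows, restrictions, 5 sessions each) runs in a few minutes on
one CPU.

## Numerical choices and degenerate inputs

* DTW ties prefer the diagonal step, making the path deterministic.
* Gimbal lock is flagged, never thrown; the free outer-angle part is reported
  in F/E with P/S zeroed.
* Constant scaler columns map to zero (half-range clamped to 1).
* Rank-deficient linear fits fall back to the SVD minimum-norm solution.
* Every stochastic step (study generation, splits, concatenation order,
  initialization) derives its seed deterministically from one master seed;
  identical seeds give bit-identical studies, fits and reports.

## Known limitations

The simulated mapping from proximal angles to wrist angles is exactly
realizable by construction (keyframes plus smooth interpolation), so absolute
correlations here exceed what heterogeneous human data yield, and they should
be read only through the *comparisons* the harness makes: time-delay versus
instant-wise versus linear, anticipation windows, object/subject restriction.
The generator's noise is white and stationary, unlike tracker artifacts. The
event segmentation at the half-grid assumes the symmetric rest-to-rest
protocol; a local-minima alternative would be needed for free-form recordings.
Real deployments would also face sensor-to-segment calibration, which the
synthetic mounting frames make exact; a static-calibration option (mean pose
over a rest interval) sketches how real data would be handled but is not a
validated substitute for anatomical calibration.
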