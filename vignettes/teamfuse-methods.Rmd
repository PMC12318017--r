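---
title: "Multi-level sensor fusion and team coordination analytics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level sensor fusion and team coordination analytics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamfuse)
```

## The problem

Team-sport tracking deployments combine heterogeneous wearables per
athlete — an IMU at 200 Hz, GPS at 10 Hz, a local positioning tag (LPS) at
40 Hz, a heart-rate strap, pressure insoles — each with its own accuracy,
transmission latency and dropout behaviour. `teamfuse` implements a
hierarchical fusion architecture for such networks and, on top of the
fused team trajectory, a system of collaborative-dynamics indicators that
quantify how coordinated a team's movement is.

Fusion proceeds through three levels. **Sensor-level** processing
harmonizes each stream: zero-lag fourth-order Butterworth filtering,
SNR-based quality assessment (`SNR = 20 log10(A_signal / A_noise)`, with
recalibration flagged below 15 dB), and complementary filtering for
orientation, `theta_t = alpha (theta_{t-1} + omega dt) + (1 - alpha) phi`.
**Individual-level** fusion combines each athlete's positional sources
with adaptive weights (below) into a common-clock kinematic and
physiological record. **Team-level** fusion assembles per-athlete records
into a team trajectory whose centroid is the plain arithmetic mean of
member positions — team-level weights are uniform by design; we found no
principled, data-independent way to set non-uniform ones.

## Adaptive weights

Source weights follow the exponential-decay recursion
`w_t = lambda w_{t-1} + (1 - lambda) q_t r_t`, renormalized per fusion
node, with `lambda = 0.65` by default — the recursion's fixed point under
constant quality is reached geometrically with ratio `lambda`. The
quality-relevance product `q r` fed into the recursion for positional
fusion is a **precision share**: each source's noise variance is tracked
block-wise (1 s blocks) from second differences of its fixes — for white
noise `E[d2^2] = 6 sigma^2`, while smooth-trajectory curvature contributes
only `O(dt^4)` — and the share is the relevance-scaled inverse variance,
normalized across sources. We chose precision shares rather than a
dB-linear map of SNR because only inverse-variance weighting attains the
optimal combined error `sigma_opt = (sum_i sigma_i^-2)^{-1/2}` for
unbiased sources; the package's own tests require the fused error to be
within 5% of that bound. A dB-linear quality `min(1, SNR/30)` is still
computed and reported per stream (it drives the recalibration flag), and
precision is monotone in SNR, so every qualitative property — e.g. a
source corrupted mid-session loses weight within a few updates — is
unchanged. The first block has no history, so the recursion is initialized
at the first quality share rather than at uniform weights.

Contextual relevance `r` is a modality-by-state lookup: IMU relevance
rises to 1 during high-dynamics windows (|a| > 2 m/s^2), GPS drops
slightly there; LPS is trusted throughout. Between positional fixes the
linear interpolation of a source is bent by the *dead-reckoning
increment*: the double time-integral of IMU acceleration minus its own
chord across the fix gap, which vanishes at the fixes and restores in-gap
curvature.

## Asynchronous alignment

Streams are aligned by phase rather than by wall clock. Movement-cycle
anchors are detected as spectral-dominant peaks; events of a stream and a
reference stream are paired in order (surplus events beyond a 25%
tolerance raise an error) and define a piecewise-linear time warp. On the
warped sample times an interpolating B-spline
`X_aligned(t) = sum_i P_i N_{i,d}(t)` of degree `d = 3` is built with a
clamped knot vector by knot averaging; the control points are solved from
the samples (banded collocation system), so the spline passes through
every measurement — degree 1 then reduces exactly to piecewise-linear
interpolation, and an identity warp reproduces the input to numerical
precision. Alignment quality is scored by the phase-coherence statistic
`C_phase = mean(cos(phi_i - phi_ref))` on Hilbert phases. A classic DTW
dynamic program (step set {(1,0), (0,1), (1,1)}, both ends anchored) is
included as the alignment baseline and is verified against an
exhaustive-path oracle in the tests.

## Multi-scale features and fusion quality

Wavelet-packet decomposition (orthonormal Daubechies filters, periodized;
default `db4`, depth `K = 5`) splits movement signals into `2^K` frequency
bands with perfect reconstruction and exact energy conservation; feature
selection keeps the top `alpha_feat = 0.15` of coefficients by energy, so
the reconstruction error is non-increasing in `alpha_feat`. Multi-channel
features are combined by tensor fusion, mode-n products
`T = X x1 W1 x2 W2 x3 W3` over the athletes x modalities x windows array.
Fusion quality is summarized by `Q_info = I(X;F) / H(X)` with a plug-in
estimator on 16 equal-frequency bins — deterministic and positively biased
at finite n (about 0.004 at n = 10^4 for independent pairs), which we
document rather than correct. Kalman (constant-velocity), fixed-weight
average and conjugate-Gaussian Bayesian fusers are provided as baselines
for the comparison harness; the Kalman filter supports an exact
information-form update under a flat prior so that its static limit equals
the precision-weighted closed form.

## Coordination indicators

All indicators are computed on sliding windows (10 s, 50% overlap) of the
team trajectory:

* **SSI** mean pairwise correlation of velocity components; **ICC** mean
  athlete-vs-centroid velocity correlation.
* **TCR** fraction of |a| > 2 m/s^2 onsets shared by at least half the
  team within 0.5 s.
* **FSQ** `1/(1 + CV)` of centroid-centred inter-athlete distances.
* **TIE** Shannon entropy of pass counts over ordered pairs, normalized
  by `log2(n_pairs)`.
* **CPR** seconds for SSI to re-enter its pre-perturbation mean +- 1 SD
  band after a perturbation (session-level; NA without perturbations —
  missing, never zero).
* **DMS** Kuramoto order parameter of athlete phases at decisive-action
  times.
* **LDH** `1 - Gini` of per-athlete load accumulated in the window.
* **S_spatial** `-sum p log2 p` over an axis-aligned zone grid (6 x 4
  cells); joint normalization over athletes and zones is the default, the
  per-athlete variant is available. **RPM** mean pairwise correlation of
  observed vs reference inter-athlete distances; a constant reference
  (static tactical template) makes the normalized covariance degenerate,
  so the documented fallback `1 - min(1, MAE/ref)` is used and flagged.

Movement phases come from the Hilbert transform of the band-passed
(0.1-2 Hz) x-displacement, with 5% trimmed at each end for transform edge
effects. The band-pass removes slow centroid drift; we deliberately do
*not* centroid-centre the signal first, because subtracting the centroid
cancels the shared oscillation that synchronization is supposed to
reveal. Cross-recurrence analysis thresholds the inter-athlete state
distance (state = z-scored x, y, vx, vy) at 10% of the maximum distance,
with block-mean coarse-graining at scales {1, 2, 4} and line statistics
RR, DET, LAM and diagonal-line entropy at `l_min = 2`; note that with
`l_min = 2` the two single-cell corner diagonals keep DET of an all-ones
matrix at `(n^2 - 2)/n^2`, the value a hand census gives.

## Performance models

The team-individual relationship is an observed-variable linear path
model `P_team = b1 C_spatial + b2 C_temporal + b3 sum_i w_i P_ind,i + e`
fitted by OLS on the three composites (contribution weights `w_i` are user
inputs, uniform by default); constant or collinear predictors raise an
identifiability error rather than a silent drop. Match outcome is
classified from (TCR, CPR, SSI, ICC) by logistic regression fitted with
an in-package IRLS (cross-checked against `glm` in the tests); complete
separation — detected by degenerate fitted probabilities — falls back to a
ridge-stabilized fit with a warning. Evaluation is always
leave-one-session-out to avoid window-level leakage. Change points on
indicator series use binary segmentation for mean shifts with a
`3 log(n) sigma^2` acceptance penalty, `sigma^2` estimated robustly from
first differences; on null white noise this keeps the false-positive rate
at or below 5% (about 1% measured at n = 100). The early-warning engine
evaluates configurable level/delta predicates; its defaults encode "rapid
SSI rise with elevated TCR".

## The session simulator

No public data accompanies the method, so the simulator is a first-class
module. Each athlete's position is
`centroid(t) + slot_i + a (cos psi_i, sin psi_i)` with phases following
Kuramoto dynamics
`dpsi_i = omega_i dt + (kappa/n) sum_j sin(psi_j - psi_i) dt + sigma dW`
(Euler-Maruyama at the 100 Hz frame rate; coupling acts within a team).
The coupling strength `kappa` is the simulator's stand-in for tactical
coordination level: every coordination indicator has a known monotone
relation to it, which is exactly what makes recovery tests possible. The
smooth bounded centroid path and grid formation slots are deliberate
idealizations — there is no opponent interaction, no game AI, no
biomechanical gait model — so passing tests demonstrate correct
*computation* of the indicators, not ecological validity on real matches.

Sensors observe the truth at their modality rates with Gaussian noise at
the deployed accuracies (GPS 0.5 m, LPS 0.1 m, accelerometer 0.02 g,
gyroscope 0.05 deg/s, HR 1 bpm), per-sample transmission latency
(half-normal jitter around the modality mean) and Bernoulli dropouts
marked by an explicit mask column, never silent NA holes. Two deliberate
deviations from the deployed rates: heart rate is generated directly in
bpm at 10 Hz through a first-order lag on speed (tau = 30 s) rather than
as kHz ECG, and insole force is a 100 Hz per-step impulse train synced to
the movement phase — only cumulative load is consumed downstream, and
desk-scale row counts matter more than raw-rate fidelity. Events are
Poisson: passes between teammates (6/min), perturbations (1/min) that
collapse the coupling tenfold for 5 s — giving CPR something measurable —
and decisive actions for DMS. All randomness derives from one root seed
via stable per-purpose child seeds, so sessions are bit-reproducible.

The "zero-noise" identity condition used in the tests switches off *all*
stochastic inputs, including the phase diffusion `sigma dW`: Wiener phase
noise makes the true acceleration rough, and no integrator can
dead-reckon a nowhere-differentiable path to 1e-6 m. With deterministic
dynamics the full pipeline reproduces truth positions to better than
1e-7 m RMSE.

## Numerical choices

* `signal::filtfilt` carries no edge-state handling, so all zero-lag
  filtering uses odd-reflection padding (transients decay inside the pad);
  this is what makes DC gain exact and the SNR estimate invariant to a
  constant offset.
* Noise amplitude `A_noise` is not operationally defined in the field; we
  estimate it as the RMS of the out-of-band residual after low-pass
  filtering, scaled by the white-noise band fraction, with the middle 80%
  of the stream used to avoid residual edge effects.
* Session CSVs are written by `readr` (shortest round-trip decimals) but
  read back with the base parser, which is correctly rounded — this is
  what makes the timestamp round-trip bit-exact.
* Equal-frequency MI binning returns a flagged NA for constant signals
  (zero entropy) instead of dividing by zero.
* Orientation is tracked per-axis with independent complementary filters;
  no quaternion algebra, since heading is the only angle the pitch-plane
  pipeline consumes.

## Problem sizes used by the tests and the acceptance script

Fusion-benefit statistics use 50 (tests) or 20 (acceptance script)
simulated 2v2 sessions of 30 s; the coupling-recovery sweep uses
`kappa in {0, 0.5, 1, 2, 5, 10}` with 20 (tests) or 10 (script) seeds of
5v5, 60 s sessions; classifier evaluation uses 200-300 sessions of the
Gaussian session-summary generator. These sizes give stable Monte-Carlo
estimates (the recovery correlations are saturated at 1 well below these
sizes) while keeping a full run in minutes on one core.

## Known limitations

Real matches violate the simulator's assumptions in ways that matter:
non-stationary coupling, role asymmetries, contested possession, sensor
biases that are neither Gaussian nor independent. The MI estimator's bias
grows with bin count relative to n. CPR needs a pre-perturbation baseline
window and returns NA early in a session. The pass-network entropy needs
enough passes per window to be meaningful; sparse windows are NA by
design. None of the printed performance figures of any particular
deployment are asserted by this package — its tests verify mathematical
properties and recovery of known synthetic ground truth.
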