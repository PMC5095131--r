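---
title: "Orientation-invariant recognition of moving objects from event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-invariant recognition of moving objects from event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerorient)
```

## The problem

Event cameras (dynamic vision sensors, DVS) do not produce frames. Each
pixel independently emits a timestamped address event when the light
intensity it sees changes: an ON event (+1) for brightening, an OFF event
(-1) for darkening. A moving object therefore appears as two traveling
clouds of events - one polarity along its leading edge, the other along its
trailing edge.

Feed-forward spiking classifiers built on this representation are accurate
but orientation-bound: a classifier trained on objects moving leftward
fails when the same object moves, say, downward, because every feature
lands at different addresses and in different orientation channels.
`aerorient` implements a recognition system that removes this limitation
without multi-orientation training data. It couples three components:

1. **Bio-inspired feature extraction** (S1/C1): event-driven convolution
   with a bank of 16 Gabor kernels (4 scales x 4 orientations), kept
   separately for ON and OFF events (32 maps), with a linear *forgetting*
   leak; then a local MAX operation, a threshold, ON/OFF superposition and
   top-k selection of peak responses.
2. **An orientation detector**: two bivariate-Gaussian blob trackers (one
   per polarity) whose center difference gives the deviation angle of
   motion, quantized into 8 classes at 45-degree spacing.
3. **Address remapping + a tempotron classifier**: a precomputed lookup
   table rotates the C1 peak addresses of a test sample back to the
   reference frame (and cyclically relabels the orientation channels);
   the corrected peaks are converted to time-to-first-spike patterns and
   classified by a bank of tempotron neurons (10 per category) with
   majority voting.

Training uses samples moving in a single reference orientation only
(defined as motion toward -x); the detector and the remapping make every
other motion direction look like the reference one at test time.

## Conventions

All addresses are 0-based, x rightward, y downward (image convention).
The deviation angle $A_n \in [0, 360)$ of a motion direction
$(\Delta x, \Delta y)$ is measured clockwise (with y pointing down) off
the $-x$ axis:

$$A_n = \begin{cases}
\frac{180}{\pi}\arccos\!\big(\tfrac{-\Delta x}{\sqrt{\Delta x^2+\Delta y^2}}\big) & \Delta y \ge 0\\[4pt]
360 - \frac{180}{\pi}\arccos\!\big(\tfrac{-\Delta x}{\sqrt{\Delta x^2+\Delta y^2}}\big) & \Delta y < 0
\end{cases}$$

so $A_n = 0$ is motion toward $-x$ and $A_n = 90$ is motion toward $+y$.
Orientation class $m \in \{1..8\}$ covers $45(m-1) \pm 22.5$ degrees,
with boundaries rounding up and $[337.5, 360)$ wrapping into class 1.
All rotations (event rotation, the address LUT, the synthetic generator)
share one convention: rotating by $A$ maps a reference-motion sample onto
a sample moving at deviation angle $A$, about the pixel-center canvas
midpoint $((W-1)/2, (H-1)/2)$, with nearest-neighbor rounding.

## S1: Gabor bank, event-driven convolution, forgetting

Each kernel is an even-phase Gabor patch of side $s \in \{3,5,7,9\}$ at
orientation $\theta \in \{0,45,90,135\}$ degrees, zero-meaned and
L2-normalized so responses are comparable across sizes. The envelope
follows the standard cortical S1 fits, $\sigma = 0.0036 s^2 + 0.35 s +
0.18$ and $\lambda = \sigma/0.8$, with aspect $\gamma = 0.3$; the source
system states no kernel parameters, so we adopt the published
parameterization of the cortical model it is patterned on, extended down
to sizes 3 and 5. Even (cosine) phase is likewise a choice: the phase is
not stated, and even phase makes each kernel symmetric about its stroke,
which suits line glyphs.

Every incoming event adds each of the 16 kernels, centered at its address
and clipped at the borders, to the map of matching (scale, orientation,
polarity). The forgetting mechanism shrinks each cell's magnitude toward
zero at leak rate $\rho = 5\times10^4$ response-units per second of
stream time, never crossing zero. Because the rule is linear with a floor,
decaying in steps equals one decay over the union interval; the
implementation therefore sweeps the whole stack at each timestamp advance
(compiled code), which is exactly equivalent to per-cell lazy evaluation.
Readout happens at the time of the last event, so the maps describe the
recent history of motion: with the default parameters a unit response
survives about 20 microseconds, i.e. about 20 pixels of travel of the
default synthetic object.

## C1: MAX, threshold, superposition, top-k

Each of the 32 maps is scanned for cells that dominate their own
$s \times s$ neighborhood (the neighborhood equals the kernel size).
Plateau ties keep only the lexicographically first (y, x) cell, making
pooling deterministic. Survivors must strictly exceed the threshold 0.1
("superior" read as strict). ON and OFF survivors are then superposed per
(scale, orientation) map; when both polarities peak at the same address
the larger value is kept — C1 is a MAX stage, and summing would
double-count an edge seen by both polarities. Finally at most
`top_k = 100` peaks (the stated ceiling) survive, ties at the cutoff
broken by address order.

## Orientation detector

Each polarity has a tracker holding a running bivariate normal
$N(\mu, \Sigma)$. An event at $u$ is accepted when its density exceeds
$\delta$, taken adaptively as the density at Mahalanobis distance 3 -
equivalently $(u-\mu)^\top\Sigma^{-1}(u-\mu) < 9$ - which is scale-free
and needs no absolute constant. Accepted events update

$$\mu \leftarrow \alpha_1 \mu + (1-\alpha_1) u,\qquad
\Sigma \leftarrow \alpha_2 \Sigma + (1-\alpha_2)(u-\mu_{old})(u-\mu_{old})^\top,$$

with $\alpha_1 = \alpha_2 = 0.99$ (slow memory, stable centers),
$\mu_0$ = canvas center, $\Sigma_0 = \mathrm{diag}(10^2, 10^2)$ px², and
eigenvalues floored at $\sigma_{min}^2 = 1$ px² to keep $\Sigma$ positive
definite. The covariance update uses the pre-update center (the update
order is not stated in the source; using $\mu_{old}$ makes the update an
exact rank-one convex combination).

For a dark object on a light background the leading edge darkens pixels,
so the OFF center leads and the motion vector is $\mu_{off} - \mu_{on}$;
a light object is the reverse. Which case applies is a configuration
choice (`contrast`), not auto-detected: the source ties it to the
relative intensity of object and background without giving an algorithm.
The angle formula above (printed with arccos; the accompanying prose
mentions arcsine, which we take as a slip since the printed formula is
self-consistent) is validated in the tests against a quadrant-aware
arctangent oracle.

With only a few hundred events per polarity and $\alpha_1 = 0.99$, the
trackers operate in steady pursuit: both lag the moving edges by the same
amount, so the lag cancels in the difference and the angle estimate on
noise-free synthetic crossings is accurate to well under a degree at all
8 canonical directions.

## Address LUT and orientation-map reordering

For class $m$ the LUT sends every address through the rotation by
$-45(m-1)$ degrees (nearest neighbor, drops outside the canvas), i.e. the
rotation that carries a class-$m$ sample's addresses back to the
reference frame. The rotation sign is pinned operationally by a
self-consistency test (rotate a stream by $45(m-1)$, remap with class
$m$, require recovery), which is robust against handedness confusion in
image coordinates. Line orientations are 180-degree periodic, so the four
orientation channels reorder cyclically: canonical $\theta_c$ is fed by
observed $(\theta_c + 45((m-1) \bmod 4)) \bmod 180$, and classes 5-8
reorder exactly like 1-4. Remapping never grows a peak set: dropped
targets are removed and collisions keep the larger value, consistent
with C1.

Nearest-neighbor rounding puts a hard ceiling on exact address recovery
for the 45-degree classes: the forward rotation maps the 1336 in-bounds
sources of a 40x40 grid onto only 1107 distinct targets, so no
deterministic inverse can exactly recover more than 82.9% of addresses
(within one pixel, recovery is essentially complete). The 90-degree
classes are exact permutations. This asymmetry propagates to
classification accuracy: 90-degree-multiple motions are recognized about
as well as unrotated ones, 45-degree motions noticeably worse - the same
degradation pattern the original experiments report.

## Tempotron classifier

C1 peaks become spikes in time-to-first-spike mode over an afferent space
of $16 \times W \times H$ addresses: $t_i = T_{win}(1 - v_i/v_{max})$,
so the strongest peak fires at $t = 0$. Each spike contributes the
normalized double-exponential PSP kernel

$$K(t) = V_0\left(e^{-t/\tau_m} - e^{-t/\tau_s}\right),\qquad
\tau_m = 0.1,\ \tau_s = \tau_m/4,$$

with $V_0$ the analytic normalizer making $\max K = 1$ (peak at
$t^* = \frac{\tau_m\tau_s}{\tau_m-\tau_s}\ln\frac{\tau_m}{\tau_s}$,
$V_0 \approx 2.1165$). $\tau_m$ is given without units; we read it in
units of the pattern window and set $T_{win} = 1$ so the membrane
constant is a tenth of the window. The membrane potential is
$V(t) = \sum_i \omega_i \sum_{t_i} K(t-t_i) + V_{rest}$, evaluated on a
grid of $T_{win}/256$; a neuron fires at the first grid time where
$V > V_{thr}$ and then shunts all later input.

Training is the error-driven tempotron rule under one-hot targets with 10
neurons per category: a neuron that should have fired but did not is
strengthened at the time $t^*$ of its potential peak
($\omega_a \mathrel{+}= \lambda K(t^* - t_a)$, which by causality touches
only spikes before $t^*$); a neuron that fired but should not have is
weakened the same way at its crossing time. Presentations are shuffled
each epoch with the run seed; training stops at 10 epochs or at the first
error-free epoch. Unstated constants are surfaced in
`tempotron_config()`: $\lambda = 3\times10^{-3}$, $V_{thr} = 1$,
$V_{rest} = 0$, weights initialized uniformly in $[0, 0.01]$. The final
decision is majority voting over fired neurons per category; ties
(including the nobody-fired case) fall back to the largest summed peak
potential, which is deterministic and uses the available evidence. The
source also mentions an STDP rule in passing; the learning procedure it
actually describes (the supervised judgment mechanism) is the tempotron
rule, which is what we implement.

A fitted model is an ordinary S3 object; persist it with `saveRDS()` and
reload with `readRDS()` - the weights LUT, address LUT and configuration
travel together.

## The synthetic generator

`generate_stream()` is the download-free test surface: a rigid stroke
glyph (bar, cross, ell, tee, ring; default side 16, stroke thickness 2)
translates across a 40x40 canvas at constant speed. At each one-pixel
step, pixels switching background to foreground emit one event and pixels
switching back emit the opposite polarity - a threshold-free DVS
idealization. The glyph is rotated by the motion angle (an object moving
along its own forward direction), Poisson background noise is added, and
the trajectory gets an integer perpendicular jitter so replicates differ
under seeded control.

Deliberate geometry choices:

* **Even glyph size.** On the even canvas the rotation center is
  (19.5, 19.5); an even glyph's pixel offsets from its own center are
  half-integers, which rotate *exactly* onto the pixel grid at 90-degree
  multiples. Rotation equivariance of the generated streams at 90-degree
  multiples is then exact, and the measured residual error at those
  angles isolates the pipeline rather than the fixture. (Odd glyphs
  desynchronize the 0- and 90-degree streams through banker's rounding
  of half-integer centers.)
* **Cropped crossings by default.** The stream starts with the glyph just
  off-canvas and stops when it sits flush against the far border, still
  fully in view - the form in which crossing recordings are consumed
  (practical samples are cut to the in-view segment). A `"full"` crossing
  (until the glyph has left entirely) is available and is what balances
  ON and OFF counts exactly; its exit phase emits only uncover events,
  which biases the final polarity centers and decayed feature maps toward
  the border.
* **Speed 1000 px/ms** (1 µs per pixel step): keeps the whole crossing
  inside the leak's memory horizon, the regime in which image-converted
  event streams operate. **Noise 5x10^5 events/s** in the default
  datasets: about 40 background events per ~80 µs stream (~4% of signal),
  i.e. a few Hz per pixel at this compressed timescale. **Jitter ±1 px.**

What the generator does *not* emulate: per-pixel threshold mismatch,
refractory periods, realistic DVS noise statistics (hot pixels, bursts),
partial occlusion, scale change, or non-rigid objects. Passing tests
therefore demonstrate the correctness and internal consistency of the
algorithms under idealized event statistics, not field performance on
recorded DVS data.

## The miniature end-to-end experiment

The system-level check trains on 4 glyph classes x 8 replicates moving
only at the reference orientation, and tests on held-out replicates at
all 8 canonical angles (2 per class per angle), plus an unrotated
held-out set (3 per class). Problem sizes were chosen so the whole
experiment is a desk-scale computation (about a minute on one core).
Expected behavior, mirroring the original experiments in miniature:
orientation detection at 100%; accuracy on 90-degree-multiple motions
within a few points of the unrotated accuracy; 45-degree classes clearly
degraded (the LUT rounding ceiling above plus Gabor anisotropy); and
disabling the remapping collapses rotated accuracy toward chance.

```{r, eval = FALSE}
train <- make_dataset(n_per_class = 8, angles = 0, seed = 11)
fit <- aer_recognizer(train)
test <- make_dataset(n_per_class = 2, angles = 45 * (0:7), seed = 123)
aer_evaluate(fit, test)                 # with remapping
aer_evaluate(fit, test, remap = FALSE)  # ablation
```

## Numerical details and degenerate inputs

* Rounding: address rotation uses `round()` (ties to even; ties are
  measure-zero off the 90-degree multiples and exact on them). Gray-level
  encoding rounds half away from zero, pinned by the stated endpoints
  0 -> 0 and 255 -> 16.
* Columns without a differencing partner are zero, keeping image size
  unchanged.
* Method-1 encoding uses a single global threshold (default 10 gray
  units); the source states no value and no per-pixel adaptation.
* Timestamps for image-derived events follow a right-to-left column sweep
  (`assign_timestamps()`), emulating the right-to-left monitor motion of
  the recorded samples; within a column the order is a seeded shuffle
  (arbiter randomness). This is one plausible reading - the source never
  specifies converted-image timestamps.
* An empty peak set yields an empty spike pattern and is classified by
  the zero-fire fallback; a stream with only one polarity makes
  `detect_orientation()` fail loudly (no center), and `predict()` then
  falls back to class 1 (no correction).
* Exact zero deviation between centers is an error (orientation
  undefined) rather than a silent default.

## Known limitations

* The 45-degree classes lose ~17% of addresses to nearest-neighbor
  rounding (provable ceiling), and correspondingly more accuracy; the
  original system shows the same qualitative gap.
* One object per stream; no tracker birth/death or multi-target support.
* The contrast mode (which polarity leads) is configuration, not
  inference.
* Recognition reads the feature maps at the last event; objects that
  leave the view before readout are effectively forgotten by the leak.
* The tempotron operates on exact addresses; its tolerance to small
  translations comes only from training variability, which is why the
  training set includes jittered replicates.
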