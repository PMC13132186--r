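---
title: "Methods: primate-adapted multi-animal tracking and identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primate-adapted multi-animal tracking and identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`primatrack`, the parameters that matter, the design decisions taken where
several readings were defensible, and what the synthetic test scenes do and
do not demonstrate about real field video.

## The tracking model

Tracking is tracking-by-detection: a detector proposes per-frame boxes
(with confidence, class, and optionally a unit-norm appearance embedding),
and the tracker links them into identities. Each track carries an
8-dimensional constant-velocity Kalman state over the measurement
`(cx, cy, a, h)` — box center, aspect ratio `w/h`, and height, all in
pixels — plus per-frame velocities. Process and measurement noise scale
with box height (weights 1/20 for position/size, 1/10 for velocity), so a
large animal close to the camera tolerates proportionally larger
innovations than a distant one. The velocity weight is deliberately high:
the filter locks onto a constant-velocity target within a handful of
frames (one-step prediction error below 10⁻³ px after ten noiseless
updates), which matters because primate motion is better described as
short linear segments than as one long smooth trajectory.

Per frame, the pipeline is, in order:

1. **Score filter.** Detections below `det_threshold` (default **0.1**, a
   deliberately low value) are dropped. A low threshold preserves track
   continuity through motion blur; the false positives it admits are
   handled by the next two mechanisms rather than by raising the cut.
2. **Border filter.** Detections whose box *center* lies strictly closer
   than `border_margin` (default **5 px**) to an image border are dropped;
   spurious detections concentrate there. The geometry of this rule
   (center versus nearest box edge) was an open choice; the center reading
   was taken because an edge-based rule would delete partially visible
   animals at the frame boundary, which contradicts the goal of tracking
   through partial occlusion.
3. **Kalman prediction** for every live track.
4. **Stage-1 association.** One Hungarian assignment on
   `cost = λ·(1 − ⟨e_track, e_det⟩)/2 + (1 − λ)·(1 − IoU(pred_box, det_box))`.
   Both terms live on `[0, 1]`: cosine distance spans `[0, 2]` and is
   halved, because a linear combination of terms on different scales would
   make `λ` meaningless. Location similarity is IoU rather than a
   Mahalanobis gate: it is bounded, unitless, and matches the view that
   location is the stronger cue when individuals look alike
   (default `appearance_weight` λ = **0.5**). Pairs with different class
   ids get infinite cost — a lemur is never matched to a feeding box.
   Assigned pairs costlier than `match_threshold` (default **0.8**) are
   demoted to unmatched.
5. **Stage-2 association** (default on). Leftover tracks are retried
   against leftover detections with the track's *last detection box* as
   its location hypothesis, same λ and threshold. This is the jump-landing
   rescue: during a leap the filter learns a high velocity, and at landing
   it predicts beyond the animal, which in fact stopped near where it was
   last detected. Re-centering the Kalman box on the last detection was a
   possible alternative reading; the last observed box itself is used, as
   the plainer interpretation of checking "at the location of the last
   detection".
6. **Lifecycle.** Matched tracks update the filter and smooth their
   embedding by an EMA (momentum **0.9**, renormalized). Unmatched tracks
   become `lost` and are removed after `max_age` (default **30**) frames
   without a match. Unmatched detections found a new track only if their
   IoU with every surviving track is at most `new_track_overlap_max`
   (default **0.5**) — the gate that keeps low-threshold duplicates from
   spawning phantom identities. Track ids increase strictly in creation
   order and are never reused.

None of the numeric defaults above are prescribed by the method itself;
they are exposed in `tracker_config()` and the YAML config, and were fixed
once at values that produce the qualitative behaviors the design calls for.

A property worth knowing when ablating: with λ = 0.5 and near-identical
embeddings the combined cost cannot exceed ~0.5 + λ/2, so `match_threshold`
= 0.8 effectively never demotes a single-candidate match, and wrong
associations are prevented by Hungarian competition instead. The
jump-rescue A/B experiment (`jump_ab_experiment()`) therefore runs
location-only (λ = 0): that is the setting in which the landing detection
is genuinely unmatched at stage 1 and the second stage is the deciding
mechanism.

## Evaluation metrics

`hota()` implements the reference HOTA: per frame, ground-truth and
predicted boxes are matched by one Hungarian assignment on the product of
frame IoU and a global id-pair alignment score (accumulated from
IoU-normalized co-occurrence over the whole sequence); for each
α ∈ {0.05, …, 0.95} the matches with IoU ≥ α yield DetA(α) and AssA(α),
and the reported scores are means over the 19 thresholds, on the 0–100
scale. Whether published HOTA scores use the official 19-α grid or a
variant is not always stated; the reference grid is implemented. `mota()`
uses per-frame Hungarian matching at IoU ≥ 0.5 and counts an identity
switch when a ground-truth id's matched track id changes between its
consecutive *matched* frames (occlusion gaps skipped — the MOTChallenge
convention). `idf1()` solves the global id bijection on the padded overlap
matrix. `average_precision()` follows the COCO convention (greedy
score-ordered matching, 101-point interpolation, IoU 0.50:0.05:0.95),
which is the standard reading of "mAP" when no variant is named.

In the box-versus-keypoint comparison, a keypoint-mode prediction is the
tight extent of a predicted skeleton (how predicted keypoints were grouped
into individuals is not standardized; the tight extent is the assumption
made here), correct when ≥ 2 keypoints of a single ground-truth individual
fall inside it, optionally after buffering the box 1.5× about its center.
Keypoint containment is *closed* — a point on the box edge counts as
inside, the generous reading. Inter-annotator consistency averages
Hungarian-matched IoU over *all* boxes, unmatched boxes contributing zero
terms (the inclusive reading of averaging "across all boxes").

All box geometry is continuous (areas `w·h`, no rasterization): whether
published IoUs are computed on continuous boxes or pixel grids is usually
unstated, and the continuous choice is resolution-independent; tests
cross-check it against a unit-cell counting oracle on integer boxes.

## Detector head decoding

`decode_detections()` reconstructs boxes from center-point detector heads:
peaks are strict 8-neighbor local maxima of the per-class heatmap (exact
plateau ties break to the smallest (row, column) cell, for determinism);
the center is `(cell + offset)·stride`; size comes from the size map at
the peak; the embedding column is L2-normalized. The offset head is
included even though schematic descriptions of such detectors often omit
it. Exact decoding hyperparameters in trained systems (top-K versus
threshold, NMS flavor) vary; threshold-plus-local-maximum is the
reconstruction used here, with `max_per_frame = 100` per class as a
generous cap for reported primate group sizes.

## Copy-paste synthesis

Label boxes come from mask extreme points with the pixel-inclusive
convention (`width = max_col − min_col + 1`). After pasting (in list
order, later instances occluding earlier ones), each label is recomputed
from the instance's **visible** pixels: a detector can only learn what is
visible, so a half-occluded animal gets a half-size box, and a fully
occluded or out-of-frame instance is dropped from the labels (with a
warning record) rather than poisoning them. Pasting uses hard mask edges
and nearest-neighbor scaling on integer pixels — no blending — both
because sharp edges are an acknowledged artifact of the technique and
because integer operations make composites bit-reproducible. Instance
transforms are scale jitter (default 0.5–1.5) and horizontal flip
(p = 0.5) only; the split is 80/20 at the image level under a seeded
shuffle.

## Individual identification

Crops are squared by growing the shorter box side to the longer
(`square_box()`), then resampled to 224×224 by nearest neighbor;
off-image regions are zero-padded (not edge-clamped), a deterministic
choice that keeps the padding visible to the classifier. Training-time
augmentation — integer jitter up to 5 px per axis, then independent
width/height zoom up to +20 %, then re-squaring — matches the contract
used when fine-tuning an identity classifier on hand-annotated boxes;
inference crops receive no augmentation (assumed, since augmenting at
inference would be unusual).

The track-level vote weights frame `t` by `exp(β·m_t)` with `m_t` the
frame's maximum confidence, and sums weighted confidence vectors. The
exact functional form of "exponentially weighted" voting is a free
parameter of such schemes; this form was chosen because it rewards frames
where the classifier committed while `β = 0` recovers plain summation,
making the sharpening explicit and ablatable (default β = **4**). Ties
break to the lowest identity index and are flagged. "Unsure" frames are
excluded from the vote by default rather than treated as a (K+1)-th
class, since unsureness is an annotation/abstention state, not an
identity; a track with no usable frame abstains and is reported as such.

## The scene simulator

The simulator emulates, at toy scale, the failure modes that matter:
piecewise-constant-velocity motion with reflecting boundaries; occlusions
during which no detection and no ground-truth row is emitted but the
identity persists (matching the annotation convention of re-using the same
id after reappearance); detection noise as Gaussian center jitter,
multiplicative size jitter, Bernoulli misses and Poisson clutter;
embeddings as unit-normalized Gaussian perturbations of per-identity
prototypes equally spaced on the unit circle (separation configurable, so
appearance informativeness can be dialed down to mimic low
inter-individual variation).

**Jump kinematics.** A jump ramps the speed linearly from the current
locomotion speed to `jump_magnitude` × (default 4–5×) over
`jump_duration` frames, aimed toward the image center (±45°) so leaps stay
in frame, then drops the velocity to zero on landing. The ramp is a
deliberate modeling decision: a single instantaneous velocity spike would
defeat *any* frame-to-frame associator at take-off (neither the predicted
box nor the last detection overlaps a detection that teleports by several
body lengths), whereas real take-offs accelerate over a few frames. The
ramp keeps take-off trackable by stage 1 while still producing the
landing overshoot that only stage 2 rescues — which is precisely the
phenomenon the A/B experiment isolates.

Default noise levels (center jitter σ = 1 px, size jitter σ = 2 %, miss
rate 5 %, clutter 0.05/frame, occlusion probability 0.003/frame with mean
duration 6 frames, segment length 30–60 frames) represent a moderately
hard but fair scene: every challenge type is present, and a correctly
working tracker should score HOTA ≥ 90 when misses are disabled. Harsher
settings — longer occlusions spanning a direction change, higher miss
rates — defeat the method itself (the filter cannot know an unseen animal
turned), and the end-to-end checks use them only to demonstrate graceful
degradation.

**What passing these tests does not show.** The simulator has no
appearance variation beyond embedding noise, no articulated bodies, no
camera motion, no lighting changes, and its clutter is spatially uniform
rather than correlated with vegetation. Synthetic results validate the
*algorithms* (association logic, lifecycle rules, metric arithmetic,
vote behavior), not field performance of any trained detector.

## Numerical and interface choices

- Boxes are `(x, y, w, h)` doubles, 0-based, top-left origin; 1-based
  conversions happen only in the MOT reader/writer. MOT files are written
  with 4-decimal coordinates, sorted by frame then id, so read→write is
  byte-stable; COCO JSON is written with fixed key order and full float
  precision.
- The assignment solver is a shortest-augmenting-path Hungarian
  (O(n²m)); forbidden pairs carry a large finite penalty internally, and
  any assigned pair above the caller's cost ceiling is demoted to
  unmatched, so the outputs always partition both index sets.
- Kalman updates symmetrize the posterior covariance and clamp tiny
  negative eigenvalues; a genuinely indefinite covariance raises an
  error. The box implied by the state clamps aspect and height to small
  positive values, since the linear filter does not constrain them.
- Zero-area boxes are legal inputs everywhere except IoU of two
  degenerate boxes, which is an error rather than an arbitrary 0.
- Test problem sizes (≤ 6×6 assignment enumeration, ≤ 5 ids / ≤ 50
  frames for metric oracles, ≤ 3 ids / ≤ 10 frames for the exhaustive
  HOTA oracle, 100 jump scenes, 600-frame end-to-end scenes) were chosen
  so enumeration oracles stay exact and the whole suite runs in minutes
  on one core.

## Known limitations

- Association is purely frame-to-frame; there is no learned association,
  global trajectory optimization, or camera-motion compensation.
- Identification is closed-set: a foreign individual will be assigned to
  the nearest known identity rather than rejected (open-set recognition
  is out of scope).
- The second association stage reuses the stage-1 λ and threshold; a
  separately tuned stage-2 ceiling might rescue more events at some
  false-match cost, and was not explored.
- Occlusions that span a change of direction are unrecoverable by
  construction, and re-identification after track death relies entirely
  on the identity-vote layer downstream.
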