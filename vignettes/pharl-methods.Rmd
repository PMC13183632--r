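---
title: "Physics-aware alignment representation learning for fall-motion windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-aware alignment representation learning for fall-motion windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharl)
```

## The problem

Visually similar fall motions can end in physically very different outcomes:
an arm-braced landing and a direct head impact may share most of their
kinematics. Clinical injury labels that would separate such cases are rare,
noisy and ethically hard to obtain. `pharl` therefore treats fall analysis as
*weakly supervised representation shaping*: coarse, simulation-style contact
outcomes — `Supported`, `Trunk`, `Head` — are used only to restructure the
relations of a contrastive objective, never as a prediction target. The hoped-
for (and here, tested) consequence is an *emergent ordinal organisation* of
the embedding space, `Supported < Trunk < Head`, without any ranking loss.

The unit of learning is a fixed-length, half-open temporal window
`W = [t0, t1)` of a trajectory (one recorded video). Windows inherit their
trajectory's train/val/test split, so no trajectory ever spans splits.

## Window labels from contact evidence

A contact descriptor is an event `(ts, te, body_part, impulse)` in frames and
N·s. Labels are built in three steps:

1. **Temporal alignment** — keep `window`-source descriptors whose interval
   overlaps the window: `(ts < t1) & (te > t0)`. Pre-impact windows of a fall
   thus correctly label `Supported` instead of inheriting the video's worst
   outcome.
2. **Boundary completion** — additionally admit `continuation`-source
   descriptors starting in `[t1, t1 + horizon)`, so impacts immediately after
   a window boundary still inform that window. The horizon defaults to one
   window stride (8 frames); the notion "short-horizon" is not quantified by
   any convention we know of, so the stride is the natural unit.
3. **Reliability filtering** — drop impulses not *strictly greater* than the
   threshold (default 0.0 N·s, which discards exactly zero-impulse artifacts),
   then merge survivors per category (head / trunk / limb) by maximum impulse.

The label is assigned by hierarchical dominance: any head contact ⇒ `Head`;
else any torso/hip contact ⇒ `Trunk`; else `Supported` (limb contacts and
empty evidence alike). Hip counts as trunk; arm, hand, leg and foot are the
non-critical branch. Non-fall trajectories skip descriptor lookup entirely.
The denoising-off ablation (`trajectory_level_labels()`) instead spreads one
dominance label over every window of the trajectory.

Two labeling decisions were genuinely open and are flagged as package
choices: continuation events qualify by their *start* falling after `t1`
(merely extending past `t1` is the ordinary overlap case), and the impulse
filter is strict (`>`) so the printed 0.0 N·s default keeps all real contacts.

## Relations and objectives

For each anchor window `i` in a batch (optionally pooled with a FIFO memory
bank) the relation graph holds:

* `P_traj(i)` — windows of the same trajectory (temporal positives),
* `A(i)` — all candidates except `i` itself,
* `M(i)` — the *denominator mask*: cross-trajectory contact windows, built
  only for contact anchors (`C_i = 1`, i.e. `Head`/`Trunk`); removing them
  from the denominator prevents false repulsion between contact windows,
* `Q(i)` — cross-trajectory candidates,
* `P_phys(i)` — physics positives: cross-trajectory windows of *exactly* the
  same class (`multiclass_physics`), or merely the same contact flag
  (`binary_physics`, the fused ablation).

The loss combines three terms,

$$\mathcal{L} = \mathcal{L}_\text{motion}
  + w(t)\,\lambda_\text{phys}\,\mathcal{L}_\text{physics}
  + \lambda_\text{var}\,\mathcal{L}_\text{var},$$

with the masked trajectory contrast
$\mathcal{L}_\text{motion} = -\log \frac{\sum_{j \in P^\text{traj}_i} e^{\mathrm{sim}(z_i,z_j)/\tau}}
{\sum_{k \in A_i \setminus M_i} e^{\mathrm{sim}(z_i,z_k)/\tau}}$
(mean over anchors with nonempty positive sets; with all masks empty this is
exactly the plain trajectory-contrast objective), the physics alignment term
of the same form over `P_phys` / `Q` at temperature $\tau_p$ (anchors with
empty positive sets are skipped), and a hinge variance regularizer
$\mathcal{L}_\text{var} = \tfrac1d\sum_j \max(0, \gamma - \sqrt{\mathrm{Var}_j + 10^{-4}})$
on the per-dimension batch statistics of the *raw* projector outputs. The
physics weight ramps linearly from 0 to 1 over the first
`warmup_fraction` of training.

Defaults: $\tau = \tau_p = 0.2$ (the established values for this objective
family), $\lambda_\text{phys} = 1$, $\lambda_\text{var} = 0.1$,
`warmup_fraction = 0.1`, $\gamma = 1$. The weights and the exact variance
formula are package decisions — only the temperatures have an established
printed value — and all are config-exposed. The variance term follows the
VICReg-style hinge because it is the simplest anti-collapse penalty that
leaves the contrastive geometry untouched once per-dimension spread reaches
$\gamma$. All softmax ratios are computed in log space (compiled in
`src/contrastive.cpp`); losses stay finite under similarity scaling far
beyond the unit-cosine range.

The temporal-only control removes every physics-specific component
($\lambda_\text{phys} = \lambda_\text{var} = 0$, no masks, no stratified
sampling) while sharing the architecture, data, learning rate and
temperature, so metric differences are attributable to supervision design,
not capacity.

## Encoder and training

The encoder is deliberately small: temporal average pooling over the window's
frames, a one-hidden-layer ReLU trunk (default width 32), a linear projection
head (default `d = 16`), and ℓ2 normalization; raw projector outputs feed the
variance term. RGB backbones are out of scope here — the simulator emits
motion features directly — and the encoder is pluggable. Inputs are
standardized with train-split statistics stored in the checkpoint. Labels
cannot enter the encode path: `encode()` accepts feature arrays only.

Training uses Adam with hand-derived gradients (exact, finite-difference
checked), physics-stratified batches (each batch keeps at least
`min_per_class = 2` windows of every class while supplies last, dealt in
blocks so scarce classes still co-occur within a batch), and a shared FIFO
memory bank whose entries join the candidate pools but never receive
gradient. Validation loss is computed each epoch at final-schedule weights
(`w = 1`) so epochs are comparable; the minimum-validation-loss checkpoint is
kept alongside the final one. Runs are bit-deterministic on one CPU under a
fixed seed; every substream (simulation, batching, POA sampling, retrieval
balancing) derives from the one global seed.

API defaults keep the reference schedule (100 epochs, lr `1e-4`, bank
capacity 4096). The *desk experiment protocol* used by the bundled
experiments and `scripts/acceptance.R` differs deliberately: lr `1e-3` and 50
epochs, because the reference schedule belongs to a far larger RGB backbone —
under it the small MLP is still far from its validation plateau at epoch 100,
while at lr `1e-3` the validation loss plateaus around epoch 40–50; and bank
capacity 512, since 4096 would exceed the desk-scale training split
(≈3,400 windows) outright. These were fixed from convergence diagnostics
before the evaluation experiments were run.

## The synthetic benchmark

No public fall dataset ships with contact descriptors, and the offline
humanoid simulation that would produce them is out of scope, so the package
bundles a statistical stand-in (it makes no claim to contact physics —
restitution, impulse scales and timing are modeled only distributionally):

* **Trajectories.** 300 videos by default, 120 frames at a nominal 25 fps;
  60% falls. Fall outcomes follow the reported training-split imbalance
  (Supported 56% / Trunk 34% / Head 10%). Falls traverse pre-impact → impact
  (8–12 frames) → rest; ADL (non-fall) trajectories stay in the pre-impact
  regime.
* **Latent severity.** Each fall carries a severity scalar in
  `[0.7, 1.3]`, `[1.7, 2.3]`, `[2.7, 3.3]` for Supported/Trunk/Head — monotone
  in the class by construction, which is what "recovering the ordering" means
  here.
* **Features.** Per frame: a smoothed 3-channel phase indicator times a
  class-dependent linear map, plus a per-video nuisance vector (constant
  within a video, i.i.d. across videos, comparable in magnitude to the
  signal) plus white noise (sd 0.5). The impact row of the map is
  `base + 2·severity·u + 0.75·w_class`; the rest row carries the same class
  signal at half strength (how one ends up lying differs by outcome). The
  severity direction `u` dominates the class-specific signature `w_class`,
  so the ordinal axis is linearly present but entangled with phase, nuisance
  and noise. An early draft weighted `w_class` at 1.5 and left the rest
  posture class-blind; with class signatures as strong as the severity
  signal the latent ordering is not dominantly recoverable even in
  principle, contradicting the generator's design goal, so the present
  feature model was fixed instead.
* **Contacts.** True impacts draw impulses from LogNormal(meanlog 1,
  sdlog 0.3) N·s; body parts encode the outcome (head; torso/hip; arm/hand),
  with an optional secondary contact nested inside the primary interval so
  dominance, not timing, decides labels. After the impact the body stays on
  the ground, so the stream keeps reporting weaker sustained contacts
  (LogNormal(0, 0.3) N·s, every ~16 frames) on the outcome's body parts
  through the rest phase — this is what gives short trimmed fall clips their
  heavy contact coverage (about two thirds of fall windows carry a contact
  label; the window-level mix is then roughly 82/14/4, the closest a
  56/34/10 *trajectory*-outcome mix can come to the reported window-level
  imbalance). Spurious impulses (≤ 0.05 N·s, Poisson rate 0.3/trajectory,
  any body part) exercise the reliability filter; with the default 0.0 N·s
  threshold a small amount of label noise survives, which is the realistic
  weak-supervision condition. With probability 0.25 the impact onset lands
  within one stride after a window boundary and the impact descriptors are
  duplicated with `source = "continuation"`, exercising boundary completion.
* **Splits.** Trajectory-level 80/10/10, stratified over ADL and the three
  fall outcomes.

What the simulator does *not* emulate: appearance, viewpoint or occlusion
effects, multi-camera geometry (one video per trajectory), environment
contact (furniture, compliant floors), and any true impact dynamics. Passing
the bundled experiments therefore shows that the objectives recover a latent
ordinal contact structure under heavy nuisance — not that the method works on
real video.

## Evaluation suite

All diagnostics are post hoc. The severity axis is the unit vector from the
`Supported` to the `Head` train-split centroid; test windows are scored by
projection. Reported, in priority order: Spearman's ρ and macro pairwise
ordering accuracy (exhaustive up to 10⁵ pairs per ordered class pair, seeded
uniform sampling beyond; ties 0.5), binary-contact AP and ROC-AUC of a
deterministic ridge probe (closed-form solve, λ = 1, train-split fit), fall
AUC (window-level, trajectory-inherited tags), the physics consistency ratio
(mean inter-class over mean intra-class Euclidean distance on normalized
embeddings; a cosine variant is config-exposed), Kendall's τ-b, and
cross-video neighborhood consistency (class-balanced database subsampled to
the minority class, cosine k-NN with same-video exclusion, k = 10,
row-normalized diagonal). Degenerate inputs (missing classes, constant
scores, single-video classes) surface as structured reasons, never silent
NaNs.

## A worked toy example

```{r toy, eval = FALSE}
toy <- make_fixture("toy_labeling")
label_dataset(toy$manifest, toy$descriptors)[, 1:4]
#>   window_id    y_phys ordinal_code contact_flag
#> 1    tA_w01 Supported            0            0
#> 2    tA_w02 Supported            0            0
#> 3    tA_w03      Head            2            1
#> 4    tA_w04      Head            2            1
#> 5    tB_w01 Supported            0            0
#> 6    tB_w02 Supported            0            0
```

Window `tA_w01` overlaps only a hand contact (non-critical branch),
`tA_w02` only a zero-impulse torso artifact (dropped by the strict filter),
`tA_w03` the head+torso impact, and `tA_w04` the straddling head impact; the
ADL video `tB` never consults the stream.

## Known limitations

* The feature simulator is linear-Gaussian at heart; encoders much larger
  than the default MLP can overfit its structure, which is why capacity is
  matched across arms rather than maximized.
* Head windows are rare (≈1% of windows at the default mix), so Head-related
  quantities (axis centroid, `Trunk<Head` ordering accuracy, Head
  neighborhood consistency) carry the largest seed-to-seed variance — the
  bundled experiments therefore aggregate over five seeds.
* The memory bank stores stale embeddings by design; with very small batches
  and aggressive learning rates the staleness can slow early training.
* `pharl` produces no severity scores or clinical predictions; projections
  onto the severity axis are diagnostics only.
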