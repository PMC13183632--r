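# pharl — physics-aware alignment representation learning for fall-motion windows

Visually similar fall motions can have very different physical outcomes: an
arm-braced landing and a direct head impact may share most of their
kinematics, and clinical injury labels that would tell them apart are rare
and noisy. `pharl` is for researchers in human-movement analysis and digital
health who want fall-motion embeddings whose *geometry* reflects
physics-derived contact outcomes — without ever training an outcome
predictor.

The package implements, end to end:

* a **synthetic fall simulator** (trajectories with pre-impact / impact /
  rest phases, per-video nuisance, contact-descriptor streams with a latent
  severity ordering, spurious impulses and boundary-straddling impacts),
* **window-level label denoising**: a window `W = [t0, t1)` keeps contact
  descriptors with `(ts < t1) ∧ (te > t0)`, admits short-horizon
  `continuation` evidence starting in `[t1, t1 + horizon)`, drops impulses
  not strictly above a threshold, merges per-category by maximum impulse,
  and labels by hierarchical dominance
  (head ⇒ `Head`; torso/hip ⇒ `Trunk`; otherwise `Supported`),
* **physics-structured contrastive learning** over relation graphs
  `P_traj / A / M / P_phys / Q`:

  ```
  L = -log Σ_{j∈P_traj} e^{sim(z_i,z_j)/τ} / Σ_{k∈A∖M} e^{sim(z_i,z_k)/τ}
      + w(t)·λ_phys · [ -log Σ_{j∈P_phys} e^{sim/τ_p} / Σ_{k∈Q} e^{sim/τ_p} ]
      + λ_var · mean_j max(0, γ − sqrt(Var_j + 1e-4))
  ```

  with denominator masking `M_i = {k : C_i = 1, C_k = 1, traj(k) ≠ traj(i)}`
  removing cross-trajectory contact windows from contact anchors'
  denominators, and exact-class cross-trajectory physics positives,
* a **deterministic training loop** (MLP encoder over pooled window
  features, hand-derived gradients, Adam, physics-stratified batches, FIFO
  memory bank, best-validation checkpointing), and
* the **ordinal/geometric diagnostic suite**: severity-axis projections,
  Spearman ρ, Kendall τ-b, macro pairwise ordering accuracy (POA), linear
  probes (contact AP/AUC, fall AUC), physics consistency ratio (PCR), and
  cross-video neighborhood consistency.

## Worked example

```r
library(pharl)

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

`tA_w01` overlaps only a hand contact (the non-critical branch maps limb
contacts to `Supported`), `tA_w02` only a zero-impulse artifact dropped by
the strict `> 0.0 N·s` filter, `tA_w03` a head + torso impact (dominance
ignores the torso's larger 9.9 N·s impulse), `tA_w04` a boundary-straddling
head impact, and the ADL video `tB` never consults the descriptor stream.

At experiment scale, the paired comparison on one 300-trajectory simulation
(seed 1; `ablation_matrix()` over the denoise and multiclass switches):

```r
cfg <- pharl_config(seed = 1, sim = list(n_trajectories = 300),
                    train = list(lr = 1e-3, epochs = 50L))
ablation_matrix(cfg, switches = c("denoise", "multiclass"))
#>       config spearman_rho poa_macro contact_ap proj_supported proj_trunk proj_head
#>      control    0.1236907 0.6153023  0.4707541      -0.056411 -0.0056298 0.0736983
#>   no_denoise    0.4510975 0.8519865  0.8290505       0.125288  0.5319115 0.7864112
#>       binary    0.5587250 0.8710713  0.8808259       0.120149  0.7443552 0.8325566
#>         full    0.5524633 0.8645944  0.8777278       0.105854  0.6984426 0.8027813
```

The full physics-aligned configuration recovers the latent severity
structure: Spearman ρ of 0.55 against 0.12 for the capacity-matched
temporal-only control, POA 0.86 vs 0.62, and mean severity-axis projections
ordered `Head > Trunk > Supported`. Dropping the denoising step (trajectory-
level labels) costs about 0.1 ρ. On this synthetic benchmark the binary-
attraction arm is statistically indistinguishable from exact-class
attraction — the generator's strictly separated severity bands leave little
for the exact-class term to add (see the methods vignette).

## Layout

* `R/` — simulator, labeling, relations, objectives (log-space, compiled
  core in `src/contrastive.cpp`), training, evaluation, IO/config/pipeline
* `vignettes/pharl-methods.Rmd` — the model, its assumptions, parameter
  choices, and what the synthetic benchmark does and does not show
* `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles
* `inst/cli/pharl` — command-line entry point
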