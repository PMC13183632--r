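# Closed forms, invariances and gradient correctness of the composite loss.

uniform_batch <- function(ctx, d = 4) {
  # identical unit embeddings: every pairwise cosine similarity is exactly 1
  z <- matrix(rep(1 / sqrt(d), d), nrow(ctx), d, byrow = TRUE)
  list(z = z, raw = z * 3)
}

random_batch <- function(n, d, seed) {
  with_seed(seed, {
    raw <- matrix(stats::rnorm(n * d), n, d)
    list(z = l2_normalize(raw), raw = raw)
  })
}

test_that("cosine similarity basics", {
  z <- c(0.6, 0.8)
  expect_equal(cosine_sim(z, z), 1)
  expect_equal(cosine_sim(z, -z), -1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_sim(c(0, 0), z), "zero-norm")
})

test_that("uniform-similarity batches hit the counting closed forms", {
  toy <- make_fixture("toy_relations")
  cfg <- loss_config()
  rel <- build_relations(toy$contexts, mode = "multiclass_physics")
  emb <- uniform_batch(toy$contexts)
  # anchor 1 is the only one with trajectory positives (|P|=1);
  # its masked denominator is A \ M = {2,3,4} \ {3} = {2,4}
  expect_equal(as.numeric(motion_loss(emb, rel, cfg)), -log(1 / 2), tolerance = 1e-9)
  relt <- build_relations(toy$contexts, mode = "temporal_only")
  expect_equal(as.numeric(motion_loss(emb, relt, cfg)), -log(1 / 3), tolerance = 1e-9)
  # binary attraction: anchors 1,2 attract the Trunk window {3} over
  # Q = {3,4}; anchor 3 attracts {1,2} over Q = {1,2,4}
  relb <- build_relations(toy$contexts, mode = "binary_physics")
  expect_equal(as.numeric(physics_loss(emb, relb, cfg)),
               mean(c(-log(1 / 2), -log(1 / 2), -log(2 / 3))), tolerance = 1e-9)
})

test_that("two same-trajectory windows with similarity one give zero loss", {
  ctx <- data.frame(trajectory_id = c("t", "t"), ordinal_code = c(0L, 0L),
                    contact_flag = c(0L, 0L))
  rel <- build_relations(ctx, mode = "multiclass_physics")
  emb <- uniform_batch(ctx)
  expect_equal(as.numeric(motion_loss(emb, rel, loss_config())), 0, tolerance = 1e-12)
})

test_that("masked loss equals the unmasked objective when no window is masked", {
  for (s in 1:10) {
    ctx <- random_contexts(12, 4, seed = s)
    ctx$ordinal_code <- 0L; ctx$contact_flag <- 0L   # all Supported: masks empty
    emb <- random_batch(12, 6, seed = 100 + s)
    cfg <- loss_config()
    lm_phys <- motion_loss(emb, build_relations(ctx, mode = "multiclass_physics"), cfg)
    lm_temp <- motion_loss(emb, build_relations(ctx, mode = "temporal_only"), cfg)
    expect_identical(as.numeric(lm_phys), as.numeric(lm_temp))
  }
})

test_that("masking never increases the motion loss", {
  for (s in 1:30) {
    ctx <- random_contexts(14, 4, seed = 200 + s)
    emb <- random_batch(14, 6, seed = 300 + s)
    cfg <- loss_config()
    masked <- motion_loss(emb, build_relations(ctx, mode = "multiclass_physics"), cfg)
    unmasked <- motion_loss(emb, build_relations(ctx, mode = "temporal_only"), cfg)
    expect_lte(as.numeric(masked), as.numeric(unmasked) + 1e-12)
  }
})

test_that("physics loss degenerate cases", {
  # P_phys = Q: two trajectories, both Head -> ratio 1, loss 0
  ctx <- data.frame(trajectory_id = c("a", "b"), ordinal_code = c(2L, 2L),
                    contact_flag = c(1L, 1L))
  rel <- build_relations(ctx, mode = "multiclass_physics")
  emb <- random_batch(2, 5, seed = 1)
  expect_equal(as.numeric(physics_loss(emb, rel, loss_config())), 0, tolerance = 1e-12)
  # Supported anchors are excluded entirely
  ctx2 <- data.frame(trajectory_id = c("a", "b"), ordinal_code = c(0L, 0L),
                     contact_flag = c(0L, 0L))
  rel2 <- build_relations(ctx2, mode = "multiclass_physics")
  lp <- physics_loss(emb, rel2, loss_config())
  expect_equal(as.numeric(lp), 0)
  expect_true(attr(lp, "no_contributors"))
})

test_that("variance regularizer closed forms", {
  cfg <- loss_config(variance_gamma = 1)
  collapsed <- matrix(0.3, 8, 5)
  expect_equal(variance_loss(collapsed, cfg), 1 - sqrt(1e-4), tolerance = 1e-12)
  spread <- with_seed(3, matrix(stats::rnorm(200 * 4, sd = 10), 200, 4))
  expect_equal(variance_loss(spread, cfg), 0)
  hand <- rbind(c(0, 0), c(2, 2))   # per-dimension sample sd = sqrt(2) >= gamma
  expect_equal(variance_loss(hand, cfg), 0)
  expect_error(variance_loss(matrix(1, 1, 3), cfg), "at least 2")
})

test_that("total loss composition and warmup schedule", {
  toy <- make_fixture("toy_relations")
  rel <- build_relations(toy$contexts, mode = "multiclass_physics")
  emb <- random_batch(4, 3, seed = 9)
  ctl <- loss_config(lambda_phys = 0, lambda_var = 0)
  tl <- total_loss(emb, rel, ctl, epoch_progress = 1)
  expect_identical(tl$total, tl$motion)
  full <- loss_config(lambda_phys = 2, lambda_var = 0.5, warmup_fraction = 0.2)
  t0 <- total_loss(emb, rel, full, epoch_progress = 0)
  expect_identical(t0$phys_weight, 0)
  expect_equal(t0$total, t0$motion + 0.5 * t0$variance)
  t_half <- total_loss(emb, rel, full, epoch_progress = 0.1)
  expect_equal(t_half$phys_weight, 0.5)
  t_full <- total_loss(emb, rel, full, epoch_progress = 0.7)
  expect_identical(t_full$phys_weight, 1)
  expect_equal(t_full$total,
               t_full$motion + 2 * t_full$physics + 0.5 * t_full$variance)
})

test_that("losses stay finite under similarity scaling and batch permutation", {
  ctx <- random_contexts(10, 3, seed = 77)
  emb <- random_batch(10, 4, seed = 78)
  rel <- build_relations(ctx, mode = "multiclass_physics")
  big <- pharl:::contrastive_term(50 * pharl:::sim_matrix(emb$z), rel$P_traj, rel$A, 0.2)
  expect_true(is.finite(big$value))

  cfg <- loss_config()
  base <- total_loss(emb, rel, cfg, epoch_progress = 1)
  perm <- with_seed(5, sample.int(10))
  ctx_p <- ctx[perm, , drop = FALSE]
  emb_p <- list(z = emb$z[perm, , drop = FALSE], raw = emb$raw[perm, , drop = FALSE])
  rel_p <- build_relations(ctx_p, mode = "multiclass_physics")
  perm_loss <- total_loss(emb_p, rel_p, cfg, epoch_progress = 1)
  expect_equal(perm_loss$total, base$total, tolerance = 1e-9)
  expect_equal(perm_loss$motion, base$motion, tolerance = 1e-9)
  expect_equal(perm_loss$physics, base$physics, tolerance = 1e-9)
})

test_that("analytic gradients match finite differences", {
  ctx <- random_contexts(7, 3, seed = 41)
  raw <- with_seed(42, matrix(stats::rnorm(7 * 4), 7, 4))
  rel <- build_relations(ctx, mode = "multiclass_physics")
  cfg <- loss_config(lambda_phys = 0.7, lambda_var = 0.3, warmup_fraction = 0)
  f <- function(r) {
    pharl:::total_loss_grad(r, l2_normalize(r), rel, cfg, epoch_progress = 1)$total
  }
  an <- pharl:::total_loss_grad(raw, l2_normalize(raw), rel, cfg, epoch_progress = 1)$dRaw
  eps <- 1e-6
  num <- raw * 0
  for (i in seq_len(nrow(raw))) {
    for (j in seq_len(ncol(raw))) {
      up <- raw; up[i, j] <- up[i, j] + eps
      dn <- raw; dn[i, j] <- dn[i, j] - eps
      num[i, j] <- (f(up) - f(dn)) / (2 * eps)
    }
  }
  expect_equal(an, num, tolerance = 1e-5)
})

test_that("one optimizer step decreases the loss on a toy batch", {
  toy <- make_fixture("toy_training")
  labels <- label_dataset(toy$manifest, toy$descriptors)
  idx <- match(toy$manifest$window_id, labels$window_id)
  ctx <- data.frame(trajectory_id = toy$manifest$trajectory_id,
                    ordinal_code = labels$ordinal_code[idx],
                    contact_flag = labels$contact_flag[idx])
  take <- which(toy$manifest$split == "train")[1:40]
  ctx <- ctx[take, ]
  enc <- encoder_init(encoder_config(feature_dim = 8, seed = 3))
  x <- pharl:::pool_features(toy$manifest$features[take])
  enc$center <- colMeans(x); enc$scale <- apply(x, 2, stats::sd)
  rel <- build_relations(ctx, mode = "multiclass_physics")
  cfg <- loss_config(warmup_fraction = 0)
  fwd <- pharl:::encoder_forward(enc, x)
  lg <- pharl:::total_loss_grad(fwd$raw, fwd$z, rel, cfg, epoch_progress = 1)
  upd <- pharl:::adam_step(enc, pharl:::encoder_backward(enc, fwd, lg$dRaw),
                           pharl:::adam_init(enc), lr = 1e-4)
  fwd2 <- pharl:::encoder_forward(upd$encoder, x)
  lg2 <- pharl:::total_loss_grad(fwd2$raw, fwd2$z, rel, cfg, epoch_progress = 1)
  expect_lt(lg2$total, lg$total)
})
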