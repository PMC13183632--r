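# Training loop: physics-stratified batching, the composite contrastive
# objective, Adam updates, per-epoch validation with final-schedule weights,
# and best-validation checkpoint selection. Deterministic on one CPU under a
# fixed seed.

#' Training configuration
#'
#' @param epochs Number of epochs; the printed schedule is 100, toy fixtures
#'   use 20.
#' @param batch_size Windows per batch.
#' @param lr Adam learning rate (printed value 1e-4).
#' @param min_per_class Per-batch class floor for stratified sampling.
#' @param mode Relation mode: `"temporal_only"`, `"binary_physics"` or
#'   `"multiclass_physics"`.
#' @param bank_enabled Use the FIFO memory bank.
#' @param bank_capacity Bank capacity when enabled.
#' @param include_bank_in_physics Whether bank entries join the physics sets.
#' @param seed Training seed (initialization and batch order).
#' @return An object of class `pharl_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L, lr = 1e-4,
                         min_per_class = 2L, mode = "multiclass_physics",
                         bank_enabled = FALSE, bank_capacity = 4096L,
                         include_bank_in_physics = TRUE, seed = 1L) {
  mode <- match.arg(mode, RELATION_MODES)
  if (!is_count(epochs) || !is_count(batch_size)) {
    stop("`epochs` and `batch_size` must be counts", call. = FALSE)
  }
  if (lr <= 0) stop("`lr` must be positive", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, min_per_class = as.integer(min_per_class), mode = mode,
                 bank_enabled = isTRUE(bank_enabled),
                 bank_capacity = as.integer(bank_capacity),
                 include_bank_in_physics = isTRUE(include_bank_in_physics),
                 seed = as.integer(seed)),
            class = "pharl_train_config")
}

assert_split_integrity <- function(manifest) {
  tab <- unique(manifest[, c("trajectory_id", "split")])
  dup <- tab$trajectory_id[duplicated(tab$trajectory_id)]
  if (length(dup)) {
    stop(sprintf("trajectory %s spans multiple splits (window leakage)", dup[1L]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Train a window encoder with the composite objective
#'
#' Joins the manifest with window-level physics labels, checks trajectory-level
#' split integrity, then trains the encoder with physics-stratified batches and
#' the masked trajectory + physics-alignment + variance objective. Validation
#' loss is computed each epoch at final-schedule weights (warmup weight 1) so
#' epochs are comparable; the minimum-validation-loss weights are kept as the
#' best checkpoint alongside the final-epoch checkpoint.
#'
#' @param manifest Window manifest (with `split` and `features`).
#' @param labels Label table from [label_dataset()].
#' @param encoder_cfg An [encoder_config()]; its `feature_dim` must match the
#'   manifest features.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list of class `pharl_train_state` with `best` and `final`
#'   checkpoints, the per-epoch `history` data frame, and configuration.
#' @export
fit_pharl <- function(manifest, labels, encoder_cfg, loss_cfg = loss_config(),
                      train_cfg = train_config(), verbose = FALSE) {
  assert_split_integrity(manifest)
  ix <- match(manifest$window_id, labels$window_id)
  if (anyNA(ix)) stop("labels are missing for some manifest windows", call. = FALSE)
  meta <- data.frame(
    window_id = manifest$window_id, trajectory_id = manifest$trajectory_id,
    video_id = manifest$video_id, split = manifest$split,
    fall_label = manifest$fall_label,
    ordinal_code = labels$ordinal_code[ix],
    contact_flag = labels$contact_flag[ix],
    stringsAsFactors = FALSE
  )
  x_all <- pool_features(manifest$features, encoder_cfg$feature_dim)
  tr <- which(meta$split == "train")
  va <- which(meta$split == "val")
  if (!length(tr)) stop("no training windows", call. = FALSE)

  enc <- encoder_init(encoder_cfg)
  enc$center <- colMeans(x_all[tr, , drop = FALSE])
  enc$scale <- pmax(apply(x_all[tr, , drop = FALSE], 2L, stats::sd), 1e-8)
  arch_hash <- config_hash(unclass(encoder_cfg))

  opt <- adam_init(enc)
  bank <- if (train_cfg$bank_enabled) {
    memory_bank(train_cfg$bank_capacity, encoder_cfg$embed_dim)
  }
  history <- vector("list", train_cfg$epochs)
  best_val <- Inf
  best_enc <- enc
  best_epoch <- NA_integer_
  steps_per_epoch <- max(1L, ceiling(length(tr) / train_cfg$batch_size))

  for (epoch in seq_len(train_cfg$epochs)) {
    batches <- stratified_batches(meta[tr, , drop = FALSE], train_cfg$batch_size,
                                  train_cfg$min_per_class,
                                  seed = derive_seed(train_cfg$seed, "batch", epoch))
    ep_losses <- numeric(0)
    ep_motion <- numeric(0); ep_phys <- numeric(0); ep_var <- numeric(0)
    for (b in seq_along(batches)) {
      rows <- tr[batches[[b]]]
      ctx <- meta[rows, , drop = FALSE]
      fwd <- encoder_forward(enc, x_all[rows, , drop = FALSE])
      bank_ctx <- if (!is.null(bank) && nrow(bank$z)) bank$contexts
      bank_z <- if (!is.null(bank) && nrow(bank$z)) bank$z
      rel <- relation_masks(ctx, bank = bank_ctx, mode = train_cfg$mode,
                            include_bank_in_physics = train_cfg$include_bank_in_physics)
      progress <- (epoch - 1 + (b - 1) / length(batches)) / train_cfg$epochs
      lg <- total_loss_grad(fwd$raw, fwd$z, rel, loss_cfg,
                            epoch_progress = progress, bank_z = bank_z)
      grads <- encoder_backward(enc, fwd, lg$dRaw)
      upd <- adam_step(enc, grads, opt, train_cfg$lr)
      enc <- upd$encoder; opt <- upd$state
      if (!is.null(bank)) bank <- memory_bank_update(bank, fwd$z, ctx)
      ep_losses <- c(ep_losses, lg$total)
      ep_motion <- c(ep_motion, lg$motion)
      ep_phys <- c(ep_phys, lg$physics)
      ep_var <- c(ep_var, lg$variance)
    }
    val_loss <- NA_real_
    if (length(va) > 1L) {
      vf <- encoder_forward(enc, x_all[va, , drop = FALSE])
      vrel <- build_relations(meta[va, , drop = FALSE], mode = train_cfg$mode)
      vl <- total_loss(list(z = vf$z, raw = vf$raw), vrel, loss_cfg,
                       epoch_progress = 1)
      val_loss <- vl$total
      if (val_loss < best_val) {
        best_val <- val_loss
        best_enc <- enc
        best_epoch <- epoch
      }
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(ep_losses), motion = mean(ep_motion),
      physics = mean(ep_phys), variance = mean(ep_var), val_loss = val_loss
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch, mean(ep_losses),
                      ifelse(is.na(val_loss), "NA", sprintf("%.4f", val_loss))))
    }
  }
  if (!is.finite(best_val)) { best_enc <- enc; best_epoch <- train_cfg$epochs }
  mk_ckpt <- function(e) structure(list(
    encoder = e, arch_hash = arch_hash, mode = train_cfg$mode,
    loss_config = loss_cfg, train_config = train_cfg
  ), class = "pharl_checkpoint")
  structure(list(
    best = mk_ckpt(best_enc), final = mk_ckpt(enc),
    best_val_loss = best_val, best_epoch = best_epoch,
    history = do.call(rbind, history), arch_hash = arch_hash,
    steps_per_epoch = steps_per_epoch
  ), class = "pharl_train_state")
}

#' Save / load a checkpoint
#'
#' Checkpoints embed the encoder weights, normalization statistics and the
#' architecture hash used for capacity-parity checks.
#'
#' @param ckpt A `pharl_checkpoint`.
#' @param path File path.
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "pharl_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "pharl_checkpoint")) stop("not a pharl checkpoint", call. = FALSE)
  ckpt
}

#' Embed every window of a manifest
#'
#' Pure feed-forward inference: consumes only the manifest's feature arrays
#' and a checkpoint; no descriptor stream and no labels are read.
#'
#' @param checkpoint A `pharl_checkpoint` or a path to one.
#' @param manifest Window manifest.
#' @return A list of class `pharl_embedding_table`: `meta` (window_id,
#'   trajectory_id, video_id, split, fall_label) and `z` (n x d unit rows).
#' @export
embed_dataset <- function(checkpoint, manifest) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  stopifnot(inherits(checkpoint, "pharl_checkpoint"))
  emb <- encode(manifest$features, checkpoint$encoder)
  structure(list(
    meta = data.frame(
      window_id = manifest$window_id, trajectory_id = manifest$trajectory_id,
      video_id = manifest$video_id, split = manifest$split,
      fall_label = manifest$fall_label, stringsAsFactors = FALSE
    ),
    z = emb$z
  ), class = "pharl_embedding_table")
}
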