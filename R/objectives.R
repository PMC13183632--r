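# Composite contrastive objective: masked trajectory contrast, auxiliary
# physics alignment, and a variance (anti-collapse) regularizer, combined as
#   L = L_motion + w(progress) * lambda_phys * L_physics + lambda_var * L_var
# with w ramping linearly from 0 to 1 over the warmup fraction of training.
# All softmax ratios are computed in log space.

#' Loss configuration
#'
#' @param tau Motion-branch temperature (> 0); default 0.2.
#' @param tau_p Physics-branch temperature (> 0); default 0.2.
#' @param lambda_phys Weight of the physics-alignment term (>= 0).
#' @param lambda_var Weight of the variance regularizer (>= 0).
#' @param warmup_fraction Fraction of training over which the physics weight
#'   ramps linearly from 0 to 1, in `[0, 1]`.
#' @param variance_gamma Target per-dimension standard deviation of the raw
#'   projector outputs (> 0); deviations below it are penalized (hinge).
#' @return An object of class `pharl_loss_config`.
#' @export
loss_config <- function(tau = 0.2, tau_p = 0.2, lambda_phys = 1.0,
                        lambda_var = 0.1, warmup_fraction = 0.1,
                        variance_gamma = 1.0) {
  if (tau <= 0 || tau_p <= 0) stop("temperatures must be strictly positive", call. = FALSE)
  if (lambda_phys < 0 || lambda_var < 0) stop("loss weights must be nonnegative", call. = FALSE)
  stop_if_not_scalar_prob(warmup_fraction, "warmup_fraction")
  if (variance_gamma <= 0) stop("`variance_gamma` must be positive", call. = FALSE)
  structure(list(tau = tau, tau_p = tau_p, lambda_phys = lambda_phys,
                 lambda_var = lambda_var, warmup_fraction = warmup_fraction,
                 variance_gamma = variance_gamma),
            class = "pharl_loss_config")
}

#' Cosine similarity of two vectors
#'
#' @param z_i,z_k Numeric vectors; zero-norm inputs are an error.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_sim <- function(z_i, z_k) {
  ni <- sqrt(sum(z_i^2)); nk <- sqrt(sum(z_k^2))
  if (ni == 0 || nk == 0) stop("cosine similarity undefined for zero-norm input", call. = FALSE)
  sum(z_i * z_k) / (ni * nk)
}

# Generic InfoNCE-style term in log space. S is the (n_batch x n_total)
# cosine-similarity matrix, pos/den are per-anchor index lists, tau the
# temperature, `anchors` the indices allowed to contribute. The per-anchor
# log-sum-exp ratios are evaluated with mask matrices (one shared row shift)
# so batches of any size stay vectorized. Returns the mean loss over
# contributing anchors and, if want_grad, dL/dS.
contrastive_term <- function(S, pos, den, tau, anchors = seq_len(nrow(S)),
                             want_grad = FALSE, warn_empty_den = TRUE) {
  n <- nrow(S); N <- ncol(S)
  P <- matrix(FALSE, n, N)
  D <- matrix(FALSE, n, N)
  pr <- rep.int(anchors, lengths(pos[anchors]))
  if (length(pr)) P[cbind(pr, unlist(pos[anchors], use.names = FALSE))] <- TRUE
  dr <- rep.int(anchors, lengths(den[anchors]))
  if (length(dr)) D[cbind(dr, unlist(den[anchors], use.names = FALSE))] <- TRUE
  contrastive_masks(S, P, D, tau, want_grad = want_grad,
                    warn_empty_den = warn_empty_den)
}

# Core of the contrastive terms on logical mask matrices P (positives) and D
# (denominator candidates): per-contributing-anchor log-sum-exp ratio,
# numerically shifted per row, mean over contributors, optional dL/dS.
# The heavy lifting is compiled (src/contrastive.cpp).
contrastive_masks <- function(S, P, D, tau, want_grad = FALSE,
                              warn_empty_den = TRUE) {
  if (warn_empty_den) {
    starved <- rowSums(P) > 0L & rowSums(D) == 0L
    for (i in which(starved)) {
      warning(sprintf("anchor %d skipped: empty denominator", i), call. = FALSE)
    }
  }
  out <- .contrastive_core(S, P, D, tau, want_grad)
  if (want_grad && is.null(out$grad)) out$grad <- matrix(0, nrow(S), ncol(S))
  out
}

sim_matrix <- function(z, bank_z = NULL) {
  z_all <- if (is.null(bank_z) || nrow(bank_z) == 0L) z else rbind(z, bank_z)
  z %*% t(z_all)
}

#' Masked trajectory-contrast loss
#'
#' Per-anchor `-log( sum_{j in P_traj} e^{sim/tau} / sum_{k in A \ M} e^{sim/tau} )`,
#' averaged over anchors with nonempty trajectory-positive sets. With all
#' masks empty this is exactly the unmasked trajectory-contrast objective.
#'
#' @param emb List with element `z`, the l2-normalized batch embeddings.
#' @param rel A [build_relations()] object for the batch.
#' @param cfg A [loss_config()].
#' @param bank_z Optional matrix of memory-bank embeddings.
#' @return Mean loss (>= 0 up to numerical slack) with attribute `n_anchors`.
#' @export
motion_loss <- function(emb, rel, cfg, bank_z = NULL) {
  S <- sim_matrix(emb$z, bank_z)
  den <- lapply(seq_len(rel$n_batch), function(i) setdiff(rel$A[[i]], rel$M[[i]]))
  out <- contrastive_term(S, rel$P_traj, den, cfg$tau)
  structure(out$value, n_anchors = out$n_anchors)
}

#' Auxiliary physics-alignment loss
#'
#' Per-anchor `-log( sum_{j in P_phys} e^{sim/tau_p} / sum_{k in Q} e^{sim/tau_p} )`,
#' averaged over contact anchors with nonempty physics-positive sets; anchors
#' with empty positive (or candidate) sets are skipped. Returns 0 with
#' attribute `no_contributors = TRUE` when no anchor qualifies.
#'
#' @inheritParams motion_loss
#' @return Mean loss with attributes `n_anchors` and `no_contributors`.
#' @export
physics_loss <- function(emb, rel, cfg, bank_z = NULL) {
  S <- sim_matrix(emb$z, bank_z)
  anchors <- which(!rel$skip_physics)
  out <- contrastive_term(S, rel$P_phys, rel$Q, cfg$tau_p, anchors = anchors,
                          warn_empty_den = FALSE)
  structure(out$value, n_anchors = out$n_anchors,
            no_contributors = out$n_anchors == 0L)
}

#' Variance (anti-collapse) regularizer
#'
#' Hinge on the per-dimension standard deviation of the raw (pre-normalization)
#' projector outputs: `mean_j max(0, gamma - sqrt(Var_j + 1e-4))`, with the
#' sample variance taken over the batch.
#'
#' @param raw Matrix of raw projector outputs (batch x dim), batch size >= 2.
#' @param cfg A [loss_config()].
#' @return The penalty (0 when every dimension's std reaches `gamma`).
#' @export
variance_loss <- function(raw, cfg) {
  if (nrow(raw) < 2L) stop("variance_loss needs a batch of at least 2", call. = FALSE)
  sds <- sqrt(apply(raw, 2L, stats::var) + 1e-4)
  mean(pmax(0, cfg$variance_gamma - sds))
}

warmup_weight <- function(epoch_progress, warmup_fraction) {
  if (epoch_progress < 0 || epoch_progress > 1) {
    stop("`epoch_progress` must be in [0, 1]", call. = FALSE)
  }
  if (warmup_fraction <= 0) 1 else min(1, epoch_progress / warmup_fraction)
}

#' Composite training loss with term breakdown
#'
#' @inheritParams motion_loss
#' @param raw Raw projector outputs for the variance term (defaults to
#'   `emb$raw`).
#' @param epoch_progress Fraction of training completed, in `[0, 1]`; sets the
#'   physics warmup weight.
#' @return A list with `total`, `motion`, `physics`, `variance`,
#'   `phys_weight`, and contributing-anchor counts.
#' @export
total_loss <- function(emb, rel, cfg, epoch_progress = 1, bank_z = NULL,
                       raw = emb$raw) {
  w <- warmup_weight(epoch_progress, cfg$warmup_fraction)
  lm <- motion_loss(emb, rel, cfg, bank_z)
  lp <- if (cfg$lambda_phys > 0 && rel$mode != "temporal_only") {
    physics_loss(emb, rel, cfg, bank_z)
  } else structure(0, n_anchors = 0L, no_contributors = TRUE)
  lv <- if (cfg$lambda_var > 0) variance_loss(raw, cfg) else 0
  list(
    total = as.numeric(lm) + w * cfg$lambda_phys * as.numeric(lp) +
      cfg$lambda_var * as.numeric(lv),
    motion = as.numeric(lm), physics = as.numeric(lp), variance = as.numeric(lv),
    phys_weight = w,
    n_motion_anchors = attr(lm, "n_anchors"),
    n_physics_anchors = attr(lp, "n_anchors")
  )
}

# Value and gradient of the composite loss with respect to the raw projector
# outputs. `z` must be l2_normalize(raw); the contrastive terms differentiate
# through the normalization, the variance term acts on raw directly. Accepts
# either a list-set relation graph (build_relations) or its mask-matrix twin
# (relation_masks).
total_loss_grad <- function(raw, z, rel, cfg, epoch_progress = 1, bank_z = NULL) {
  n <- nrow(z); d <- ncol(z)
  w <- warmup_weight(epoch_progress, cfg$warmup_fraction)
  S <- sim_matrix(z, bank_z)
  if (is.matrix(rel$A)) {
    m <- contrastive_masks(S, rel$P_traj, rel$D, cfg$tau, want_grad = TRUE,
                           warn_empty_den = FALSE)
  } else {
    den <- lapply(seq_len(rel$n_batch), function(i) setdiff(rel$A[[i]], rel$M[[i]]))
    m <- contrastive_term(S, rel$P_traj, den, cfg$tau, want_grad = TRUE,
                          warn_empty_den = FALSE)
  }
  G <- m$grad
  phys_value <- 0; phys_anchors <- 0L
  if (cfg$lambda_phys > 0 && rel$mode != "temporal_only") {
    ph <- if (is.matrix(rel$A)) {
      contrastive_masks(S, rel$P_phys, rel$Q, cfg$tau_p, want_grad = TRUE,
                        warn_empty_den = FALSE)
    } else {
      contrastive_term(S, rel$P_phys, rel$Q, cfg$tau_p,
                       anchors = which(!rel$skip_physics),
                       want_grad = TRUE, warn_empty_den = FALSE)
    }
    phys_value <- ph$value; phys_anchors <- ph$n_anchors
    G <- G + w * cfg$lambda_phys * ph$grad
  }
  z_all <- if (is.null(bank_z) || nrow(bank_z) == 0L) z else rbind(z, bank_z)
  dZ <- G %*% z_all + t(G[, seq_len(n), drop = FALSE]) %*% z

  # back through row normalization z = raw / ||raw||
  norms <- sqrt(rowSums(raw^2))
  dRaw <- (dZ - z * rowSums(dZ * z)) / norms

  var_value <- 0
  if (cfg$lambda_var > 0) {
    var_value <- variance_loss(raw, cfg)
    v <- apply(raw, 2L, stats::var)
    sds <- sqrt(v + 1e-4)
    active <- sds < cfg$variance_gamma
    if (any(active)) {
      ctr <- sweep(raw, 2L, colMeans(raw))
      coef <- ifelse(active, -1 / (d * (n - 1) * sds), 0)
      dRaw <- dRaw + cfg$lambda_var * sweep(ctr, 2L, coef, `*`)
    }
  }
  list(
    total = m$value + w * cfg$lambda_phys * phys_value + cfg$lambda_var * var_value,
    motion = m$value, physics = phys_value, variance = var_value,
    phys_weight = w, n_motion_anchors = m$n_anchors,
    n_physics_anchors = phys_anchors, dRaw = dRaw
  )
}
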