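# Window encoder: temporal average pooling over the frames of each window,
# a one-hidden-layer MLP trunk with ReLU, a linear projection head, and l2
# normalization. The raw projector outputs are retained for the variance
# regularizer. Label columns cannot reach this path: the encoder consumes
# only feature arrays.

#' Encoder configuration
#'
#' @param feature_dim Input feature dimension (per frame).
#' @param hidden Width of the hidden trunk layer.
#' @param embed_dim Embedding dimension `d` (>= 2).
#' @param seed Seed for deterministic weight initialization.
#' @return An object of class `pharl_encoder_config`.
#' @export
encoder_config <- function(feature_dim, hidden = 32L, embed_dim = 16L, seed = 1L) {
  if (!is_count(feature_dim) || !is_count(hidden)) {
    stop("`feature_dim` and `hidden` must be counts", call. = FALSE)
  }
  if (!is_count(embed_dim) || embed_dim < 2) stop("`embed_dim` must be >= 2", call. = FALSE)
  structure(list(feature_dim = as.integer(feature_dim), hidden = as.integer(hidden),
                 embed_dim = as.integer(embed_dim), seed = as.integer(seed)),
            class = "pharl_encoder_config")
}

#' Initialize encoder weights
#'
#' He-style initialization, deterministic under `cfg$seed`. Normalization
#' statistics (`center`, `scale`) are filled in by [fit_pharl()] from the
#' training split.
#'
#' @param cfg An [encoder_config()].
#' @return An object of class `pharl_encoder`.
#' @export
encoder_init <- function(cfg) {
  stopifnot(inherits(cfg, "pharl_encoder_config"))
  p <- cfg$feature_dim; h <- cfg$hidden; d <- cfg$embed_dim
  with_seed(cfg$seed, {
    structure(list(
      config = cfg,
      W1 = matrix(stats::rnorm(p * h, 0, sqrt(2 / p)), p, h),
      b1 = numeric(h),
      W2 = matrix(stats::rnorm(h * d, 0, sqrt(1 / h)), h, d),
      b2 = numeric(d),
      center = NULL, scale = NULL
    ), class = "pharl_encoder")
  })
}

# Pool a list of (T x feature_dim) window feature matrices to an (n x p)
# matrix of temporal means.
pool_features <- function(features, feature_dim = NULL) {
  if (is.matrix(features)) return(features)
  p <- feature_dim %||% ncol(features[[1L]])
  bad <- which(vapply(features, function(f) !is.matrix(f) || ncol(f) != p, logical(1)))
  if (length(bad)) {
    stop(sprintf("window %d: feature array is not a (T x %d) matrix", bad[1L], p),
         call. = FALSE)
  }
  t(vapply(features, colMeans, numeric(p)))
}

encoder_forward <- function(enc, x) {
  if (ncol(x) != enc$config$feature_dim) {
    stop(sprintf("feature dimension mismatch: got %d, encoder expects %d",
                 ncol(x), enc$config$feature_dim), call. = FALSE)
  }
  if (!is.null(enc$center)) {
    x <- sweep(sweep(x, 2L, enc$center), 2L, enc$scale, `/`)
  }
  a1 <- sweep(x %*% enc$W1, 2L, enc$b1, `+`)
  h1 <- pmax(a1, 0)
  raw <- sweep(h1 %*% enc$W2, 2L, enc$b2, `+`)
  list(x = x, h1 = h1, raw = raw, z = l2_normalize(raw))
}

#' Encode window feature sequences
#'
#' Temporal average pooling over each window's frames followed by the MLP
#' trunk, projection head and l2 normalization. The encode path accepts only
#' feature arrays; labels have no way in.
#'
#' @param features A list of `(T x feature_dim)` matrices (one per window) or
#'   an already pooled `(n x feature_dim)` matrix.
#' @param enc A `pharl_encoder` (from [encoder_init()] or a checkpoint).
#' @return A list of class `pharl_batch_embeddings` with `z` (unit rows) and
#'   `raw` (pre-normalization projector outputs).
#' @export
encode <- function(features, enc) {
  stopifnot(inherits(enc, "pharl_encoder"))
  fwd <- encoder_forward(enc, pool_features(features, enc$config$feature_dim))
  structure(list(z = fwd$z, raw = fwd$raw), class = "pharl_batch_embeddings")
}

encoder_backward <- function(enc, fwd, dRaw) {
  dW2 <- t(fwd$h1) %*% dRaw
  db2 <- colSums(dRaw)
  dH1 <- dRaw %*% t(enc$W2)
  dH1[fwd$h1 <= 0] <- 0
  dW1 <- t(fwd$x) %*% dH1
  db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_init <- function(enc) {
  st <- list(t = 0)
  for (nm in c("W1", "b1", "W2", "b2")) {
    st[[paste0("m_", nm)]] <- enc[[nm]] * 0
    st[[paste0("v_", nm)]] <- enc[[nm]] * 0
  }
  st
}

adam_step <- function(enc, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in c("W1", "b1", "W2", "b2")) {
    m <- beta1 * state[[paste0("m_", nm)]] + (1 - beta1) * grads[[nm]]
    v <- beta2 * state[[paste0("v_", nm)]] + (1 - beta2) * grads[[nm]]^2
    state[[paste0("m_", nm)]] <- m
    state[[paste0("v_", nm)]] <- v
    enc[[nm]] <- enc[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(encoder = enc, state = state)
}
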