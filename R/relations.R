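# Per-anchor contrastive relations over a batch plus an optional memory bank.
#
# For anchor i (a batch entry), over the pooled index space batch (1..n)
# followed by bank entries (n+1..N):
#   P_traj(i)  other windows of the same trajectory
#   A(i)       all entries except i itself
#   M(i)       masked denominators: cross-trajectory contact windows, only for
#              contact anchors (C_i = 1); empty in temporal_only mode
#   Q(i)       cross-trajectory candidates
#   P_phys(i)  cross-trajectory physics positives: exact class match
#              (multiclass) or contact-flag match (binary); empty otherwise
# Sets are materialized as sorted integer vectors for reproducibility.

RELATION_MODES <- c("temporal_only", "binary_physics", "multiclass_physics")

#' Build per-anchor contrastive relation sets
#'
#' @param batch Data frame of anchor contexts with columns `trajectory_id` and,
#'   for physics modes, `ordinal_code` and `contact_flag`.
#' @param bank Optional data frame of memory-bank contexts (same columns);
#'   bank entries join the candidate pools but are never anchors.
#' @param mode One of `"temporal_only"`, `"binary_physics"`,
#'   `"multiclass_physics"`.
#' @param include_bank_in_physics If `FALSE`, bank entries are excluded from
#'   the physics sets `M`, `P_phys` and `Q` (they always remain in `A`).
#' @return A list of class `pharl_relations` with per-anchor integer-vector
#'   lists `P_traj`, `A`, `M`, `P_phys`, `Q`, the logical vector
#'   `skip_physics` (anchors with empty physics-positive sets), and sizes
#'   `n_batch`, `n_total`.
#' @export
build_relations <- function(batch, bank = NULL, mode = "multiclass_physics",
                            include_bank_in_physics = TRUE) {
  mode <- match.arg(mode, RELATION_MODES)
  n <- nrow(batch)
  traj <- c(batch$trajectory_id, bank$trajectory_id)
  n_total <- length(traj)
  if (mode != "temporal_only") {
    y <- c(batch$ordinal_code, bank$ordinal_code)
    cf <- c(batch$contact_flag, bank$contact_flag)
    if (anyNA(y) || anyNA(cf)) {
      stop("physics modes require `ordinal_code` and `contact_flag` for every entry",
           call. = FALSE)
    }
  } else {
    y <- rep(NA_integer_, n_total)
    cf <- rep(NA_integer_, n_total)
  }
  in_phys_pool <- rep(TRUE, n_total)
  if (!include_bank_in_physics && n_total > n) {
    in_phys_pool[(n + 1L):n_total] <- FALSE
  }

  idx <- seq_len(n_total)
  P_traj <- vector("list", n); A <- vector("list", n)
  M <- vector("list", n); P_phys <- vector("list", n); Q <- vector("list", n)
  for (i in seq_len(n)) {
    same <- traj == traj[i]
    A[[i]] <- idx[idx != i]
    P_traj[[i]] <- idx[same & idx != i]
    Q[[i]] <- idx[!same]
    if (mode != "temporal_only" && cf[i] == 1L) {
      M[[i]] <- idx[!same & cf == 1L & in_phys_pool]
      P_phys[[i]] <- switch(mode,
        multiclass_physics = if (y[i] %in% c(1L, 2L))
          idx[!same & y == y[i] & in_phys_pool] else integer(0),
        binary_physics = idx[!same & cf == 1L & in_phys_pool]
      )
    } else {
      M[[i]] <- integer(0)
      P_phys[[i]] <- integer(0)
    }
  }
  structure(list(
    P_traj = P_traj, A = A, M = M, P_phys = P_phys, Q = Q,
    skip_physics = lengths(P_phys) == 0L,
    contact_flag = cf[seq_len(n)],
    n_batch = n, n_total = n_total, mode = mode
  ), class = "pharl_relations")
}

#' Physics-stratified batch streams
#'
#' Partitions `seq_len(nrow(labels))` into batches such that each batch holds
#' at least `min_per_class` windows of every physics class present (while that
#' class has windows left to deal), every window appears exactly once per
#' epoch, and the stream is deterministic under `seed`. `min_per_class = 0`
#' reduces to plain shuffled batching.
#'
#' @param labels Data frame with an `ordinal_code` column (one row per window).
#' @param batch_size Target batch size.
#' @param min_per_class Minimum windows of each present class per batch.
#' @param seed Integer seed.
#' @return List of integer index vectors (row indices into `labels`).
#' @export
stratified_batches <- function(labels, batch_size = 64L, min_per_class = 2L,
                               seed = 1L) {
  codes <- labels$ordinal_code
  n <- length(codes)
  classes <- sort(unique(codes))
  if (batch_size < length(classes) * min_per_class) {
    stop("`batch_size` must be at least n_classes * min_per_class", call. = FALSE)
  }
  with_seed(seed, {
    nb <- max(1L, as.integer(ceiling(n / batch_size)))
    batches <- rep(list(integer(0)), nb)
    leftover <- integer(0)
    for (cl in classes) {
      cidx <- which(codes == cl)
      cidx <- cidx[sample.int(length(cidx))]
      quota <- min(length(cidx), nb * min_per_class)
      if (quota > 0L) {
        # Deal in blocks of min_per_class so scarce classes still co-occur
        # within a batch (needed for cross-trajectory same-class positives)
        # instead of being spread one per batch.
        target <- rep(seq_len(nb), each = min_per_class, length.out = quota)
        for (b in seq_len(nb)) {
          batches[[b]] <- c(batches[[b]], cidx[which(target == b)])
        }
      }
      if (length(cidx) > quota) leftover <- c(leftover, cidx[(quota + 1L):length(cidx)])
    }
    if (length(leftover)) leftover <- leftover[sample.int(length(leftover))]
    for (b in seq_len(nb)) {
      room <- batch_size - length(batches[[b]])
      if (room > 0L && length(leftover)) {
        take <- seq_len(min(room, length(leftover)))
        batches[[b]] <- c(batches[[b]], leftover[take])
        leftover <- leftover[-take]
      }
    }
    b <- 1L
    while (length(leftover)) {  # spillover when quotas overfilled some batches
      batches[[b]] <- c(batches[[b]], leftover[1L])
      leftover <- leftover[-1L]
      b <- if (b == nb) 1L else b + 1L
    }
    batches[lengths(batches) > 0L]
  })
}

# Mask-matrix twin of build_relations() used by the training hot path: the
# same set definitions materialized as (n_batch x n_total) logical matrices.
# Equivalence with the list representation is pinned by tests.
relation_masks <- function(batch, bank = NULL, mode = "multiclass_physics",
                           include_bank_in_physics = TRUE) {
  mode <- match.arg(mode, RELATION_MODES)
  n <- nrow(batch)
  traj <- c(batch$trajectory_id, bank$trajectory_id)
  N <- length(traj)
  tid <- match(traj, unique(traj))
  same <- outer(tid[seq_len(n)], tid, `==`)
  self <- matrix(FALSE, n, N)
  self[cbind(seq_len(n), seq_len(n))] <- TRUE
  A <- !self
  P_traj <- same & !self
  Q <- !same
  if (mode == "temporal_only") {
    M <- matrix(FALSE, n, N)
    P_phys <- matrix(FALSE, n, N)
  } else {
    y <- c(batch$ordinal_code, bank$ordinal_code)
    cf <- c(batch$contact_flag, bank$contact_flag)
    if (anyNA(y) || anyNA(cf)) {
      stop("physics modes require `ordinal_code` and `contact_flag` for every entry",
           call. = FALSE)
    }
    pool <- rep(TRUE, N)
    if (!include_bank_in_physics && N > n) pool[(n + 1L):N] <- FALSE
    anchor_c <- batch$contact_flag == 1L
    contact_k <- matrix(cf == 1L & pool, n, N, byrow = TRUE)
    M <- anchor_c & contact_k & !same
    P_phys <- if (mode == "binary_physics") M else {
      exact <- matrix(FALSE, n, N)
      for (cl in c(1L, 2L)) {
        rows <- batch$ordinal_code == cl & anchor_c
        if (any(rows)) {
          exact[rows, ] <- matrix(y == cl & pool, sum(rows), N, byrow = TRUE)
        }
      }
      exact & !same
    }
  }
  list(P_traj = P_traj, A = A, M = M, D = A & !M, P_phys = P_phys, Q = Q,
       n_batch = n, n_total = N, mode = mode)
}

#' Create an empty FIFO memory bank
#'
#' @param capacity Maximum number of stored embeddings.
#' @param dim Embedding dimension.
#' @return A list of class `pharl_memory_bank` with an embedding matrix and a
#'   context data frame (trajectory, labels, contact flag, video).
#' @export
memory_bank <- function(capacity = 4096L, dim) {
  structure(list(
    capacity = as.integer(capacity),
    z = matrix(numeric(0), 0L, dim),
    contexts = data.frame(trajectory_id = character(0), video_id = character(0),
                          ordinal_code = integer(0), contact_flag = integer(0),
                          stringsAsFactors = FALSE)
  ), class = "pharl_memory_bank")
}

#' FIFO update of a memory bank
#'
#' Appends embeddings with their contexts and evicts the oldest entries beyond
#' capacity. Bank entries enter candidate pools but never receive gradient and
#' are never anchors.
#'
#' @param bank A [memory_bank()].
#' @param z Matrix of new (detached) embeddings, one row per entry.
#' @param contexts Data frame with `trajectory_id`, `video_id`,
#'   `ordinal_code`, `contact_flag` for the new entries.
#' @return The updated bank.
#' @export
memory_bank_update <- function(bank, z, contexts) {
  stopifnot(inherits(bank, "pharl_memory_bank"), nrow(z) == nrow(contexts))
  zc <- rbind(bank$z, z)
  cols <- names(bank$contexts)
  cc <- lapply(cols, function(cl) c(bank$contexts[[cl]], contexts[[cl]]))
  names(cc) <- cols
  if (nrow(zc) > bank$capacity) {
    keep <- (nrow(zc) - bank$capacity + 1L):nrow(zc)
    zc <- zc[keep, , drop = FALSE]
    cc <- lapply(cc, `[`, keep)
  }
  bank$z <- zc
  bank$contexts <- structure(cc, class = "data.frame",
                             row.names = seq_along(cc[[1L]]))
  bank
}
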