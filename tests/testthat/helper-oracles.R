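# Independent oracles used across the suite: naive set-comprehension relation
# builder, brute-force rank statistics, and small random-instance generators.
# These deliberately mirror the definitions, not the package's implementation.

# O(n^2) set-comprehension oracle for relation graphs.
naive_relations <- function(batch, bank = NULL, mode = "multiclass_physics",
                            include_bank_in_physics = TRUE) {
  traj <- c(batch$trajectory_id, bank$trajectory_id)
  y <- c(batch$ordinal_code, bank$ordinal_code)
  cf <- c(batch$contact_flag, bank$contact_flag)
  n <- nrow(batch)
  N <- length(traj)
  phys_ok <- function(k) include_bank_in_physics || k <= n
  out <- list(P_traj = list(), A = list(), M = list(), P_phys = list(), Q = list())
  for (i in seq_len(n)) {
    A <- integer(0); P <- integer(0); M <- integer(0); PP <- integer(0); Q <- integer(0)
    for (k in seq_len(N)) {
      if (k != i) A <- c(A, k)
      if (k != i && traj[k] == traj[i]) P <- c(P, k)
      if (traj[k] != traj[i]) Q <- c(Q, k)
      if (mode != "temporal_only" && cf[i] == 1L && cf[k] == 1L &&
          traj[k] != traj[i] && phys_ok(k)) {
        M <- c(M, k)
      }
      if (mode == "multiclass_physics" && cf[i] == 1L && y[i] %in% c(1L, 2L) &&
          y[k] == y[i] && traj[k] != traj[i] && phys_ok(k)) {
        PP <- c(PP, k)
      }
      if (mode == "binary_physics" && cf[i] == 1L && cf[k] == 1L &&
          traj[k] != traj[i] && phys_ok(k)) {
        PP <- c(PP, k)
      }
    }
    out$P_traj[[i]] <- P; out$A[[i]] <- A; out$M[[i]] <- M
    out$P_phys[[i]] <- PP; out$Q[[i]] <- Q
  }
  out
}

random_contexts <- function(n, n_traj, seed) {
  with_seed(seed, {
    code <- sample(0:2, n, replace = TRUE)
    data.frame(
      window_id = sprintf("w%03d", seq_len(n)),
      trajectory_id = sprintf("t%02d", sample.int(n_traj, n, replace = TRUE)),
      video_id = sprintf("v%02d", sample.int(n_traj, n, replace = TRUE)),
      ordinal_code = code,
      contact_flag = as.integer(code > 0L),
      stringsAsFactors = FALSE
    )
  })
}

# Brute-force Spearman (average ranks) and Kendall tau-b from pair
# concordance counts.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

brute_kendall_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Exhaustive pairwise ordering accuracy for one ordered class pair.
brute_poa_pair <- function(scores_lo, scores_hi) {
  tot <- 0; acc <- 0
  for (a in scores_lo) {
    for (b in scores_hi) {
      tot <- tot + 1
      acc <- acc + if (a < b) 1 else if (a == b) 0.5 else 0
    }
  }
  acc / tot
}

# Brute-force k-NN neighborhood consistency with same-video exclusion over an
# explicit database index set.
brute_neighborhood <- function(z, codes, videos, db_idx, k) {
  z <- z / sqrt(rowSums(z^2))
  classes <- sort(unique(codes))
  out <- stats::setNames(rep(NA_real_, length(classes)), as.character(classes))
  for (cl in classes) {
    fr <- c()
    for (q in which(codes == cl)) {
      valid <- db_idx[videos[db_idx] != videos[q]]
      if (!length(valid)) next
      sims <- drop(z[valid, , drop = FALSE] %*% z[q, ])
      take <- valid[order(-sims, valid)][seq_len(min(k, length(valid)))]
      fr <- c(fr, mean(codes[take] == cl))
    }
    if (length(fr)) out[as.character(cl)] <- mean(fr)
  }
  out
}

relations_equal <- function(a, b, n) {
  for (i in seq_len(n)) {
    for (f in c("P_traj", "A", "M", "P_phys", "Q")) {
      if (!identical(sort(a[[f]][[i]]), sort(as.integer(b[[f]][[i]])))) return(FALSE)
    }
  }
  TRUE
}
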