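# Desk-scale structure-recovery experiment shared by the acceptance blocks:
# 300 simulated trajectories per seed, the full PHARL configuration plus the
# temporal-only control and the denoise-off / binary-attraction ablation arms,
# trained with the package's desk experiment protocol (50 epochs, Adam lr
# 1e-3, shared memory bank of 512, physics-stratified batches). Computed once
# per test session and cached.

.pharl_experiment_cache <- new.env(parent = emptyenv())

experiment_config <- function(seed, n_trajectories = 300L) {
  pharl_config(
    seed = seed,
    sim = list(n_trajectories = n_trajectories),
    train = list(lr = 1e-3, epochs = 50L)
  )
}

structure_recovery_sweep <- function(seeds = 1:5) {
  key <- paste0("sweep_", paste(seeds, collapse = "_"))
  if (!exists(key, envir = .pharl_experiment_cache)) {
    rows <- lapply(seeds, function(s) {
      ab <- ablation_matrix(experiment_config(s),
                            switches = c("denoise", "multiclass"))
      ab$base_seed <- s
      ab
    })
    assign(key, do.call(rbind, rows), envir = .pharl_experiment_cache)
  }
  get(key, envir = .pharl_experiment_cache)
}

sweep_arm <- function(sweep, arm) sweep[sweep$config == arm, , drop = FALSE]
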