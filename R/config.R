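# Run configuration: nested sim/label/relations/loss/train/eval sections plus
# a global seed, schema-validated before any stage runs (unknown keys are
# rejected). YAML is the on-disk format.

pharl_config_template <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    paired_control = TRUE,
    sim = list(
      n_trajectories = 300L, fall_fraction = 0.6,
      class_mix = c(0.56, 0.34, 0.10),
      frames_per_trajectory = 120L, window_len = 16L, window_stride = 8L,
      feature_dim = 12L, nuisance_dim = 4L, noise_sd = 0.5,
      spurious_impulse_rate = 0.3, spurious_impulse_max = 0.05,
      boundary_straddle_prob = 0.25
    ),
    label = list(
      sources = c("window", "continuation"), threshold = 0.0,
      horizon = 8L, denoise = TRUE
    ),
    relations = list(
      mode = "multiclass_physics", min_per_class = 2L,
      bank_enabled = TRUE, bank_capacity = 512L,
      include_bank_in_physics = TRUE
    ),
    loss = list(
      tau = 0.2, tau_p = 0.2, lambda_phys = 1.0, lambda_var = 0.1,
      warmup_fraction = 0.1, variance_gamma = 1.0
    ),
    train = list(
      epochs = 100L, batch_size = 64L, lr = 1e-4,
      hidden = 32L, embed_dim = 16L
    ),
    eval = list(
      k = 10L, poa_cap = 1e5, probe_lambda = 1.0
    )
  )
}

merge_validated <- function(template, user, path = "") {
  if (is.null(user)) return(template)
  unknown <- setdiff(names(user), names(template))
  if (length(unknown)) {
    stop(sprintf("unknown config key%s: %s", ifelse(length(unknown) > 1, "s", ""),
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      template[[nm]] <- merge_validated(template[[nm]], user[[nm]],
                                        path = paste0(path, nm, "."))
    } else {
      template[[nm]] <- user[[nm]]
    }
  }
  template
}

#' Build and validate a run configuration
#'
#' Merges user overrides into the default nested configuration
#' (`sim`/`label`/`relations`/`loss`/`train`/`eval` sections plus the global
#' `seed`, `out_dir` and `paired_control`). Unknown keys are rejected.
#'
#' @param ... Named overrides, e.g. `sim = list(n_trajectories = 40)`.
#' @return A validated list of class `pharl_run_config`.
#' @export
pharl_config <- function(...) {
  user <- list(...)
  cfg <- merge_validated(pharl_config_template(), user)
  cfg$relations$mode <- match.arg(cfg$relations$mode, RELATION_MODES)
  if (!all(cfg$label$sources %in% LABEL_SOURCES)) {
    stop("label.sources must be a subset of {window, continuation}", call. = FALSE)
  }
  structure(cfg, class = "pharl_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys follow
#'   [pharl_config()].
#' @return A validated `pharl_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pharl_config, raw)
}

sim_config_from <- function(cfg) {
  sim_config(
    n_trajectories = cfg$sim$n_trajectories,
    fall_fraction = cfg$sim$fall_fraction,
    class_mix = cfg$sim$class_mix,
    frames_per_trajectory = cfg$sim$frames_per_trajectory,
    window_len = cfg$sim$window_len,
    window_stride = cfg$sim$window_stride,
    feature_dim = cfg$sim$feature_dim,
    nuisance_dim = cfg$sim$nuisance_dim,
    noise_sd = cfg$sim$noise_sd,
    spurious_impulse_rate = cfg$sim$spurious_impulse_rate,
    spurious_impulse_max = cfg$sim$spurious_impulse_max,
    boundary_straddle_prob = cfg$sim$boundary_straddle_prob,
    seed = derive_seed(cfg$seed, "sim")
  )
}
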