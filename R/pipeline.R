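# End-to-end pipeline: simulate -> label -> train -> embed -> evaluate, with
# provenance sidecars, plus the ablation grid runner. After the labeling
# stage no component reads the descriptor stream again; embedding and
# evaluation consume only the manifest, checkpoints and label tables.

provenance <- function(cfg, stage, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(stage = stage, config_hash = config_hash(unclass(cfg)),
       package_version = as.character(utils::packageVersion("pharl")),
       input_digests = digests, timestamp = format(Sys.time(), tz = "UTC"))
}

write_provenance <- function(prov, path) {
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

fit_arm <- function(mode, manifest, labels, cfg) {
  enc_cfg <- encoder_config(
    feature_dim = cfg$sim$feature_dim, hidden = cfg$train$hidden,
    embed_dim = cfg$train$embed_dim, seed = derive_seed(cfg$seed, "init")
  )
  fit_pharl(
    manifest, labels, enc_cfg,
    loss_cfg = loss_config(
      tau = cfg$loss$tau, tau_p = cfg$loss$tau_p,
      lambda_phys = if (mode == "temporal_only") 0 else cfg$loss$lambda_phys,
      lambda_var = if (mode == "temporal_only") 0 else cfg$loss$lambda_var,
      warmup_fraction = cfg$loss$warmup_fraction,
      variance_gamma = cfg$loss$variance_gamma
    ),
    train_cfg = train_config(
      epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
      lr = cfg$train$lr,
      # physics-stratified sampling applies only to physics-supervised arms;
      # the temporal-only control uses plain shuffled batching
      min_per_class = if (mode == "temporal_only") 0L else cfg$relations$min_per_class,
      mode = mode, bank_enabled = cfg$relations$bank_enabled,
      bank_capacity = cfg$relations$bank_capacity,
      include_bank_in_physics = cfg$relations$include_bank_in_physics,
      seed = derive_seed(cfg$seed, "train")
    )
  )
}

report_metric_row <- function(report) {
  val <- function(x) if (is.numeric(x) && length(x) == 1L) x else NA_real_
  data.frame(
    spearman_rho = val(report$spearman_rho),
    poa_macro = val(report$poa_macro),
    contact_ap = val(report$contact_ap),
    contact_auc = val(report$contact_auc),
    fall_auc = val(report$fall_auc),
    pcr = val(report$pcr),
    kendall_tau = val(report$kendall_tau),
    proj_supported = if (length(report$mean_projection)) report$mean_projection[["Supported"]] else NA_real_,
    proj_trunk = if (length(report$mean_projection)) report$mean_projection[["Trunk"]] else NA_real_,
    proj_head = if (length(report$mean_projection)) report$mean_projection[["Head"]] else NA_real_
  )
}

#' Run the full pipeline
#'
#' Simulates a dataset, derives window-level physics labels, trains the
#' physics-regularized encoder (plus a capacity-matched temporal-only control
#' when `paired_control` is set), embeds every window with the best
#' checkpoint, and writes per-arm diagnostic reports and a comparison table
#' into `out_dir`.
#'
#' @param cfg A [pharl_config()] (or path to a YAML config).
#' @param out_dir Output directory (defaults to `cfg$out_dir`).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the run directory, per-arm reports and the
#'   comparison data frame.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "pharl_run_config"))
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[simulate] n_trajectories=%d", cfg$sim$n_trajectories)
  sim <- simulate_dataset(sim_config_from(cfg))
  manifest_path <- file.path(out_dir, "manifest.jsonl")
  descriptors_path <- file.path(out_dir, "descriptors.jsonl")
  write_manifest(sim$manifest, manifest_path)
  write_descriptors(sim$descriptors, descriptors_path)
  write_ground_truth(sim$ground_truth[, setdiff(names(sim$ground_truth), "nuisance")],
                     file.path(out_dir, "ground_truth.json"))

  say("[label] sources=%s threshold=%g denoise=%s",
      paste(cfg$label$sources, collapse = ","), cfg$label$threshold,
      cfg$label$denoise)
  labels <- label_dataset(sim$manifest, sim$descriptors,
                          sources = cfg$label$sources,
                          threshold = cfg$label$threshold,
                          horizon = cfg$label$horizon,
                          denoise = cfg$label$denoise,
                          verbose = verbose)
  labels_path <- file.path(out_dir, "labels.csv")
  write_labels(labels, labels_path)
  write_provenance(provenance(cfg, "label", c(manifest_path, descriptors_path)),
                   file.path(out_dir, "labels.provenance.json"))

  arms <- cfg$relations$mode
  if (isTRUE(cfg$paired_control) && cfg$relations$mode != "temporal_only") {
    arms <- c(arms, "temporal_only")
  }
  reports <- list()
  comparison <- list()
  for (mode in arms) {
    say("[train] arm=%s epochs=%d", mode, cfg$train$epochs)
    state <- fit_arm(mode, sim$manifest, labels, cfg)
    ckpt_path <- file.path(out_dir, sprintf("checkpoint_%s.rds", mode))
    save_checkpoint(state$best, ckpt_path)
    utils::write.csv(state$history,
                     file.path(out_dir, sprintf("history_%s.csv", mode)),
                     row.names = FALSE)
    say("[embed] arm=%s", mode)
    emb <- embed_dataset(state$best, sim$manifest)
    write_embeddings(emb, file.path(out_dir, sprintf("embeddings_%s.csv", mode)))
    say("[eval] arm=%s", mode)
    report <- metrics_report(emb, labels, k = cfg$eval$k,
                             poa_cap = cfg$eval$poa_cap,
                             seed = derive_seed(cfg$seed, "eval"),
                             probe_lambda = cfg$eval$probe_lambda)
    write_report(report, file.path(out_dir, sprintf("report_%s.json", mode)))
    write_provenance(provenance(cfg, paste0("arm_", mode), c(manifest_path, labels_path)),
                     file.path(out_dir, sprintf("report_%s.provenance.json", mode)))
    reports[[mode]] <- report
    comparison[[mode]] <- cbind(data.frame(arm = mode), report_metric_row(report))
  }
  comparison <- do.call(rbind, comparison)
  rownames(comparison) <- NULL
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  invisible(list(out_dir = out_dir, reports = reports, comparison = comparison,
                 labels = labels, sim = sim))
}

ABLATION_SWITCHES <- c("denoise", "multiclass", "source_window", "source_continuation")

ablation_rows <- function(switches) {
  rows <- list()
  if (length(switches)) {
    rows$control <- list(denoise = FALSE, multiclass = FALSE, window = FALSE,
                         continuation = FALSE, mode = "temporal_only")
    if ("denoise" %in% switches) {
      rows$no_denoise <- list(denoise = FALSE, multiclass = TRUE, window = TRUE,
                              continuation = TRUE, mode = "multiclass_physics")
    }
    if ("multiclass" %in% switches) {
      rows$binary <- list(denoise = TRUE, multiclass = FALSE, window = TRUE,
                          continuation = TRUE, mode = "binary_physics")
    }
    if ("source_window" %in% switches) {
      rows$continuation_only <- list(denoise = TRUE, multiclass = TRUE, window = FALSE,
                                     continuation = TRUE, mode = "multiclass_physics")
    }
    if ("source_continuation" %in% switches) {
      rows$window_only <- list(denoise = TRUE, multiclass = TRUE, window = TRUE,
                               continuation = FALSE, mode = "multiclass_physics")
    }
  }
  rows$full <- list(denoise = TRUE, multiclass = TRUE, window = TRUE,
                    continuation = TRUE, mode = "multiclass_physics")
  rows
}

#' Run the component-ablation grid
#'
#' Re-runs labeling + training + evaluation over the ablation grid (temporal
#' control, denoising off, binary attraction, window-only and
#' continuation-only supervision sources, full configuration), all under one
#' shared seed, and returns one metric row per configuration.
#'
#' @param cfg A [pharl_config()].
#' @param switches Which components to ablate, a subset of
#'   `c("denoise", "multiclass", "source_window", "source_continuation")`.
#'   The full configuration is always run; an empty `switches` runs only it.
#' @param sim Optionally a pre-simulated `pharl_sim` to reuse across rows.
#' @param verbose Print progress.
#' @return Data frame, one row per configuration, with the switch settings
#'   and the diagnostic metrics.
#' @export
ablation_matrix <- function(cfg, switches = ABLATION_SWITCHES, sim = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(cfg, "pharl_run_config"))
  bad <- setdiff(switches, ABLATION_SWITCHES)
  if (length(bad)) stop(sprintf("unknown switch(es): %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  rows <- ablation_rows(switches)
  if (!length(rows)) stop("empty ablation grid", call. = FALSE)
  if (is.null(sim)) sim <- simulate_dataset(sim_config_from(cfg))
  # evaluation labels always come from the full denoised configuration so
  # every row is scored against the same reference
  eval_labels <- label_dataset(sim$manifest, sim$descriptors,
                               sources = LABEL_SOURCES,
                               threshold = cfg$label$threshold,
                               horizon = cfg$label$horizon, denoise = TRUE)
  out <- list()
  for (nm in names(rows)) {
    r <- rows[[nm]]
    if (verbose) message(sprintf("[ablate] %s", nm))
    sources <- c(if (r$window) "window", if (r$continuation) "continuation")
    if (is.null(sources)) sources <- LABEL_SOURCES  # control arm: labels unused
    labels <- label_dataset(sim$manifest, sim$descriptors, sources = sources,
                            threshold = cfg$label$threshold,
                            horizon = cfg$label$horizon, denoise = r$denoise)
    state <- fit_arm(r$mode, sim$manifest, labels, cfg)
    emb <- embed_dataset(state$best, sim$manifest)
    report <- metrics_report(emb, eval_labels, k = cfg$eval$k,
                             poa_cap = cfg$eval$poa_cap,
                             seed = derive_seed(cfg$seed, "eval"),
                             probe_lambda = cfg$eval$probe_lambda)
    out[[nm]] <- cbind(
      data.frame(config = nm, denoise = r$denoise, multiclass = r$multiclass,
                 source_window = r$window, source_continuation = r$continuation,
                 seed = cfg$seed),
      report_metric_row(report)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
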