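# Hand-sized bundled scenarios with hand-computable expected labels and
# relation sets, used throughout the test suite and the examples.

#' Bundled toy scenarios
#'
#' Returns one of three small fixtures:
#' * `"toy_labeling"` - two trajectories (one fall, one ADL) with a worked
#'   descriptor stream exercising the half-open overlap rule, the strictly
#'   greater-than impulse filter, limb contacts, hierarchical dominance and a
#'   boundary-straddling continuation event. Windows are 8 frames, stride 8.
#' * `"toy_relations"` - 3 trajectories x up to 2 windows with known labels
#'   (`Head, Head | Trunk | Supported`) and hand-enumerable masks/positives.
#' * `"toy_training"` - a 40-trajectory simulated dataset (feature_dim 8) small
#'   enough to train in well under a minute.
#'
#' @param name One of `"toy_labeling"`, `"toy_relations"`, `"toy_training"`.
#' @return A list; for `toy_labeling` elements `manifest` and `descriptors`,
#'   for `toy_relations` elements `contexts` and `z` (unit embeddings), for
#'   `toy_training` a `pharl_sim` object.
#' @export
make_fixture <- function(name) {
  switch(name,
    toy_labeling = fixture_toy_labeling(),
    toy_relations = fixture_toy_relations(),
    toy_training = simulate_dataset(sim_config(
      n_trajectories = 40L, frames_per_trajectory = 96L, feature_dim = 8L,
      seed = 7L
    )),
    stop(sprintf("unknown fixture name '%s'", name), call. = FALSE)
  )
}

fixture_toy_labeling <- function() {
  wl <- 8L
  t0 <- c(0L, 8L, 16L, 24L)
  features <- with_seed(42L, lapply(1:6, function(i) matrix(stats::rnorm(wl * 4L), wl, 4L)))
  manifest <- data.frame(
    window_id = c(sprintf("tA_w%02d", 1:4), sprintf("tB_w%02d", 1:2)),
    trajectory_id = c(rep("tA", 4L), rep("tB", 2L)),
    video_id = c(rep("vA", 4L), rep("vB", 2L)),
    split = "train",
    t0 = c(t0, 0L, 8L),
    t1 = c(t0 + wl, 8L, 16L),
    fall_label = c(rep(1L, 4L), rep(0L, 2L)),
    stringsAsFactors = FALSE
  )
  manifest$features <- features
  class(manifest) <- c("pharl_manifest", "data.frame")
  descriptors <- data.frame(
    video_id = c("vA", "vA", "vA", "vA", "vA", "vA", "vB"),
    ts = c(17L, 17L, 5L, 9L, 24L, 24L, 3L),
    te = c(20L, 19L, 7L, 10L, 27L, 27L, 4L),
    body_part = c("head", "torso", "hand", "torso", "head", "head", "torso"),
    impulse_ns = c(5.0, 9.9, 3.0, 0.0, 2.0, 2.0, 0.04),
    source = c("window", "window", "window", "window", "continuation", "window", "window"),
    stringsAsFactors = FALSE
  )
  list(manifest = manifest, descriptors = descriptors,
       window_len = wl, stride = wl)
}

fixture_toy_relations <- function() {
  contexts <- data.frame(
    window_id = c("t1_w01", "t1_w02", "t2_w01", "t3_w01"),
    trajectory_id = c("t1", "t1", "t2", "t3"),
    video_id = c("v1", "v1", "v2", "v3"),
    y_phys = c("Head", "Head", "Trunk", "Supported"),
    ordinal_code = c(2L, 2L, 1L, 0L),
    contact_flag = c(1L, 1L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  z <- with_seed(11L, l2_normalize(matrix(stats::rnorm(4L * 3L), 4L, 3L)))
  list(contexts = contexts, z = z)
}
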