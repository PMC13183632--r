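# Unit behavior of the labeling pipeline: the overlap predicate, evidence
# filtering and merging, hierarchical dominance, dataset-level labeling and
# the trajectory-level (denoising-off) variant.

test_that("half-open overlap predicate matches the interval algebra", {
  w <- list(t0 = 10, t1 = 20)
  expect_true(overlaps(w, list(ts = 19, te = 25)))
  expect_false(overlaps(w, list(ts = 20, te = 25)))
  expect_false(overlaps(w, list(ts = 0, te = 10)))
  expect_true(overlaps(w, list(ts = 0, te = 11)))
})

test_that("impulse sets filter strictly, merge by per-category max, and honor sources", {
  w <- list(video_id = "v", t0 = 10, t1 = 20)
  stream <- data.frame(
    video_id = "v",
    ts = c(11, 15, 12, 22, 9),
    te = c(13, 18, 13, 24, 10),
    body_part = c("head", "head", "torso", "head", "torso"),
    impulse_ns = c(2.0, 5.0, 0.0, 4.0, 7.0),
    source = c("window", "window", "window", "continuation", "window"),
    stringsAsFactors = FALSE
  )
  s <- build_impulse_set(w, stream, sources = "window", threshold = 0)
  expect_equal(unname(s[["head"]]), 5.0)       # max of the two overlapping head events
  expect_false("trunk" %in% names(s))          # 0.0 impulse dropped at threshold 0... but torso at [9,10) does not overlap either

  # a zero-impulse event alone yields an empty set under the strict filter
  z <- build_impulse_set(list(video_id = "v", t0 = 10, t1 = 20),
                         stream[3, , drop = FALSE], threshold = 0)
  expect_length(z, 0L)

  # continuation admission: start within [t1, t1 + horizon) and the source switch
  s_win <- build_impulse_set(w, stream, sources = "window", horizon = 8)
  s_both <- build_impulse_set(w, stream, sources = c("window", "continuation"),
                              horizon = 8)
  expect_equal(unname(s_win[["head"]]), 5.0)
  expect_equal(unname(s_both[["head"]]), 5.0)  # continuation 4.0 < in-window 5.0
  s_cont <- build_impulse_set(w, stream, sources = "continuation", horizon = 8)
  expect_equal(unname(s_cont[["head"]]), 4.0)
  s_short <- build_impulse_set(w, stream, sources = c("window", "continuation"),
                               horizon = 2)
  expect_equal(unname(s_short[["head"]]), 5.0) # ts=22 outside [20, 22)

  expect_error(build_impulse_set(w, stream, threshold = -1), "nonnegative")
  expect_error(build_impulse_set(w, stream, horizon = -1), "nonnegative")
  expect_error(build_impulse_set(w, stream, sources = "video"), "subset")
})

test_that("dominance is total, magnitude-blind, and defaults to Supported", {
  mk <- function(...) {
    v <- c(...)
    structure(if (is.null(v)) numeric(0) else v, class = "pharl_impulse_set")
  }
  expect_identical(assign_label(mk(head = 1.2, trunk = 9.9))$y_phys, "Head")
  expect_identical(assign_label(mk())$y_phys, "Supported")
  expect_identical(assign_label(mk(limb = 3.0))$y_phys, "Supported")
  expect_identical(assign_label(mk(trunk = 0.1, limb = 8))$y_phys, "Trunk")
  lab <- assign_label(mk(head = 0.2))
  expect_identical(lab$ordinal_code, 2L)
  expect_identical(lab$contact_flag, 1L)
  expect_identical(assign_label(mk(limb = 1))$contact_flag, 0L)
})

test_that("labeling is idempotent and errors on duplicate window ids", {
  toy <- make_fixture("toy_labeling")
  a <- label_dataset(toy$manifest, toy$descriptors)
  b <- label_dataset(toy$manifest, toy$descriptors)
  expect_identical(a, b)
  dup <- rbind(toy$manifest[1, ], toy$manifest)
  expect_error(label_dataset(dup, toy$descriptors), "duplicate window_id")
})

test_that("trajectory-level labels spread the dominance label over all windows", {
  # fall video with a single head impact late in the trajectory: every window,
  # including pre-impact ones, inherits Head
  m <- data.frame(
    window_id = sprintf("t1_w%02d", 1:6), trajectory_id = "t1", video_id = "v1",
    split = "train", t0 = seq(0, 80, 16), t1 = seq(16, 96, 16), fall_label = 1L,
    stringsAsFactors = FALSE
  )
  m$features <- replicate(6, matrix(0, 16, 2), simplify = FALSE)
  stream <- data.frame(video_id = "v1", ts = 90L, te = 93L, body_part = "head",
                       impulse_ns = 3.0, source = "window", stringsAsFactors = FALSE)
  tl <- trajectory_level_labels(m, stream)
  expect_true(all(tl$y_phys == "Head"))

  adl <- m; adl$fall_label <- 0L
  expect_true(all(trajectory_level_labels(adl, stream)$y_phys == "Supported"))

  # on the worked fixture, denoised and trajectory-level labels differ exactly
  # on the pre-impact windows
  toy <- make_fixture("toy_labeling")
  den <- label_dataset(toy$manifest, toy$descriptors)
  off <- trajectory_level_labels(toy$manifest, toy$descriptors)
  differs <- den$window_id[den$y_phys != off$y_phys]
  expect_setequal(differs, c("tA_w01", "tA_w02"))
})

test_that("raising the threshold never increases contact-flagged windows", {
  sim <- simulate_dataset(sim_config(n_trajectories = 40, spurious_impulse_rate = 1,
                                     seed = 31))
  counts <- vapply(c(0, 0.02, 0.05, 1, 2, 5), function(thr) {
    sum(label_dataset(sim$manifest, sim$descriptors, threshold = thr)$contact_flag)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("adding head evidence never lowers a window's ordinal code", {
  toy <- make_fixture("toy_labeling")
  base <- label_dataset(toy$manifest, toy$descriptors)
  for (i in which(toy$manifest$fall_label == 1L)) {
    extra <- rbind(toy$descriptors, data.frame(
      video_id = toy$manifest$video_id[i], ts = toy$manifest$t0[i],
      te = toy$manifest$t1[i], body_part = "head", impulse_ns = 1.0,
      source = "window", stringsAsFactors = FALSE
    ))
    upd <- label_dataset(toy$manifest, extra)
    expect_true(all(upd$ordinal_code >= base$ordinal_code))
  }
})

test_that("a threshold above the spurious maximum reproduces the spurious-free labels", {
  sim <- simulate_dataset(sim_config(n_trajectories = 50, spurious_impulse_rate = 2,
                                     seed = 19))
  clean_stream <- sim$descriptors[sim$descriptors$impulse_ns > 0.05, ]
  noisy <- label_dataset(sim$manifest, sim$descriptors, threshold = 0.05)
  clean <- label_dataset(sim$manifest, clean_stream, threshold = 0)
  expect_identical(noisy[c("window_id", "y_phys", "ordinal_code", "contact_flag")],
                   clean[c("window_id", "y_phys", "ordinal_code", "contact_flag")])
})
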