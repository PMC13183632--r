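# Diagnostic metrics against independent oracles: axis algebra, brute-force
# rank statistics, exhaustive POA, permutation nulls, k-NN enumeration and
# rotation invariance.

test_that("severity axis algebra and train-split reuse", {
  z <- with_seed(1, l2_normalize(matrix(stats::rnorm(30 * 4), 30, 4)))
  codes <- rep(c(0L, 1L, 2L), each = 10)
  ax <- severity_axis(z, codes)
  expect_equal(sqrt(sum(ax$v_hat^2)), 1, tolerance = 1e-12)
  # s(mu_head) - s(mu_supported) equals the centroid distance
  gap <- sum(ax$mu_head * ax$v_hat) - sum(ax$mu_supported * ax$v_hat)
  expect_equal(gap, sqrt(sum((ax$mu_head - ax$mu_supported)^2)), tolerance = 1e-12)
  # 1-D embeddings with mu_S = 0, mu_H = 1 project to themselves
  z1 <- matrix(c(0, 0, 1, 1, 0.3, 0.7), ncol = 1)
  ax1 <- severity_axis(z1, c(0L, 0L, 2L, 2L, 1L, 1L))
  expect_equal(project_severity(z1, ax1), drop(z1), tolerance = 1e-12)
  expect_error(severity_axis(z, rep(1L, 30)), "Head")
  expect_error(severity_axis(rbind(z[1, ], z[1, ]), c(0L, 2L)), "coincident")
})

test_that("Spearman and Kendall match brute-force concordance", {
  # untied codes with strictly increasing scores: perfect concordance
  perfect <- spearman_kendall(c(0, 1, 2), c(-1, 0.2, 3))
  expect_equal(perfect$rho, 1)
  expect_equal(perfect$tau, 1)
  reversed <- spearman_kendall(c(0, 1, 2), c(3, 0.2, -1))
  expect_equal(reversed$rho, -1, tolerance = 1e-12)
  expect_equal(reversed$tau, -1, tolerance = 1e-12)
  # with tied codes both statistics stay below 1 but match the oracle
  tied <- spearman_kendall(c(0, 0, 1, 2), c(-1, -0.5, 0.2, 3))
  expect_equal(tied$rho, brute_spearman(c(0, 0, 1, 2), c(-1, -0.5, 0.2, 3)),
               tolerance = 1e-12)
  expect_equal(tied$tau, brute_kendall_b(c(0, 0, 1, 2), c(-1, -0.5, 0.2, 3)),
               tolerance = 1e-12)

  hand_codes <- c(0L, 0L, 1L, 2L)
  hand_scores <- c(0.1, 0.2, 0.15, 0.9)
  got <- spearman_kendall(hand_codes, hand_scores)
  expect_equal(got$rho, brute_spearman(hand_codes, hand_scores), tolerance = 1e-12)
  expect_equal(got$tau, brute_kendall_b(hand_codes, hand_scores), tolerance = 1e-12)

  for (s in 1:5) {
    n <- 150
    codes <- with_seed(s, sample(0:2, n, replace = TRUE))
    scores <- with_seed(1000 + s, stats::rnorm(n) + 0.5 * codes)
    got <- spearman_kendall(codes, scores)
    expect_equal(got$rho, brute_spearman(codes, scores), tolerance = 1e-10)
    expect_equal(got$tau, brute_kendall_b(codes, scores), tolerance = 1e-10)
  }
  expect_error(spearman_kendall(c(0, 0, 0), c(1, 2, 3)), "distinct")
  expect_error(spearman_kendall(c(0, 1, 2), c(1, 1, 1)), "constant")
})

test_that("POA matches exhaustive enumeration and the hand-worked example", {
  expect_equal(as.numeric(poa_macro(c(0, 0, 1, 2), c(0, 0.1, 0.5, 0.9))), 1)
  expect_equal(as.numeric(poa_macro(c(0, 0, 1, 2), c(0.9, 0.8, 0.5, 0.1))), 0)
  # S scores (0.1, 0.4), T score 0.3, H score 0.2: the three ordered-pair
  # accuracies enumerate to (0.5, 0.5, 0) whose macro mean is 1/3
  hand <- poa_macro(c(0, 0, 1, 2), c(0.1, 0.4, 0.3, 0.2))
  expect_equal(as.numeric(hand), 1 / 3, tolerance = 1e-12)
  pp <- attr(hand, "per_pair")
  expect_equal(unname(pp["Supported<Trunk"]), brute_poa_pair(c(0.1, 0.4), 0.3))
  expect_equal(unname(pp["Trunk<Head"]), brute_poa_pair(0.3, 0.2))
  # absent class: remaining pairs are averaged and the gap is reported
  part <- poa_macro(c(0, 0, 1), c(0.1, 0.2, 0.5))
  expect_equal(as.numeric(part), 1)
  expect_true("Supported<Head" %in% attr(part, "skipped"))
})

test_that("sampled POA agrees with exhaustive POA within 0.02", {
  n <- 1000
  codes <- with_seed(5, sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)))
  scores <- with_seed(6, stats::rnorm(n) + codes)
  exact <- poa_macro(codes, scores, cap = 1e7)
  sampled <- poa_macro(codes, scores, cap = 2e4, seed = 3)
  expect_lt(abs(as.numeric(exact) - as.numeric(sampled)), 0.02)
})

test_that("linear probes separate separable clusters and pass the pROC cross-check", {
  n <- 60
  z <- with_seed(2, l2_normalize(rbind(
    matrix(stats::rnorm(n * 3, mean = 2), n, 3),
    matrix(stats::rnorm(n * 3, mean = -2), n, 3)
  )))
  lab <- data.frame(contact_flag = rep(c(1L, 0L), each = n),
                    fall_label = rep(c(1L, 0L), each = n))
  pr <- linear_probes(z, lab, z, lab)
  expect_equal(pr$contact_ap, 1)
  expect_equal(pr$contact_auc, 1)
  expect_equal(pr$fall_auc, 1)
  expect_error(linear_probes(z, data.frame(contact_flag = 1L, fall_label = 1L)[rep(1, 2 * n), ],
                             z, lab), "single-class")

  scores <- with_seed(9, stats::rnorm(80))
  y <- with_seed(10, sample(0:1, 80, replace = TRUE))
  expect_equal(pharl:::auc_roc(scores, y),
               as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("probe AUC under label permutation is chance level", {
  z <- with_seed(20, l2_normalize(matrix(stats::rnorm(400 * 6), 400, 6)))
  aucs <- vapply(1:20, function(r) {
    lab <- with_seed(500 + r, data.frame(
      contact_flag = sample(rep(0:1, each = 200)),
      fall_label = sample(rep(0:1, each = 200))
    ))
    linear_probes(z[1:200, ], lab[1:200, ], z[201:400, ], lab[201:400, ])$contact_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("PCR closed form, construction and permutation null", {
  # two classes of two points each arranged so mean inter = 2 * mean intra
  a <- 2 * atan(0.25)
  z <- rbind(c(cos(a), sin(a)), c(cos(a), -sin(a)),
             c(-cos(a), sin(a)), c(-cos(a), -sin(a)))
  expect_equal(pcr(z, c(0L, 0L, 1L, 1L)), 2, tolerance = 1e-12)

  # three tight, mutually distant clusters give a large ratio
  centers <- diag(3)
  zc <- with_seed(4, l2_normalize(do.call(rbind, lapply(1:3, function(k) {
    matrix(stats::rnorm(20 * 3, sd = 0.01), 20, 3) +
      matrix(centers[k, ], 20, 3, byrow = TRUE)
  }))))
  expect_gt(pcr(zc, rep(0:2, each = 20)), 10)

  # shuffled labels on isotropic embeddings: ratio ~ 1
  zn <- with_seed(8, matrix(stats::rnorm(300 * 6), 300, 6))
  ratios <- vapply(1:20, function(r) {
    pcr(zn, with_seed(700 + r, sample(rep(0:2, each = 100))))
  }, numeric(1))
  expect_true(all(abs(ratios - 1) <= 0.05))
  expect_error(pcr(z, c(0L, 1L, 1L, 1L)), ">= 2")
})

test_that("neighborhood consistency matches exhaustive k-NN enumeration", {
  # pure, well-separated, multi-video clusters: consistency 1 per class
  base <- rbind(c(1, 0), c(0, 1))
  z <- l2_normalize(do.call(rbind, lapply(1:2, function(k) {
    with_seed(30 + k, matrix(stats::rnorm(20 * 2, sd = 0.02), 20, 2) +
                matrix(base[k, ], 20, 2, byrow = TRUE))
  })))
  codes <- rep(c(0L, 1L), each = 20)
  videos <- paste0("v", rep(rep(1:4, each = 5), 2), rep(c("a", "b"), each = 20))
  nc <- neighborhood_consistency(z, codes, videos, k = 5, balance_seed = 1)
  expect_equal(unname(nc$consistency), c(1, 1))

  # a class confined to one video is undefined
  videos1 <- c(rep("x", 20), paste0("y", rep(1:2, each = 10)))
  nc1 <- neighborhood_consistency(z, codes, videos1, k = 5)
  expect_true(is.na(nc1$consistency[["Supported"]]))
  expect_match(nc1$reasons[["Supported"]], "single video")

  # randomized layout against the brute-force oracle (balanced classes keep
  # the whole set as database)
  z2 <- with_seed(44, l2_normalize(matrix(stats::rnorm(24 * 3), 24, 3)))
  codes2 <- rep(c(0L, 1L), each = 12)
  videos2 <- paste0("v", rep(1:6, each = 4))
  nc2 <- neighborhood_consistency(z2, codes2, videos2, k = 3, balance_seed = 2)
  oracle <- brute_neighborhood(z2, codes2, videos2, db_idx = 1:24, k = 3)
  expect_equal(unname(nc2$consistency), unname(oracle), tolerance = 1e-12)
})

test_that("axis metrics are invariant to global rotation", {
  n <- 90
  z <- with_seed(60, l2_normalize(matrix(stats::rnorm(n * 5), n, 5) +
                                    0.8 * outer(rep(0:2, each = 30), rep(1, 5))))
  codes <- rep(0:2, each = 30)
  qr_q <- qr.Q(qr(with_seed(61, matrix(stats::rnorm(25), 5, 5))))
  zr <- z %*% qr_q
  ax <- severity_axis(z, codes); axr <- severity_axis(zr, codes)
  s <- project_severity(z, ax); sr <- project_severity(zr, axr)
  expect_equal(s, sr, tolerance = 1e-9)
  expect_equal(pcr(z, codes), pcr(zr, codes), tolerance = 1e-9)
  expect_equal(as.numeric(poa_macro(codes, s)), as.numeric(poa_macro(codes, sr)))
})

test_that("the report aggregates metrics and flags failures structurally", {
  toy <- make_fixture("toy_training")
  labels <- label_dataset(toy$manifest, toy$descriptors)
  enc <- encoder_init(encoder_config(feature_dim = 8, embed_dim = 8, seed = 2))
  x <- pharl:::pool_features(toy$manifest$features)
  enc$center <- colMeans(x); enc$scale <- pmax(apply(x, 2, stats::sd), 1e-8)
  emb <- structure(list(
    meta = data.frame(window_id = toy$manifest$window_id,
                      trajectory_id = toy$manifest$trajectory_id,
                      video_id = toy$manifest$video_id,
                      split = toy$manifest$split,
                      fall_label = toy$manifest$fall_label,
                      stringsAsFactors = FALSE),
    z = encode(toy$manifest$features, enc)$z
  ), class = "pharl_embedding_table")
  rep1 <- metrics_report(emb, labels, seed = 4)
  rep2 <- metrics_report(emb, labels, seed = 4)
  expect_identical(report_json <- jsonlite::toJSON(pharl:::report_to_list(rep1), digits = NA),
                   jsonlite::toJSON(pharl:::report_to_list(rep2), digits = NA))
  expect_true(is.numeric(rep1$spearman_rho) ||
                inherits(rep1$spearman_rho, "pharl_metric_failure"))
  p <- tempfile(fileext = ".json")
  write_report(rep1, p)
  back <- read_report(p)
  expect_true("counts" %in% names(back))
  unlink(p)

  # missing Head class: axis-dependent entries carry reasons
  labels_nohead <- labels
  labels_nohead$ordinal_code[labels_nohead$ordinal_code == 2L] <- 1L
  labels_nohead$y_phys[labels_nohead$y_phys == "Head"] <- "Trunk"
  rep3 <- metrics_report(emb, labels_nohead, seed = 4)
  expect_s3_class(rep3$spearman_rho, "pharl_metric_failure")
  expect_match(rep3$spearman_rho$reason, "Head")
})
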