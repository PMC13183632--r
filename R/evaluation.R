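# Rank-prioritized diagnostics of embedding geometry: a post-hoc severity axis
# from train-split centroids, Spearman/Kendall rank correlations, macro
# pairwise ordering accuracy (POA), linear probes (contact AP/AUC, fall AUC),
# the physics consistency ratio (PCR), and cross-video neighborhood
# consistency. All metrics are post-hoc: none feeds back into training.

#' Post-hoc severity axis from train-split centroids
#'
#' Unit vector from the Supported centroid to the Head centroid, computed on
#' train-split embeddings only and reused unchanged on other splits.
#'
#' @param z Train-split embedding matrix (unit rows).
#' @param codes Ordinal codes (0 = Supported, 1 = Trunk, 2 = Head).
#' @return A list of class `pharl_severity_axis` with `v_hat`, `mu_head`,
#'   `mu_supported`.
#' @export
severity_axis <- function(z, codes) {
  if (!any(codes == 2L) || !any(codes == 0L)) {
    stop("severity axis needs at least one Head and one Supported window", call. = FALSE)
  }
  mu_head <- colMeans(z[codes == 2L, , drop = FALSE])
  mu_sup <- colMeans(z[codes == 0L, , drop = FALSE])
  diff <- mu_head - mu_sup
  nrm <- sqrt(sum(diff^2))
  if (nrm < 1e-12) stop("coincident class centroids: severity axis undefined", call. = FALSE)
  structure(list(v_hat = diff / nrm, mu_head = mu_head, mu_supported = mu_sup),
            class = "pharl_severity_axis")
}

#' Project embeddings onto a severity axis
#'
#' @param z Embedding matrix.
#' @param axis A [severity_axis()].
#' @return Numeric vector of scalar projection scores `s_i = z_i . v_hat`.
#' @export
project_severity <- function(z, axis) {
  stopifnot(inherits(axis, "pharl_severity_axis"))
  drop(z %*% axis$v_hat)
}

#' Spearman and Kendall rank correlations
#'
#' Spearman on average-ranked ties and Kendall's tau-b between ordinal codes
#' and projection scores. Constant scores are a flagged error, not a silent
#' NaN.
#'
#' @param codes Ordinal codes (>= 2 distinct values required).
#' @param scores Projection scores.
#' @return List with `rho` and `tau`.
#' @export
spearman_kendall <- function(codes, scores) {
  if (length(unique(codes)) < 2L) {
    stop("rank correlation needs at least two distinct ordinal codes", call. = FALSE)
  }
  if (stats::sd(scores) == 0) {
    stop("constant projection scores: rank correlation undefined", call. = FALSE)
  }
  list(rho = stats::cor(codes, scores, method = "spearman"),
       tau = stats::cor(codes, scores, method = "kendall"))
}

#' Macro-averaged pairwise ordering accuracy
#'
#' For each ordered class pair (Supported<Trunk, Supported<Head, Trunk<Head),
#' the fraction of cross-class instance pairs whose scores respect the
#' ordering (ties count 0.5), macro-averaged over the pairs that have at least
#' one instance pair. Enumeration is exhaustive up to `cap` pairs per class
#' pair, and a seeded uniform sample of `cap` pairs beyond that.
#'
#' @param codes Ordinal codes.
#' @param scores Projection scores.
#' @param cap Maximum enumerated/sampled pairs per class pair.
#' @param seed Seed for the sampled regime.
#' @return Macro POA in `[0, 1]` with attributes `per_pair` (named fractions)
#'   and `skipped` (class pairs without instances).
#' @export
poa_macro <- function(codes, scores, cap = 1e5, seed = 1L) {
  pairs <- list(c(0L, 1L), c(0L, 2L), c(1L, 2L))
  names(pairs) <- c("Supported<Trunk", "Supported<Head", "Trunk<Head")
  per <- c(); skipped <- character(0)
  for (nm in names(pairs)) {
    lo <- scores[codes == pairs[[nm]][1L]]
    hi <- scores[codes == pairs[[nm]][2L]]
    n_pairs <- as.double(length(lo)) * length(hi)
    if (n_pairs == 0) { skipped <- c(skipped, nm); next }
    if (n_pairs <= cap) {
      cmp <- outer(lo, hi, function(a, b) (a < b) + 0.5 * (a == b))
      per[nm] <- mean(cmp)
    } else {
      per[nm] <- with_seed(derive_seed(seed, "poa", nm), {
        a <- lo[sample.int(length(lo), cap, replace = TRUE)]
        b <- hi[sample.int(length(hi), cap, replace = TRUE)]
        mean((a < b) + 0.5 * (a == b))
      })
    }
  }
  if (!length(per)) stop("no class pair has instance pairs; POA undefined", call. = FALSE)
  structure(mean(per), per_pair = per, skipped = skipped)
}

# Deterministic ridge-regularized linear probe: closed-form solve on the
# train-split embeddings; the intercept is unpenalized.
ridge_probe <- function(z, y, lambda = 1.0) {
  x <- cbind(1, z)
  pen <- diag(c(0, rep(lambda, ncol(z))))
  solve(crossprod(x) + pen, crossprod(x, y))
}

probe_scores <- function(beta, z) drop(cbind(1, z) %*% beta)

# Threshold-free ROC-AUC via the rank (Mann-Whitney) formula; ties get 0.5.
auc_roc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision as the step-wise area under the precision-recall curve,
# evaluated at distinct score thresholds (descending).
average_precision <- function(scores, y) {
  y <- as.integer(y)
  if (!any(y == 1L)) stop("AP needs positive examples", call. = FALSE)
  ord <- order(-scores)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1L - ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # block ends of tied scores
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / sum(y)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Linear-probe diagnostics
#'
#' Fits deterministic ridge probes (fixed regularization, closed-form solver)
#' on train-split embeddings and scores the test split: average precision and
#' ROC-AUC for contact (Head/Trunk) vs Supported, and ROC-AUC for fall vs
#' no-fall (window-level, trajectory-inherited fall tags).
#'
#' @param z_train,z_test Embedding matrices.
#' @param labels_train,labels_test Data frames with `contact_flag` and
#'   `fall_label`.
#' @param lambda Ridge regularization strength.
#' @return List with `contact_ap`, `contact_auc`, `fall_auc`.
#' @export
linear_probes <- function(z_train, labels_train, z_test, labels_test,
                          lambda = 1.0) {
  for (col in c("contact_flag", "fall_label")) {
    if (length(unique(labels_train[[col]])) < 2L ||
        length(unique(labels_test[[col]])) < 2L) {
      stop(sprintf("probe target `%s` is single-class in a split", col), call. = FALSE)
    }
  }
  bc <- ridge_probe(z_train, labels_train$contact_flag, lambda)
  bf <- ridge_probe(z_train, labels_train$fall_label, lambda)
  sc <- probe_scores(bc, z_test)
  sf <- probe_scores(bf, z_test)
  list(contact_ap = average_precision(sc, labels_test$contact_flag),
       contact_auc = auc_roc(sc, labels_test$contact_flag),
       fall_auc = auc_roc(sf, labels_test$fall_label))
}

#' Physics consistency ratio
#'
#' Mean pairwise distance between different-class embeddings divided by the
#' mean within-class pairwise distance, on l2-normalized embeddings. Values
#' above 1 indicate class-consistent geometry.
#'
#' @param z Embedding matrix.
#' @param codes Class codes; every present class needs >= 2 members.
#' @param metric `"euclidean"` (default) or `"cosine"` (1 - cosine similarity).
#' @return The ratio (> 0).
#' @export
pcr <- function(z, codes, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  counts <- table(codes)
  if (any(counts < 2L)) stop("every present class needs >= 2 members for PCR", call. = FALSE)
  z <- l2_normalize(z)
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(z))
  } else {
    1 - z %*% t(z)
  }
  same <- outer(codes, codes, `==`)
  ut <- upper.tri(d)
  intra <- mean(d[ut & same])
  inter_vals <- d[ut & !same]
  if (!length(inter_vals)) stop("only one class present; PCR undefined", call. = FALSE)
  if (intra == 0) stop("zero intra-class distance; PCR undefined", call. = FALSE)
  mean(inter_vals) / intra
}

#' Cross-video neighborhood consistency
#'
#' Builds a class-balanced retrieval database by subsampling every class to
#' the minority-class size (seeded), queries with all windows of each class,
#' retrieves up to `k` cosine nearest neighbors after excluding same-video
#' database entries, and reports the per-class mean fraction of neighbors
#' sharing the query's class (row-normalized diagonal consistency).
#'
#' @param z Embedding matrix (rows normalized internally).
#' @param codes Class codes.
#' @param video_ids Video identifier per window.
#' @param k Neighbors per query (default 10).
#' @param balance_seed Seed for the balanced subsample.
#' @return A list with `consistency` (named per-class values, `NA` when
#'   undefined), `reasons` (per-class explanation strings for undefined
#'   entries), `k` and `db_per_class`.
#' @export
neighborhood_consistency <- function(z, codes, video_ids, k = 10L,
                                     balance_seed = 1L) {
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  z <- l2_normalize(z)
  classes <- sort(unique(codes))
  m <- min(table(codes))
  db_idx <- with_seed(derive_seed(balance_seed, "balance"), {
    unlist(lapply(classes, function(cl) {
      ci <- which(codes == cl)
      sort(ci[sample.int(length(ci), m)])
    }))
  })
  sims <- z %*% t(z[db_idx, , drop = FALSE])
  cons <- stats::setNames(rep(NA_real_, length(classes)),
                          PHARL_CLASSES[classes + 1L])
  reasons <- stats::setNames(rep(NA_character_, length(classes)),
                             PHARL_CLASSES[classes + 1L])
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    q_idx <- which(codes == cl)
    if (length(unique(video_ids[q_idx])) < 2L) {
      reasons[ci] <- "undefined: class present in a single video"
      next
    }
    fracs <- numeric(0)
    for (q in q_idx) {
      valid <- which(video_ids[db_idx] != video_ids[q])
      if (!length(valid)) next
      sv <- sims[q, valid]
      take <- valid[order(-sv, db_idx[valid])][seq_len(min(k, length(valid)))]
      fracs <- c(fracs, mean(codes[db_idx[take]] == cl))
    }
    if (length(fracs)) cons[ci] <- mean(fracs) else {
      reasons[ci] <- "undefined: same-video exclusion empties the pool"
    }
  }
  list(consistency = cons, reasons = reasons, k = as.integer(k),
       db_per_class = m)
}

#' Full diagnostic report for an embedding table
#'
#' Fits the severity axis on the train split, then computes every diagnostic
#' on the test split: Spearman/Kendall, macro POA, contact AP/AUC and fall AUC
#' linear probes (trained on the train split), PCR, and cross-video
#' neighborhood consistency. Metric failures are recorded as structured nulls
#' with reason strings rather than propagated.
#'
#' @param emb A `pharl_embedding_table` from [embed_dataset()] covering all
#'   splits.
#' @param labels Label table from [label_dataset()].
#' @param k Neighborhood-consistency k.
#' @param poa_cap POA pair cap per class pair.
#' @param seed Seed for POA sampling and the balanced retrieval database.
#' @param probe_lambda Ridge strength of the linear probes.
#' @return A list of class `pharl_metrics_report`.
#' @export
metrics_report <- function(emb, labels, k = 10L, poa_cap = 1e5, seed = 1L,
                           probe_lambda = 1.0) {
  stopifnot(inherits(emb, "pharl_embedding_table"))
  ix <- match(emb$meta$window_id, labels$window_id)
  if (anyNA(ix)) stop("labels are missing for some embedded windows", call. = FALSE)
  meta <- cbind(emb$meta,
                labels[ix, c("ordinal_code", "contact_flag"), drop = FALSE])
  tr <- which(meta$split == "train")
  te <- which(meta$split == "test")
  z_tr <- emb$z[tr, , drop = FALSE]
  z_te <- emb$z[te, , drop = FALSE]

  res <- list()
  grab <- function(expr) {
    tryCatch(expr, error = function(e) {
      structure(list(value = NULL, reason = conditionMessage(e)),
                class = "pharl_metric_failure")
    })
  }
  axis <- grab(severity_axis(z_tr, meta$ordinal_code[tr]))
  if (inherits(axis, "pharl_metric_failure")) {
    res$spearman_rho <- res$kendall_tau <- res$poa_macro <- axis
  } else {
    s_te <- project_severity(z_te, axis)
    sk <- grab(spearman_kendall(meta$ordinal_code[te], s_te))
    if (inherits(sk, "pharl_metric_failure")) {
      res$spearman_rho <- res$kendall_tau <- sk
    } else {
      res$spearman_rho <- sk$rho
      res$kendall_tau <- sk$tau
    }
    poa <- grab(poa_macro(meta$ordinal_code[te], s_te, cap = poa_cap,
                          seed = derive_seed(seed, "poa")))
    if (inherits(poa, "pharl_metric_failure")) {
      res$poa_macro <- poa
      res$poa_per_pair <- NULL
    } else {
      res$poa_macro <- as.numeric(poa)
      res$poa_per_pair <- as.list(attr(poa, "per_pair"))
    }
    res$mean_projection <- vapply(0:2, function(cl) {
      if (any(meta$ordinal_code[te] == cl)) mean(s_te[meta$ordinal_code[te] == cl])
      else NA_real_
    }, numeric(1))
    names(res$mean_projection) <- PHARL_CLASSES
  }
  probes <- grab(linear_probes(z_tr, meta[tr, , drop = FALSE],
                               z_te, meta[te, , drop = FALSE],
                               lambda = probe_lambda))
  if (inherits(probes, "pharl_metric_failure")) {
    res$contact_ap <- res$contact_auc <- res$fall_auc <- probes
  } else {
    res[c("contact_ap", "contact_auc", "fall_auc")] <- probes
  }
  res$pcr <- grab(pcr(z_te, meta$ordinal_code[te]))
  nc <- grab(neighborhood_consistency(z_te, meta$ordinal_code[te],
                                      meta$video_id[te], k = k,
                                      balance_seed = derive_seed(seed, "balance")))
  res$neighborhood <- if (inherits(nc, "pharl_metric_failure")) nc else nc
  res$counts <- list(
    n_train = length(tr), n_test = length(te),
    test_class_counts = as.list(table(factor(meta$ordinal_code[te], levels = 0:2,
                                             labels = PHARL_CLASSES)))
  )
  res$settings <- list(k = k, poa_cap = poa_cap, seed = seed,
                       probe_lambda = probe_lambda)
  structure(res, class = "pharl_metrics_report")
}

# Flatten a report into JSON-friendly structure (failures become
# {value: null, reason: ...}).
report_to_list <- function(report) {
  conv <- function(x) {
    if (inherits(x, "pharl_metric_failure")) {
      list(value = NULL, reason = x$reason)
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, conv)
    } else x
  }
  lapply(unclass(report), conv)
}

#' Write / read a metrics report as JSON
#'
#' @param report A `pharl_metrics_report`.
#' @param path Output path.
#' @return `path` (write) or the parsed report list (read).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
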