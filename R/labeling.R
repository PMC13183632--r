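# Window-level physics labels from contact-descriptor streams.
#
# A window W = [t0, t1) collects contact evidence in three steps: temporal
# alignment (keep window-source descriptors whose half-open interval overlaps
# W), boundary completion (admit continuation-source descriptors that start
# within a short horizon after t1), and reliability filtering (drop impulses
# not strictly above the threshold, then aggregate survivors by per-category
# maximum impulse). The label is then assigned by hierarchical dominance:
# head > torso/hip > everything else, with the empty set defaulting to
# Supported. All coordinates are 0-based frames with half-open intervals.

LABEL_SOURCES <- c("window", "continuation")

body_part_category <- function(part) {
  ifelse(part == "head", "head",
         ifelse(part %in% c("torso", "hip"), "trunk", "limb"))
}

#' Half-open temporal overlap between a window and a descriptor
#'
#' Implements the predicate `(ts < t1) & (te > t0)` on half-open intervals.
#'
#' @param window A list or one-row data frame with fields `t0`, `t1`.
#' @param d A list or one-row data frame with fields `ts`, `te`.
#' @return `TRUE` if the intervals overlap.
#' @export
overlaps <- function(window, d) {
  (d$ts < window$t1) && (d$te > window$t0)
}

#' Filtered, merged per-window impulse evidence
#'
#' Builds the per-window impulse set: window-source descriptors overlapping the
#' window, plus (when `"continuation"` is in `sources`) continuation-source
#' descriptors whose start lies in `[t1, t1 + horizon)`. Descriptors with
#' impulse not strictly greater than `threshold` are dropped; survivors are
#' aggregated by per-category (head / trunk / limb) maximum impulse.
#'
#' @param window A list or one-row data frame with `video_id`, `t0`, `t1`.
#' @param stream Descriptor data frame (`video_id`, `ts`, `te`, `body_part`,
#'   `impulse_ns`, `source`).
#' @param sources Character subset of `c("window", "continuation")`.
#' @param threshold Minimum impulse in N.s; survivors must be strictly greater.
#' @param horizon Continuation admission horizon in frames after `t1`.
#' @return Named numeric vector of class `pharl_impulse_set` with at most the
#'   names `head`, `trunk`, `limb` (categories with no surviving evidence are
#'   absent).
#' @export
build_impulse_set <- function(window, stream, sources = LABEL_SOURCES,
                              threshold = 0, horizon = 8L) {
  if (!all(sources %in% LABEL_SOURCES)) {
    stop("`sources` must be a subset of {window, continuation}", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be nonnegative", call. = FALSE)
  if (horizon < 0) stop("`horizon` must be nonnegative", call. = FALSE)
  s <- stream[stream$video_id == window$video_id, , drop = FALSE]
  keep <- rep(FALSE, nrow(s))
  if ("window" %in% sources) {
    keep <- keep | (s$source == "window" & s$ts < window$t1 & s$te > window$t0)
  }
  if ("continuation" %in% sources) {
    keep <- keep | (s$source == "continuation" &
                      s$ts >= window$t1 & s$ts < window$t1 + horizon)
  }
  s <- s[keep & s$impulse_ns > threshold, , drop = FALSE]
  out <- numeric(0)
  if (nrow(s)) {
    cat_of <- body_part_category(s$body_part)
    out <- vapply(split(s$impulse_ns, cat_of), max, numeric(1))
    out <- out[intersect(c("head", "trunk", "limb"), names(out))]
  }
  structure(out, class = "pharl_impulse_set")
}

#' Hierarchical dominance label from an impulse set
#'
#' Head if any head-category impulse is present, else Trunk if any torso/hip
#' impulse, else Supported (limb contacts and empty evidence both map to
#' Supported). Magnitudes never override the hierarchy.
#'
#' @param s A `pharl_impulse_set` (or named numeric vector).
#' @return A list with `y_phys` (factor level name), `ordinal_code`
#'   (0 = Supported, 1 = Trunk, 2 = Head) and `contact_flag`
#'   (`1` iff Head or Trunk).
#' @export
assign_label <- function(s) {
  nm <- names(s) %||% character(0)
  code <- if ("head" %in% nm) 2L else if ("trunk" %in% nm) 1L else 0L
  list(y_phys = PHARL_CLASSES[code + 1L],
       ordinal_code = code,
       contact_flag = as.integer(code > 0L))
}

#' Label every window of a manifest
#'
#' Produces one physics label per window. Windows of non-fall trajectories
#' skip descriptor lookup entirely and label Supported. With `denoise = FALSE`
#' the temporally aligned procedure is replaced by trajectory-level labels
#' (see [trajectory_level_labels()]), the denoising-off ablation.
#'
#' @param manifest Window manifest data frame.
#' @param stream Descriptor data frame.
#' @param sources,threshold,horizon Passed to [build_impulse_set()].
#' @param denoise Logical; `FALSE` selects trajectory-level labeling.
#' @param verbose Emit a per-split class histogram via `message()`.
#' @return Data frame with columns `window_id`, `y_phys`, `ordinal_code`,
#'   `contact_flag`, `max_impulse_head`, `max_impulse_trunk`,
#'   `max_impulse_limb` (NA when the category is absent).
#' @export
label_dataset <- function(manifest, stream, sources = LABEL_SOURCES,
                          threshold = 0, horizon = 8L, denoise = TRUE,
                          verbose = FALSE) {
  if (anyDuplicated(manifest$window_id)) {
    stop("duplicate window_id in manifest", call. = FALSE)
  }
  if (!denoise) {
    return(trajectory_level_labels(manifest, stream, sources = sources,
                                   threshold = threshold, verbose = verbose))
  }
  by_video <- split(stream, stream$video_id)
  n <- nrow(manifest)
  sets <- vector("list", n)
  empty <- structure(numeric(0), class = "pharl_impulse_set")
  for (i in seq_len(n)) {
    if (manifest$fall_label[i] == 0L) {
      sets[[i]] <- empty
      next
    }
    vs <- by_video[[manifest$video_id[i]]]
    if (is.null(vs)) {
      sets[[i]] <- empty
      next
    }
    sets[[i]] <- build_impulse_set(
      list(video_id = manifest$video_id[i], t0 = manifest$t0[i], t1 = manifest$t1[i]),
      vs, sources = sources, threshold = threshold, horizon = horizon
    )
  }
  out <- label_table_from_sets(manifest, sets)
  if (verbose) log_label_histogram(out, manifest$split)
  out
}

#' Trajectory-level labels (denoising-off ablation)
#'
#' Every window of a trajectory inherits the dominance label computed from the
#' trajectory's full descriptor stream, with no temporal alignment; only the
#' source filter and the impulse threshold are applied. Non-fall trajectories
#' label Supported.
#'
#' @inheritParams label_dataset
#' @return Same shape as [label_dataset()].
#' @export
trajectory_level_labels <- function(manifest, stream, sources = LABEL_SOURCES,
                                    threshold = 0, verbose = FALSE) {
  if (anyDuplicated(manifest$window_id)) {
    stop("duplicate window_id in manifest", call. = FALSE)
  }
  if (!all(sources %in% LABEL_SOURCES)) {
    stop("`sources` must be a subset of {window, continuation}", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be nonnegative", call. = FALSE)
  empty <- structure(numeric(0), class = "pharl_impulse_set")
  video_sets <- lapply(split(stream, stream$video_id), function(s) {
    s <- s[s$source %in% sources & s$impulse_ns > threshold, , drop = FALSE]
    if (!nrow(s)) return(empty)
    cat_of <- body_part_category(s$body_part)
    out <- vapply(split(s$impulse_ns, cat_of), max, numeric(1))
    structure(out[intersect(c("head", "trunk", "limb"), names(out))],
              class = "pharl_impulse_set")
  })
  sets <- lapply(seq_len(nrow(manifest)), function(i) {
    if (manifest$fall_label[i] == 0L) return(empty)
    video_sets[[manifest$video_id[i]]] %||% empty
  })
  out <- label_table_from_sets(manifest, sets)
  if (verbose) log_label_histogram(out, manifest$split)
  out
}

label_table_from_sets <- function(manifest, sets) {
  pick <- function(s, cat) if (cat %in% names(s)) unname(s[[cat]]) else NA_real_
  labs <- lapply(sets, assign_label)
  data.frame(
    window_id = manifest$window_id,
    y_phys = vapply(labs, `[[`, character(1), "y_phys"),
    ordinal_code = vapply(labs, `[[`, integer(1), "ordinal_code"),
    contact_flag = vapply(labs, `[[`, integer(1), "contact_flag"),
    max_impulse_head = vapply(sets, pick, numeric(1), "head"),
    max_impulse_trunk = vapply(sets, pick, numeric(1), "trunk"),
    max_impulse_limb = vapply(sets, pick, numeric(1), "limb"),
    stringsAsFactors = FALSE
  )
}

log_label_histogram <- function(labels, split) {
  tab <- table(split, factor(labels$y_phys, levels = PHARL_CLASSES))
  for (s in rownames(tab)) {
    message(sprintf("labels [%s]: %s", s,
                    paste(sprintf("%s=%d", colnames(tab), tab[s, ]), collapse = " ")))
  }
}
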