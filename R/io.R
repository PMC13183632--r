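# Format readers and writers: manifest JSONL, descriptor JSONL, labels CSV,
# embedding tables (CSV or Parquet), ground truth JSON and report JSON.
# Every reader performs line-level schema validation with row-indexed errors;
# writers serialize at full double precision so write -> read -> write is
# byte-stable.

MANIFEST_FIELDS <- c("window_id", "trajectory_id", "video_id", "split",
                     "t0", "t1", "fall_label", "features")
DESCRIPTOR_FIELDS <- c("video_id", "ts", "te", "body_part", "impulse_ns", "source")

#' Write / read a window manifest (JSONL)
#'
#' One JSON object per line with fields `window_id`, `trajectory_id`,
#' `video_id`, `split`, `t0`, `t1`, `fall_label` and the inline `features`
#' array (frames x feature_dim).
#'
#' @param manifest Manifest data frame (with the `features` list column).
#' @param path File path.
#' @return `path` (write) or the manifest (read).
#' @export
write_manifest <- function(manifest, path) {
  lines <- vapply(seq_len(nrow(manifest)), function(i) {
    jsonlite::toJSON(list(
      window_id = manifest$window_id[i],
      trajectory_id = manifest$trajectory_id[i],
      video_id = manifest$video_id[i],
      split = manifest$split[i],
      t0 = manifest$t0[i], t1 = manifest$t1[i],
      fall_label = manifest$fall_label[i],
      features = manifest$features[[i]]
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop(sprintf(
                      "manifest line %d: invalid JSON (%s)", i, conditionMessage(e)),
                      call. = FALSE))
    missing <- setdiff(MANIFEST_FIELDS, names(rec))
    if (length(missing)) {
      stop(sprintf("manifest line %d: missing field(s) %s", i,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (rec$t0 >= rec$t1) stop(sprintf("manifest line %d: t0 >= t1", i), call. = FALSE)
    rec$features <- as.matrix(rec$features)
    rec
  })
  out <- data.frame(
    window_id = vapply(rows, `[[`, character(1), "window_id"),
    trajectory_id = vapply(rows, `[[`, character(1), "trajectory_id"),
    video_id = vapply(rows, `[[`, character(1), "video_id"),
    split = vapply(rows, `[[`, character(1), "split"),
    t0 = vapply(rows, function(r) as.integer(r$t0), integer(1)),
    t1 = vapply(rows, function(r) as.integer(r$t1), integer(1)),
    fall_label = vapply(rows, function(r) as.integer(r$fall_label), integer(1)),
    stringsAsFactors = FALSE
  )
  out$features <- lapply(rows, `[[`, "features")
  if (anyDuplicated(out$window_id)) stop("duplicate window_id in manifest", call. = FALSE)
  class(out) <- c("pharl_manifest", "data.frame")
  out
}

#' Write / read a contact-descriptor stream (JSONL)
#'
#' One JSON object per line with fields `video_id`, `ts`, `te`, `body_part`
#' (head/torso/hip/arm/hand/leg/foot), `impulse_ns` (>= 0) and `source`
#' (window/continuation).
#'
#' @param descriptors Descriptor data frame.
#' @param path File path.
#' @return `path` (write) or the descriptor data frame (read).
#' @export
write_descriptors <- function(descriptors, path) {
  lines <- vapply(seq_len(nrow(descriptors)), function(i) {
    jsonlite::toJSON(as.list(descriptors[i, DESCRIPTOR_FIELDS]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(empty_descriptor_stream())
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop(sprintf(
                      "descriptor line %d: invalid JSON (%s)", i, conditionMessage(e)),
                      call. = FALSE))
    missing <- setdiff(DESCRIPTOR_FIELDS, names(rec))
    if (length(missing)) {
      stop(sprintf("descriptor line %d: missing field(s) %s", i,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (!rec$body_part %in% PHARL_BODY_PARTS) {
      stop(sprintf("descriptor line %d: unknown body_part '%s'", i, rec$body_part),
           call. = FALSE)
    }
    if (!rec$source %in% LABEL_SOURCES) {
      stop(sprintf("descriptor line %d: unknown source '%s'", i, rec$source),
           call. = FALSE)
    }
    if (rec$ts >= rec$te) stop(sprintf("descriptor line %d: ts >= te", i), call. = FALSE)
    if (rec$impulse_ns < 0) stop(sprintf("descriptor line %d: negative impulse", i),
                                 call. = FALSE)
    rec
  })
  data.frame(
    video_id = vapply(rows, `[[`, character(1), "video_id"),
    ts = vapply(rows, function(r) as.integer(r$ts), integer(1)),
    te = vapply(rows, function(r) as.integer(r$te), integer(1)),
    body_part = vapply(rows, `[[`, character(1), "body_part"),
    impulse_ns = vapply(rows, function(r) as.numeric(r$impulse_ns), numeric(1)),
    source = vapply(rows, `[[`, character(1), "source"),
    stringsAsFactors = FALSE
  )
}

#' Write / read a label table (CSV)
#'
#' @param labels Label table from [label_dataset()].
#' @param path File path.
#' @return `path` (write) or the label table (read).
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("window_id", "y_phys", "ordinal_code", "contact_flag")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop(sprintf("label file missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Write / read an embedding table (CSV or Parquet)
#'
#' CSV stores the metadata columns followed by `e1..ed`; Parquet (via the
#' arrow package, when installed) stores the same flat table.
#'
#' @param emb A `pharl_embedding_table`.
#' @param path File path; format inferred from the `.csv` / `.parquet`
#'   extension unless given.
#' @param format `"csv"` or `"parquet"`.
#' @return `path` (write) or the embedding table (read).
#' @export
write_embeddings <- function(emb, path, format = c("auto", "csv", "parquet")) {
  format <- resolve_emb_format(match.arg(format), path)
  flat <- cbind(emb$meta, as.data.frame(emb$z))
  names(flat) <- c(names(emb$meta), paste0("e", seq_len(ncol(emb$z))))
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, quote = TRUE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet output requires the arrow package", call. = FALSE)
    }
    arrow::write_parquet(flat, path)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path, format = c("auto", "csv", "parquet")) {
  format <- resolve_emb_format(match.arg(format), path)
  flat <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet input requires the arrow package", call. = FALSE)
    }
    as.data.frame(arrow::read_parquet(path))
  }
  e_cols <- grep("^e[0-9]+$", names(flat), value = TRUE)
  meta_cols <- setdiff(names(flat), e_cols)
  structure(list(meta = flat[, meta_cols, drop = FALSE],
                 z = as.matrix(flat[, e_cols, drop = FALSE])),
            class = "pharl_embedding_table")
}

resolve_emb_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.parquet$", path)) "parquet" else "csv"
}

#' Write / read the ground-truth sidecar (JSON)
#'
#' @param gt Ground-truth data frame from [simulate_dataset()].
#' @param path File path.
#' @return `path` (write) or a data frame (read).
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
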