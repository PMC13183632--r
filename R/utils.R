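# Shared numerics and RNG plumbing. All randomness in the package flows through
# with_seed()/derive_seed() so that a single top-level seed yields bit-identical
# runs on one CPU.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded helpers do not perturb the global random stream.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named sub-seed from a base seed
#'
#' Deterministically maps a base seed plus one or more stream labels (e.g.
#' `"sim"`, `"batch"`, an epoch number) to a new 32-bit seed, so independent
#' random substreams can be drawn from one global seed.
#'
#' @param seed Base integer seed.
#' @param ... Labels (coerced to character) naming the substream.
#' @return A single integer seed in `[1, 2^31 - 20)`.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "."),
                         character(1)), collapse = "/")
  h <- abs(as.double(as.integer(seed))) %% 2147483629
  for (v in utf8ToInt(labels)) h <- (h * 131 + v) %% 2147483629
  as.integer(h + 1)
}

# Row-wise log-sum-exp with -Inf-safe shifting; rows that are entirely -Inf
# return -Inf rather than NaN.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  shifted <- sweep(m, 1L, ifelse(is.finite(mx), mx, 0))
  out <- mx + log(rowSums(exp(shifted)))
  out[!is.finite(mx)] <- -Inf
  out
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Row-normalize to unit l2 norm; zero rows are an error because cosine
# similarity is undefined for them.
l2_normalize <- function(x) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("cannot l2-normalize a zero-norm row", call. = FALSE)
  x / nrm
}

unit_vector <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) stop("zero vector", call. = FALSE)
  x / n
}

# Content hash of an R object via its canonical JSON form (used for config /
# architecture identity checks and provenance sidecars).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

# sample() without the scalar-x surprise.
sample_one <- function(x) x[sample.int(length(x), 1L)]

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
}
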