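#' @importFrom stats rnorm runif rbinom rpois var sd cor optim optimHess
#'   model.matrix setNames aggregate pchisq qnorm
#' @importFrom utils write.csv read.csv head combn
NULL

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in the package flows from one integer base seed. Each
#' stage (founders, meiosis, field noise, CV sampling, ...) derives its own
#' seed from the base seed, a stage name and an index, so any stage can be
#' re-run in isolation and still reproduce exactly.
#'
#' @param base integer base seed.
#' @param stage character stage label.
#' @param index optional integer index (e.g. repetition number).
#' @return An integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
derive_seed <- function(base, stage, index = 0L) {
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  # simple LCG-style mix, kept within 32-bit integer range
  x <- (as.double(base) %% 2147483647) * 48271 + h * 16807 + as.double(index) * 69621
  as.integer(x %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_prob <- function(x, name, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
      (if (upper_open) x >= 1 else x > 1)) {
    stop(sprintf("`%s` must be a single finite value in [0,%s]", name,
                 if (upper_open) "1)" else "1"), call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}

#' Write a file atomically (temp file + rename)
#'
#' @param writer function taking a path and writing the payload.
#' @param path destination path.
#' @return `path`, invisibly.
#' @keywords internal
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

#' Harmonic mean
#' @param x positive numeric vector.
#' @keywords internal
harmonic_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) return(NA_real_)
  length(x) / sum(1 / x)
}

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
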