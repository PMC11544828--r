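# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream. Used by every generator that takes a `seed`.
#'
#' @param seed integer scalar, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic splitting rule used by [runStudy()] to fan one master seed
#' out to per-stage and per-subject seeds: a fixed-multiplier integer hash,
#' reduced modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed master seed (integer).
#' @param ... one or more integer or character stream labels.
#' @return A single non-negative integer seed.
#' @export
#' @examples
#' childSeed(17, "cohort")
#' childSeed(17, "scg", 12, 2)
childSeed <- function(seed, ...) {
  labels <- list(...)
  h <- as.double(seed) %% 2147483647
  for (lab in labels) {
    if (is.character(lab)) lab <- sum(utf8ToInt(paste(lab, collapse = "")))
    for (v in as.double(lab)) {
      h <- (h * 48271 + v + 11) %% 2147483647
    }
  }
  as.integer(h)
}

# Stable per-subject standard-normal draw, derived from the subject id alone.
# Gives subject-level physiology (e.g. resting HR offset) that is identical
# across repeated recordings of the same subject without widening the
# SubjectProfile contract.
subjectNormal <- function(subject_id, stream) {
  withSeed(childSeed(0L, "subject", subject_id, stream), stats::rnorm(1L))
}

# Validation helper: stop with a message naming the offending field.
assertField <- function(ok, field, what) {
  if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, what), call. = FALSE)
  invisible(TRUE)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# Time-weighted (trapezoidal) mean of y over x.
trapzMean <- function(x, y) {
  span <- x[length(x)] - x[1L]
  if (span <= 0) return(mean(y))
  trapz(x, y) / span
}
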