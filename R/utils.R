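## Internal utilities: seed scoping, substreams, logging.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that seeded package functions
#' never perturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Counter-based substream derivation: a single user seed expands to
## reproducible, well-separated per-element seeds. Plain integer arithmetic
## below 2^31; constants are arbitrary odd primes.
substream_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483629)
  x <- (s * 48271 + as.double(counter) * 16807 + 12345) %% 2147483629
  as.integer(x %% 2147483563) + 1L
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

#' Leveled key=value logger
#'
#' Timestamped, leveled, machine-parsable logging used across the package
#' and its command-line wrapper. The threshold is the option
#' `DiffGRN.log_level` (`"debug"` < `"info"` < `"warn"`; default `"info"`).
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`.
#' @param msg Human-readable message.
#' @param ... Named values appended as a `key=value` tail.
#' @return `NULL`, invisibly.
#' @export
log_msg <- function(level = "info", msg, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  opt <- getOption("DiffGRN.log_level", "info")
  if (levels[[level]] < levels[[opt]]) return(invisible(NULL))
  kv <- list(...)
  tail <- if (length(kv))
    paste(sprintf("%s=%s", names(kv), vapply(kv, format, character(1))),
          collapse = " ")
  else ""
  message(sprintf("[%s] %s %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  toupper(level), msg, tail))
  invisible(NULL)
}

## Stable fingerprint of an R object (written through a canonical text dump).
object_fingerprint <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(deparse(x, control = c("exact", "niceNames")), tf)
  unname(tools::md5sum(tf))
}
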