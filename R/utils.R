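#' @keywords internal
#' @useDynLib e2ennet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Fail with a formatted message.
stop2 <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop2(...)
  invisible(TRUE)
}

#' Derive a child seed from a base seed and a stream index
#'
#' Deterministic, keeps the result inside the 32-bit integer range so it can
#' be passed to [set.seed()]. Used to give every fold / repetition its own
#' reproducible random stream.
#'
#' @param seed base integer seed.
#' @param index non-negative stream index (fold number, repeat number, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 30269 + 11) %% 2147483629
  as.integer(s) + 1L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Near-equality helper for internal checks.
is_close <- function(a, b, tol = 1e-8) all(abs(a - b) <= tol)
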