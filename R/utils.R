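#' @keywords internal
"_PACKAGE"

# Deterministic seed fan-out: one user seed governs every stochastic stage.
# Sub-seeds are derived from (seed, label) with a small multiplicative hash so
# that independent stages never share an RNG stream.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half-up (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_oct <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_oct(...)
  invisible(TRUE)
}
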