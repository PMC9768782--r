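# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG, evaluates `expr`, and restores whatever RNG state the
#' caller had, so package functions are deterministic per their own `seed`
#' arguments without disturbing user code.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Deterministic sub-seed for a named pipeline stage, kept inside 32-bit
# integer range. Distinct offsets keep stage streams independent.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_prob_vector <- function(p, what, names_expected = NULL) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0))
    stop_input("%s must be non-negative numeric proportions", what)
  if (abs(sum(p) - 1) > 1e-9)
    stop_input("%s must sum to 1 (got %.12f)", what, sum(p))
  if (!is.null(names_expected)) {
    if (is.null(names(p)) || !identical(sort(names(p)), sort(names_expected)))
      stop_input("%s must be named with {%s}", what,
                 paste(names_expected, collapse = ", "))
    p <- p[names_expected]
  }
  p
}
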