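#' @keywords internal
"_PACKAGE"

# Canonical analyte order used everywhere in the package.
HISS_ANALYTES <- c("glucose", "lactate", "ph", "potassium", "po2")

HISS_CLASSES <- 0:4
HISS_CLASS_NAMES <- c("LOW", "GUARDED", "ELEVATED", "HIGH", "SEVERE")

# Hard plausibility gates, deliberately wider than the normal bands: panels
# outside these are rejected as physically implausible rather than abnormal.
PH_GATE <- c(6.5, 8.0)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the global
#' random stream. A `NULL` seed leaves the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
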