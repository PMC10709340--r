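#' @keywords internal
"_PACKAGE"

## Condition helper: all package errors carry class "orcaseq_error" plus a
## specific subclass so callers and tests can branch on the failure mode.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "orcaseq_error", "error", "condition")))
}

## Evaluate `code` with a locally-seeded RNG, restoring the caller's RNG
## state afterwards so seeded generators never perturb the session stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
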