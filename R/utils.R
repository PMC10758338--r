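#' @importFrom stats plogis qlogis rbinom rnbinom runif rnorm sd var
#'   uniroot model.matrix glm binomial predict coef quantile setNames
#'   aggregate
#' @importFrom utils head tail
#' @import data.table
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Clip probabilities away from {0, 1} before taking logits or logs.
clip_prob <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}
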