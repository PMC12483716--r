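# Shared numerical helpers.

#' Inverse logit
#'
#' Numerically stable logistic transform `1 / (1 + exp(-x))`.
#'
#' @param x numeric vector on the logit scale.
#' @return probabilities in `[0, 1]`.
#' @export
invlogit <- function(x) stats::plogis(as.numeric(x))

#' Logit
#' @param p probabilities strictly inside `(0, 1)`.
#' @return logits.
#' @export
logit <- function(p) log(p) - log1p(-p)

# Derive a reproducible sub-seed from a master seed and a counter.
# Kept below 2^31 - 1 so it is a valid R integer seed.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629 + 1)
}

# Run an expression under a local RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eirmrf <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "eirmrf_error")))
}
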