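# Internal helpers: seed-stream derivation and argument checks.

#' Derive a per-stage sub-seed from a master seed
#'
#' A single master seed spawns independent, named sub-seeds, one per pipeline
#' stage, so that adding or reordering stages never perturbs the draws of the
#' other stages. The stage name is hashed with a small polynomial string hash
#' and mixed with the master seed modulo 2^31 - 1, keeping the result a valid
#' 32-bit integer seed.
#'
#' @param seed master seed (single integer-valued number).
#' @param stage character stage name, e.g. `"genotypes"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under a local RNG state seeded from (seed, stage); the
# caller's RNG state is untouched.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  expr
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("cyclegrs_invalid_argument", "error")))
}

stop_missing_data <- function(field, ...) {
  stop(errorCondition(
    paste0("missing data in field '", field, "'", ...),
    class = c("cyclegrs_missing_data", "error"),
    field = field
  ))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_invalid(name, " must be a probability in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop_invalid(name, if (positive) " must be a positive integer" else
      " must be a non-negative integer")
  }
  invisible(as.integer(x))
}

# round-half-up to the nearest integer (0.5 always rounds away from zero
# for the non-negative values used here); base round() is round-half-even.
round_half_up <- function(x) floor(x + 0.5)
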