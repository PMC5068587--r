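# Seed substreams and internal argument checks.

#' Derive a named random substream seed
#'
#' Named substreams derived from one master seed so that schedule, behaviour,
#' noise and trait randomness are independently reproducible.  The offset is
#' a small stable hash of the stream name; results stay below 2^31 - 1, so
#' they are always valid `set.seed()` inputs.
#'
#' @param master_seed integer master seed.
#' @param stream single character stream name.
#' @return a derived integer-valued seed.
#' @export
substream_seed <- function(master_seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.double(master_seed) * 1009 + h * 7919) %% 2147483647
}

#' Evaluate an expression under a named random substream
#'
#' Runs `expr` with the RNG seeded from [substream_seed()] and restores the
#' caller's RNG state afterwards, so simulation stages do not perturb each
#' other.
#'
#' @inheritParams substream_seed
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_substream <- function(master_seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master_seed, stream))
  force(expr)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0
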