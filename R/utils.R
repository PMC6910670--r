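#' Derive a reproducible sub-seed
#'
#' Deterministically combines a base seed with an arbitrary set of string or
#' integer tags (fold index, selector name, iteration number, ...) into a new
#' seed below 2^31, so that every stochastic stage of a run can be seeded
#' independently from one user-facing seed.
#'
#' @param base integer base seed.
#' @param ... tags (coerced to character) identifying the consumer.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base, ...) {
  tags <- paste(vapply(list(...), function(x) paste(as.character(x),
                                                    collapse = "\r"),
                       character(1)), collapse = "\n")
  h <- as.double(base %% 2147483647L)
  for (code in utf8ToInt(tags)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h %% 2147483645) + 1L
}

# evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_deltarad <- function(...) stop(..., call. = FALSE)
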