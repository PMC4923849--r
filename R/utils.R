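# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a substream seed from a global seed
#'
#' Deterministically maps a global seed and a stream label to a new seed,
#' so each pipeline stage can be re-run standalone with the same stream.
#' Result is always a positive integer below 2^31.
#'
#' @param seed integer global seed.
#' @param stream character label of the substream.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # cheap string hash (djb2), folded into [1, 2^31 - 2]
  h <- 5381
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 33 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483646 + 1)
}

# run code with a local RNG state; leaves the caller's stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x)
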