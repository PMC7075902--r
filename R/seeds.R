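#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one integer master seed. Stage-
#' and unit-specific seeds are derived by folding a string key (for example
#' `"schedule/animal03/session07"`) into the master seed with a polynomial
#' string hash, so that every simulated object has its own reproducible
#' stream and adding animals or sessions never shifts the streams of the
#' others.
#'
#' @param seed integer master seed.
#' @param ... character or numeric key components identifying the consumer.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' child_seed(1, "schedule", 3)
child_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
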