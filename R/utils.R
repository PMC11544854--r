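#' Round a proportion to a percentage, half away from zero
#'
#' Clinical reports round on the percent scale with halves rounded up
#' (so 52.94 -> 53 at integer precision and 37.09 -> 37.1 at one decimal),
#' unlike base R's round-half-even.
#'
#' @param p proportion(s) in \[0, 1\].
#' @param digits decimal places on the percent scale (0 gives "53%",
#'   1 gives "37.1%").
#' @return Numeric percentage(s).
#' @export
percent_round <- function(p, digits = 0L) {
  scale <- 10^digits
  floor(p * 100 * scale + 0.5) / scale
}

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
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
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
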