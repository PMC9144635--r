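#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom tibble tibble as_tibble
NULL

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive independent sub-seeds from a master seed
#'
#' All randomness in the package flows from one integer seed. Functions that
#' need several independent random streams (e.g. one per benchmark cell) draw
#' sub-seeds from this splitter so that every stage is replayable in isolation.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to derive.
#' @return An integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 0)
  if (n == 0) return(integer(0))
  withr::with_seed(as.integer(seed), sample.int(2147483645L, n, replace = FALSE))
}

# shared argument checks ------------------------------------------------------

check_rate <- function(rate, upper = 1) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) ||
      rate < 0 || rate >= upper) {
    abort(sprintf("`rate` must be a single number in [0, %s).", upper))
  }
  rate
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed)
}
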