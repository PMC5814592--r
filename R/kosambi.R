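#' Kosambi map function and its inverse
#'
#' Converts a recombination fraction to a map distance under the Kosambi
#' map function, `d = 25 * log((1 + 2r) / (1 - 2r))` centiMorgan, which
#' allows for partial crossover interference, and back.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return `kosambi_cm` returns the distance in cM; `kosambi_inverse`
#'   the recombination fraction. Both are vectorised and exact inverses
#'   of each other.
#' @examples
#' kosambi_cm(0.1)            # 25 * log(1.5) = 10.1366
#' kosambi_inverse(10.1366)   # ~0.1
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) stop2("r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop2("d must be >= 0")
  # analytic inverse: r = (exp(d/25) - 1) / (2 (exp(d/25) + 1)) = tanh(d/50)/2
  tanh(d / 50) / 2
}

#' Haldane map function (no interference)
#'
#' Reference map function used for comparison and in tests; the simulated
#' crossover process (Poisson, no interference) follows Haldane exactly.
#'
#' @inheritParams kosambi_cm
#' @return distance in cM, or recombination fraction for the inverse.
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) stop2("r must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @export
haldane_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop2("d must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}
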