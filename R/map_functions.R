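#' Map functions: recombination fraction <-> genetic distance
#'
#' `kosambi()` and `haldane()` convert a recombination fraction `r` into a
#' genetic distance in centimorgans; `kosambi_inverse()` and
#' `haldane_inverse()` go the other way.  Kosambi allows partial crossover
#' interference and is the convention used for the map positions throughout
#' this package; Haldane (no interference) is used for Markov-consistent
#' hidden-Markov-model transition probabilities.
#'
#' Kosambi: d = 25 log((1 + 2r)/(1 - 2r)), inverse r = tanh(d/50)/2.
#' Haldane: d = -50 log(1 - 2r), inverse r = (1 - exp(-d/50))/2.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Genetic distance(s) in cM, `>= 0`.
#' @return Distance in cM, or recombination fraction, as a numeric vector.
#' @examples
#' kosambi(0.25)             # 27.47 cM
#' kosambi_inverse(50)       # 0.3808
#' haldane(0.25)             # 34.66 cM
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("recombination fraction must lie in [0, 0.5): r = 0.5 maps to infinite distance")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("genetic distance must be >= 0")
  0.5 * tanh(d / 50)
}

#' @rdname kosambi
#' @export
haldane <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("recombination fraction must lie in [0, 0.5): r = 0.5 maps to infinite distance")
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi
#' @export
haldane_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("genetic distance must be >= 0")
  (1 - exp(-d / 50)) / 2
}
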