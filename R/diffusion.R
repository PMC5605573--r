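#' Kimura-Ohta neutral diffusion allele age
#'
#' Classical diffusion approximation to the expected age of a neutral allele
#' observed at population frequency `q` in a diploid population of effective
#' size `Ne`, with no mutation:
#' `E[age] = -4 * Ne * (q / (1 - q)) * log(q)` generations. Serves as an
#' independent baseline for the exact Markov-chain computation; across the
#' neutral comparisons it overestimates the exact age by a few generations.
#'
#' @param Ne effective diploid population size.
#' @param q observed mutant frequency in `(0, 1)`; alternatively give the
#'   copy count `x` and `q = x / (2 * Ne)` is used.
#' @param x observed copy count (used when `q` is missing).
#' @return expected allele age in generations (vectorized over `q`).
#' @examples
#' kimura_ohta_age(1000, x = 10)    # ~106.5 generations
#' kimura_ohta_age(1000, q = 0.5)   # ~2772.6 generations
#' @export
kimura_ohta_age <- function(Ne, q = NULL, x = NULL) {
  if (is.null(q)) {
    if (is.null(x)) stop("supply either 'q' or 'x'")
    q <- x / (2 * Ne)
  }
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly inside (0, 1)")
  -4 * Ne * (q / (1 - q)) * log(q)
}
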