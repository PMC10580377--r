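# Intermutation distances.

#' Compute intermutation distances for one chromosome
#'
#' The intermutation distance (IMD) of the first variant is its position; for
#' every later variant it is the distance to its closest upstream variant.
#' One pseudo-IMD — the distance from the last variant to the chromosome end
#' — is appended so that the IMDs of a chromosome sum exactly to its length
#' in base pairs.
#'
#' @param positions Strictly increasing integer vector of variant start
#'   positions (1-based).
#' @param chromosome_length Chromosome length in base pairs; at least
#'   `max(positions)`.
#' @return A tibble with one row per observation and columns `index`,
#'   `position` (`NA` for the pseudo-IMD row), `imd`, and `pseudo`.
#' @examples
#' compute_imd(c(100, 150, 1150), 2000)
#' @export
compute_imd <- function(positions, chromosome_length) {
  if (length(positions) == 0) {
    abort("`positions` is empty; skip chromosomes without variants.")
  }
  positions <- as.numeric(positions)
  if (any(diff(positions) <= 0)) {
    abort("`positions` must be strictly increasing; run preprocess_variants().")
  }
  if (positions[1] < 1 || positions[length(positions)] > chromosome_length) {
    abort("`positions` must lie within [1, chromosome_length].")
  }
  k <- length(positions)
  imds <- diff(c(0, positions))
  pseudo <- chromosome_length - positions[k]
  tibble(
    index = seq_len(k + 1),
    position = c(positions, NA_real_),
    imd = c(imds, pseudo),
    pseudo = c(rep(FALSE, k), TRUE)
  )
}
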