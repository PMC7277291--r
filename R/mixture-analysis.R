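#' Probability that a two-person mixture reveals three or more alleles
#'
#' Two unrelated individuals drawn under Hardy--Weinberg contribute four
#' independent allele draws; a mixture is detectable when those four draws
#' span at least three distinct alleles. By inclusion--exclusion over the
#' event "all four draws fall within one allele or one allele pair":
#' \deqn{p = 1 - \Bigl[\sum_a p_a^4 +
#'   \sum_{a<b}\bigl((p_a+p_b)^4 - p_a^4 - p_b^4\bigr)\Bigr].}
#' A locus with two or fewer alleles can never show a third allele, so
#' \eqn{p = 0} there.
#'
#' @param freqs an \code{\link{mh_freqs}} spectrum (or numeric frequencies
#'   summing to 1).
#' @return detection probability in \eqn{[0, 1]}.
#' @seealso \code{\link{mixture_probability_oracle}} for the brute-force
#'   enumeration this closed form is checked against.
#' @export
mixture_detection_probability <- function(freqs) {
  p <- as.numeric(freqs)
  k <- length(p)
  if (k <= 2L) return(0)
  le2 <- sum(p^4)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    le2 <- le2 + (p[i] + p[j])^4 - p[i]^4 - p[j]^4
  }
  max(0, 1 - le2)
}

#' Mixture detection probability at equal allele frequencies
#'
#' Closed form at \eqn{p_i = 1/k}, the frequency configuration that maximises
#' the detection probability for a given allele count:
#' \deqn{p = 1 - \frac{k + \binom{k}{2}(2^4 - 2)}{k^4}, \quad k \ge 2,}
#' giving \eqn{4/9 = 0.4444} at \eqn{k = 3} and \eqn{21/32 = 0.65625} at
#' \eqn{k = 4}.
#'
#' @param k allele count (vectorised), \eqn{k \ge 1}.
#' @return detection probability.
#' @export
mixture_detection_probability_equal <- function(k) {
  if (any(k < 1)) stop_mh("allele count must be >= 1")
  k <- as.numeric(k)
  ifelse(k < 2, 0, 1 - (k + choose(k, 2) * 14) / k^4)
}

#' Enumeration oracle for the mixture detection probability
#'
#' Exact computation by summing the probability of every ordered 4-tuple of
#' allele draws whose union has three or more distinct alleles. Independent of
#' the inclusion--exclusion closed form; intended as a cross-check.
#'
#' @inheritParams mixture_detection_probability
#' @return detection probability; agrees with
#'   \code{\link{mixture_detection_probability}} to 1e-12.
#' @export
mixture_probability_oracle <- function(freqs) {
  p <- as.numeric(freqs)
  k <- length(p)
  if (k > 12L) stop_mh("enumeration oracle limited to <= 12 alleles")
  idx <- as.matrix(expand.grid(a = 1:k, b = 1:k, c = 1:k, d = 1:k))
  prob <- p[idx[, 1]] * p[idx[, 2]] * p[idx[, 3]] * p[idx[, 4]]
  ndistinct <- apply(idx, 1L, function(r) length(unique(r)))
  sum(prob[ndistinct >= 3L])
}

#' Cumulative panel probability of detecting a two-person mixture
#'
#' Follows the floor rule: each locus contributes the equal-frequency
#' detection probability at \eqn{k = \lfloor A_e \rfloor} alleles (the
#' minimal integral value of the effective number of alleles), and the panel
#' combines by complement product,
#' \eqn{P = 1 - \prod_i (1 - p_i)}. Loci whose floor is below 3 contribute a
#' factor of 1 (their detection probability is 0).
#'
#' @param ae_values numeric vector of per-locus effective numbers of alleles
#'   (all \eqn{\ge 1}).
#' @return cumulative detection probability; 0 for an empty panel.
#' @export
panel_mixture_probability <- function(ae_values) {
  if (length(ae_values) == 0L) return(0)
  if (any(ae_values < 1)) stop_mh("Ae values must be >= 1")
  p <- mixture_detection_probability_equal(floor(ae_values))
  -expm1(sum(log1p(-p)))
}
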