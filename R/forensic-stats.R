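#' Effective number of alleles
#'
#' The equivalent number of equally frequent neutral alleles,
#' \eqn{A_e = 1 / \sum_i p_i^2}. Equals the allele count \eqn{k} exactly when
#' all frequencies are \eqn{1/k}.
#'
#' @param freqs an \code{\link{mh_freqs}} spectrum (or bare numeric vector of
#'   frequencies summing to 1).
#' @return \eqn{A_e \in [1, k]}.
#' @export
effective_num_alleles <- function(freqs) {
  p <- as.numeric(freqs)
  if (length(p) == 0L) stop_mh("empty frequency set")
  1 / sum(p^2)
}

#' Expected heterozygosity
#'
#' \eqn{H_e = 1 - \sum_i p_i^2 = 1 - 1/A_e}.
#'
#' @inheritParams effective_num_alleles
#' @return \eqn{H_e \in [0, 1)}.
#' @export
expected_heterozygosity <- function(freqs) {
  1 - 1 / effective_num_alleles(freqs)
}

#' Observed heterozygosity of a genotype column
#'
#' Fraction of non-missing genotypes whose two alleles differ. Missing
#' genotypes (\code{"./."} or \code{NA}) are excluded pairwise.
#'
#' @param column character vector of canonical \code{"A/B"} genotype strings.
#' @return \eqn{H_o \in [0, 1]}.
#' @export
observed_heterozygosity <- function(column) {
  g <- column[!is_missing_geno(column)]
  if (length(g) == 0L) stop_mh("no non-missing genotypes")
  al <- split_geno(g)
  mean(al[, 1] != al[, 2])
}

#' Matching probability and power of discrimination
#'
#' The matching probability MP is the probability that two randomly selected
#' individuals share a genotype at the locus, estimated from observed genotype
#' counts as \eqn{\sum_G (n_G/n)^2}; the power of discrimination is its
#' complement, \eqn{PD = 1 - MP}.
#'
#' @inheritParams observed_heterozygosity
#' @return \code{matching_probability}: MP in (0, 1].
#' @export
matching_probability <- function(column) {
  g <- column[!is_missing_geno(column)]
  if (length(g) == 0L) stop_mh("no non-missing genotypes")
  sum((table(g) / length(g))^2)
}

#' @rdname matching_probability
#' @return \code{power_of_discrimination}: PD = 1 - MP.
#' @export
power_of_discrimination <- function(column) 1 - matching_probability(column)

#' Power of exclusion from observed heterozygosity
#'
#' The classic exclusion-power function of the observed heterozygosity used by
#' forensic parameter calculators:
#' \deqn{PE = H_o^2 \,\bigl(1 - 2 H_o (1 - H_o)^2\bigr).}
#' It is monotone nondecreasing on \eqn{[0,1]} with PE(0) = 0 and PE(1) = 1,
#' and reproduces e.g. PE(0.70) = 0.428 and PE(0.84) = 0.675 (3 d.p.).
#'
#' @param ho observed heterozygosity in \eqn{[0, 1]} (vectorised).
#' @return PE in \eqn{[0, 1]}.
#' @export
power_of_exclusion <- function(ho) {
  if (any(ho < 0 | ho > 1)) stop_mh("Ho must lie in [0, 1]")
  ho^2 * (1 - 2 * ho * (1 - ho)^2)
}

#' Per-locus forensic parameter summary
#'
#' Computes \code{LocusStats} for one locus: Ae and He from the frequency
#' spectrum (when given, otherwise from allele counts observed in the column),
#' Ho, MP, PD from observed genotype counts, and PE from Ho.
#'
#' @param column genotype column (canonical \code{"A/B"} strings).
#' @param freqs optional \code{\link{mh_freqs}} for the locus.
#' @param locus locus id for labelling.
#' @return one-row data.frame: \code{locus}, \code{n}, \code{ae}, \code{ho},
#'   \code{he}, \code{mp}, \code{pd}, \code{pe}.
#' @export
locus_stats <- function(column, freqs = NULL, locus = NA_character_) {
  g <- column[!is_missing_geno(column)]
  if (is.null(freqs)) {
    al <- split_geno(g)
    cnt <- table(c(al[, 1], al[, 2]))
    freqs <- mh_freqs(as.numeric(cnt) / sum(cnt), alleles = names(cnt))
  }
  ho <- observed_heterozygosity(column)
  mp <- matching_probability(column)
  data.frame(locus = locus, n = length(g),
             ae = effective_num_alleles(freqs),
             ho = ho, he = expected_heterozygosity(freqs),
             mp = mp, pd = 1 - mp, pe = power_of_exclusion(ho),
             stringsAsFactors = FALSE)
}

#' Panel-level forensic parameters for a genotype table
#'
#' Applies \code{\link{locus_stats}} to every locus column of a genotype
#' table.
#'
#' @param genotypes an \code{mh_genotypes} table.
#' @param freq_db optional named list of \code{\link{mh_freqs}} per locus.
#' @return data.frame, one row per locus.
#' @export
panel_stats <- function(genotypes, freq_db = NULL) {
  loci <- locus_cols(genotypes)
  do.call(rbind, lapply(loci, function(loc)
    locus_stats(genotypes[[loc]], freqs = freq_db[[loc]], locus = loc)))
}

#' Combine per-locus statistics into panel-level cumulative parameters
#'
#' Cumulative power of discrimination \eqn{CPD = 1 - \prod_i (1 - PD_i)},
#' cumulative power of exclusion \eqn{CPE = 1 - \prod_i (1 - PE_i)} and
#' combined matching probability \eqn{CMP = \prod_i MP_i}. Products are
#' accumulated in log space, so the complements \code{one_minus_cpd} /
#' \code{one_minus_cpe} remain accurate down to the 1e-18 scale typical of a
#' 20-locus panel.
#'
#' @param stats data.frame with columns \code{pd}, \code{pe} and optionally
#'   \code{mp}, \code{ae}, \code{ho} (as from \code{\link{panel_stats}}).
#' @return list of class \code{mh_panel_stats}: \code{per_locus}, \code{cpd},
#'   \code{cpe}, \code{cmp}, \code{one_minus_cpd}, \code{one_minus_cpe},
#'   \code{cumulative_mixture} (when \code{ae} is present) and a
#'   \code{summary} data.frame of column means/mins/maxs.
#' @export
combine_panel <- function(stats) {
  if (nrow(stats) < 1L) stop_mh("need at least one locus")
  log1m_cpd <- sum(log1p(-stats$pd))
  log1m_cpe <- sum(log1p(-stats$pe))
  cmp <- if (!is.null(stats$mp)) exp(sum(log(stats$mp))) else NA_real_
  cols <- intersect(c("ae", "ho", "he", "mp", "pd", "pe"), names(stats))
  summ <- data.frame(
    statistic = cols,
    mean = vapply(cols, function(cl) mean(stats[[cl]]), numeric(1)),
    min = vapply(cols, function(cl) min(stats[[cl]]), numeric(1)),
    max = vapply(cols, function(cl) max(stats[[cl]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    per_locus = stats,
    cpd = -expm1(log1m_cpd), one_minus_cpd = exp(log1m_cpd),
    cpe = -expm1(log1m_cpe), one_minus_cpe = exp(log1m_cpe),
    cmp = cmp,
    cumulative_mixture = if (!is.null(stats$ae))
      panel_mixture_probability(stats$ae) else NA_real_,
    summary = summ), class = "mh_panel_stats")
}

#' @export
print.mh_panel_stats <- function(x, ...) {
  cat("<mh_panel_stats> ", nrow(x$per_locus), " loci\n", sep = "")
  cat(sprintf("  CPD = 1 - %.4g   CPE = 1 - %.4g   CMP = %.4g\n",
              x$one_minus_cpd, x$one_minus_cpe, x$cmp))
  if (!is.na(x$cumulative_mixture))
    cat(sprintf("  cumulative two-person mixture detection = %.9f\n",
                x$cumulative_mixture))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Theta-corrected match probability (Balding-Nichols)
#'
#' Probability that two individuals from the same subpopulation share a
#' genotype at a locus, allowing for coancestry \eqn{\theta}. The first
#' individual's genotype follows Hardy--Weinberg proportions; the second
#' individual's conditional genotype probabilities are the Balding--Nichols
#' forms
#' \deqn{P(aa \mid aa) = \frac{(2\theta + (1-\theta)p_a)(3\theta + (1-\theta)p_a)}
#'   {(1+\theta)(1+2\theta)}}
#' \deqn{P(ab \mid ab) = \frac{2(\theta + (1-\theta)p_a)(\theta + (1-\theta)p_b)}
#'   {(1+\theta)(1+2\theta)}.}
#' At \eqn{\theta = 0} this reduces exactly to \eqn{\sum_G P(G)^2}.
#'
#' @param freqs an \code{\link{mh_freqs}} spectrum.
#' @param theta coancestry coefficient in \eqn{[0, 1)} (default 0).
#' @return per-locus match probability.
#' @export
bn_match_probability <- function(freqs, theta = 0) {
  if (theta < 0 || theta >= 1) stop_mh("theta must lie in [0, 1)")
  p <- as.numeric(freqs)
  k <- length(p)
  denom <- (1 + theta) * (1 + 2 * theta)
  mp <- sum(p^2 * (2 * theta + (1 - theta) * p) *
              (3 * theta + (1 - theta) * p) / denom)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      prior <- 2 * p[i] * p[j]
      cond <- 2 * (theta + (1 - theta) * p[i]) *
        (theta + (1 - theta) * p[j]) / denom
      mp <- mp + prior * cond
    }
  }
  mp
}

#' @rdname bn_match_probability
#' @param freq_db named list of \code{\link{mh_freqs}}.
#' @return \code{bn_combined_match_probability}: product of per-locus match
#'   probabilities over the panel.
#' @export
bn_combined_match_probability <- function(freq_db, theta = 0) {
  exp(sum(log(vapply(freq_db, bn_match_probability, numeric(1), theta = theta))))
}
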