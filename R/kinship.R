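#' Mendelian consistency of a parent/child genotype pair
#'
#' A duo is Mendelian-consistent at a locus iff the two genotypes share at
#' least one allele. Returns \code{NA} when either genotype is missing
#' (indeterminate; such loci are excluded from CPI).
#'
#' @param parent_genotype,child_genotype canonical \code{"A/B"} genotype
#'   strings (vectorised).
#' @return logical vector.
#' @export
mendelian_check <- function(parent_genotype, child_genotype) {
  out <- rep(NA, length(parent_genotype))
  ok <- !is_missing_geno(parent_genotype) & !is_missing_geno(child_genotype)
  if (any(ok)) {
    pa <- split_geno(parent_genotype[ok])
    ca <- split_geno(child_genotype[ok])
    out[ok] <- ca[, 1] == pa[, 1] | ca[, 1] == pa[, 2] |
      ca[, 2] == pa[, 1] | ca[, 2] == pa[, 2]
  }
  out
}

# P(allele x transmitted | parent genotype), with single-step uniform
# replacement mutation at rate mu over the k alleles of the locus.
transmission_prob <- function(x, parent_alleles, all_alleles, mu = 0) {
  k <- length(all_alleles)
  pr <- 0
  for (a in parent_alleles) {
    p_pass <- if (a == x) 1 - mu else if (mu > 0 && k > 1) mu / (k - 1) else 0
    pr <- pr + 0.5 * p_pass
  }
  pr
}

#' Paternity index for a single-parent duo at one locus
#'
#' Likelihood ratio \eqn{PI = P(\mathrm{child}\mid\mathrm{parent},
#' \mathrm{parentage}) / P(\mathrm{child}\mid\mathrm{unrelated})}: under
#' parentage the child receives one parental allele (probability 1/2 each)
#' and one population allele; the unrelated denominator is the
#' Hardy--Weinberg genotype probability. Under the default no-mutation policy
#' an allele-sharing violation gives PI = 0 (an exclusion); with
#' \code{mutation_rate} > 0 the transmitted allele may mutate by single-step
#' uniform replacement, giving small nonzero PI at exclusions.
#'
#' Standard special cases (parent/child, \eqn{p} = shared-allele frequency):
#' both homozygous \eqn{aa/aa}: \eqn{1/p_a}; \eqn{ab/ac}: \eqn{1/(4 p_a)};
#' \eqn{aa/ab} or \eqn{ab/aa}: \eqn{1/(2 p_a)};
#' \eqn{ab/ab}: \eqn{(p_a + p_b)/(4 p_a p_b)}.
#'
#' @param parent_genotype,child_genotype canonical \code{"A/B"} strings.
#' @param freqs \code{\link{mh_freqs}} for the locus.
#' @param mutation_rate per-transmission mutation probability (default 0,
#'   the no-mutation policy).
#' @param rare_allele_freq frequency assigned to an observed allele absent
#'   from \code{freqs}; defaults to the minimum-allele-count floor
#'   \eqn{5/(2n+2)} when the spectrum carries its sample size, otherwise an
#'   error. Applied with a warning.
#' @return paternity index \eqn{\ge 0}.
#' @export
duo_pi <- function(parent_genotype, child_genotype, freqs,
                   mutation_rate = 0, rare_allele_freq = NULL) {
  if (is_missing_geno(parent_genotype) || is_missing_geno(child_genotype))
    stop_mh("missing genotype: locus is indeterminate, exclude it from CPI")
  pa <- split_geno(parent_genotype)[1, ]
  ca <- split_geno(child_genotype)[1, ]
  p <- as.numeric(freqs)
  names(p) <- names(freqs)
  absent <- setdiff(c(pa, ca), names(p))
  if (length(absent)) {
    if (is.null(rare_allele_freq)) {
      ns <- attr(freqs, "n_samples")
      if (is.null(ns))
        stop_mh("allele(s) ", paste(absent, collapse = ","),
                " absent from frequency set and no rare_allele_freq given")
      rare_allele_freq <- 5 / (2 * ns + 2)
    }
    warning("applying rare-allele floor frequency ", signif(rare_allele_freq, 4),
            " for: ", paste(absent, collapse = ","), call. = FALSE)
    p <- c(p, setNames(rep(rare_allele_freq, length(absent)), absent))
    p <- p / sum(p)
  }
  alleles <- names(p)
  c1 <- ca[1]; c2 <- ca[2]
  if (c1 == c2) {
    num <- transmission_prob(c1, pa, alleles, mutation_rate) * p[[c1]]
    den <- p[[c1]]^2
  } else {
    num <- transmission_prob(c1, pa, alleles, mutation_rate) * p[[c2]] +
      transmission_prob(c2, pa, alleles, mutation_rate) * p[[c1]]
    den <- 2 * p[[c1]] * p[[c2]]
  }
  num / den
}

#' Combined paternity index over a panel for simulated or observed duos
#'
#' Computes per-locus PI for each duo, the combined paternity index
#' \eqn{CPI = \prod_i PI_i} (accumulated in log10 space), the list of
#' exclusion loci (PI = 0 under the no-mutation policy), and a verdict
#' against the confirmation threshold.
#'
#' @param duos an \code{mh_duos} object (aligned \code{parent}/\code{child}
#'   genotype tables, e.g. from \code{\link{simulate_duos}}).
#' @param freq_db named list of \code{\link{mh_freqs}} per locus.
#' @param threshold CPI confirmation threshold (default 10000).
#' @param exclude_loci loci omitted from the product by policy (e.g. markers
#'   flagged by LD tests); logged in the result.
#' @param mutation_rate,rare_allele_freq passed to \code{\link{duo_pi}}.
#' @param max_exclusions_supported number of exclusions at which a duo is
#'   classified \code{"excluded"} (default 1).
#' @return data.frame of class \code{mh_kinship}, one row per duo:
#'   \code{duo}, \code{n_loci}, \code{cpi}, \code{log10_cpi},
#'   \code{n_exclusions}, \code{exclusion_loci}, \code{verdict}; per-locus PI
#'   matrix attached as attribute \code{"pi"}.
#' @export
cpi <- function(duos, freq_db, threshold = 1e4, exclude_loci = NULL,
                mutation_rate = 0, rare_allele_freq = NULL,
                max_exclusions_supported = 1L) {
  loci <- intersect(locus_cols(duos$parent), names(freq_db))
  loci <- setdiff(loci, exclude_loci)
  if (length(loci) == 0L) stop_mh("no loci with genotypes and frequencies")
  n_duos <- nrow(duos$parent)
  pim <- matrix(NA_real_, nrow = n_duos, ncol = length(loci),
                dimnames = list(duos$parent$sample, loci))
  for (loc in loci) {
    f <- freq_db[[loc]]
    for (d in seq_len(n_duos)) {
      pg <- duos$parent[[loc]][d]; cg <- duos$child[[loc]][d]
      if (is_missing_geno(pg) || is_missing_geno(cg)) next
      pim[d, loc] <- duo_pi(pg, cg, f, mutation_rate = mutation_rate,
                            rare_allele_freq = rare_allele_freq)
    }
  }
  rows <- lapply(seq_len(n_duos), function(d) {
    pis <- pim[d, ]
    used <- !is.na(pis)
    if (!any(used)) stop_mh("duo ", d, ": zero included loci")
    excl <- names(pis)[used & pis == 0]
    cpi_val <- if (length(excl)) 0 else 10^sum(log10(pis[used]))
    data.frame(duo = sub("-P$", "", duos$parent$sample[d]),
               n_loci = sum(used),
               cpi = cpi_val,
               log10_cpi = if (length(excl)) -Inf else sum(log10(pis[used])),
               n_exclusions = length(excl),
               exclusion_loci = paste(excl, collapse = ";"),
               verdict = classify_cpi(cpi_val, threshold = threshold,
                                      n_exclusions = length(excl),
                                      max_exclusions_supported =
                                        max_exclusions_supported),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pi") <- pim
  attr(out, "excluded_by_policy") <- exclude_loci
  class(out) <- c("mh_kinship", "data.frame")
  out
}

#' Classify a combined paternity index against the confirmation threshold
#'
#' @param cpi_value CPI \eqn{\ge 0}.
#' @param threshold confirmation threshold (default 10000): CPI at or above
#'   it is direct support for parentage.
#' @param n_exclusions number of exclusion loci observed.
#' @param max_exclusions_supported exclusion count at which the verdict
#'   becomes \code{"excluded"}.
#' @return \code{"supported"}, \code{"excluded"} or \code{"inconclusive"}.
#' @export
classify_cpi <- function(cpi_value, threshold = 1e4, n_exclusions = 0L,
                         max_exclusions_supported = 1L) {
  if (cpi_value < 0) stop_mh("CPI must be >= 0")
  if (cpi_value == 0 || n_exclusions >= max_exclusions_supported) return("excluded")
  if (cpi_value >= threshold) return("supported")
  "inconclusive"
}
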