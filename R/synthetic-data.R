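# Synthetic-data generators: every input the pipeline consumes can be
# produced here with known ground truth and full seed determinism. One base
# seed expands into per-locus substreams (derive_seed) so adding loci never
# perturbs earlier draws.

#' Sample a random allele-frequency spectrum
#'
#' Draws \code{k} frequencies from a symmetric Dirichlet with the given
#' concentration. Large concentrations approach the equal-frequency spectrum
#' \eqn{1/k}; concentrations below 1 give skewed spectra.
#'
#' @param k allele count, \eqn{\ge 2}.
#' @param concentration positive Dirichlet concentration (default 1, the
#'   uniform simplex).
#' @param seed integer seed.
#' @param locus optional locus id; also used to derive allele strings.
#' @param n_snps length of the haplotype allele strings (default
#'   \code{ceiling(log(k, 2))}, enough to keep strings distinct).
#' @return an \code{\link{mh_freqs}} spectrum with haplotype-string allele
#'   names.
#' @export
sample_allele_freqs <- function(k, concentration = 1, seed = 1, locus = NULL,
                                n_snps = NULL) {
  if (k < 2) stop_mh("need at least 2 alleles")
  if (concentration <= 0) stop_mh("concentration must be positive")
  set.seed(seed)
  f <- as.numeric(rdirichlet(1, rep(concentration, k)))
  mh_freqs(f, alleles = haplotype_labels(k, n_snps), locus = locus)
}

# Distinct haplotype strings over {A,C,G,T}, one base per SNP.
haplotype_labels <- function(k, n_snps = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(n_snps)) n_snps <- max(2L, ceiling(log(k, base = 4)))
  while (4^n_snps < k) n_snps <- n_snps + 1L
  grid <- do.call(expand.grid, rep(list(bases), n_snps))
  labs <- do.call(paste0, rev(grid))
  labs[seq_len(k)]
}

#' Simulate Hardy-Weinberg genotypes at one locus
#'
#' Each genotype is two independent allele draws from the spectrum, stored as
#' a canonical unordered \code{"A/B"} string.
#'
#' @param freqs an \code{\link{mh_freqs}} spectrum.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return character vector of \code{n} genotype strings.
#' @export
hwe_genotypes <- function(freqs, n, seed = 1) {
  if (n < 1) stop_mh("n must be >= 1")
  set.seed(seed)
  al <- names(freqs)
  draws <- sample(al, 2 * n, replace = TRUE, prob = as.numeric(freqs))
  geno_string(draws[seq_len(n)], draws[n + seq_len(n)])
}

#' Simulate a multi-locus Hardy-Weinberg genotype table
#'
#' @param freq_db named list of \code{\link{mh_freqs}} per locus.
#' @param n number of individuals.
#' @param seed base seed; each locus consumes its own derived substream.
#' @param sample_prefix prefix for generated sample ids.
#' @return an \code{mh_genotypes} data.frame.
#' @export
simulate_genotype_table <- function(freq_db, n, seed = 1, sample_prefix = "S") {
  tab <- data.frame(sample = sprintf("%s%03d", sample_prefix, seq_len(n)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(freq_db)) {
    tab[[names(freq_db)[i]]] <-
      hwe_genotypes(freq_db[[i]], n, seed = derive_seed(seed, i))
  }
  as_mh_genotypes(tab)
}

#' Simulate Mendelian parent/child duos
#'
#' Parents are drawn under Hardy--Weinberg; each child receives one uniformly
#' chosen parental allele plus one population allele. With probability
#' \code{mutation_rate} the transmitted allele is replaced by a uniformly
#' chosen \emph{different} allele (single-step uniform replacement; default 0,
#' i.e. strictly Mendelian transmission).
#'
#' @param freq_db named list of \code{\link{mh_freqs}} per locus.
#' @param n_duos number of parent/child pairs.
#' @param seed base seed.
#' @param mutation_rate per-transmission haplotype mutation probability in
#'   \eqn{[0, 1]}.
#' @return list of class \code{mh_duos} with aligned \code{mh_genotypes}
#'   tables \code{parent} and \code{child} (rows are duos \code{D001}, ...).
#' @export
simulate_duos <- function(freq_db, n_duos, seed = 1, mutation_rate = 0) {
  if (mutation_rate < 0 || mutation_rate > 1)
    stop_mh("mutation_rate must lie in [0, 1]")
  parent <- data.frame(sample = sprintf("D%03d-P", seq_len(n_duos)),
                       stringsAsFactors = FALSE)
  child <- data.frame(sample = sprintf("D%03d-C", seq_len(n_duos)),
                      stringsAsFactors = FALSE)
  for (i in seq_along(freq_db)) {
    f <- freq_db[[i]]
    al <- names(f)
    set.seed(derive_seed(seed, i))
    p1 <- sample(al, n_duos, replace = TRUE, prob = as.numeric(f))
    p2 <- sample(al, n_duos, replace = TRUE, prob = as.numeric(f))
    transmit <- ifelse(runif(n_duos) < 0.5, p1, p2)
    if (mutation_rate > 0 && length(al) > 1L) {
      mut <- runif(n_duos) < mutation_rate
      if (any(mut)) {
        transmit[mut] <- vapply(transmit[mut], function(a)
          sample(setdiff(al, a), 1L), character(1))
      }
    }
    other <- sample(al, n_duos, replace = TRUE, prob = as.numeric(f))
    parent[[names(freq_db)[i]]] <- geno_string(p1, p2)
    child[[names(freq_db)[i]]] <- geno_string(transmit, other)
  }
  structure(list(parent = as_mh_genotypes(parent),
                 child = as_mh_genotypes(child)),
            class = "mh_duos")
}

#' Simulate subpopulation spectra under the Balding-Nichols drift model
#'
#' Each subpopulation's frequencies are drawn from a Dirichlet with parameters
#' \eqn{p_i (1-\theta)/\theta}, where \eqn{p} is the ancestral spectrum and
#' \eqn{\theta} the drift parameter; the expected Fst between independently
#' drifted populations is \eqn{\theta}. Ancestral alleles with frequency 0 are
#' dropped with a warning (the Dirichlet is degenerate there).
#'
#' @param ancestral an \code{\link{mh_freqs}} ancestral spectrum.
#' @param theta_drift drift parameter in (0, 1).
#' @param n_pops number of subpopulations.
#' @param seed integer seed.
#' @return list of \code{n_pops} \code{\link{mh_freqs}} spectra.
#' @export
bn_population_freqs <- function(ancestral, theta_drift, n_pops, seed = 1) {
  if (theta_drift <= 0 || theta_drift >= 1)
    stop_mh("theta_drift must lie in (0, 1)")
  p <- as.numeric(ancestral)
  al <- names(ancestral)
  if (any(p == 0)) {
    warning("dropping ancestral alleles with frequency 0", call. = FALSE)
    al <- al[p > 0]; p <- p[p > 0]; p <- p / sum(p)
  }
  set.seed(seed)
  draws <- rdirichlet(n_pops, p * (1 - theta_drift) / theta_drift)
  lapply(seq_len(n_pops), function(i)
    mh_freqs(draws[i, ], alleles = al, locus = attr(ancestral, "locus")))
}

#' Simulate two-person mixture allele profiles
#'
#' Unions the genotypes of two independent Hardy--Weinberg individuals into a
#' set of 1--4 distinct alleles, as seen in a two-contributor DNA mixture
#' without dropout.
#'
#' @param freqs an \code{\link{mh_freqs}} spectrum.
#' @param n_mixtures number of mixtures.
#' @param seed integer seed.
#' @return list of character vectors (the distinct allele sets).
#' @export
simulate_mixture_profiles <- function(freqs, n_mixtures, seed = 1) {
  set.seed(seed)
  al <- names(freqs)
  p <- as.numeric(freqs)
  draws <- matrix(sample(al, 4 * n_mixtures, replace = TRUE, prob = p),
                  ncol = 4L)
  lapply(seq_len(n_mixtures), function(i) sort(unique(draws[i, ])))
}

#' Strip phase from a haplotype genotype column
#'
#' Converts phase-known haplotype-pair genotypes into per-SNP unordered
#' genotypes, the input for EM haplotype-frequency estimation. A sample that
#' is heterozygous at two or more SNPs becomes phase-ambiguous.
#'
#' @param column genotype column of \code{"HAP1/HAP2"} strings, all haplotype
#'   strings of equal length.
#' @return character matrix (samples x SNPs) of per-SNP \code{"x/y"}
#'   genotypes (alleles sorted), \code{NA} rows for missing genotypes.
#' @export
unphased_from_haplotypes <- function(column) {
  al <- split_geno(column)
  n_snps <- max(nchar(al[, 1]), 0, na.rm = TRUE)
  out <- matrix(NA_character_, nrow = length(column), ncol = n_snps)
  ok <- which(!is.na(al[, 1]))
  for (s in seq_len(n_snps)) {
    x <- substr(al[ok, 1], s, s)
    y <- substr(al[ok, 2], s, s)
    out[ok, s] <- geno_string(x, y)
  }
  colnames(out) <- paste0("snp", seq_len(n_snps))
  out
}

#' Construct a spectrum with a prescribed effective number of alleles
#'
#' Builds a k-allele spectrum with one major allele at frequency \eqn{a} and
#' the rest equally frequent, solving
#' \eqn{a^2 + (1-a)^2/(k-1) = 1/A_e} for the root with \eqn{a \ge 1/k}.
#' Deterministic; used to assemble panels whose Ae profile matches a target.
#'
#' @param k allele count.
#' @param ae target effective number of alleles, in \eqn{(1, k]}.
#' @param locus optional locus id.
#' @return an \code{\link{mh_freqs}} spectrum with \eqn{A_e} equal to
#'   \code{ae} (to numerical precision).
#' @export
spectrum_with_ae <- function(k, ae, locus = NULL) {
  if (ae <= 1 || ae > k) stop_mh("need 1 < ae <= k")
  # quadratic in a: (k/(k-1)) a^2 - (2/(k-1)) a + 1/(k-1) - 1/ae = 0
  A <- k / (k - 1); B <- -2 / (k - 1); C <- 1 / (k - 1) - 1 / ae
  disc <- B^2 - 4 * A * C
  a <- (-B + sqrt(max(disc, 0))) / (2 * A)
  mh_freqs(c(a, rep((1 - a) / (k - 1), k - 1)),
           alleles = haplotype_labels(k), locus = locus)
}

#' Default 20-locus synthetic frequency panel
#'
#' A deterministic frequency database whose Ae profile mirrors the bundled
#' reference panel (\code{\link{mh_reference_panel}}): 15 loci with
#' \eqn{3 \le A_e < 4}, 4 loci with \eqn{A_e \ge 4} and one locus with
#' \eqn{A_e < 3}, so panel-level computations exercise the same Ae-floor path
#' as the reference panel. Allele counts are one above the Ae ceiling, giving
#' realistic skewed spectra.
#'
#' @return named list of 20 \code{\link{mh_freqs}} keyed by the reference
#'   panel locus ids.
#' @export
default_panel_freqs <- function() {
  ref <- mh_reference_panel()
  out <- lapply(seq_len(nrow(ref)), function(i) {
    ae <- ref$ae[i]
    spectrum_with_ae(k = ceiling(ae) + 1L, ae = ae, locus = ref$id[i])
  })
  names(out) <- ref$id
  out
}
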