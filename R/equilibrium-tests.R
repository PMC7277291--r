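#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Multi-allelic exact test in the Guo--Thompson style: the \eqn{2n} observed
#' alleles are repeatedly shuffled into \eqn{n} unordered pairs, and each
#' permuted genotype table is compared with the observed one by its
#' conditional probability given the allele counts. The p-value uses the
#' add-one permutation estimator
#' \eqn{p = (\#\{T_{perm} \le T_{obs}\} + 1)/(B + 1)}, so it can never fall
#' below \eqn{1/(B+1)}.
#'
#' @param column genotype column of canonical \code{"A/B"} strings (missing
#'   genotypes excluded).
#' @param n_permutations number of Monte-Carlo shuffles \eqn{B} (default
#'   1e5).
#' @param seed integer seed (logged in the result).
#' @return list of class \code{mh_hwe_test}: \code{p_value},
#'   \code{n_permutations}, \code{seed}, \code{statistic} (observed
#'   log-conditional-probability up to a constant), \code{n}, \code{k}.
#'   A locus with fewer than 2 distinct alleles is untestable: p = 1 with a
#'   warning.
#' @export
hwe_exact_test <- function(column, n_permutations = 1e5, seed = 1) {
  g <- column[!is_missing_geno(column)]
  if (length(g) == 0L) stop_mh("no non-missing genotypes")
  al <- split_geno(g)
  alleles <- sort(unique(c(al[, 1], al[, 2])))
  k <- length(alleles)
  res <- list(p_value = 1, n_permutations = as.integer(n_permutations),
              seed = as.integer(seed), statistic = NA_real_,
              n = length(g), k = k)
  class(res) <- "mh_hwe_test"
  if (k < 2L) {
    warning("monomorphic locus: HWE test undefined, p = 1", call. = FALSE)
    return(res)
  }
  if (n_permutations < 1e3) stop_mh("need at least 1e3 permutations")
  a1 <- match(al[, 1], alleles) - 1L
  a2 <- match(al[, 2], alleles) - 1L
  set.seed(seed)
  n_le <- hwe_perm_count(a1, a2, k, as.integer(n_permutations))
  res$p_value <- (n_le + 1) / (n_permutations + 1)
  # observed statistic: h*log2 - sum lgamma(n_G + 1)
  het <- al[, 1] != al[, 2]
  res$statistic <- sum(het) * log(2) - sum(lgamma(table(g) + 1))
  res
}

#' @export
print.mh_hwe_test <- function(x, ...) {
  cat(sprintf("HWE Monte-Carlo exact test: p = %.5g (B = %d, n = %d, k = %d)\n",
              x$p_value, x$n_permutations, x$n, x$k))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests, \eqn{\ge 1}.
#' @return \code{alpha / n_tests} (e.g. 0.05/20 = 0.0025 for a 20-locus HWE
#'   scan).
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop_mh("alpha must lie in (0, 1)")
  if (n_tests < 1) stop_mh("n_tests must be >= 1")
  alpha / n_tests
}

# Two-locus haplotype-frequency EM on unordered genotype pairs.
# ia/ib: n x 2 integer allele matrices for locus 1 / locus 2.
# Returns k1 x k2 haplotype frequency matrix.
em_two_locus <- function(ia, ib, k1, k2, tol = 1e-8, max_iter = 200) {
  n <- nrow(ia)
  i11 <- (ib[, 1] - 1L) * k1 + ia[, 1]
  i22 <- (ib[, 2] - 1L) * k1 + ia[, 2]
  i12 <- (ib[, 2] - 1L) * k1 + ia[, 1]
  i21 <- (ib[, 1] - 1L) * k1 + ia[, 2]
  K <- k1 * k2
  h <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w1 <- h[i11] * h[i22]
    w2 <- h[i12] * h[i21]
    tot <- w1 + w2
    r <- ifelse(tot > 0, w1 / tot, 0.5)
    grp <- c(i11, i22, i12, i21)
    wts <- c(r, r, 1 - r, 1 - r)
    agg <- rowsum(wts, grp)
    h <- numeric(K)
    h[as.integer(rownames(agg))] <- agg
    h <- h / (2 * n)
    ll <- sum(log(pmax(tot, 1e-300)))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  matrix(h, nrow = k1, ncol = k2)
}

#' Multi-allelic r-squared from a joint haplotype distribution
#'
#' For loci with marginal allele frequencies \eqn{p_i}, \eqn{q_j} and joint
#' haplotype frequencies \eqn{h_{ij}}, the pairwise disequilibria are
#' \eqn{D_{ij} = h_{ij} - p_i q_j} and
#' \eqn{r^2_{ij} = D_{ij}^2 / (p_i(1-p_i)\,q_j(1-q_j))}. The overall summary
#' is the frequency-weighted average \eqn{r^2 = \sum_{ij} p_i q_j r^2_{ij}}
#' (the convention of common haplotype-analysis web tools). Allele pairs with
#' a fixed allele (zero denominator) are skipped and the weights renormalised
#' over the remaining pairs. Invariant to allele relabelling and to
#' transposition.
#'
#' @param joint numeric matrix of joint haplotype frequencies (rows = alleles
#'   of locus 1, columns = locus 2), entries summing to 1.
#' @return overall \eqn{r^2 \in [0, 1]}, with the \eqn{D_{ij}} table attached
#'   as attribute \code{"D"}.
#' @export
multiallelic_r2 <- function(joint) {
  if (abs(sum(joint) - 1) > 1e-6) stop_mh("joint frequencies must sum to 1")
  p <- rowSums(joint); q <- colSums(joint)
  D <- joint - outer(p, q)
  den <- outer(p * (1 - p), q * (1 - q))
  w <- outer(p, q)
  ok <- den > 0
  if (!any(ok)) return(structure(0, D = D))
  r2 <- sum(w[ok] * D[ok]^2 / den[ok]) / sum(w[ok])
  structure(r2, D = D)
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' The observed statistic is the chi-square over the two-locus joint
#' haplotype table, \eqn{\chi^2 = 2n \sum_{ij} D_{ij}^2/(p_i q_j)}, with
#' haplotype frequencies estimated by EM when phase is unavailable (double
#' heterozygotes are phase-ambiguous). The null distribution is generated by
#' permuting one locus's genotypes across samples, which preserves both
#' single-locus genotype distributions while destroying inter-locus
#' association; the p-value is the add-one permutation fraction.
#'
#' @param column1,column2 genotype columns over the same samples (canonical
#'   \code{"A/B"} strings; samples missing at either locus are dropped).
#' @param n_permutations number of permutations \eqn{B} (default 1e4).
#' @param seed integer seed (logged).
#' @return list of class \code{mh_ld_test}: \code{p_value}, \code{r2},
#'   \code{D} (pairwise disequilibrium table), \code{chisq},
#'   \code{n_permutations}, \code{seed}, \code{n}. Monomorphic loci give
#'   p = 1, r2 = 0.
#' @export
ld_permutation_test <- function(column1, column2, n_permutations = 1e4,
                                seed = 1) {
  keep <- !is_missing_geno(column1) & !is_missing_geno(column2)
  g1 <- column1[keep]; g2 <- column2[keep]
  n <- length(g1)
  if (n == 0L) stop_mh("no samples typed at both loci")
  al1 <- split_geno(g1); al2 <- split_geno(g2)
  alleles1 <- sort(unique(c(al1[, 1], al1[, 2])))
  alleles2 <- sort(unique(c(al2[, 1], al2[, 2])))
  k1 <- length(alleles1); k2 <- length(alleles2)
  res <- list(p_value = 1, r2 = 0, D = NULL, chisq = 0,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed), n = n)
  class(res) <- "mh_ld_test"
  if (k1 < 2L || k2 < 2L) return(res)
  if (n_permutations < 1e3) stop_mh("need at least 1e3 permutations")
  ia <- matrix(match(al1, alleles1), ncol = 2L)
  ib <- matrix(match(al2, alleles2), ncol = 2L)

  chisq_of <- function(ib_perm) {
    h <- em_two_locus(ia, ib_perm, k1, k2)
    p <- rowSums(h); q <- colSums(h)
    e <- outer(p, q)
    ok <- e > 0
    2 * n * sum((h[ok] - e[ok])^2 / e[ok])
  }

  h_obs <- em_two_locus(ia, ib, k1, k2)
  dimnames(h_obs) <- list(alleles1, alleles2)
  p <- rowSums(h_obs); q <- colSums(h_obs)
  e <- outer(p, q); ok <- e > 0
  chisq_obs <- 2 * n * sum((h_obs[ok] - e[ok])^2 / e[ok])

  set.seed(seed)
  n_ge <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    if (chisq_of(ib[perm, , drop = FALSE]) >= chisq_obs - 1e-12)
      n_ge <- n_ge + 1L
  }
  r2 <- multiallelic_r2(h_obs)
  res$p_value <- (n_ge + 1) / (n_permutations + 1)
  res$r2 <- as.numeric(r2)
  res$D <- attr(r2, "D")
  res$chisq <- chisq_obs
  res
}

#' @export
print.mh_ld_test <- function(x, ...) {
  cat(sprintf("LD permutation test: chisq = %.3f, p = %.5g, r2 = %.4f (B = %d, n = %d)\n",
              x$chisq, x$p_value, x$r2, x$n_permutations, x$n))
  invisible(x)
}
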