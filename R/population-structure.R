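#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Standard haplotype EM: the E-step distributes each phase-ambiguous
#' multi-SNP genotype over its consistent haplotype pairs in proportion to
#' the current frequency products; the M-step re-estimates frequencies from
#' the expected haplotype counts. Iteration stops when the log-likelihood
#' improves by less than \code{tol}; the log-likelihood is nondecreasing
#' across iterations. Multiple random restarts guard against local optima,
#' with deterministic best-likelihood selection under a fixed seed.
#'
#' This estimator is the package's desk-scale substitute for Bayesian phasing
#' tools; all outputs are labelled \code{method = "haplotype-EM"}.
#'
#' @param snp_genos character matrix (samples x SNPs) of per-SNP unordered
#'   genotypes \code{"x/y"} (as from \code{\link{unphased_from_haplotypes}});
#'   rows with any \code{NA} are dropped. At most 6 SNPs.
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter iteration cap per restart (default 500).
#' @param n_restarts random restarts beyond the uniform start (default 3).
#' @param seed integer seed for restart initialisation.
#' @param locus optional locus id.
#' @return list of class \code{mh_em}: \code{freqs} (an
#'   \code{\link{mh_freqs}} over the haplotypes with nonzero support),
#'   \code{loglik_trace}, \code{iterations}, \code{converged}, \code{method}.
#' @export
em_haplotype_freqs <- function(snp_genos, tol = 1e-8, max_iter = 500,
                               n_restarts = 3, seed = 1, locus = NULL) {
  if (is.null(dim(snp_genos))) snp_genos <- matrix(snp_genos, ncol = 1L)
  keep <- !apply(snp_genos, 1L, anyNA)
  snp_genos <- snp_genos[keep, , drop = FALSE]
  n <- nrow(snp_genos); S <- ncol(snp_genos)
  if (n < 1L) stop_mh("no complete samples")
  if (S > 6L) stop_mh("haplotype EM limited to 6 SNPs per locus")

  # enumerate consistent (unordered) haplotype pairs per sample
  dict <- new.env(parent = emptyenv())
  hap_id <- function(h) {
    id <- get0(h, envir = dict)
    if (is.null(id)) {
      id <- length(ls(dict)) + 1L
      assign(h, id, envir = dict)
    }
    id
  }
  pairs <- vector("list", n)
  for (s in seq_len(n)) {
    gs <- split_geno(snp_genos[s, ])
    het <- which(gs[, 1] != gs[, 2])
    if (length(het) == 0L) {
      h <- paste(gs[, 1], collapse = "")
      pairs[[s]] <- cbind(hap_id(h), hap_id(h))
    } else {
      # fix the first het SNP's orientation; free choice at the others
      free <- het[-1]
      m <- max(1L, 2L^length(free))
      pm <- matrix(0L, nrow = m, ncol = 2L)
      for (cfg in seq_len(m) - 1L) {
        hapA <- gs[, 1]; hapB <- gs[, 2]
        if (length(free)) {
          flip <- free[bitwAnd(cfg, 2L^(seq_along(free) - 1L)) > 0L]
          hapA[flip] <- gs[flip, 2]; hapB[flip] <- gs[flip, 1]
        }
        pm[cfg + 1L, ] <- c(hap_id(paste(hapA, collapse = "")),
                            hap_id(paste(hapB, collapse = "")))
      }
      pairs[[s]] <- pm
    }
  }
  haps <- ls(dict)
  D <- length(haps)
  code <- vapply(haps, function(h) get(h, envir = dict), integer(1))
  hap_names <- character(D); hap_names[code] <- haps

  run_em <- function(f0) {
    f <- f0
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      counts <- numeric(D)
      ll <- 0
      for (s in seq_len(n)) {
        pm <- pairs[[s]]
        w <- f[pm[, 1]] * f[pm[, 2]]
        tw <- sum(w)
        if (tw <= 0) { w <- rep(1 / nrow(pm), nrow(pm)); tw <- 1 } else w <- w / tw
        ll <- ll + log(max(tw, 1e-300))
        counts[pm[, 1]] <- counts[pm[, 1]] + w
        counts[pm[, 2]] <- counts[pm[, 2]] + w
      }
      f <- counts / (2 * n)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    list(f = f, trace = trace, iterations = it, converged = converged)
  }

  best <- run_em(rep(1 / D, D))
  if (n_restarts > 0 && D > 1L) {
    for (r in seq_len(n_restarts)) {
      set.seed(derive_seed(seed, r))
      cand <- run_em(as.numeric(rdirichlet(1, rep(1, D))))
      if (max(cand$trace) > max(best$trace) + 1e-9) best <- cand
    }
  }
  nz <- best$f > 1e-12
  structure(list(
    freqs = mh_freqs(best$f[nz] / sum(best$f[nz]),
                     alleles = hap_names[nz], locus = locus),
    loglik_trace = best$trace,
    iterations = best$iterations,
    converged = best$converged,
    method = "haplotype-EM"), class = "mh_em")
}

#' @export
print.mh_em <- function(x, ...) {
  cat(sprintf("<haplotype-EM> %d haplotypes, loglik %.4f, %d iterations%s\n",
              length(x$freqs), max(x$loglik_trace), x$iterations,
              if (x$converged) "" else " (not converged)"))
  print(x$freqs)
  invisible(x)
}

# Per-population per-locus spectra + sample sizes from either a frequency DB
# list or a genotype table.
pop_spectra <- function(pop) {
  if (inherits(pop, "mh_genotypes") || (is.data.frame(pop) && "sample" %in% names(pop))) {
    loci <- locus_cols(pop)
    out <- lapply(loci, function(loc) {
      g <- pop[[loc]][!is_missing_geno(pop[[loc]])]
      al <- split_geno(g)
      cnt <- table(c(al[, 1], al[, 2]))
      mh_freqs(as.numeric(cnt) / sum(cnt), alleles = names(cnt),
               locus = loc, n_samples = length(g))
    })
    names(out) <- loci
    out
  } else pop
}

#' Pairwise Fst between populations
#'
#' Hudson-style estimator on haplotype frequencies. Per locus,
#' \eqn{H_B = 1 - \sum_i p_{1i} p_{2i}} is the between-population
#' heterozygosity and \eqn{H_W} the average within-population heterozygosity,
#' corrected for sample size (\eqn{2n/(2n-1)} factor) when genotype tables
#' are supplied; the multi-locus estimate is the ratio of averages
#' \eqn{\hat F_{st} = 1 - \sum_\ell H_W^{(\ell)} / \sum_\ell H_B^{(\ell)}}.
#' Negative estimates are truncated to 0 in the returned distance matrix (for
#' tree building); the raw estimates are attached as attribute \code{"raw"}.
#'
#' @param pops named list of populations, each either a named list of
#'   \code{\link{mh_freqs}} per locus or an \code{mh_genotypes} table.
#' @return symmetric nonnegative matrix of class \code{mh_dist} with zero
#'   diagonal, attributes \code{"raw"} (untruncated) and \code{"estimator"}.
#' @export
pairwise_fst <- function(pops) {
  if (length(pops) < 2L) stop_mh("need at least 2 populations")
  if (is.null(names(pops))) names(pops) <- paste0("pop", seq_along(pops))
  spectra <- lapply(pops, pop_spectra)
  labs <- names(pops)
  m <- matrix(0, length(pops), length(pops), dimnames = list(labs, labs))
  raw <- m
  for (i in seq_len(length(pops) - 1L)) for (j in seq(i + 1L, length(pops))) {
    loci <- intersect(names(spectra[[i]]), names(spectra[[j]]))
    if (length(loci) == 0L) stop_mh("populations ", labs[i], " and ", labs[j],
                                    " share no loci")
    hb_sum <- 0; hw_sum <- 0
    for (loc in loci) {
      f1 <- spectra[[i]][[loc]]; f2 <- spectra[[j]][[loc]]
      al <- union(names(f1), names(f2))
      p1 <- setNames(numeric(length(al)), al); p1[names(f1)] <- as.numeric(f1)
      p2 <- setNames(numeric(length(al)), al); p2[names(f2)] <- as.numeric(f2)
      hb <- 1 - sum(p1 * p2)
      corr <- function(f) {
        ns <- attr(f, "n_samples")
        h <- 1 - sum(as.numeric(f)^2)
        if (!is.null(ns) && ns > 0) h * 2 * ns / (2 * ns - 1) else h
      }
      hw <- (corr(f1) + corr(f2)) / 2
      hb_sum <- hb_sum + hb; hw_sum <- hw_sum + hw
    }
    fst <- if (hb_sum > 0) 1 - hw_sum / hb_sum else 0
    raw[i, j] <- raw[j, i] <- fst
    m[i, j] <- m[j, i] <- max(fst, 0)
  }
  structure(m, raw = raw, estimator = "Hudson-style, ratio of averages",
            class = c("mh_dist", "matrix", "array"))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou--Nei neighbour joining (via \pkg{ape}) over a symmetric,
#' zero-diagonal, nonnegative distance matrix such as pairwise Fst. For an
#' additive (tree-derived) matrix the generating topology and branch lengths
#' are recovered exactly. Two taxa produce the trivial split with each branch
#' carrying half the distance.
#'
#' @param distances symmetric numeric matrix with labelled rows/columns (e.g.
#'   from \code{\link{pairwise_fst}}).
#' @return an unrooted \code{phylo} tree; serialise with
#'   \code{\link{write_newick}}.
#' @export
nj_tree <- function(distances) {
  d <- unclass(distances)
  attr(d, "raw") <- NULL; attr(d, "estimator") <- NULL
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_mh("distances must be square")
  if (max(abs(d - t(d))) > 1e-9) stop_mh("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop_mh("distance matrix diagonal must be zero")
  if (any(d < 0)) stop_mh("distances must be nonnegative")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("pop", seq_len(nrow(d)))
  if (nrow(d) == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), ncol = 2, byrow = TRUE),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  if (nrow(d) < 2L) stop_mh("need at least 2 taxa")
  ape::nj(stats::as.dist(d))
}
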