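# Shared fixtures built in code.

tri_freqs <- function(locus = "L1") {
  mh_freqs(c(0.5, 0.3, 0.2), alleles = c("AA", "AC", "CA"), locus = locus)
}

# Small multi-locus frequency database with varied allele counts.
small_freq_db <- function() {
  list(
    L1 = tri_freqs("L1"),
    L2 = mh_freqs(c(0.4, 0.3, 0.2, 0.1), alleles = c("AA", "AC", "CA", "CC"),
                  locus = "L2"),
    L3 = mh_freqs(c(0.6, 0.4), alleles = c("G", "T"), locus = "L3"))
}

# A minimal variants row in the read_vcf_candidates layout.
make_var <- function(chrom, pos, freqs, id = sprintf("rs%d", pos)) {
  stopifnot(!is.null(names(freqs)))
  v <- data.frame(chrom = as.character(chrom), pos = pos, id = id,
                  ref = names(freqs)[1],
                  alt = paste(names(freqs)[-1], collapse = ","),
                  n_alleles = length(freqs),
                  tri_allelic = length(freqs) >= 3L,
                  stringsAsFactors = FALSE)
  v$freqs <- list(freqs)
  v
}

# Brute-force likelihood-ratio oracle for duo paternity indices: enumerates
# parental transmissions (prob 1/2 each, optional single-step uniform
# mutation) and population draws for the untransmitted allele.
duo_pi_oracle <- function(parent, child, p, mu = 0) {
  alleles <- names(p)
  k <- length(alleles)
  pg <- strsplit(parent, "/")[[1]]
  cg <- sort(strsplit(child, "/")[[1]])
  num <- 0
  for (t in pg) {                       # transmitted parental origin
    for (x in alleles) {                # allele actually passed on
      px <- if (x == t) 1 - mu else if (mu > 0) mu / (k - 1) else 0
      if (px == 0) next
      for (o in alleles) {              # untransmitted, from the population
        if (identical(sort(c(x, o)), cg))
          num <- num + 0.5 * px * p[[o]]
      }
    }
  }
  den <- if (cg[1] == cg[2]) p[[cg[1]]]^2 else 2 * p[[cg[1]]] * p[[cg[2]]]
  num / den
}
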