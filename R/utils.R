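# Internal helpers shared across modules.

# Derive a reproducible substream seed from a base seed; keeps results stable
# when independent operations each consume their own stream. Stays < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 9973 * as.double(i)) %% 2147483629)
}

# Canonical unordered genotype string "A/B" with A <= B lexicographically.
geno_string <- function(a1, a2) {
  swap <- a2 < a1
  lo <- ifelse(swap, a2, a1)
  hi <- ifelse(swap, a1, a2)
  paste0(lo, "/", hi)
}

MISSING_GENO <- "./."

# Split "A/B" genotype strings into a 2-column character matrix (NA for missing).
split_geno <- function(g) {
  g[is.na(g) | g == MISSING_GENO] <- NA_character_
  parts <- strsplit(g, "/", fixed = TRUE)
  a1 <- vapply(parts, function(p) if (length(p) == 2L) p[[1L]] else NA_character_, character(1))
  a2 <- vapply(parts, function(p) if (length(p) == 2L) p[[2L]] else NA_character_, character(1))
  cbind(a1, a2)
}

is_missing_geno <- function(g) is.na(g) | g == MISSING_GENO

# Locus columns of a genotype table (everything except the sample id column).
locus_cols <- function(tab) setdiff(names(tab), "sample")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mh <- function(...) stop(..., call. = FALSE)

# Dirichlet draw (rows = draws). Uses the gamma construction.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(x)
  # guard against all-zero rows at tiny concentrations
  zero <- sw == 0
  if (any(zero)) {
    x[zero, ] <- matrix(rep(1 / k, k), nrow = sum(zero), ncol = k, byrow = TRUE)
    sw[zero] <- 1
  }
  x / sw
}
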