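test_that("Dirichlet spectra are seeded, symmetric on average, and flatten at high concentration", {
  f1 <- sample_allele_freqs(4, seed = 42)
  f2 <- sample_allele_freqs(4, seed = 42)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_error(sample_allele_freqs(1), "2 alleles")

  flat <- sample_allele_freqs(5, concentration = 1e6, seed = 1)
  expect_equal(as.numeric(flat), rep(0.2, 5), tolerance = 1e-2)

  # law of large numbers over seeds: mean component frequency is 1/3
  draws <- vapply(1:2000, function(s)
    as.numeric(sample_allele_freqs(3, seed = s)), numeric(3))
  se <- sqrt(1 / 18 / 2000)  # Dirichlet(1,1,1) component variance = 1/18
  expect_true(all(abs(rowMeans(draws) - 1 / 3) < 3 * se))
})

test_that("HWE genotype simulation matches Hardy-Weinberg expectations", {
  mono <- mh_freqs(1, alleles = "AC")
  expect_true(all(hwe_genotypes(mono, 20, seed = 1) == "AC/AC"))

  eq3 <- mh_freqs(rep(1 / 3, 3), alleles = c("AA", "AC", "CA"))
  g <- hwe_genotypes(eq3, 20000, seed = 3)
  se <- sqrt((2 / 3) * (1 / 3) / 20000)
  expect_lt(abs(observed_heterozygosity(g) - 2 / 3), 3 * se)

  expect_identical(hwe_genotypes(eq3, 100, seed = 5),
                   hwe_genotypes(eq3, 100, seed = 5))

  # genotype frequencies converge to p_i^2 and 2 p_i p_j
  f <- tri_freqs()
  g2 <- hwe_genotypes(f, 50000, seed = 9)
  counts <- table(g2)
  p <- as.numeric(f); names(p) <- names(f)
  expected <- c("AA/AA" = p[["AA"]]^2, "AC/AC" = p[["AC"]]^2,
                "CA/CA" = p[["CA"]]^2,
                "AA/AC" = 2 * p[["AA"]] * p[["AC"]],
                "AA/CA" = 2 * p[["AA"]] * p[["CA"]],
                "AC/CA" = 2 * p[["AC"]] * p[["CA"]])
  chi <- suppressWarnings(stats::chisq.test(
    as.numeric(counts[names(expected)]), p = unname(expected)))
  expect_gt(chi$p.value, 0.001)
})

test_that("duo simulation is Mendelian at mutation rate 0 and deterministic mutation at rate 1", {
  db <- small_freq_db()
  duos <- simulate_duos(db, 500, seed = 7)
  for (loc in names(db))
    expect_true(all(mendelian_check(duos$parent[[loc]], duos$child[[loc]])))

  # at rate 1 with 2 alleles the transmitted allele is always flipped:
  # a homozygous G/G parent can never pass G, so the child always carries T
  bi <- list(L3 = small_freq_db()$L3)
  m <- simulate_duos(bi, 400, seed = 8, mutation_rate = 1)
  hom_g <- m$parent$L3 == "G/G"
  expect_gt(sum(hom_g), 10)
  expect_true(all(grepl("T", m$child$L3[hom_g])))
})

test_that("apparent exclusion rate under mutation matches enumeration", {
  f <- tri_freqs()
  p <- setNames(as.numeric(f), names(f))
  alleles <- names(p)
  mu <- 0.05
  # enumeration: P(child shares no allele with parent) under the generative
  # model — parent HWE, transmitted allele mutated at rate mu, other allele
  # from the population
  p_excl <- 0
  for (a1 in alleles) for (a2 in alleles) {
    pg <- p[[a1]] * p[[a2]]
    for (t in c(a1, a2)) for (x in alleles) {
      px <- if (x == t) 1 - mu else mu / (length(alleles) - 1)
      for (o in alleles) {
        child <- c(x, o)
        if (!any(child %in% c(a1, a2)))
          p_excl <- p_excl + pg * 0.5 * px * p[[o]]
      }
    }
  }
  duos <- simulate_duos(list(L1 = f), 4000, seed = 21, mutation_rate = mu)
  obs <- mean(!mendelian_check(duos$parent$L1, duos$child$L1))
  se <- sqrt(p_excl * (1 - p_excl) / 4000)
  expect_lt(abs(obs - p_excl), 3.5 * se)
})

test_that("Balding-Nichols drift approaches the ancestral spectrum as theta -> 0", {
  anc <- mh_freqs(c(0.5, 0.3, 0.2), alleles = c("A", "C", "G"))
  pops <- bn_population_freqs(anc, theta_drift = 1e-5, n_pops = 3, seed = 2)
  for (f in pops)
    expect_lt(max(abs(as.numeric(f) - as.numeric(anc))), 0.05)
  expect_identical(
    as.numeric(bn_population_freqs(anc, 0.05, 2, seed = 4)[[1]]),
    as.numeric(bn_population_freqs(anc, 0.05, 2, seed = 4)[[1]]))
  expect_error(bn_population_freqs(anc, 0, 2), "theta_drift")

  anc0 <- mh_freqs(c(0.5, 0.5, 0), alleles = c("A", "C", "G"))
  expect_warning(bn_population_freqs(anc0, 0.05, 2, seed = 1), "frequency 0")
})

test_that("mixture profiles reproduce the >=3-distinct-allele probabilities", {
  bi <- mh_freqs(c(0.7, 0.3), alleles = c("A", "C"))
  expect_true(all(lengths(simulate_mixture_profiles(bi, 2000, seed = 1)) <= 2))

  for (k in 3:4) {
    eq <- mh_freqs(rep(1 / k, k), alleles = sprintf("H%d", 1:k))
    prof <- simulate_mixture_profiles(eq, 50000, seed = k)
    frac <- mean(lengths(prof) >= 3)
    truth <- mixture_detection_probability_equal(k)  # 0.4444 / 0.65625
    se <- sqrt(truth * (1 - truth) / 50000)
    expect_lt(abs(frac - truth), 3 * se)
  }
})

test_that("phase stripping keeps per-SNP genotypes and exposes the classic ambiguity", {
  # homozygous haplotype pair: phase trivially recoverable
  un <- unphased_from_haplotypes(c("AC/AC"))
  expect_identical(un[1, ], c(snp1 = "A/A", snp2 = "C/C"))
  # double heterozygote: two consistent phase configurations
  un2 <- unphased_from_haplotypes(c("AC/CA"))
  expect_identical(un2[1, ], c(snp1 = "A/C", snp2 = "A/C"))
  em <- em_haplotype_freqs(rbind(un2, un2), n_restarts = 0)
  # both configurations are consistent: AC/CA and AA/CC explain the data
  expect_true(all(names(em$freqs) %in% c("AC", "CA", "AA", "CC")))
})

test_that("prescribed-Ae spectra hit their target and the default panel mirrors the reference Ae profile", {
  for (ae in c(2.8, 3.5, 4.9)) {
    f <- spectrum_with_ae(k = ceiling(ae) + 1, ae = ae)
    expect_equal(effective_num_alleles(f), ae, tolerance = 1e-9)
  }
  db <- default_panel_freqs()
  expect_length(db, 20L)
  ae <- vapply(db, effective_num_alleles, numeric(1))
  fl <- table(factor(floor(ae), levels = 2:4))
  expect_identical(as.integer(fl), c(1L, 15L, 4L))
})
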