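test_that("locus names follow the mh nomenclature", {
  expect_identical(make_locus_name(2, "zha", 12), "mh02zha012")
  expect_identical(make_locus_name(11, "zha", 6, "a"), "mh11zha006a")
  expect_error(make_locus_name(23, "zha", 1), "1-22")
  expect_error(make_locus_name(0, "zha", 1), "1-22")
  expect_error(make_locus_name(4, "zha", 7, "A"), "suffix")

  ref <- mh_reference_panel()
  expect_true(all(is_valid_locus_id(ref$id)))
  # mutated forms: missing zero padding, uppercase suffix, short serial
  expect_false(is_valid_locus_id("mh2zha012"))
  expect_false(is_valid_locus_id("mh11zha006A"))
  expect_false(is_valid_locus_id("mh02zha12"))
  expect_false(is_valid_locus_id("mh23zha001"))
  expect_false(is_valid_locus_id("MH02zha012"))
})

test_that("panel parsing recomputes spans (1-based inclusive) and validates", {
  ref <- mh_reference_panel()
  panel <- mh_reference_panel(parameters = FALSE)
  expect_s3_class(panel, "mh_panel")
  expect_equal(nrow(panel), 20L)
  # every recomputed span equals the printed length column, 20/20
  expect_identical(panel$span_bp, ref$length_bp)
  expect_equal(panel$span_bp[panel$id == "mh14zha003"], 8)
  expect_equal(panel$span_bp[panel$id == "mh02zha012"], 105)
  expect_identical(attr(panel, "build"), "GRCh37")
  # one locus (mh22zha008) has no tri-allelic member
  expect_equal(sum(is.na(panel$tri_allelic_snp)), 1L)

  bad <- data.frame(id = "mh01abc001", chromosome = 1, start = 100, end = 150,
                    snp_ids = "rs1", stringsAsFactors = FALSE)
  expect_error(parse_panel_definition(bad), "at least 2 SNPs")
  bad2 <- data.frame(id = "mh01abc001", chromosome = 1, start = 100, end = 150,
                     snp_ids = "rs1;rs2", length_bp = 60)
  expect_error(parse_panel_definition(bad2), "disagrees")
  bad3 <- data.frame(id = "mh01abc001", chromosome = 23, start = 100, end = 150,
                     snp_ids = "rs1;rs2")
  expect_error(parse_panel_definition(bad3))
  bad4 <- data.frame(id = "mh01abc001", chromosome = 1, start = 150, end = 100,
                     snp_ids = "rs1;rs2")
  expect_error(parse_panel_definition(bad4), "increasing")
})

test_that("frequency tables round-trip and enforce the sum-to-one contract", {
  db <- small_freq_db()
  path <- withr::local_tempfile(fileext = ".csv")
  write_frequency_table(db, path)
  back <- read_frequency_table(path)
  expect_identical(names(back), names(db))
  for (loc in names(db)) {
    expect_identical(names(back[[loc]]), names(db[[loc]]))
    expect_equal(as.numeric(back[[loc]]), as.numeric(db[[loc]]), tolerance = 1e-9)
  }
  # renormalised when within 1e-6 of 1
  f <- mh_freqs(c(0.5, 0.5000004), alleles = c("A", "C"))
  expect_equal(sum(as.numeric(f)), 1, tolerance = 1e-15)
  # hard failures
  expect_error(mh_freqs(c(0.5, 0.6), alleles = c("A", "C")), "sum")
  expect_error(mh_freqs(c(-0.1, 1.1), alleles = c("A", "C")), "negative")
  expect_error(mh_freqs(c(0.5, 0.5), alleles = c("A", "A")), "duplicate")
  dup <- data.frame(locus = "L1", allele = c("A", "A"), frequency = c(0.5, 0.5))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, p2, row.names = FALSE)
  expect_error(read_frequency_table(p2), "duplicate")
})

test_that("genotype tables store unordered pairs canonically and round-trip", {
  tab <- data.frame(sample = c("s1", "s2", "s3"),
                    L1 = c("ACT/ATT", "ATT/ACT", "./."),
                    stringsAsFactors = FALSE)
  g <- as_mh_genotypes(tab)
  expect_identical(g$L1[1], g$L1[2])
  expect_identical(g$L1[3], "./.")

  db <- small_freq_db()
  sim <- simulate_genotype_table(db, n = 50, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(sim, path)
  back <- read_genotype_table(path)
  expect_identical(as.data.frame(back), as.data.frame(sim))

  panel <- data.frame(id = "L1", n_snps = 4)
  expect_error(as_mh_genotypes(tab[1:2, ], panel = panel), "inconsistent")
})

test_that("VCF candidate reader handles multi-allelic records and AF complements", {
  v <- rbind(make_var(1, 100, c(A = 0.1, C = 0.6, T = 0.3)),
             make_var(1, 200, c(G = 0.7, T = 0.3)))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, path)
  back <- read_vcf_candidates(path)
  expect_equal(nrow(back), 2L)
  # ALT "C,T" record is tri-allelic; REF frequency is the AF complement
  expect_true(back$tri_allelic[1])
  expect_false(back$tri_allelic[2])
  expect_equal(unname(back$freqs[[1]]), c(0.1, 0.6, 0.3), tolerance = 1e-6)
  expect_equal(sum(back$freqs[[1]]), 1, tolerance = 1e-6)

  # fixture generator output parses back with a known record count
  sv <- simulate_screening_variants()
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sv$variants, p2)
  parsed <- read_vcf_candidates(p2)
  expect_equal(nrow(parsed), nrow(sv$variants))
  expect_equal(sum(parsed$tri_allelic), sum(sv$variants$tri_allelic))

  # record with neither AF nor GT is rejected
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("1", "100", "rs1", "A", "C", ".", "PASS", "DP=10",
                     sep = "\t")),
             p3 <- withr::local_tempfile(fileext = ".vcf"))
  expect_error(read_vcf_candidates(p3), "AF")
})

test_that("newick export carries branch lengths and leaf labels", {
  two <- nj_tree(matrix(c(0, 0.2, 0.2, 0), 2, 2,
                        dimnames = list(c("A", "B"), c("A", "B"))))
  expect_identical(write_newick(two), "(A:0.1,B:0.1);")

  # equidistant 3 taxa: all terminal branches equal
  d3 <- matrix(0.4, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(d3) <- 0
  tr3 <- nj_tree(d3)
  expect_equal(length(unique(round(tr3$edge.length, 9))), 1L)
  expect_setequal(tr3$tip.label, LETTERS[1:3])

  # additive 4-taxon matrix: newick re-reads to the generating metric
  d4 <- matrix(c(0, 3, 9, 10,
                 3, 0, 10, 11,
                 9, 10, 0, 7,
                 10, 11, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- ape::read.tree(text = write_newick(nj_tree(d4)))
  expect_equal(max(abs(ape::cophenetic.phylo(tr4)[LETTERS[1:4], LETTERS[1:4]] - d4)),
               0, tolerance = 1e-9)
})
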