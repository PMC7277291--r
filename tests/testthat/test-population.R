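test_that("haplotype EM equals direct counting when phase is unambiguous", {
  # no double-heterozygotes: every sample has at most one het SNP
  col <- c(rep("AC/AC", 30), rep("AC/CC", 20), rep("CC/CC", 10))
  em <- em_haplotype_freqs(unphased_from_haplotypes(col), n_restarts = 0)
  direct <- table(unlist(strsplit(gsub("/", ",", col), ","))) / (2 * 60)
  expect_equal(as.numeric(em$freqs[names(direct)]), as.numeric(direct),
               tolerance = 1e-6)

  # forced two-haplotype configuration
  col2 <- c(rep("AC/AC", 50), rep("GT/GT", 50))
  em2 <- em_haplotype_freqs(unphased_from_haplotypes(col2), n_restarts = 0)
  expect_equal(sort(as.numeric(em2$freqs)), c(0.5, 0.5), tolerance = 1e-9)
  expect_setequal(names(em2$freqs), c("AC", "GT"))
})

test_that("haplotype EM recovers a known spectrum from phase-stripped data", {
  truth <- mh_freqs(c(0.4, 0.3, 0.2, 0.1),
                    alleles = c("AA", "AC", "CA", "CC"), locus = "L")
  col <- hwe_genotypes(truth, 500, seed = 71)
  em <- em_haplotype_freqs(unphased_from_haplotypes(col), seed = 2)
  expect_true(em$converged)
  # log-likelihood is nondecreasing across iterations
  expect_true(all(diff(em$loglik_trace) > -1e-8))
  for (h in names(truth)) {
    p <- as.numeric(truth[h])
    se <- sqrt(p * (1 - p) / (2 * 500))
    expect_lt(abs(as.numeric(em$freqs[h]) - p), 3 * se)
  }
  # deterministic under a fixed seed (multi-restart selection included)
  em2 <- em_haplotype_freqs(unphased_from_haplotypes(col), seed = 2)
  expect_identical(as.numeric(em$freqs), as.numeric(em2$freqs))
  expect_error(em_haplotype_freqs(matrix("A/A", 2, 7)), "6 SNPs")
})

test_that("pairwise Fst: degenerate cases and invariances", {
  f <- tri_freqs()
  same <- list(A = list(L1 = f), B = list(L1 = f))
  expect_equal(unname(pairwise_fst(same)["A", "B"]), 0, tolerance = 1e-12)

  fixA <- mh_freqs(c(1, 0), alleles = c("X", "Y"))
  fixB <- mh_freqs(c(0, 1), alleles = c("X", "Y"))
  fixed <- list(A = list(L1 = fixA), B = list(L1 = fixB))
  expect_equal(unname(pairwise_fst(fixed)["A", "B"]), 1)

  # symmetry, zero diagonal, invariance to population order
  db1 <- list(L1 = f, L2 = small_freq_db()$L2)
  db2 <- lapply(db1, function(x)
    mh_freqs(rev(as.numeric(x)), alleles = names(x)))
  db3 <- list(L1 = small_freq_db()$L2, L2 = f)
  m <- pairwise_fst(list(A = db1, B = db2, C = db3))
  expect_equal(m, t(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(diag(m) == 0))
  m2 <- pairwise_fst(list(C = db3, A = db1, B = db2))
  expect_equal(unname(m["A", "B"]), unname(m2["A", "B"]), tolerance = 1e-12)
  # truncation: raw value preserved
  expect_true(all(m >= 0))
  expect_true(is.matrix(attr(m, "raw")))
})

test_that("Fst estimates recover the generating Balding-Nichols theta", {
  anc_alleles <- c("AA", "AC", "CA", "CC")
  means <- vapply(1:10, function(rep) {
    db1 <- list(); db2 <- list()
    for (l in 1:100) {
      anc <- sample_allele_freqs(4, concentration = 2,
                                 seed = 90000 + rep * 1000 + l)
      ps <- bn_population_freqs(anc, theta_drift = 0.05, n_pops = 2,
                                seed = 50000 + rep * 1000 + l)
      loc <- paste0("L", l)
      db1[[loc]] <- ps[[1]]; db2[[loc]] <- ps[[2]]
    }
    unname(pairwise_fst(list(A = db1, B = db2))["A", "B"])
  }, numeric(1))
  expect_gt(mean(means), 0.04)
  expect_lt(mean(means), 0.06)
})

test_that("neighbour joining recovers additive trees and validates input", {
  # 3 taxa: branch lengths solve the three-point equations
  d3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  co <- ape::cophenetic.phylo(tr3)
  expect_equal(max(abs(co[rownames(d3), colnames(d3)] - d3)), 0,
               tolerance = 1e-9)

  # additive 4-taxon matrix from a known tree: exact recovery
  d4 <- matrix(c(0, 3, 9, 10,
                 3, 0, 10, 11,
                 9, 10, 0, 7,
                 10, 11, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- nj_tree(d4)
  co4 <- ape::cophenetic.phylo(tr4)
  expect_equal(max(abs(co4[LETTERS[1:4], LETTERS[1:4]] - d4)), 0,
               tolerance = 1e-9)
  # internal edge of length 5 separates {A,B} from {C,D}
  expect_true(any(abs(tr4$edge.length - 5) < 1e-9))

  # equidistant 5 taxa: all pairwise path lengths equal
  d5 <- matrix(0.3, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  diag(d5) <- 0
  co5 <- ape::cophenetic.phylo(nj_tree(d5))
  expect_equal(max(co5) - min(co5[co5 > 0]), 0, tolerance = 1e-9)

  bad <- d3; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  bad2 <- d3; diag(bad2) <- 1
  expect_error(nj_tree(bad2), "diagonal")
})

test_that("NJ separates two Balding-Nichols clusters of populations", {
  hits <- 0L
  n_rep <- 10L
  for (rep in seq_len(n_rep)) {
    pops <- vector("list", 6)
    for (l in 1:40) {
      anc <- sample_allele_freqs(4, concentration = 2, seed = 70000 + rep * 100 + l)
      centres <- bn_population_freqs(anc, theta_drift = 0.2, n_pops = 2,
                                     seed = 71000 + rep * 100 + l)
      loc <- paste0("L", l)
      for (cl in 1:2) {
        leaves <- bn_population_freqs(centres[[cl]], theta_drift = 0.01,
                                      n_pops = 3,
                                      seed = 72000 + rep * 100 + l * 2 + cl)
        for (i in 1:3) {
          idx <- (cl - 1) * 3 + i
          if (is.null(pops[[idx]])) pops[[idx]] <- list()
          pops[[idx]][[loc]] <- leaves[[i]]
        }
      }
    }
    names(pops) <- c(paste0("X", 1:3), paste0("Y", 1:3))
    tr <- nj_tree(pairwise_fst(pops))
    parts <- ape::prop.part(tr)
    tipsets <- lapply(parts, function(p) sort(tr$tip.label[p]))
    target <- list(sort(paste0("X", 1:3)), sort(paste0("Y", 1:3)))
    if (any(vapply(tipsets, function(ts)
      identical(ts, target[[1]]) || identical(ts, target[[2]]), logical(1))))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
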