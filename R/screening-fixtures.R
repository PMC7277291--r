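# Ground-truth screening fixtures: a deterministic variant table with planted
# candidate windows whose screening outcome is known by construction.

#' Simulate a variant table with planted screening candidates
#'
#' Builds clusters of 3 SNPs (span 121 bp) with allele-frequency spectra
#' chosen so each cluster has a known screening fate under the default
#' \code{\link{screening_params}}:
#' \describe{
#'   \item{pass}{tri-allelic SNP (0.5, 0.3, 0.2) plus two informative
#'     biallelic SNPs; product Ae about 10.}
#'   \item{no_tri}{three biallelic SNPs (Ae passes, tri-allelic check fails).}
#'   \item{low_ae}{skewed spectra with product Ae about 2.5 (< 3).}
#'   \item{dup_spectrum}{two SNPs with identical spectra; deduplication
#'     leaves 2 SNPs (< \code{min_snps}).}
#'   \item{spacing}{a passing-grade cluster planted 1 Mb from a higher-Ae
#'     pass cluster on the same chromosome, so the spacing rule drops it.}
#' }
#'
#' @param n_pass,n_no_tri,n_low_ae,n_dup,n_spacing cluster counts per type.
#' @return list: \code{variants} (data.frame accepted by
#'   \code{\link{write_vcf}} / \code{\link{candidate_windows}}) and
#'   \code{truth} (one row per planted cluster: \code{type}, \code{chrom},
#'   \code{start}, \code{expect_accept}).
#' @export
simulate_screening_variants <- function(n_pass = 8, n_no_tri = 4, n_low_ae = 4,
                                        n_dup = 2, n_spacing = 2) {
  if (n_spacing > n_pass) stop_mh("each spacing plant needs a pass cluster")
  spectra <- list(
    pass = list(c(A = 0.5, C = 0.3, T = 0.2), c(A = 0.6, G = 0.4),
                c(C = 0.55, T = 0.45)),
    no_tri = list(c(A = 0.6, G = 0.4), c(C = 0.55, T = 0.45),
                  c(A = 0.5, T = 0.5)),
    low_ae = list(c(A = 0.78, C = 0.11, T = 0.11), c(A = 0.88, G = 0.12),
                  c(C = 0.87, T = 0.13)),
    dup_spectrum = list(c(A = 0.5, C = 0.3, T = 0.2),
                        c(G = 0.5, T = 0.3, A = 0.2), c(A = 0.6, G = 0.4)),
    spacing = list(c(A = 0.5, C = 0.3, T = 0.2), c(A = 0.6, G = 0.4),
                   c(C = 0.7, T = 0.3)))
  types <- c(rep("pass", n_pass), rep("no_tri", n_no_tri),
             rep("low_ae", n_low_ae), rep("dup_spectrum", n_dup))
  chroms <- rep(1:22, length.out = length(types))
  starts <- 10e6 + 3e6 * (seq_along(types) - 1L)  # > 2 Mb apart everywhere
  # spacing plants sit 1 Mb after the first n_spacing pass clusters
  types <- c(types, rep("spacing", n_spacing))
  chroms <- c(chroms, chroms[seq_len(n_spacing)])
  starts <- c(starts, starts[seq_len(n_spacing)] + 1e6)

  rows <- list(); rs <- 0L
  for (i in seq_along(types)) {
    sp <- spectra[[types[i]]]
    for (s in seq_along(sp)) {
      f <- sp[[s]]
      rs <- rs + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(chroms[i]), pos = starts[i] + (s - 1L) * 60,
        id = sprintf("rs9%06d", rs), ref = names(f)[1],
        alt = paste(names(f)[-1], collapse = ","),
        n_alleles = length(f), tri_allelic = length(f) >= 3L,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$freqs <- list(f)
    }
  }
  variants <- do.call(rbind, rows)
  variants <- variants[order(suppressWarnings(as.integer(variants$chrom)),
                             variants$pos), , drop = FALSE]
  truth <- data.frame(type = types, chrom = as.character(chroms),
                      start = starts,
                      expect_accept = types == "pass",
                      stringsAsFactors = FALSE)
  list(variants = variants, truth = truth[order(as.integer(truth$chrom),
                                                truth$start), , drop = FALSE])
}
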