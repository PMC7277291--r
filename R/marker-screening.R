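#' Screening parameter set for microhaplotype candidate selection
#'
#' Defaults follow the published filter chain for tri-allelic microhaplotype
#' panels: per-SNP minor allele frequency above 0.10, window span under
#' 200 bp, at least 3 SNPs, one tri-allelic member required, effective number
#' of alleles above 3.0, an expected-heterozygosity criterion at 0.6, and
#' inter-locus spacing above 2.0 Mb on the same chromosome. For multi-allelic
#' SNPs the MAF is taken as the minimum allele frequency.
#'
#' The heterozygosity direction is configurable because the published
#' criterion is stated as "at most 0.6" while every reported locus has
#' heterozygosity above 0.6; the default keeps loci with heterozygosity at or
#' above the threshold (\code{het_direction = "ge"}), with the literal
#' reading available as \code{"le"}.
#'
#' @param maf_min minimum per-SNP minor allele frequency (exclusive bound).
#' @param span_max_bp maximum window span in bp (exclusive; 1-based inclusive
#'   span).
#' @param min_snps minimum SNPs per candidate.
#' @param require_triallelic must the window contain a SNP with 3+ alleles?
#' @param ae_min minimum effective number of alleles (exclusive).
#' @param het_threshold expected-heterozygosity threshold.
#' @param het_direction \code{"ge"} (keep He >= threshold, default) or
#'   \code{"le"}.
#' @param spacing_min_bp minimum distance between retained loci on the same
#'   chromosome (exclusive).
#' @param dedup_action \code{"remove_snp"} (default): drop redundant SNPs
#'   with spectra identical to an earlier SNP in the window, then re-check
#'   \code{min_snps}; \code{"reject"}: reject the whole candidate instead.
#' @return list of class \code{mh_screening_params}.
#' @export
screening_params <- function(maf_min = 0.10, span_max_bp = 200, min_snps = 3,
                             require_triallelic = TRUE, ae_min = 3.0,
                             het_threshold = 0.6, het_direction = c("ge", "le"),
                             spacing_min_bp = 2e6,
                             dedup_action = c("remove_snp", "reject")) {
  het_direction <- match.arg(het_direction)
  dedup_action <- match.arg(dedup_action)
  stopifnot(maf_min > 0, span_max_bp > 0, min_snps >= 2, ae_min > 0,
            het_threshold > 0, spacing_min_bp > 0)
  structure(list(maf_min = maf_min, span_max_bp = span_max_bp,
                 min_snps = min_snps, require_triallelic = require_triallelic,
                 ae_min = ae_min, het_threshold = het_threshold,
                 het_direction = het_direction,
                 spacing_min_bp = spacing_min_bp,
                 dedup_action = dedup_action),
            class = "mh_screening_params")
}

snp_maf <- function(freqs) min(freqs)
snp_ae <- function(freqs) 1 / sum(freqs^2)

#' Window sorted variants into microhaplotype candidates
#'
#' Builds maximal sliding windows of MAF-passing SNPs whose first-to-last
#' span (1-based inclusive) stays under \code{span_max_bp} and which contain
#' at least \code{min_snps} SNPs. Windows are enumerated per chromosome; a
#' window contained in a larger one is not reported.
#'
#' @param variants data.frame as returned by
#'   \code{\link{read_vcf_candidates}}, sorted by chromosome and position.
#' @param params an \code{\link{screening_params}} object.
#' @return list of candidate data.frames (rows = member SNPs), each with
#'   attributes \code{chrom}, \code{start}, \code{end}, \code{span_bp}.
#' @export
candidate_windows <- function(variants, params = screening_params()) {
  maf <- vapply(variants$freqs, snp_maf, numeric(1))
  v <- variants[maf > params$maf_min, , drop = FALSE]
  out <- list()
  for (chrom in unique(v$chrom)) {
    vc <- v[v$chrom == chrom, , drop = FALSE]
    if (is.unsorted(vc$pos)) stop_mh("variants unsorted on chromosome ", chrom)
    n <- nrow(vc)
    if (n < params$min_snps) next
    jmax <- integer(n)
    for (i in seq_len(n)) {
      j <- i
      while (j < n && vc$pos[j + 1L] - vc$pos[i] + 1 < params$span_max_bp)
        j <- j + 1L
      jmax[i] <- j
    }
    for (i in seq_len(n)) {
      if (i > 1L && jmax[i] <= jmax[i - 1L]) next  # contained in previous
      if (jmax[i] - i + 1L < params$min_snps) next
      w <- vc[i:jmax[i], , drop = FALSE]
      attr(w, "chrom") <- chrom
      attr(w, "start") <- w$pos[1L]
      attr(w, "end") <- w$pos[nrow(w)]
      attr(w, "span_bp") <- w$pos[nrow(w)] - w$pos[1L] + 1
      out[[length(out) + 1L]] <- w
    }
  }
  out
}

#' Apply the published filter chain to one candidate window
#'
#' Checks, in order and without short-circuiting (all failures accumulate):
#' per-SNP MAF above \code{maf_min}; redundant SNPs with spectra identical to
#' an earlier window member removed (identical spectra imply complete LD),
#' re-checking \code{min_snps}; a tri-allelic member present when required;
#' haplotype effective number of alleles above \code{ae_min}; expected
#' heterozygosity against the threshold. The candidate haplotype spectrum is
#' the product of per-SNP spectra (linkage-equilibrium assumption), so the
#' candidate Ae is the product of per-SNP Ae values, unless explicit
#' haplotype frequencies are supplied.
#'
#' @param candidate one candidate from \code{\link{candidate_windows}}.
#' @param params an \code{\link{screening_params}} object.
#' @param hap_freqs optional \code{\link{mh_freqs}} of observed haplotype
#'   frequencies for the window, used for the Ae/heterozygosity criteria in
#'   place of the product spectrum.
#' @return list: \code{pass} flag, \code{reasons} (character vector, empty on
#'   acceptance), \code{ae}, \code{he}, \code{n_snps} retained.
#' @export
apply_filters <- function(candidate, params = screening_params(),
                          hap_freqs = NULL) {
  reasons <- character(0)
  fr <- candidate$freqs
  if (is.null(fr) || any(vapply(fr, function(f) anyNA(f), logical(1))))
    return(list(pass = FALSE, reasons = "unevaluable: missing frequency data",
                ae = NA_real_, he = NA_real_, n_snps = nrow(candidate)))
  maf <- vapply(fr, snp_maf, numeric(1))
  if (any(maf <= params$maf_min))
    reasons <- c(reasons, sprintf("MAF <= %.2f at %s", params$maf_min,
                                  paste(candidate$id[maf <= params$maf_min],
                                        collapse = ",")))
  # criterion: SNPs in one window with identical allele-frequency spectra are
  # redundant (complete LD); drop later duplicates
  keys <- vapply(fr, function(f) paste(sprintf("%.9f", sort(f)), collapse = ","),
                 character(1))
  dup <- duplicated(keys)
  retained <- candidate
  if (any(dup)) {
    if (params$dedup_action == "reject") {
      reasons <- c(reasons, "redundant SNPs with identical frequency spectra")
    } else {
      retained <- candidate[!dup, , drop = FALSE]
      if (nrow(retained) < params$min_snps)
        reasons <- c(reasons, "insufficient SNPs after deduplication")
    }
  }
  if (params$require_triallelic && !any(retained$n_alleles >= 3L))
    reasons <- c(reasons, "no tri-allelic SNP")
  if (is.null(hap_freqs)) {
    ae <- prod(vapply(retained$freqs, snp_ae, numeric(1)))
  } else {
    ae <- effective_num_alleles(hap_freqs)
  }
  he <- 1 - 1 / ae
  if (ae <= params$ae_min)
    reasons <- c(reasons, sprintf("Ae %.3f not > %.1f", ae, params$ae_min))
  het_fail <- if (params$het_direction == "ge") he < params$het_threshold
              else he > params$het_threshold
  if (het_fail)
    reasons <- c(reasons, sprintf("heterozygosity %.3f fails %s %.2f criterion",
                                  he, if (params$het_direction == "ge") ">="
                                      else "<=", params$het_threshold))
  list(pass = length(reasons) == 0L, reasons = reasons, ae = ae, he = he,
       n_snps = nrow(retained))
}

#' Enforce minimum spacing between accepted loci
#'
#' Greedy retention in descending Ae order (ties broken by chromosome then
#' start position): a locus is dropped when it lies within
#' \code{spacing_min_bp} of an already-retained locus on the same chromosome.
#' Distance is the gap between windows (start of the later minus end of the
#' earlier).
#'
#' @param accepted data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{ae}.
#' @param spacing_min_bp minimum inter-locus distance (exclusive bound).
#' @return \code{accepted} with added logical column \code{retained}.
#' @export
enforce_spacing <- function(accepted, spacing_min_bp = 2e6) {
  if (nrow(accepted) == 0L) { accepted$retained <- logical(0); return(accepted) }
  ord <- order(-accepted$ae, accepted$chrom, accepted$start)
  retained <- logical(nrow(accepted))
  kept <- list()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (accepted$chrom[i] != accepted$chrom[k]) next
      gap <- max(accepted$start[i], accepted$start[k]) -
        min(accepted$end[i], accepted$end[k])
      if (gap <= spacing_min_bp) { ok <- FALSE; break }
    }
    if (ok) { retained[i] <- TRUE; kept[[length(kept) + 1L]] <- i }
  }
  accepted$retained <- retained
  accepted
}

#' Run the full candidate-screening pipeline
#'
#' Windows variants into candidates, applies the filter chain, enforces
#' inter-locus spacing, and assigns nomenclature ids to the accepted panel
#' (serial numbers per chromosome in position order). The report records
#' every candidate with its verdict and the ordered list of failed criteria;
#' the pipeline is fully deterministic, so reruns on identical input produce
#' identical reports.
#'
#' @param x VCF path or a variants data.frame from
#'   \code{\link{read_vcf_candidates}}.
#' @param params an \code{\link{screening_params}} object.
#' @param lab_code laboratory code used in assigned locus names.
#' @return list of class \code{mh_screening_report}: \code{candidates} (one
#'   row per candidate: \code{chrom}, \code{start}, \code{end},
#'   \code{span_bp}, \code{n_snps}, \code{ae}, \code{he}, \code{verdict},
#'   \code{reasons}), \code{panel} (accepted loci with assigned ids),
#'   \code{params}.
#' @export
screen_candidates <- function(x, params = screening_params(),
                              lab_code = "sim") {
  variants <- if (is.character(x)) read_vcf_candidates(x) else x
  wins <- candidate_windows(variants, params)
  if (length(wins) == 0L) {
    return(structure(list(candidates = data.frame(), panel = data.frame(),
                          params = params), class = "mh_screening_report"))
  }
  rows <- lapply(wins, function(w) {
    res <- apply_filters(w, params)
    data.frame(chrom = attr(w, "chrom"), start = attr(w, "start"),
               end = attr(w, "end"), span_bp = attr(w, "span_bp"),
               n_snps = res$n_snps, ae = res$ae, he = res$he,
               verdict = if (res$pass) "accepted" else "rejected",
               reasons = paste(res$reasons, collapse = "; "),
               snp_ids = paste(w$id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  acc <- cand[cand$verdict == "accepted", , drop = FALSE]
  if (nrow(acc)) {
    spaced <- enforce_spacing(acc, params$spacing_min_bp)
    dropped <- !spaced$retained
    if (any(dropped)) {
      key <- paste(cand$chrom, cand$start)
      dk <- paste(spaced$chrom[dropped], spaced$start[dropped])
      cand$verdict[key %in% dk] <- "rejected"
      cand$reasons[key %in% dk] <-
        sprintf("within %.1f Mb of a higher-Ae retained locus",
                params$spacing_min_bp / 1e6)
    }
    panel <- spaced[spaced$retained, , drop = FALSE]
    panel <- panel[order(suppressWarnings(as.integer(sub("^chr", "", panel$chrom))),
                         panel$start), , drop = FALSE]
    chrom_int <- as.integer(sub("^chr", "", panel$chrom))
    serial <- stats::ave(seq_len(nrow(panel)), chrom_int, FUN = seq_along)
    panel$id <- mapply(make_locus_name, chrom_int, lab_code, serial)
    panel$retained <- NULL
  } else panel <- acc
  structure(list(candidates = cand, panel = panel, params = params),
            class = "mh_screening_report")
}

#' @export
print.mh_screening_report <- function(x, ...) {
  cat("<mh_screening_report> ", nrow(x$candidates), " candidates, ",
      nrow(x$panel), " accepted\n", sep = "")
  if (nrow(x$candidates))
    print(x$candidates[c("chrom", "start", "span_bp", "n_snps", "ae",
                         "verdict", "reasons")], digits = 4)
  invisible(x)
}
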