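#' Allele frequency set for one microhaplotype locus
#'
#' Constructs a validated frequency spectrum: a named numeric vector whose
#' names are haplotype allele strings (one base per SNP, in positional order)
#' and whose values are the allele frequencies \eqn{p_i}.
#'
#' @param frequencies numeric vector of nonnegative frequencies. Must sum to 1
#'   within \code{1e-6}; sums within tolerance are renormalised exactly to 1.
#' @param alleles character vector of allele labels (defaults to
#'   \code{names(frequencies)}). All labels must be unique and, when longer
#'   than one character, of equal length.
#' @param locus optional locus id carried as an attribute.
#' @param n_samples optional number of genotyped individuals the spectrum was
#'   estimated from (used e.g. for rare-allele floors and Fst corrections).
#' @return an object of class \code{mh_freqs}.
#' @export
mh_freqs <- function(frequencies, alleles = names(frequencies), locus = NULL,
                     n_samples = NULL) {
  if (length(frequencies) == 0L) stop_mh("empty frequency set")
  if (is.null(alleles)) alleles <- paste0("A", seq_along(frequencies))
  if (length(alleles) != length(frequencies))
    stop_mh("alleles and frequencies differ in length")
  if (anyDuplicated(alleles)) stop_mh("duplicate allele labels")
  if (any(frequencies < 0)) stop_mh("negative allele frequency")
  if (length(unique(nchar(alleles))) > 1L)
    stop_mh("allele strings must all have the same length")
  s <- sum(frequencies)
  if (abs(s - 1) > 1e-6)
    stop_mh(sprintf("frequencies sum to %.8f, not 1 (tolerance 1e-6)", s))
  f <- as.numeric(frequencies) / s
  names(f) <- as.character(alleles)
  structure(f, class = "mh_freqs", locus = locus, n_samples = n_samples)
}

#' @export
print.mh_freqs <- function(x, ...) {
  loc <- attr(x, "locus")
  cat("<mh_freqs", if (!is.null(loc)) paste0(" ", loc) else "", "> ",
      length(x), " alleles, Ae = ", round(1 / sum(unclass(x)^2), 3), "\n",
      sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Regex for microhaplotype nomenclature: mh + 2-digit chromosome + lowercase
# lab code + 3-digit serial + optional single lowercase suffix.
MH_ID_REGEX <- "^mh(0[1-9]|1[0-9]|2[0-2])[a-z]+[0-9]{3}[a-z]?$"

#' Validate a microhaplotype locus id
#'
#' @param id character vector of candidate ids.
#' @return logical vector: does each id follow the mh nomenclature
#'   (\code{mh} + zero-padded chromosome 01--22 + lab code + 3-digit serial +
#'   optional single lower-case suffix, e.g. \code{mh11zha006a})?
#' @export
is_valid_locus_id <- function(id) grepl(MH_ID_REGEX, id)

#' Compose a microhaplotype locus name
#'
#' Builds an id following the community nomenclature: loci in the same
#' molecular region with different SNP compositions are distinguished by a
#' lower-case suffix letter.
#'
#' @param chromosome integer 1--22.
#' @param lab_code lower-case laboratory code (e.g. \code{"zha"}).
#' @param serial positive integer, zero-padded to 3 digits.
#' @param suffix optional single letter \code{a}--\code{z}.
#' @return id string, e.g. \code{make_locus_name(2, "zha", 12)} is
#'   \code{"mh02zha012"}.
#' @export
make_locus_name <- function(chromosome, lab_code, serial, suffix = NULL) {
  if (!is.numeric(chromosome) || chromosome != as.integer(chromosome) ||
      chromosome < 1 || chromosome > 22)
    stop_mh("chromosome must be an integer in 1-22")
  if (!grepl("^[a-z]+$", lab_code)) stop_mh("lab_code must be lower-case letters")
  if (!is.numeric(serial) || serial < 1 || serial != as.integer(serial))
    stop_mh("serial must be a positive integer")
  if (serial > 999) stop_mh("serial exceeds 3-digit nomenclature")
  sfx <- ""
  if (!is.null(suffix) && !identical(suffix, "")) {
    if (!grepl("^[a-z]$", suffix)) stop_mh("suffix must be a single letter a-z")
    sfx <- suffix
  }
  sprintf("mh%02d%s%03d%s", as.integer(chromosome), lab_code, as.integer(serial), sfx)
}

#' Parse a panel definition table into validated loci
#'
#' Reads a panel table (one row per microhaplotype) and validates every locus:
#' id nomenclature, chromosome range, strictly increasing SNP positions, at
#' least two SNPs, and span consistency. Coordinates are 1-based inclusive, so
#' \code{span_bp = end - start + 1}.
#'
#' @param x a data.frame with columns \code{id}, \code{chromosome},
#'   \code{start}, \code{end}, \code{snp_ids} (rsIDs separated by \code{";"},
#'   tri-allelic member suffixed \code{"*"}); optional \code{length_bp}
#'   (cross-checked against the recomputed span) and \code{snp_positions}
#'   (\code{";"}-separated 1-based coordinates), or a path to a CSV file with
#'   those columns.
#' @param build genome build label carried as metadata (default
#'   \code{"GRCh37"}).
#' @param strict if \code{TRUE} (default), spans of 200 bp or more are an
#'   error (the screening contract); otherwise a warning.
#' @return data.frame of class \code{mh_panel} with columns \code{id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{span_bp},
#'   \code{n_snps}, \code{snp_ids}, \code{tri_allelic_snp} and attribute
#'   \code{build}.
#' @export
parse_panel_definition <- function(x, build = "GRCh37", strict = TRUE) {
  if (is.character(x) && length(x) == 1L)
    x <- read.csv(x, stringsAsFactors = FALSE)
  need <- c("id", "chromosome", "start", "end", "snp_ids")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_mh("missing panel columns: ", paste(miss, collapse = ", "))

  out <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    id <- as.character(row$id)
    if (!is_valid_locus_id(id)) stop_mh("malformed locus id: ", id)
    chrom <- as.integer(row$chromosome)
    if (is.na(chrom) || chrom < 1 || chrom > 22)
      stop_mh(id, ": chromosome outside 1-22")
    id_chrom <- as.integer(substr(id, 3, 4))
    if (id_chrom != chrom)
      stop_mh(id, ": id encodes chromosome ", id_chrom, " but table says ", chrom)
    snps <- strsplit(as.character(row$snp_ids), ";", fixed = TRUE)[[1]]
    snps <- trimws(snps)
    tri <- sub("\\*$", "", snps[grepl("\\*$", snps)])
    snps_clean <- sub("\\*$", "", snps)
    if (length(snps_clean) < 2L)
      stop_mh(id, ": a microhaplotype needs at least 2 SNPs")
    start <- as.numeric(row$start); end <- as.numeric(row$end)
    pos <- c(start, end)
    if (!is.null(x$snp_positions) && !is.na(row$snp_positions) &&
        nzchar(row$snp_positions)) {
      pos <- as.numeric(strsplit(as.character(row$snp_positions), ";")[[1]])
    }
    if (any(diff(pos) <= 0))
      stop_mh(id, ": SNP positions must be strictly increasing")
    span <- as.integer(end - start + 1)
    if (!is.null(x$length_bp) && !is.na(row$length_bp) &&
        span != as.numeric(row$length_bp))
      stop_mh(id, sprintf(": recomputed span %d bp disagrees with length column %s",
                          span, row$length_bp))
    if (span >= 200) {
      msg <- sprintf("%s: span %d bp is not < 200 bp", id, span)
      if (strict) stop_mh(msg) else warning(msg, call. = FALSE)
    }
    data.frame(id = id, chromosome = chrom, start = start, end = end,
               span_bp = span, n_snps = length(snps_clean),
               snp_ids = paste(snps_clean, collapse = ";"),
               tri_allelic_snp = if (length(tri)) tri[[1]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, out)
  structure(panel, build = build, class = c("mh_panel", "data.frame"))
}

#' The bundled 20-locus reference microhaplotype panel
#'
#' A panel of 20 microhaplotypes built around tri-allelic SNPs (every locus
#' except mh22zha008 contains one tri-allelic member), characterised in a
#' Chinese Han sample of 50 unrelated individuals. Coordinates are 1-based on
#' build GRCh37. Alongside the locus definitions the table carries the
#' published per-locus forensic parameters estimated from that sample:
#' effective number of alleles (\code{ae}), observed heterozygosity
#' (\code{ho}), power of discrimination (\code{pd}) and power of exclusion
#' (\code{pe}).
#'
#' Note: locus mh17zha001 prints Ho 0.64 with PE 0.562, which is inconsistent
#' with the exclusion-power formula reproduced by
#' \code{\link{power_of_exclusion}} for every other row (PE(0.64) = 0.342;
#' PE(0.78) = 0.562); it is flagged here rather than silently corrected.
#'
#' @param parameters if \code{TRUE} (default) return the full table including
#'   the \code{ae}, \code{ho}, \code{pd}, \code{pe} columns; otherwise return
#'   the validated \code{mh_panel} locus definitions only.
#' @return a data.frame (see \code{parameters}).
#' @export
mh_reference_panel <- function(parameters = TRUE) {
  path <- system.file("extdata", "mh_reference_panel.csv", package = "mhpanel",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (parameters) return(tab)
  parse_panel_definition(tab[c("id", "chromosome", "start", "end",
                               "snp_ids", "length_bp")])
}

#' Read and write per-locus allele frequency tables
#'
#' Long-format CSV with columns \code{locus}, \code{allele}, \code{frequency}.
#' Frequencies per locus must sum to 1 within \code{1e-6} (renormalised
#' exactly); larger deviations, negative values or duplicate allele rows are
#' errors.
#'
#' @param path CSV file path.
#' @return \code{read_frequency_table}: a named list of \code{\link{mh_freqs}}
#'   keyed by locus id.
#' @export
read_frequency_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "allele", "frequency")
  if (!all(need %in% names(tab)))
    stop_mh("frequency table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$locus), function(d) {
    if (anyDuplicated(d$allele))
      stop_mh("duplicate allele rows at locus ", d$locus[[1]])
    mh_freqs(d$frequency, alleles = d$allele, locus = d$locus[[1]])
  })
  out[unique(tab$locus)]
}

#' @rdname read_frequency_table
#' @param freq_db named list of \code{\link{mh_freqs}}.
#' @export
write_frequency_table <- function(freq_db, path) {
  rows <- lapply(names(freq_db), function(loc) {
    f <- freq_db[[loc]]
    data.frame(locus = loc, allele = names(f), frequency = as.numeric(f),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write genotype tables
#'
#' Wide-format CSV: a \code{sample} column plus one column per locus, each
#' cell an unordered pair of haplotype alleles encoded \code{"ALLELE1/ALLELE2"}
#' (\code{"./."} for missing). Genotypes are stored canonically with the two
#' alleles sorted, so \code{"ACT/ATT"} and \code{"ATT/ACT"} are the same
#' genotype.
#'
#' @param path CSV file path.
#' @param panel optional \code{mh_panel}; when supplied, allele string lengths
#'   are validated against each locus's SNP count.
#' @return a data.frame of class \code{mh_genotypes}.
#' @export
read_genotype_table <- function(path, panel = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(tab)) stop_mh("genotype table needs a 'sample' column")
  as_mh_genotypes(tab, panel = panel)
}

#' @rdname read_genotype_table
#' @param table an \code{mh_genotypes} data.frame.
#' @export
write_genotype_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coerce a data.frame to a canonical genotype table
#'
#' @param tab data.frame with a \code{sample} column and one genotype column
#'   per locus.
#' @inheritParams read_genotype_table
#' @return data.frame of class \code{mh_genotypes} with canonically sorted
#'   genotype strings.
#' @export
as_mh_genotypes <- function(tab, panel = NULL) {
  for (loc in locus_cols(tab)) {
    g <- as.character(tab[[loc]])
    al <- split_geno(g)
    bad <- !is_missing_geno(g) & (is.na(al[, 1]) | is.na(al[, 2]))
    if (any(bad)) stop_mh("malformed genotype at locus ", loc, ": ", g[bad][1])
    ok <- !is.na(al[, 1])
    g[ok] <- geno_string(al[ok, 1], al[ok, 2])
    g[!ok] <- MISSING_GENO
    if (!is.null(panel) && loc %in% panel$id) {
      n_snps <- panel$n_snps[match(loc, panel$id)]
      len <- nchar(al[ok, 1])
      if (any(len != n_snps))
        stop_mh(loc, ": allele string length inconsistent with ", n_snps, " SNPs")
    }
    tab[[loc]] <- g
  }
  class(tab) <- c("mh_genotypes", "data.frame")
  tab
}

#' Read candidate variants from a VCF
#'
#' Thin ingestion path for marker screening: parses a VCF (v4.x) via
#' \pkg{vcfR}, keeping multi-allelic records whole — tri-allelic status is a
#' property of one record, flagged when a site carries two or more ALT
#' alleles. Allele frequencies are taken from the INFO \code{AF} field (ALT
#' frequencies; REF gets the complement), from \code{AC}/\code{AN}, or
#' computed from GT columns; a record with none of these is an error.
#'
#' @param path VCF file path.
#' @param region optional \code{c(chrom, start, end)} filter.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{id},
#'   \code{ref}, \code{alt}, \code{n_alleles}, \code{tri_allelic} and a list
#'   column \code{freqs} (named per-allele frequencies, REF first).
#' @export
read_vcf_candidates <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(), pos = numeric(), id = character(),
                      ref = character(), alt = character(),
                      n_alleles = integer(), tri_allelic = logical()))
  gt <- if (ncol(vcf@gt) > 1L) vcfR::extract.gt(vcf, element = "GT") else NULL

  freqs <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- c(ref, alts)
    info <- fix$INFO[i] %||% ""
    af_m <- regmatches(info, regexpr("(?:^|;)AF=([0-9eE.,+-]+)", info))
    f <- NULL
    if (length(af_m) == 1L) {
      af <- as.numeric(strsplit(sub(".*AF=", "", af_m), ",")[[1]])
      f <- c(1 - sum(af), af)
    } else if (grepl("(^|;)AC=", info) && grepl("(^|;)AN=", info)) {
      ac <- as.numeric(strsplit(sub(".*?(^|;)AC=([0-9,]+).*", "\\2", info), ",")[[1]])
      an <- as.numeric(sub(".*?(^|;)AN=([0-9]+).*", "\\2", info))
      f <- c(1 - sum(ac) / an, ac / an)
    } else if (!is.null(gt)) {
      codes <- unlist(strsplit(gt[i, ], "[/|]"))
      codes <- suppressWarnings(as.integer(codes[codes != "."]))
      if (length(codes) == 0L)
        stop_mh("record ", fix$ID[i], ": no AF field and no called genotypes")
      f <- tabulate(codes + 1L, nbins = length(alleles)) / length(codes)
    } else {
      stop_mh("record ", fix$ID[i], ": neither AF/AC+AN nor GT available")
    }
    if (length(f) != length(alleles) || any(is.na(f)))
      stop_mh("record ", fix$ID[i], ": malformed allele frequencies")
    freqs[[i]] <- setNames(f, alleles)
  }

  out <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                    id = fix$ID, ref = fix$REF, alt = fix$ALT,
                    n_alleles = 1L + lengths(regmatches(fix$ALT, gregexpr(",", fix$ALT))) + 0L,
                    stringsAsFactors = FALSE)
  out$n_alleles <- vapply(strsplit(fix$ALT, ","), length, integer(1)) + 1L
  out$tri_allelic <- out$n_alleles >= 3L
  out$freqs <- freqs
  if (!is.null(region)) {
    keep <- out$chrom == as.character(region[[1]]) &
      out$pos >= as.numeric(region[[2]]) & out$pos <= as.numeric(region[[3]])
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write a minimal VCF of candidate variants
#'
#' Emits a VCF v4.2 with INFO \code{AF} fields that
#' \code{\link{read_vcf_candidates}} reads back unchanged. Intended for
#' synthetic screening fixtures.
#'
#' @param variants data.frame in the layout returned by
#'   \code{\link{read_vcf_candidates}} (columns \code{chrom}, \code{pos},
#'   \code{id}, \code{ref}, \code{alt}, list column \code{freqs}).
#' @param path output path.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    f <- variants$freqs[[i]]
    af <- paste(format(unname(f[-1]), trim = TRUE, digits = 8), collapse = ",")
    paste(variants$chrom[i], format(variants$pos[i], scientific = FALSE, trim = TRUE),
          variants$id[i], variants$ref[i], variants$alt[i], ".", "PASS",
          paste0("AF=", af), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Serialise a tree to Newick
#'
#' @param tree a \code{phylo} object (e.g. from \code{\link{nj_tree}}).
#' @return single Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "phylo")) stop_mh("tree must be a 'phylo' object")
  ape::write.tree(tree)
}
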