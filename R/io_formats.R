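# Readers/writers for the external formats and the internal conventions every
# other module assumes:
#   * internal coordinates are 0-based half-open; VCF stays 1-based at the
#     boundary; BED output is 0-based half-open,
#   * haplotype matrices are coded 0 = ancestral / 1 = derived whenever the
#     ancestral allele is resolvable, otherwise 0 = REF / 1 = ALT with the
#     SNP flagged unpolarized,
#   * UTR sequences are stored as DNA (T) in mRNA sense orientation; miRNA
#     seeds are RNA (U); the comparison layer maps U <-> T.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_dna <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' @keywords internal
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Construct a haplotype panel
#'
#' The central container: a 0/1 haplotype matrix (rows = phased haplotypes,
#' columns = SNPs ordered by (chrom, pos)) plus the SNP index and the
#' haplotype-to-population assignment.
#'
#' @param haplotypes integer matrix of 0/1, rows = haplotypes, cols = SNPs.
#' @param snp data.frame with columns snp_id, chrom, pos, ref, alt,
#'   ancestral (NA when unknown), polarized (logical), functional (logical).
#' @param hap_sample character, sample id of each haplotype row.
#' @param hap_population character, population id of each haplotype row.
#' @return an object of class `HaplotypePanel`.
#' @export
haplotype_panel <- function(haplotypes, snp, hap_sample, hap_population) {
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) == length(hap_sample),
            length(hap_sample) == length(hap_population),
            ncol(haplotypes) == nrow(snp))
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotype matrix entries must be 0/1")
  ord <- order(snp$chrom, snp$pos)
  snp <- snp[ord, , drop = FALSE]
  rownames(snp) <- NULL
  haplotypes <- haplotypes[, ord, drop = FALSE]
  colnames(haplotypes) <- snp$snp_id
  structure(list(haplotypes = haplotypes, snp = snp,
                 hap_sample = hap_sample,
                 hap_population = hap_population,
                 populations = unique(hap_population)),
            class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d SNPs, %d population(s): %s\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              length(x$populations), paste(x$populations, collapse = ", ")))
  cat(sprintf("  polarized SNPs: %d / %d\n",
              sum(x$snp$polarized), nrow(x$snp)))
  invisible(x)
}

#' Subset the haplotype rows of a panel to one population
#' @param panel a `HaplotypePanel`.
#' @param population population id.
#' @return integer row indices.
#' @export
panel_rows <- function(panel, population = NULL) {
  if (is.null(population)) return(seq_len(nrow(panel$haplotypes)))
  idx <- which(panel$hap_population == population)
  if (length(idx) == 0L) stop("unknown population: ", population)
  idx
}

#' Per-population derived allele frequencies
#' @param panel a `HaplotypePanel`.
#' @return matrix SNPs x populations of allele-1 frequencies (derived where
#'   polarized).
#' @export
panel_frequencies <- function(panel) {
  out <- sapply(panel$populations, function(p) {
    colMeans(panel$haplotypes[panel_rows(panel, p), , drop = FALSE])
  })
  out <- matrix(out, ncol = length(panel$populations),
                dimnames = list(panel$snp$snp_id, panel$populations))
  out
}

#' Read phased genotypes from a VCF into a haplotype panel
#'
#' Biallelic SNP records are transcribed to two haplotype rows per sample.
#' When the `AA` INFO tag carries a valid ancestral allele, the 0/1 coding is
#' polarized so 1 = derived; otherwise coding is REF-relative and the SNP is
#' flagged unpolarized. Multiallelic or non-SNP records are skipped and
#' counted (attribute `"skipped"`).
#'
#' @param path path to a VCF 4.x file with phased diploid GT.
#' @param population_map named character vector, sample id -> population id.
#' @return a `HaplotypePanel`; attribute `"skipped"` holds the skip count.
#' @export
read_vcf <- function(path, population_map) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% DNA_BASES & ref %in% DNA_BASES
  skipped <- sum(!keep)

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  samples <- colnames(gt)
  if (is.data.frame(population_map))
    population_map <- stats::setNames(as.character(population_map[[2]]),
                                      population_map[[1]])
  missing_s <- setdiff(samples, names(population_map))
  if (length(missing_s))
    stop("sample(s) absent from population_map: ",
         paste(missing_s, collapse = ", "))

  gt <- gt[keep, , drop = FALSE]
  unph <- which(!grepl("^[01]\\|[01]$", gt))
  if (length(unph)) {
    i <- arrayInd(unph[1], dim(gt))
    stop(sprintf("unphased or invalid genotype '%s' at record %s, sample %s",
                 gt[unph[1]], rownames(gt)[i[1]], samples[i[2]]))
  }
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))

  # interleave the two haplotypes of each sample
  n_rec <- nrow(gt)
  hap <- matrix(0L, nrow = 2L * length(samples), ncol = n_rec)
  hap[seq(1L, by = 2L, length.out = length(samples)), ] <- t(a1)
  hap[seq(2L, by = 2L, length.out = length(samples)), ] <- t(a2)

  aa <- rep(NA_character_, length(ref))
  info <- VariantAnnotation::info(vcf)
  if ("AA" %in% colnames(info)) aa <- toupper(as.character(info$AA))
  ref <- ref[keep]; alt1 <- alt1[keep]; aa <- aa[keep]
  valid_aa <- !is.na(aa) & (aa == ref | aa == alt1)
  aa[!valid_aa] <- NA_character_

  # polarize: column coding flipped where the ancestral allele is ALT
  flip <- which(valid_aa & aa == alt1)
  if (length(flip)) hap[, flip] <- 1L - hap[, flip]

  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("snp", seq_len(n_rec))
  snp <- data.frame(
    snp_id = ids,
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = ref, alt = alt1, ancestral = aa,
    polarized = valid_aa,
    functional = FALSE,
    stringsAsFactors = FALSE
  )
  panel <- haplotype_panel(
    hap, snp,
    hap_sample = rep(samples, each = 2L),
    hap_population = rep(unname(population_map[samples]), each = 2L)
  )
  attr(panel, "skipped") <- skipped
  panel
}

#' Read a miRNA family table
#'
#' @param path TSV with columns `family_id`, `seed` (7 RNA bases, the miRNA
#'   nucleotides at positions 2-8), `members` (comma-separated miRNA names).
#' @return data.frame of validated families.
#' @export
read_mirna_families <- function(path) {
  fam <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("family_id", "seed", "members")
  if (!all(need %in% names(fam)))
    stop("family table must have columns: ", paste(need, collapse = ", "))
  fam$seed <- toupper(fam$seed)
  bad_len <- nchar(fam$seed) != 7L
  bad_chr <- !grepl("^[ACGU]+$", fam$seed)
  if (any(bad_len | bad_chr)) {
    i <- which(bad_len | bad_chr)[1]
    stop(sprintf("row %d (family '%s'): seed must be 7 RNA bases, got '%s'",
                 i, fam$family_id[i], fam$seed[i]))
  }
  if (anyDuplicated(fam$family_id))
    stop("duplicate family id(s): ",
         paste(unique(fam$family_id[duplicated(fam$family_id)]),
               collapse = ", "))
  fam
}

#' Read a SNP annotation table
#'
#' Columns: snp_id, chrom, pos (1-based), ref, alt, ancestral ("." or a base),
#' functional (0/1 flag used by the hitchhiking filter).
#' @param path TSV path.
#' @return data.frame with `ancestral` NA where unknown and logical columns
#'   `polarized`, `functional`.
#' @export
read_snp_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", colClasses = NA)
  tab$chrom <- as.character(tab$chrom)
  tab$ancestral <- as.character(tab$ancestral)
  tab$ancestral[!(tab$ancestral %in% DNA_BASES)] <- NA_character_
  tab$polarized <- !is.na(tab$ancestral) &
    (tab$ancestral == tab$ref | tab$ancestral == tab$alt)
  tab$ancestral[!tab$polarized] <- NA_character_
  tab$functional <- as.logical(as.integer(tab$functional))
  tab
}

#' Write the internal SNP table (round-trips through [read_snp_table()])
#' @param snp SNP data.frame (panel `$snp` layout).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snp, path) {
  out <- snp[, c("snp_id", "chrom", "pos", "ref", "alt",
                 "ancestral", "functional")]
  out$ancestral[is.na(out$ancestral)] <- "."
  out$functional <- as.integer(out$functional)
  write_tsv(out, path)
}

#' Read population metadata
#' @param path TSV with columns population_id, n_samples, absolute_latitude,
#'   excluded (0/1), reason.
#' @return data.frame; `excluded` logical.
#' @export
read_population_meta <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  if (any(meta$absolute_latitude < 0 | meta$absolute_latitude > 90))
    stop("absolute_latitude must lie in [0, 90]")
  meta$excluded <- as.logical(as.integer(meta$excluded))
  meta
}

#' Merge a SNP annotation table into a panel
#'
#' Adds functional flags and, for panel SNPs left unpolarized by the VCF,
#' applies the table's ancestral call (flipping the 0/1 coding when the
#' ancestral allele is ALT).
#' @param panel a `HaplotypePanel`.
#' @param snp_table data.frame from [read_snp_table()].
#' @return the annotated panel.
#' @export
annotate_panel <- function(panel, snp_table) {
  m <- match(panel$snp$snp_id, snp_table$snp_id)
  hit <- !is.na(m)
  panel$snp$functional[hit] <- snp_table$functional[m[hit]]
  fix <- hit & !panel$snp$polarized & snp_table$polarized[m]
  if (any(fix)) {
    aa <- snp_table$ancestral[m[fix]]
    panel$snp$ancestral[fix] <- aa
    panel$snp$polarized[fix] <- TRUE
    flip <- which(fix)[aa == panel$snp$alt[fix]]
    if (length(flip))
      panel$haplotypes[, flip] <- 1L - panel$haplotypes[, flip]
  }
  panel
}

#' Read 3'UTR sequences and map SNPs onto them
#'
#' FASTA headers follow `transcript|gene|chrom|strand|genomic_start`.
#' Sequences are stored genomic plus-strand in the FASTA; minus-strand
#' transcripts are reverse-complemented at load so all downstream scanning
#' happens in mRNA sense space. When several transcripts share a gene the
#' longest is retained. SNPs whose (strand-adjusted) ref base mismatches the
#' sequence are dropped and counted (attribute `"dropped"`).
#'
#' @param fasta_path FASTA of 3'UTRs.
#' @param snp_table data.frame with snp_id, chrom, pos, ref, alt.
#' @return named list of `UtrSequence` objects (transcript_id, gene_id,
#'   chrom, strand, genomic_start, length, sequence (sense), and per mapped
#'   SNP: 0-based `snp_offsets`, sense-strand `snp_ref` / `snp_alt`).
#' @export
read_utrs <- function(fasta_path, snp_table) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(hdr) != 5L))
    stop("FASTA headers must be transcript|gene|chrom|strand|genomic_start")
  info <- data.frame(
    transcript_id = vapply(hdr, `[`, "", 1L),
    gene_id = vapply(hdr, `[`, "", 2L),
    chrom = vapply(hdr, `[`, "", 3L),
    strand = vapply(hdr, `[`, "", 4L),
    genomic_start = as.integer(vapply(hdr, `[`, "", 5L)),
    len = Biostrings::width(seqs),
    stringsAsFactors = FALSE
  )
  # longest transcript per gene (first wins on ties)
  keep <- unlist(lapply(split(seq_len(nrow(info)), info$gene_id),
                        function(i) i[which.max(info$len[i])]))
  keep <- sort(unname(keep))
  dropped <- 0L
  utrs <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    seq_plus <- as.character(seqs[[i]])
    minus <- info$strand[i] == "-"
    sense <- if (minus) revcomp_dna(seq_plus) else seq_plus
    g0 <- info$genomic_start[i]
    L <- info$len[i]
    cand <- which(snp_table$chrom == info$chrom[i] &
                    snp_table$pos >= g0 & snp_table$pos <= g0 + L - 1L)
    offs <- integer(0); refs <- character(0); alts <- character(0)
    ids <- character(0)
    for (j in cand) {
      pos <- snp_table$pos[j]
      off <- if (minus) (g0 + L - 1L - pos) else (pos - g0)
      sref <- if (minus) revcomp_dna(snp_table$ref[j]) else snp_table$ref[j]
      salt <- if (minus) revcomp_dna(snp_table$alt[j]) else snp_table$alt[j]
      if (substr(sense, off + 1L, off + 1L) != sref) {
        dropped <- dropped + 1L
        next
      }
      offs <- c(offs, off); refs <- c(refs, sref); alts <- c(alts, salt)
      ids <- c(ids, snp_table$snp_id[j])
    }
    utrs[[k]] <- structure(
      list(transcript_id = info$transcript_id[i], gene_id = info$gene_id[i],
           chrom = info$chrom[i], strand = info$strand[i],
           genomic_start = g0, length = L, sequence = sense,
           snp_offsets = stats::setNames(offs, ids),
           snp_ref = stats::setNames(refs, ids),
           snp_alt = stats::setNames(alts, ids)),
      class = "UtrSequence")
  }
  names(utrs) <- info$transcript_id[keep]
  attr(utrs, "dropped") <- dropped
  utrs
}

#' Deterministic TSV writer
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

#' Write target-site calls as BED (0-based half-open, transcript coordinates)
#' @param calls data.frame of target-site calls (see [scan_alleles()]).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(calls)) {
    lines <- sprintf("%s\t%d\t%d\t%s:%s\t0\t+",
                     calls$transcript_id, calls$site_start,
                     calls$site_start + calls$site_length,
                     calls$snp_id, calls$family_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a named list of result tables to a directory
#'
#' Each element becomes `<name>.tsv`; an element named `calls` additionally
#' produces `calls.bed`. Output is byte-identical across runs for identical
#' inputs.
#' @param results named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths.
#' @export
write_results_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(results[[nm]], p)
    paths <- c(paths, p)
    if (nm == "calls" && all(c("transcript_id", "site_start", "site_length")
                             %in% names(results[[nm]]))) {
      pb <- file.path(out_dir, "calls.bed")
      write_calls_bed(results[[nm]], pb)
      paths <- c(paths, pb)
    }
  }
  paths
}
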