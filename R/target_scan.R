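# Allele-aware miRNA seed-site detection at SNPs.
#
# Site classes are defined on the mRNA sense strand from the miRNA seed
# (positions 2-8, 7 RNA bases):
#   heptamer = reverse complement of seed positions 2-8
#   hexamer  = reverse complement of seed positions 2-7
#   8mer     = heptamer followed by A (the base opposite miRNA position 1)
#   7mer-m8  = heptamer alone
#   7mer-A1  = hexamer followed by A
#   6mer     = hexamer alone (only when allow_6mer)
# Priority 8mer > 7mer-m8 > 7mer-A1 > 6mer; leftmost occurrence on ties.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
SITE_LENGTHS <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)

#' mRNA match patterns for a miRNA seed
#' @param seed 7 RNA bases, miRNA positions 2-8.
#' @return named character vector of DNA site patterns per site type.
#' @export
seed_site_patterns <- function(seed) {
  seed <- toupper(seed)
  if (nchar(seed) != 7L || !grepl("^[ACGU]+$", seed))
    stop("seed must be 7 RNA bases (ACGU), got '", seed, "'")
  hept <- revcomp_dna(rna_to_dna(seed))
  hex <- revcomp_dna(rna_to_dna(substr(seed, 1L, 6L)))
  c("8mer" = paste0(hept, "A"),
    "7mer-m8" = hept,
    "7mer-A1" = paste0(hex, "A"),
    "6mer" = hex)
}

#' Classify the best seed-match site in a sequence
#'
#' @param sequence DNA sequence in mRNA sense orientation.
#' @param seed 7-base RNA seed (miRNA positions 2-8).
#' @param allow_6mer accept bare 6mer matches (default FALSE; the
#'   fine-resolution re-scan uses TRUE).
#' @return list with `type` ("8mer", "7mer-m8", "7mer-A1", "6mer" or "none"),
#'   0-based `start` offset and `length` (NA when none).
#' @export
classify_site <- function(sequence, seed, allow_6mer = FALSE) {
  pats <- seed_site_patterns(seed)
  types <- if (allow_6mer) SITE_TYPES else SITE_TYPES[1:3]
  sequence <- rna_to_dna(toupper(sequence))   # accept RNA input (U ~ T)
  for (ty in types) {
    hit <- regexpr(pats[[ty]], sequence, fixed = TRUE)
    if (hit > 0L)
      return(list(type = ty, start = as.integer(hit) - 1L,
                  length = SITE_LENGTHS[[ty]]))
  }
  list(type = "none", start = NA_integer_, length = NA_integer_)
}

#' Build 15-nt polymorphic windows around mapped SNPs
#'
#' A window spans offsets -7..+7 around the SNP on the sense sequence,
#' clipped at the UTR boundaries (truncation flagged). Both allele versions
#' are emitted; they differ only at the center.
#'
#' @param utr a `UtrSequence` from [read_utrs()].
#' @param snps optional character vector of SNP ids (default: all mapped).
#' @param flank bases on each side of the SNP (default 7, the 15-nt window).
#' @return data.frame, one row per SNP: snp_id, transcript_id, gene_id,
#'   window_start (0-based offset of the window in the UTR), center (0-based
#'   offset of the SNP in the window), seq_ref, seq_alt, truncated.
#' @export
build_windows <- function(utr, snps = NULL, flank = 7L) {
  ids <- names(utr$snp_offsets)
  if (!is.null(snps)) ids <- intersect(snps, ids)
  if (length(ids) == 0L)
    return(data.frame(snp_id = character(0), transcript_id = character(0),
                      gene_id = character(0), window_start = integer(0),
                      center = integer(0), seq_ref = character(0),
                      seq_alt = character(0), truncated = logical(0),
                      stringsAsFactors = FALSE))
  off <- utr$snp_offsets[ids]
  if (any(off < 0L | off >= utr$length))
    stop("SNP offset outside UTR: ",
         paste(ids[off < 0L | off >= utr$length], collapse = ", "))
  lo <- pmax(off - flank, 0L)
  hi <- pmin(off + flank, utr$length - 1L)
  seq_ref <- substring(utr$sequence, lo + 1L, hi + 1L)
  center <- off - lo
  seq_alt <- seq_ref
  substr(seq_alt, center + 1L, center + 1L) <- utr$snp_alt[ids]
  data.frame(snp_id = ids, transcript_id = utr$transcript_id,
             gene_id = utr$gene_id, window_start = as.integer(lo),
             center = as.integer(center), seq_ref = seq_ref,
             seq_alt = seq_alt,
             truncated = (off - flank < 0L) | (off + flank > utr$length - 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Allele-aware scan of polymorphic windows against miRNA families
#'
#' Classifies both allele versions of every window for every family and
#' assigns a verdict: `disrupting` / `creating` iff exactly one allele has an
#' accepted site type (the derived allele respectively losing or gaining the
#' site when polarity is known, otherwise relative to ALT), `both-intact`
#' when both alleles carry a site (including sites not overlapping the SNP),
#' `none` otherwise. When context scores are supplied, calls scoring above
#' `score_threshold` are dropped (less-negative = less confident).
#'
#' @param windows data.frame from [build_windows()] (rows from several UTRs
#'   may be concatenated).
#' @param families family data.frame from [read_mirna_families()].
#' @param allow_6mer accept bare 6mer matches.
#' @param score_threshold context-score cutoff, default -0.2.
#' @param context_scores optional data.frame (snp_id, family_id, score).
#' @param derived_is_alt optional named logical by snp_id; TRUE (default)
#'   means the ALT allele is derived.
#' @return data.frame of calls: snp_id, family_id, transcript_id, gene_id,
#'   site_type_ref, site_type_alt, site_type_anc, site_type_der, verdict,
#'   site_start (0-based UTR offset), site_length.
#' @export
scan_alleles <- function(windows, families, allow_6mer = FALSE,
                         score_threshold = -0.2, context_scores = NULL,
                         derived_is_alt = NULL) {
  out <- vector("list", nrow(families))
  for (fi in seq_len(nrow(families))) {
    fam <- families$family_id[fi]
    seed <- families$seed[fi]
    rows <- vector("list", nrow(windows))
    for (wi in seq_len(nrow(windows))) {
      w <- windows[wi, ]
      cr <- classify_site(w$seq_ref, seed, allow_6mer)
      ca <- classify_site(w$seq_alt, seed, allow_6mer)
      if (cr$type == "none" && ca$type == "none") next
      ref_has <- cr$type != "none"
      alt_has <- ca$type != "none"
      da <- if (is.null(derived_is_alt) || is.na(derived_is_alt[w$snp_id]))
        TRUE else derived_is_alt[[w$snp_id]]
      t_anc <- if (da) cr$type else ca$type
      t_der <- if (da) ca$type else cr$type
      verdict <- if (ref_has && alt_has) "both-intact"
      else if (t_anc != "none") "disrupting"   # derived allele loses the site
      else "creating"                          # derived allele gains the site
      site <- if (ref_has) cr else ca
      rows[[wi]] <- data.frame(
        snp_id = w$snp_id, family_id = fam,
        transcript_id = w$transcript_id, gene_id = w$gene_id,
        site_type_ref = cr$type, site_type_alt = ca$type,
        site_type_anc = t_anc, site_type_der = t_der,
        verdict = verdict,
        site_start = w$window_start + site$start,
        site_length = site$length,
        stringsAsFactors = FALSE)
    }
    out[[fi]] <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(calls))
    calls <- data.frame(snp_id = character(0), family_id = character(0),
                        transcript_id = character(0), gene_id = character(0),
                        site_type_ref = character(0),
                        site_type_alt = character(0),
                        site_type_anc = character(0),
                        site_type_der = character(0),
                        verdict = character(0), site_start = integer(0),
                        site_length = integer(0), stringsAsFactors = FALSE)
  if (!is.null(context_scores) && nrow(calls)) {
    key <- paste(calls$snp_id, calls$family_id)
    skey <- paste(context_scores$snp_id, context_scores$family_id)
    sc <- context_scores$score[match(key, skey)]
    # calls without a supplied score pass (no score source)
    calls <- calls[is.na(sc) | sc <= score_threshold, , drop = FALSE]
  }
  rownames(calls) <- NULL
  calls[order(calls$snp_id, calls$family_id), , drop = FALSE]
}

#' Summarize allele-dependent site calls
#'
#' @param calls data.frame from [scan_alleles()].
#' @return list: `by_verdict` (call-level counts), `by_site_type`
#'   (call-level counts of the intact allele's site type for
#'   disrupting/creating calls), `n_calls_polymorphic` and
#'   `n_snps_polymorphic` (SNPs with at least one disrupting/creating call;
#'   a SNP hit by several families counts once), `n_genes_polymorphic`.
#' @export
count_polymorphic_sites <- function(calls) {
  verd <- factor(calls$verdict,
                 levels = c("disrupting", "creating", "both-intact"))
  poly <- calls$verdict %in% c("disrupting", "creating")
  intact_type <- ifelse(calls$site_type_anc != "none",
                        calls$site_type_anc, calls$site_type_der)
  list(
    by_verdict = table(verdict = verd),
    by_site_type = table(site_type = factor(intact_type[poly],
                                            levels = SITE_TYPES)),
    n_calls_polymorphic = sum(poly),
    n_snps_polymorphic = length(unique(calls$snp_id[poly])),
    n_genes_polymorphic = length(unique(calls$gene_id[poly]))
  )
}
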