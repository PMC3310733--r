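# Latitude-allele-frequency clines: Pearson correlation of derived allele
# frequency with absolute latitude over non-excluded populations, and the
# genome-wide empirical extremeness percentile of that correlation.

#' Pearson correlation of derived allele frequency with absolute latitude
#'
#' Populations flagged excluded in the metadata are dropped before
#' computing; at least 3 non-excluded populations with latitude variance
#' are required. Zero variance in frequency or latitude yields an undefined
#' (flagged) result rather than an error.
#'
#' @param freqs named numeric vector of derived allele frequencies by
#'   population id.
#' @param meta data.frame from [read_population_meta()] (population_id,
#'   absolute_latitude, excluded).
#' @return list: pearson_R, n_populations, undefined flag.
#' @export
latitude_correlation <- function(freqs, meta) {
  use <- meta[!meta$excluded & meta$population_id %in% names(freqs), ,
              drop = FALSE]
  if (nrow(use) < 3L) stop("need >= 3 non-excluded populations")
  lat <- use$absolute_latitude
  f <- unname(freqs[use$population_id])
  if (stats::var(lat) == 0) stop("zero latitude variance")
  if (stats::var(f) == 0)
    return(list(pearson_R = NA_real_, n_populations = nrow(use),
                undefined = TRUE))
  list(pearson_R = stats::cor(f, lat), n_populations = nrow(use),
       undefined = FALSE)
}

#' Genome-wide extremeness percentile of a cline correlation
#'
#' Fraction of genome-wide SNPs whose correlation is at least as extreme as
#' the focal one (self-inclusive: a focal SNP more extreme than every other
#' SNP in a set of N gets 1/N). Two-sided on |R| by default.
#'
#' @param focal_R the focal SNP's correlation.
#' @param all_R genome-wide correlations (include the focal SNP for the
#'   self-inclusive convention).
#' @param two_sided compare |R| (default) or the signed value in the focal
#'   tail.
#' @return the percentile in (0, 1].
#' @export
genome_percentile <- function(focal_R, all_R, two_sided = TRUE) {
  all_R <- all_R[!is.na(all_R)]
  if (!length(all_R)) stop("all_R is empty")
  if (two_sided) mean(abs(all_R) >= abs(focal_R))
  else if (focal_R < 0) mean(all_R <= focal_R) else mean(all_R >= focal_R)
}

#' Cline test for a set of SNPs with a genome-wide null
#'
#' Computes the latitude correlation per focal SNP plus its extremeness
#' percentile against all supplied SNPs, and (as in the high-differentiation
#' restriction) against the subset with F_ST >= `fst_threshold` when an
#' F_ST table is given.
#'
#' @param freq_table matrix/data.frame SNPs x populations of derived
#'   frequencies (rownames = snp ids).
#' @param meta population metadata.
#' @param focal_snps snp ids to report (default: all).
#' @param fst optional named F_ST vector by snp id.
#' @param fst_threshold threshold for the restricted percentile
#'   (default 0.5).
#' @param two_sided passed to [genome_percentile()].
#' @return data.frame: snp_id, pearson_R, n_populations, percentile,
#'   restricted_percentile (NA when no F_ST supplied).
#' @export
cline_test <- function(freq_table, meta, focal_snps = NULL, fst = NULL,
                       fst_threshold = 0.5, two_sided = TRUE) {
  freq_table <- as.matrix(freq_table)
  snps <- rownames(freq_table)
  if (is.null(snps)) stop("freq_table needs snp ids as rownames")
  all_R <- vapply(snps, function(s)
    latitude_correlation(freq_table[s, ], meta)$pearson_R, numeric(1))
  if (is.null(focal_snps)) focal_snps <- snps
  high <- if (!is.null(fst))
    all_R[names(all_R) %in% names(fst)[!is.na(fst) & fst >= fst_threshold]]
  else NULL
  res <- lapply(focal_snps, function(s) {
    R <- all_R[[s]]
    data.frame(
      snp_id = s, pearson_R = R,
      n_populations = sum(!meta$excluded &
                            meta$population_id %in% colnames(freq_table)),
      percentile = if (is.na(R)) NA_real_
      else genome_percentile(R, all_R, two_sided),
      restricted_percentile = if (is.null(high) || is.na(R)) NA_real_
      else genome_percentile(R, high, two_sided),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
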