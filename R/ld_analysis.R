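# Pairwise linkage disequilibrium on phased haplotypes and the
# hitchhiking-control filter: target-site SNPs with r^2 >= 0.5 to an
# annotated functional variant within +/- 500 kb are excluded.

#' Pairwise LD statistics from phased haplotypes
#'
#' Haplotype frequencies by direct counting. With allele "A"/"a" the
#' allele-1/0 state at SNP i and "B"/"b" at SNP j:
#' D = p_AB - p_A p_B; D' = D / D_max with D_max = min(p_A p_b, p_a p_B)
#' for D > 0 and min(p_A p_B, p_a p_b) for D < 0; r^2 = D^2 /
#' (p_A p_a p_B p_b); LOD = log10 multinomial likelihood ratio of the
#' observed haplotype frequencies against linkage equilibrium.
#'
#' @param panel a `HaplotypePanel`.
#' @param snp_i,snp_j SNP ids.
#' @param population population id (NULL = all haplotypes).
#' @return list: n (haplotypes), counts (2x2 haplotype counts), D, D_prime,
#'   r2, lod, undefined flag (TRUE when either SNP is monomorphic in the
#'   evaluated haplotypes).
#' @export
ld_pair <- function(panel, snp_i, snp_j, population = NULL) {
  rows <- panel_rows(panel, population)
  i <- match(snp_i, panel$snp$snp_id)
  j <- match(snp_j, panel$snp$snp_id)
  if (is.na(i) || is.na(j)) stop("unknown SNP id")
  x <- panel$haplotypes[rows, i]
  y <- panel$haplotypes[rows, j]
  n <- length(x)
  counts <- matrix(c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
                     sum(x == 0 & y == 1), sum(x == 0 & y == 0)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("A", "a"), c("B", "b")))
  pA <- mean(x); pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(n = n, counts = counts, D = NA_real_, D_prime = NA_real_,
                r2 = NA_real_, lod = NA_real_, undefined = TRUE))
  pAB <- counts["A", "B"] / n
  D <- pAB - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  D_prime <- if (D == 0) 0 else D / d_max
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  # multinomial LR: observed haplotype freqs vs independence
  p_obs <- counts / n
  p_exp <- outer(c(pA, 1 - pA), c(pB, 1 - pB))
  nz <- counts > 0
  lod <- sum(counts[nz] * (log10(p_obs[nz]) - log10(p_exp[nz])))
  list(n = n, counts = counts, D = D, D_prime = D_prime, r2 = r2,
       lod = lod, undefined = FALSE)
}

#' Hitchhiking-control filter for target SNPs
#'
#' A target SNP is excluded iff some annotated functional SNP on the same
#' chromosome within +/- `window_bp` has r^2 >= `r2_threshold` with it; the
#' exclusion log records the triggering pair.
#'
#' @param target_snps character vector of SNP ids.
#' @param panel a `HaplotypePanel` (`$snp$functional` marks functional SNPs).
#' @param window_bp physical window (default 500,000).
#' @param r2_threshold r^2 cutoff (default 0.5).
#' @param populations population id(s) in which r^2 is evaluated (default:
#'   every panel population separately; the SNP is excluded if the cutoff
#'   is reached in any of them). Pooling haplotypes across differentiated
#'   populations would inflate r^2 between any two high-F_ST SNPs through
#'   structure alone, so per-population evaluation is the default.
#' @return list: `retained` (snp ids), `excluded` (data.frame snp_id,
#'   functional_snp, population, distance_bp, r2).
#' @export
hitchhike_filter <- function(target_snps, panel, window_bp = 500000L,
                             r2_threshold = 0.5, populations = NULL) {
  if (is.null(populations)) populations <- panel$populations
  func <- panel$snp[panel$snp$functional, , drop = FALSE]
  excluded <- list()
  retained <- character(0)
  for (id in target_snps) {
    k <- match(id, panel$snp$snp_id)
    if (is.na(k)) stop("target SNP not in panel: ", id)
    near <- func[func$chrom == panel$snp$chrom[k] &
                   abs(func$pos - panel$snp$pos[k]) <= window_bp &
                   func$snp_id != id, , drop = FALSE]
    hit <- NULL
    for (f in near$snp_id) {
      for (p in populations) {
        ld <- ld_pair(panel, id, f, p)
        if (!ld$undefined && ld$r2 >= r2_threshold) {
          hit <- data.frame(snp_id = id, functional_snp = f, population = p,
                            distance_bp = abs(panel$snp$pos[k] -
                                                near$pos[near$snp_id == f]),
                            r2 = ld$r2, stringsAsFactors = FALSE)
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) retained <- c(retained, id)
    else excluded[[length(excluded) + 1L]] <- hit
  }
  excl <- if (length(excluded)) do.call(rbind, excluded)
  else data.frame(snp_id = character(0), functional_snp = character(0),
                  population = character(0), distance_bp = numeric(0),
                  r2 = numeric(0), stringsAsFactors = FALSE)
  list(retained = retained, excluded = excl)
}

#' r^2 of every SNP in a region with a focal SNP, per population
#'
#' SNPs monomorphic within a population get NA (a missing-value marker),
#' not 0.
#' @param panel a `HaplotypePanel`.
#' @param focal_snp focal SNP id.
#' @param region c(start, end) positions (default: whole chromosome).
#' @param populations population ids (default: all panel populations).
#' @return data.frame: snp_id, pos, then one r2 column per population.
#' @export
region_ld_profile <- function(panel, focal_snp, region = NULL,
                              populations = NULL) {
  k <- match(focal_snp, panel$snp$snp_id)
  if (is.na(k)) stop("focal SNP not in panel: ", focal_snp)
  if (is.null(populations)) populations <- panel$populations
  sel <- panel$snp$chrom == panel$snp$chrom[k]
  if (!is.null(region))
    sel <- sel & panel$snp$pos >= region[1] & panel$snp$pos <= region[2]
  ids <- panel$snp$snp_id[sel]
  out <- data.frame(snp_id = ids, pos = panel$snp$pos[sel],
                    stringsAsFactors = FALSE)
  for (p in populations) {
    out[[paste0("r2_", p)]] <- vapply(ids, function(id)
      ld_pair(panel, focal_snp, id, p)$r2, numeric(1))
  }
  rownames(out) <- NULL
  out
}
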