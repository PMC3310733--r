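# Selection statistics from first principles: Weir-Cockerham F_ST, the
# unfolded site frequency spectrum and Fay-Wu's H, EHH curves and iHS with
# frequency-bin standardization, and a composite likelihood ratio sweep scan
# against a background SFS.

#' Per-SNP Weir-Cockerham F_ST from allele counts
#'
#' The 1984 variance-component estimator theta-hat in its haploid form
#' (samples are phased chromosomes): with r populations, sample sizes n_i,
#' allele frequencies p_i,
#'   n_bar = mean(n_i);  n_c = (r n_bar - sum(n_i^2)/(r n_bar)) / (r - 1)
#'   p_bar = sum(n_i p_i) / (r n_bar)
#'   s2    = sum(n_i (p_i - p_bar)^2) / ((r - 1) n_bar)
#'   a = (n_bar/n_c) * (s2 - (p_bar(1-p_bar) - s2 (r-1)/r) / (n_bar - 1))
#'   b = (n_bar/(n_bar - 1)) * (p_bar(1-p_bar) - s2 (r-1)/r)
#'   theta = a / (a + b)
#' The estimator may return small negative values; these are kept (flooring,
#' if wanted, is a reporting choice). SNPs monomorphic across all populations
#' are undefined (NA, flagged), not 0. A Hudson-style alternative
#' (two populations only) is available via `estimator = "hudson"`.
#'
#' @param derived_counts matrix SNPs x populations of allele counts (derived
#'   where polarized; any consistent allele works, F_ST is label-invariant).
#' @param sizes integer vector (or matrix) of sampled chromosomes per
#'   population.
#' @param estimator "wc" (default) or "hudson".
#' @return data.frame: fst, monomorphic flag, and the a/b components
#'   (wc only).
#' @export
fst_per_snp <- function(derived_counts, sizes, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  derived_counts <- as.matrix(derived_counts)
  r <- ncol(derived_counts)
  if (r < 2L) stop("need >= 2 populations")
  if (is.matrix(sizes)) n <- sizes
  else n <- matrix(sizes, nrow = nrow(derived_counts), ncol = r, byrow = TRUE)
  if (any(n < 2L)) stop("each population needs >= 2 sampled chromosomes")
  p <- derived_counts / n
  mono <- rowSums(derived_counts) == 0L | rowSums(n - derived_counts) == 0L
  if (estimator == "hudson") {
    if (r != 2L) stop("hudson estimator is defined here for 2 populations")
    num <- (p[, 1] - p[, 2])^2 -
      p[, 1] * (1 - p[, 1]) / (n[, 1] - 1) -
      p[, 2] * (1 - p[, 2]) / (n[, 2] - 1)
    den <- p[, 1] * (1 - p[, 2]) + p[, 2] * (1 - p[, 1])
    fst <- num / den
    fst[mono] <- NA_real_
    return(data.frame(fst = fst, monomorphic = mono))
  }
  n_tot <- rowSums(n)
  n_bar <- n_tot / r
  n_c <- (n_tot - rowSums(n^2) / n_tot) / (r - 1)
  p_bar <- rowSums(n * p) / n_tot
  s2 <- rowSums(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  pq <- p_bar * (1 - p_bar)
  a <- (n_bar / n_c) * (s2 - (pq - s2 * (r - 1) / r) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * (pq - s2 * (r - 1) / r)
  fst <- a / (a + b)
  fst[mono] <- NA_real_
  data.frame(fst = fst, monomorphic = mono, a = a, b = b)
}

#' Multi-locus Weir-Cockerham F_ST
#'
#' The ratio of summed variance components sum(a) / sum(a + b) over loci --
#' the 1984 multi-locus estimator. Unlike the mean of per-SNP ratios (which
#' is biased low, a Jensen effect), this recovers the Balding-Nichols drift
#' parameter in calibration.
#' @param fst_df data.frame from [fst_per_snp()] / [panel_fst()] with
#'   columns a, b, monomorphic.
#' @return the multi-locus estimate.
#' @export
fst_multilocus <- function(fst_df) {
  ok <- !fst_df$monomorphic & is.finite(fst_df$a) & is.finite(fst_df$b)
  sum(fst_df$a[ok]) / sum(fst_df$a[ok] + fst_df$b[ok])
}

#' F_ST per SNP straight from a panel
#' @param panel a `HaplotypePanel`.
#' @param ... passed to [fst_per_snp()].
#' @return data.frame with snp_id, chrom, pos, fst, monomorphic.
#' @export
panel_fst <- function(panel, ...) {
  counts <- sapply(panel$populations, function(p)
    colSums(panel$haplotypes[panel_rows(panel, p), , drop = FALSE]))
  sizes <- vapply(panel$populations,
                  function(p) length(panel_rows(panel, p)), integer(1))
  res <- fst_per_snp(matrix(counts, ncol = length(panel$populations)),
                     sizes, ...)
  cbind(panel$snp[, c("snp_id", "chrom", "pos")], res)
}

#' Unfolded site frequency spectrum of a window
#'
#' @param panel a `HaplotypePanel`.
#' @param window c(start, end) positions (1-based, inclusive); NULL = all.
#' @param population population id (NULL = all haplotypes).
#' @param chrom chromosome (default: first in panel).
#' @return list: n (chromosomes), S (counts S_i of sites with derived count
#'   i = 1..n-1), n_seg, empty flag (no polarized SNPs in the window).
#' @export
unfolded_sfs <- function(panel, window = NULL, population = NULL,
                         chrom = NULL) {
  rows <- panel_rows(panel, population)
  if (is.null(chrom)) chrom <- panel$snp$chrom[1]
  keep <- panel$snp$polarized & panel$snp$chrom == chrom
  if (!is.null(window))
    keep <- keep & panel$snp$pos >= window[1] & panel$snp$pos <= window[2]
  n <- length(rows)
  S <- integer(n - 1L)
  if (any(keep)) {
    cnt <- colSums(panel$haplotypes[rows, keep, drop = FALSE])
    cnt <- cnt[cnt > 0L & cnt < n]
    S <- tabulate(cnt, nbins = n - 1L)
  }
  list(n = n, S = S, n_seg = sum(S), empty = !any(keep))
}

#' Fay-Wu's H from an unfolded SFS
#'
#' theta_pi = sum_i S_i 2 i (n-i) / (n(n-1)); theta_H = sum_i S_i 2 i^2 /
#' (n(n-1)); H = theta_pi - theta_H (unnormalized, as in the original test).
#' Strongly negative H indicates an excess of high-frequency derived
#' alleles, the hitchhiking signature.
#'
#' @param sfs list from [unfolded_sfs()] (fields n, S).
#' @return list: theta_pi, theta_H, H.
#' @export
fay_wu_h <- function(sfs) {
  n <- sfs$n
  if (n < 2L) stop("need n >= 2 chromosomes")
  i <- seq_len(n - 1L)
  denom <- n * (n - 1)
  theta_pi <- sum(sfs$S * 2 * i * (n - i)) / denom
  theta_H <- sum(sfs$S * 2 * i^2) / denom
  list(theta_pi = theta_pi, theta_H = theta_H, H = theta_pi - theta_H)
}

#' Sliding-window Fay-Wu H over a panel
#' @param panel a `HaplotypePanel`.
#' @param population population id (NULL = all).
#' @param window_bp window size in bp (default 50 kb).
#' @param step_bp step in bp (default 10 kb).
#' @param chrom chromosome (default: first in panel).
#' @return data.frame: start, end, n_seg, theta_pi, theta_H, H, empty.
#' @export
windowed_h <- function(panel, population = NULL, window_bp = 50000L,
                       step_bp = 10000L, chrom = NULL) {
  if (is.null(chrom)) chrom <- panel$snp$chrom[1]
  pos <- panel$snp$pos[panel$snp$chrom == chrom]
  starts <- seq(from = min(pos), to = max(pos), by = step_bp)
  res <- lapply(starts, function(s) {
    sfs <- unfolded_sfs(panel, c(s, s + window_bp - 1L), population, chrom)
    h <- fay_wu_h(sfs)
    data.frame(start = s, end = s + window_bp - 1L, n_seg = sfs$n_seg,
               theta_pi = h$theta_pi, theta_H = h$theta_H, H = h$H,
               empty = sfs$empty)
  })
  do.call(rbind, res)
}

# incremental haplotype grouping: returns EHH values at each step outward
.ehh_side <- function(hap, cols, cutoff, force_all = FALSE) {
  c_n <- nrow(hap)
  pairs_tot <- c_n * (c_n - 1) / 2
  g <- rep(1L, c_n)
  ehh <- numeric(length(cols))
  for (k in seq_along(cols)) {
    key <- g * 2L + hap[, cols[k]]
    g <- match(key, unique(key))
    tab <- tabulate(g)
    ehh[k] <- sum(tab * (tab - 1) / 2) / pairs_tot
    if (!force_all && ehh[k] < cutoff) {
      ehh <- ehh[seq_len(k)]
      break
    }
  }
  ehh
}

#' Extended haplotype homozygosity around a core allele
#'
#' EHH at a SNP boundary is the probability that two random haplotypes
#' carrying the core allele are identical from the core out to that SNP:
#' sum_h C(c_h, 2) / C(c, 2) over distinct extended haplotypes among the c
#' carriers. EHH(0) = 1 and the curve is non-increasing outward on each
#' side. iHH is the trapezoidal integral of EHH over physical distance,
#' truncated once EHH drops below `cutoff` (the segment reaching the first
#' sub-cutoff point is included) or at `max_distance`; left and right
#' contributions are summed.
#'
#' @param panel a `HaplotypePanel`.
#' @param core_snp SNP id.
#' @param core_allele "ancestral" (0) or "derived" (1).
#' @param max_distance max distance in bp from the core (default Inf).
#' @param population population id (NULL = all haplotypes).
#' @param cutoff EHH truncation threshold for iHH (default 0.05).
#' @param full_curve compute EHH to max_distance even below cutoff.
#' @return list: curve (data.frame pos, distance (signed bp), ehh), ihh,
#'   n_carriers, undefined flag.
#' @export
ehh <- function(panel, core_snp, core_allele = c("derived", "ancestral"),
                max_distance = Inf, population = NULL, cutoff = 0.05,
                full_curve = FALSE) {
  core_allele <- match.arg(core_allele)
  j <- match(core_snp, panel$snp$snp_id)
  if (is.na(j)) stop("unknown SNP: ", core_snp)
  rows <- panel_rows(panel, population)
  want <- if (core_allele == "derived") 1L else 0L
  carriers <- rows[panel$haplotypes[rows, j] == want]
  if (length(carriers) < 2L)
    return(list(curve = NULL, ihh = NA_real_, n_carriers = length(carriers),
                undefined = TRUE))
  hap <- panel$haplotypes[carriers, , drop = FALSE]
  chrom <- panel$snp$chrom[j]
  pos <- panel$snp$pos
  on_chr <- panel$snp$chrom == chrom
  right <- which(on_chr & pos > pos[j] & pos - pos[j] <= max_distance)
  left <- rev(which(on_chr & pos < pos[j] & pos[j] - pos <= max_distance))
  e_r <- .ehh_side(hap, right, cutoff, full_curve)
  e_l <- .ehh_side(hap, left, cutoff, full_curve)
  curve <- data.frame(
    pos = c(rev(pos[left[seq_along(e_l)]]), pos[j],
            pos[right[seq_along(e_r)]]),
    distance = c(rev(pos[left[seq_along(e_l)]] - pos[j]), 0L,
                 pos[right[seq_along(e_r)]] - pos[j]),
    ehh = c(rev(e_l), 1, e_r))
  ihh <- .ihh_integrate(c(0, pos[right[seq_along(e_r)]] - pos[j]),
                        c(1, e_r), cutoff) +
    .ihh_integrate(c(0, pos[j] - pos[left[seq_along(e_l)]]),
                   c(1, e_l), cutoff)
  list(curve = curve, ihh = ihh, n_carriers = length(carriers),
       undefined = FALSE)
}

# trapezoidal integral of a one-sided EHH curve, truncated after the first
# point below cutoff
.ihh_integrate <- function(d, e, cutoff) {
  if (length(d) < 2L) return(0)
  stop_at <- which(e < cutoff)
  last <- if (length(stop_at)) stop_at[1] else length(d)
  if (last < 2L) return(0)
  idx <- seq_len(last)
  sum(diff(d[idx]) * (utils::head(e[idx], -1) + utils::tail(e[idx], -1)) / 2)
}

#' Integrated haplotype score (iHS) for panel SNPs
#'
#' For each eligible SNP the unstandardized score is ln(iHH_ancestral /
#' iHH_derived); scores are then standardized to mean 0 / SD 1 within
#' derived-allele-frequency bins across the panel. Requires polarized SNPs
#' with both alleles carried by at least 2 haplotypes and derived frequency
#' within [min_maf, 1 - min_maf]. iHH_derived = 0 yields an undefined
#' (flagged) score.
#'
#' @param panel a `HaplotypePanel`.
#' @param population population id (NULL = all haplotypes).
#' @param snps SNP ids to score (default: all eligible).
#' @param n_bins equal-width derived-frequency bins for standardization
#'   (default 20).
#' @param min_maf minor-allele-frequency floor (default 0.05).
#' @param max_distance bp bound for EHH integration (default Inf).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param moments optional per-bin standardization moments from
#'   [ihs_bin_moments()], e.g. computed on a sweep-free (genome-wide)
#'   reference panel. Default: moments of this panel's own scores. A small
#'   simulated region that *is* a sweep locus contaminates its own
#'   frequency bins, so calibration tests standardize against a neutral
#'   reference, mirroring genome-wide empirical standardization.
#' @return data.frame: snp_id, pos, derived_freq, ihh_a, ihh_d,
#'   uns (ln(iHH_A/iHH_D)), bin, ihs (standardized), undefined.
#' @export
ihs <- function(panel, population = NULL, snps = NULL, n_bins = 20L,
                min_maf = 0.05, max_distance = Inf, cutoff = 0.05,
                moments = NULL) {
  rows <- panel_rows(panel, population)
  freq <- colMeans(panel$haplotypes[rows, , drop = FALSE])
  eligible <- panel$snp$polarized & freq >= min_maf & freq <= 1 - min_maf &
    colSums(panel$haplotypes[rows, , drop = FALSE]) >= 2L &
    colSums(1L - panel$haplotypes[rows, , drop = FALSE]) >= 2L
  ids <- panel$snp$snp_id[eligible]
  if (!is.null(snps)) ids <- intersect(ids, snps)
  res <- lapply(ids, function(id) {
    ea <- ehh(panel, id, "ancestral", max_distance, population, cutoff)
    ed <- ehh(panel, id, "derived", max_distance, population, cutoff)
    j <- match(id, panel$snp$snp_id)
    uns <- if (ed$ihh > 0 && ea$ihh > 0) log(ea$ihh / ed$ihh) else NA_real_
    data.frame(snp_id = id, pos = panel$snp$pos[j], derived_freq = freq[j],
               ihh_a = ea$ihh, ihh_d = ed$ihh, uns = uns,
               undefined = is.na(uns))
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) return(res)
  res$bin <- pmin(floor(res$derived_freq * n_bins) + 1L, n_bins)
  if (is.null(moments)) {
    mu <- tapply(res$uns, res$bin, mean, na.rm = TRUE)
    sdv <- tapply(res$uns, res$bin, stats::sd, na.rm = TRUE)
    res$ihs <- as.numeric((res$uns - mu[as.character(res$bin)]) /
                            sdv[as.character(res$bin)])
  } else {
    m <- match(res$bin, moments$bin)
    res$ihs <- (res$uns - moments$mean[m]) / moments$sd[m]
  }
  rownames(res) <- NULL
  res
}

#' Per-bin standardization moments of unstandardized iHS scores
#'
#' Mean and SD of `uns` per derived-frequency bin, computed on a reference
#' (e.g. sweep-free, genome-wide) score table and passed to [ihs()] via
#' `moments`.
#' @param ihs_table data.frame from [ihs()] (columns bin, uns).
#' @return data.frame: bin, mean, sd, n.
#' @export
ihs_bin_moments <- function(ihs_table) {
  sp <- split(ihs_table$uns, ihs_table$bin)
  data.frame(bin = as.integer(names(sp)),
             mean = vapply(sp, mean, numeric(1), na.rm = TRUE),
             sd = vapply(sp, stats::sd, numeric(1), na.rm = TRUE),
             n = lengths(sp), row.names = NULL)
}

#' Background site frequency spectrum for the CLR scan
#'
#' Probability of each derived count 0..n estimated from all SNP columns of
#' the panel in the given population (counts of 0 or n arise for SNPs
#' monomorphic within the population), with Laplace smoothing `pseudo` so no
#' observable count has probability zero.
#'
#' @param panel a `HaplotypePanel`.
#' @param population population id (NULL = all haplotypes).
#' @param pseudo smoothing pseudocount (default 0.5).
#' @return list: n, phi (length n+1, sums to 1).
#' @export
background_sfs <- function(panel, population = NULL, pseudo = 0.5) {
  rows <- panel_rows(panel, population)
  keep <- panel$snp$polarized
  if (!any(keep)) stop("no polarized SNPs for the background SFS")
  cnt <- colSums(panel$haplotypes[rows, keep, drop = FALSE])
  n <- length(rows)
  tab <- tabulate(cnt + 1L, nbins = n + 1L) + pseudo
  list(n = n, phi = tab / sum(tab))
}

#' Composite likelihood ratio sweep scan
#'
#' At each grid position the composite likelihood of the observed per-SNP
#' derived counts is computed under a sweep model in which each of the n
#' lineages escapes the sweep with probability p_e = 1 - exp(-alpha * d)
#' (d = distance to the grid point); escaped lineages keep states drawn from
#' the background SFS configuration, non-escaped lineages carry the swept
#' haplotype's state. alpha is maximized over `alpha_grid`; the grid always
#' includes the null point p_e = 1 (alpha = Inf), so
#' CLR = 2 (ln CL_sweep - ln CL_background) >= 0 with equality at the null.
#'
#' Note on the sign of alpha: escape probability grows with alpha * d, so
#' the no-sweep submodel is the alpha -> Inf limit; small alpha means a wide
#' sweep footprint.
#'
#' @param panel a `HaplotypePanel`.
#' @param population population id (NULL = all haplotypes).
#' @param background list from [background_sfs()] (defaults to the panel-wide
#'   spectrum for the population).
#' @param grid positions (bp) to test (default 25 points across the region).
#' @param alpha_grid decay rates (1/bp); default log-spaced 1e-6..3e-3
#'   plus Inf.
#' @param chrom chromosome (default: first in panel).
#' @return data.frame: pos, clr, alpha_hat; attribute `"argmax"` is the grid
#'   position with the highest CLR.
#' @export
clr_scan <- function(panel, population = NULL, background = NULL,
                     grid = NULL, alpha_grid = NULL, chrom = NULL) {
  rows <- panel_rows(panel, population)
  if (is.null(chrom)) chrom <- panel$snp$chrom[1]
  keep <- panel$snp$polarized & panel$snp$chrom == chrom
  if (!any(keep)) stop("no polarized SNPs on chromosome ", chrom)
  if (is.null(background)) background <- background_sfs(panel, population)
  if (length(background$phi) == 0L || all(background$phi == 0))
    stop("empty background SFS")
  n <- background$n
  phi <- background$phi
  cnt <- colSums(panel$haplotypes[rows, keep, drop = FALSE])
  pos <- panel$snp$pos[keep]
  if (is.null(grid))
    grid <- round(seq(min(pos), max(pos), length.out = 25))
  if (is.null(alpha_grid))
    alpha_grid <- c(10^seq(-6, log10(3e-3), length.out = 10), Inf)
  ll_bg <- sum(log(phi[cnt + 1L]))
  # per-site likelihood under the sweep model: with pre-sweep derived count
  # b0 ~ phi, each lineage escapes independently with probability pe and
  # keeps its original state; the non-escaped lineages all carry the swept
  # haplotype's state (derived with probability b0/n). Marginally,
  #   P(b) = (1 - b0/n) Binom(b; b0, pe) + (b0/n) Binom(n - b; n - b0, pe)
  # which collapses to a point mass at b0 when pe = 1 (the exact null).
  S <- length(cnt)
  b0 <- 0:n
  b0r <- rep(b0, times = S)
  cnt_r <- rep(cnt, each = n + 1L)
  w_anc <- 1 - b0r / n
  w_der <- b0r / n
  phir <- rep(phi, times = S)
  res <- lapply(grid, function(g) {
    d <- abs(pos - g)
    best <- -Inf; best_a <- Inf
    for (a in alpha_grid) {
      pe <- if (is.infinite(a)) rep(1, S) else 1 - exp(-a * d)
      pe_r <- rep(pe, each = n + 1L)
      pr <- w_anc * stats::dbinom(cnt_r, b0r, pe_r) +
        w_der * stats::dbinom(n - cnt_r, n - b0r, pe_r)
      ll <- sum(log(colSums(matrix(phir * pr, nrow = n + 1L))))
      if (ll > best) { best <- ll; best_a <- a }
    }
    data.frame(pos = g, clr = 2 * (best - ll_bg), alpha_hat = best_a)
  })
  res <- do.call(rbind, res)
  # numerical guard: the null point makes true CLR >= 0
  res$clr[res$clr < 0 & res$clr > -1e-8] <- 0
  attr(res, "argmax") <- res$pos[which.max(res$clr)]
  res
}

#' Empirical genome-wide percentile threshold
#'
#' Linear-interpolated empirical quantile (type 7) of a panel-wide statistic
#' distribution, e.g. the 5% extreme value line for Fay-Wu's H.
#' @param values numeric statistic values (>= 20).
#' @param quantile probability in [0,1].
#' @return the threshold value.
#' @export
genome_percentile_threshold <- function(values, quantile = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 20L) stop("need >= 20 values")
  unname(stats::quantile(values, quantile, type = 7))
}
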