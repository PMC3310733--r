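# The headline test: F_ST binning, per-bin enrichment of target-site SNPs
# over the 3'UTR background, a bootstrap null, and the hypergeometric tail
# probability for the extreme bin.

#' Default F_ST bin edges
#'
#' The top bin starts at 0.5 so that it matches the extreme-differentiation
#' criterion F_ST >= 0.5.
#' @export
default_fst_edges <- function() c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 1.0)

#' Assign F_ST values to bins
#'
#' Half-open bins [e_i, e_{i+1}); the last bin is closed at 1. Small negative
#' estimator values clamp to bin 1 (count returned as attribute
#' `"n_clamped"`).
#' @param values F_ST values in [-eps, 1].
#' @param edges strictly increasing edges covering [0, 1].
#' @return integer bin index per value (NA values stay NA).
#' @export
bin_fst <- function(values, edges = default_fst_edges()) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (edges[1] != 0 || edges[length(edges)] != 1)
    stop("edges must cover [0, 1]")
  ok <- !is.na(values)
  if (any(values[ok] > 1)) stop("F_ST value > 1")
  clamped <- ok & values < 0
  v <- pmax(values, 0)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  bin[!ok] <- NA_integer_
  attr(bin, "n_clamped") <- sum(clamped)
  bin
}

#' Per-bin enrichment scores of target SNPs over background
#'
#' E_b = (t_b / T) / (g_b / G): the fraction of target-site SNPs in the bin
#' divided by the fraction of background 3'UTR SNPs in the same bin. Bins
#' with zero background count get NA (flagged).
#' @param target_fst F_ST values of target-site SNPs.
#' @param background_fst F_ST values of background 3'UTR SNPs.
#' @param edges bin edges.
#' @return data.frame: bin, lo, hi, target_count, background_count,
#'   enrichment.
#' @export
enrichment_scores <- function(target_fst, background_fst,
                              edges = default_fst_edges()) {
  if (length(target_fst) == 0L) stop("empty target set")
  if (length(background_fst) == 0L) stop("empty background set")
  nb <- length(edges) - 1L
  tb <- tabulate(bin_fst(target_fst, edges), nbins = nb)
  gb <- tabulate(bin_fst(background_fst, edges), nbins = nb)
  e <- (tb / sum(tb)) / (gb / sum(gb))
  e[gb == 0L] <- NA_real_
  data.frame(bin = seq_len(nb), lo = edges[-length(edges)], hi = edges[-1],
             target_count = tb, background_count = gb, enrichment = e)
}

#' Bootstrap null distribution of the enrichment score
#'
#' Each replicate draws `n_draw` SNPs from the background (without
#' replacement by default) and recomputes E_b; per bin the mean, SD (the
#' error bars) and a percentile interval of the null are reported. Seeded
#' and reproducible.
#' @param background_fst background F_ST values.
#' @param n_draw SNPs per replicate (the observed target-set size).
#' @param n_reps replicates (>= 2; 1000 in the headline analysis).
#' @param edges bin edges.
#' @param seed RNG seed.
#' @param replace draw with replacement (default FALSE).
#' @param level interval coverage (default 0.95).
#' @return data.frame: bin, lo, hi, null_mean, null_sd, null_lo, null_hi.
#' @export
bootstrap_null <- function(background_fst, n_draw, n_reps = 1000L,
                           edges = default_fst_edges(), seed = 1L,
                           replace = FALSE, level = 0.95) {
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (!replace && n_draw > length(background_fst))
    stop("n_draw exceeds background size for without-replacement sampling")
  nb <- length(edges) - 1L
  gb <- tabulate(bin_fst(background_fst, edges), nbins = nb)
  gfrac <- gb / sum(gb)
  E <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      draw <- sample(background_fst, n_draw, replace = replace)
      tb <- tabulate(bin_fst(draw, edges), nbins = nb)
      (tb / n_draw) / gfrac
    }, numeric(nb))
  })
  E <- matrix(E, nrow = nb)
  a <- (1 - level) / 2
  qs <- apply(E, 1L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  data.frame(bin = seq_len(nb), lo = edges[-length(edges)], hi = edges[-1],
             null_mean = rowMeans(E), null_sd = apply(E, 1L, stats::sd),
             null_lo = qs[1, ], null_hi = qs[2, ])
}

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) for X ~ Hypergeom(N, K, n): population N (all 3'UTR SNPs), K
#' marked (target-site SNPs), n drawn (SNPs in the extreme bin), k marked
#' among drawn. Computed by summing pmf terms in log space.
#' @param N population size.
#' @param K marked in population.
#' @param n draw size.
#' @param k observed marked in draw.
#' @return the tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (k < 0 || k > n || n > N || K > N || K < 0)
    stop("inconsistent counts: need 0 <= k <= n <= N and 0 <= K <= N")
  if (k == 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  x <- k:hi
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  lp <- lp[is.finite(lp)]
  if (!length(lp)) return(0)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Filter calls to high-differentiation candidate SNPs
#'
#' SNPs with an allele-dependent site call (verdict disrupting or creating)
#' and F_ST at or above the threshold.
#' @param calls data.frame from [scan_alleles()].
#' @param fst_table data.frame with snp_id and fst.
#' @param threshold F_ST cutoff (default 0.5).
#' @return list: `snps` (candidate snp ids), `genes` (deduplicated gene
#'   ids), `calls` (the retained call rows with fst attached).
#' @export
candidate_filter <- function(calls, fst_table, threshold = 0.5) {
  keep <- calls$verdict %in% c("disrupting", "creating")
  sub <- calls[keep, , drop = FALSE]
  sub$fst <- fst_table$fst[match(sub$snp_id, fst_table$snp_id)]
  sub <- sub[!is.na(sub$fst) & sub$fst >= threshold, , drop = FALSE]
  list(snps = unique(sub$snp_id), genes = unique(sub$gene_id), calls = sub)
}
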