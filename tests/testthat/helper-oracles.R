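# Independent brute-force oracles. These re-derive every statistic from its
# definition (loops, enumeration, pairwise comparison) without sharing code
# with the implementation under test.

# --- Weir-Cockerham theta-hat, transcribed loop-by-loop -------------------
oracle_fst_wc <- function(counts, sizes) {
  r <- length(counts)
  p <- counts / sizes
  n_bar <- mean(sizes)
  n_c <- (r * n_bar - sum(sizes^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(sizes * p) / (r * n_bar)
  s2 <- sum(sizes * (p - p_bar)^2) / ((r - 1) * n_bar)
  pq <- p_bar * (1 - p_bar)
  a <- (n_bar / n_c) * (s2 - (pq - s2 * (r - 1) / r) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * (pq - s2 * (r - 1) / r)
  a / (a + b)
}

# --- Fay-Wu H from a raw 0/1 window matrix --------------------------------
# theta_pi by literal average pairwise difference; theta_H by the
# definitional per-site weight.
oracle_fay_wu_h <- function(mat) {
  cnt <- colSums(mat)
  n <- nrow(mat)
  mat <- mat[, cnt > 0 & cnt < n, drop = FALSE]   # segregating sites only
  diffs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + sum(mat[i, ] != mat[j, ])
  theta_pi <- diffs / choose(n, 2)
  cnt <- colSums(mat)
  theta_H <- sum(2 * cnt^2 / (n * (n - 1)))
  theta_pi - theta_H
}

# --- EHH as the literal share of identical haplotype pairs ----------------
oracle_ehh <- function(carrier_mat, cols) {
  n <- nrow(carrier_mat)
  same <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (all(carrier_mat[i, cols] == carrier_mat[j, cols])) same <- same + 1
  same / choose(n, 2)
}

# --- pairwise LD from definitions -----------------------------------------
oracle_ld <- function(x, y) {
  n <- length(x)
  pA <- mean(x); pB <- mean(y)
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  cells <- c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
             sum(x == 0 & y == 1), sum(x == 0 & y == 0))
  probs <- cells / n
  exp_p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  nz <- cells > 0
  lod <- sum(cells[nz] * (log10(probs[nz]) - log10(exp_p[nz])))
  list(D = D, D_prime = if (D == 0) 0 else D / d_max, r2 = r2, lod = lod)
}

# --- hypergeometric upper tail by direct pmf summation --------------------
oracle_hypergeom_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  tot <- 0
  for (x in k:min(n, K)) {
    term <- choose(K, x) * choose(N - K, n - x) / choose(N, n)
    tot <- tot + term
  }
  tot
}

# --- type-7 quantile by sorting and interpolation -------------------------
oracle_quantile <- function(values, q) {
  v <- sort(values)
  h <- (length(v) - 1) * q
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  v[lo] + (h - floor(h)) * (v[hi] - v[lo])
}

# --- exhaustive seed-site classifier --------------------------------------
# Tests every substring position against every class definition by per-base
# complementarity (antiparallel pairing), in priority order.
oracle_classify <- function(sequence, seed, allow_6mer = FALSE) {
  sq <- strsplit(toupper(sequence), "")[[1]]
  sd <- strsplit(toupper(seed), "")[[1]]     # positions 2..8
  pair <- c(A = "T", C = "G", G = "C", U = "A")
  matches_k <- function(s, k, sub) {
    # seed sub-window `sub` (indices into sd, 5'->3'); site length k
    for (j in seq_len(k)) {
      need <- pair[[sd[sub[k + 1 - j]]]]
      if (s + j - 1 > length(sq) || sq[s + j - 1] != need) return(FALSE)
    }
    TRUE
  }
  find_first <- function(k, sub, need_A) {
    for (s in seq_len(length(sq))) {
      if (s + k - 1 + as.integer(need_A) > length(sq)) break
      if (matches_k(s, k, sub)) {
        if (!need_A || sq[s + k] == "A") return(s - 1L)
      }
    }
    NA_integer_
  }
  checks <- list(
    list(type = "8mer", k = 7L, sub = 1:7, need_A = TRUE, len = 8L),
    list(type = "7mer-m8", k = 7L, sub = 1:7, need_A = FALSE, len = 7L),
    list(type = "7mer-A1", k = 6L, sub = 1:6, need_A = TRUE, len = 7L),
    list(type = "6mer", k = 6L, sub = 1:6, need_A = FALSE, len = 6L))
  if (!allow_6mer) checks <- checks[1:3]
  for (ch in checks) {
    s <- find_first(ch$k, ch$sub, ch$need_A)
    if (!is.na(s)) return(list(type = ch$type, start = s, length = ch$len))
  }
  list(type = "none", start = NA_integer_, length = NA_integer_)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
random_seed_rna <- function() paste(sample(c("A", "C", "G", "U"), 7,
                                           replace = TRUE), collapse = "")

# small random panel for property tests
random_panel <- function(n_hap = 20L, n_snp = 12L, n_pop = 1L,
                         polarized = TRUE) {
  hap <- matrix(rbinom(n_hap * n_pop * n_snp, 1L, runif(1, 0.2, 0.8)),
                nrow = n_hap * n_pop)
  # ensure panel-wide polymorphism
  for (j in seq_len(n_snp)) {
    if (sum(hap[, j]) == 0L) hap[sample(nrow(hap), 1L), j] <- 1L
    if (sum(hap[, j]) == nrow(hap)) hap[sample(nrow(hap), 1L), j] <- 0L
  }
  pos <- sort(sample.int(n_snp * 1000L, n_snp))
  snp <- data.frame(snp_id = sprintf("s%03d", seq_len(n_snp)), chrom = "1",
                    pos = pos, ref = "A", alt = "G",
                    ancestral = if (polarized) "A" else NA_character_,
                    polarized = polarized, functional = FALSE,
                    stringsAsFactors = FALSE)
  pops <- paste0("P", seq_len(n_pop))
  haplotype_panel(hap, snp,
                  hap_sample = paste0("S", seq_len(n_hap * n_pop)),
                  hap_population = rep(pops, each = n_hap))
}
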