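# popgen_stats: F_ST, SFS/Fay-Wu H, EHH/iHS, CLR, empirical thresholds.

test_that("Weir-Cockerham F_ST: degenerate cases and dual-implementation oracle", {
  # no differentiation
  r <- fst_per_snp(matrix(c(50, 50), 1), c(100, 100))
  expect_lt(abs(r$fst), 0.02)
  # populations fixed for alternate alleles -> theta = 1
  r1 <- fst_per_snp(matrix(c(100, 0), 1), c(100, 100))
  expect_equal(r1$fst, 1)
  # printed example against the independent transcription
  r2 <- fst_per_snp(matrix(c(30, 70), 1), c(100, 100))
  expect_equal(r2$fst, oracle_fst_wc(c(30, 70), c(100, 100)),
               tolerance = 1e-14)
  # monomorphic across populations: flagged NA, not zero
  r3 <- fst_per_snp(matrix(c(0, 0), 1), c(100, 100))
  expect_true(is.na(r3$fst) && r3$monomorphic)
  expect_error(fst_per_snp(matrix(5, 1, 1), 10), ">= 2 populations")
})

test_that("F_ST properties: random configs, label invariance, hudson agreement", {
  set.seed(201)
  for (i in 1:200) {
    r <- sample(2:5, 1)
    sizes <- sample(4:80, r, replace = TRUE) * 2
    counts <- vapply(sizes, function(n) sample(0:n, 1), numeric(1))
    if (sum(counts) == 0 || sum(sizes - counts) == 0) next
    got <- fst_per_snp(matrix(counts, 1), sizes)$fst
    expect_equal(got, oracle_fst_wc(counts, sizes), tolerance = 1e-12)
    # allele-label swap leaves theta unchanged
    swapped <- fst_per_snp(matrix(sizes - counts, 1), sizes)$fst
    expect_equal(got, swapped, tolerance = 1e-12)
  }
  h <- fst_per_snp(matrix(c(90, 10), 1), c(100, 100), estimator = "hudson")
  expect_true(is.finite(h$fst) && h$fst > 0.5)
})

test_that("unfolded SFS: direct tally, conservation, brute force", {
  set.seed(202)
  p <- random_panel(n_hap = 4L, n_snp = 1L)
  p$haplotypes[, 1] <- c(1L, 1L, 1L, 0L)
  sfs <- unfolded_sfs(p)
  expect_equal(sfs$S, c(0L, 0L, 1L))
  for (i in 1:20) {
    q <- random_panel(n_hap = sample(c(6L, 10L), 1), n_snp = 10L)
    s <- unfolded_sfs(q)
    cnt <- colSums(q$haplotypes)
    expect_equal(s$n_seg, sum(cnt > 0 & cnt < s$n))
    brute <- sapply(seq_len(s$n - 1), function(k) sum(cnt == k))
    expect_equal(s$S, unname(brute))
  }
  # window with no polarized SNPs: all-zero, flagged
  q <- random_panel(polarized = FALSE)
  s0 <- unfolded_sfs(q)
  expect_true(s0$empty)
  expect_true(all(s0$S == 0))
})

test_that("Fay-Wu H: definitional values and permutation invariance", {
  h0 <- fay_wu_h(list(n = 10L, S = rep(0L, 9)))
  expect_equal(h0$H, 0)
  # n = 4, one site at derived count 1: theta_pi = 0.5, theta_H = 1/6
  h1 <- fay_wu_h(list(n = 4L, S = c(1L, 0L, 0L)))
  expect_equal(h1$theta_pi, 0.5)
  expect_equal(h1$theta_H, 1 / 6)
  expect_equal(h1$H, 1 / 3)
  # n = 4, one site at derived count 3: H = 0.5 - 1.5 = -1
  h3 <- fay_wu_h(list(n = 4L, S = c(0L, 0L, 1L)))
  expect_equal(h3$H, -1)
  expect_error(fay_wu_h(list(n = 1L, S = integer(0))), "n >= 2")

  set.seed(203)
  for (i in 1:30) {
    q <- random_panel(n_hap = 8L, n_snp = 12L)
    H <- fay_wu_h(unfolded_sfs(q))$H
    expect_equal(H, oracle_fay_wu_h(q$haplotypes), tolerance = 1e-12)
    # row permutation leaves H unchanged
    q2 <- q; q2$haplotypes <- q$haplotypes[sample(8), ]
    expect_equal(fay_wu_h(unfolded_sfs(q2))$H, H)
  }
})

test_that("EHH: definition, worked 2/2 split, pairwise oracle, monotonicity", {
  set.seed(204)
  # 4 carriers splitting 2/2 at the adjacent SNP -> EHH = 1/3
  hap <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  snp <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                    pos = c(100L, 200L, 300L), ref = "A", alt = "G",
                    ancestral = "A", polarized = TRUE, functional = FALSE)
  p <- haplotype_panel(hap, snp, hap_sample = paste0("s", 1:4),
                       hap_population = rep("P1", 4))
  e <- ehh(p, "a", "derived", full_curve = TRUE)
  expect_equal(e$curve$ehh[e$curve$distance == 0], 1)
  expect_equal(e$curve$ehh[e$curve$distance == 100], 1 / 3)
  expect_equal(e$curve$ehh[e$curve$distance == 200],
               oracle_ehh(hap, 2:3))
  # all carriers identical -> EHH = 1 everywhere
  hap1 <- hap; hap1[, 2:3] <- 0L
  p1 <- haplotype_panel(hap1, snp, paste0("s", 1:4), rep("P1", 4))
  e1 <- ehh(p1, "a", "derived", full_curve = TRUE)
  expect_true(all(e1$curve$ehh == 1))
  # < 2 carriers: flagged undefined
  hap2 <- hap; hap2[, 1] <- c(1L, 0L, 0L, 0L)
  p2 <- haplotype_panel(hap2, snp, paste0("s", 1:4), rep("P1", 4))
  expect_true(ehh(p2, "a", "derived")$undefined)

  for (i in 1:40) {
    q <- random_panel(n_hap = 12L, n_snp = 10L)
    core <- sample(q$snp$snp_id, 1)
    allele <- sample(c("derived", "ancestral"), 1)
    e <- ehh(q, core, allele, full_curve = TRUE)
    if (e$undefined) next
    j <- match(core, q$snp$snp_id)
    want <- if (allele == "derived") 1L else 0L
    carr <- q$haplotypes[q$haplotypes[, j] == want, , drop = FALSE]
    for (k in seq_len(nrow(e$curve))) {
      d <- e$curve$distance[k]
      cols <- if (d > 0) which(q$snp$pos > q$snp$pos[j] &
                                 q$snp$pos <= q$snp$pos[j] + d)
      else if (d < 0) which(q$snp$pos < q$snp$pos[j] &
                              q$snp$pos >= q$snp$pos[j] + d)
      else integer(0)
      if (!length(cols)) next
      expect_equal(e$curve$ehh[k], oracle_ehh(carr, cols),
                   tolerance = 1e-12)
    }
    # monotone non-increasing outward on each side
    right <- e$curve$ehh[e$curve$distance >= 0]
    left <- rev(e$curve$ehh[e$curve$distance <= 0])
    expect_true(all(diff(right) <= 1e-12))
    expect_true(all(diff(left) <= 1e-12))
    # iHH invariant to haplotype row order
    q2 <- q; q2$haplotypes <- q$haplotypes[sample(nrow(q$haplotypes)), ]
    expect_equal(ehh(q2, core, allele, full_curve = TRUE)$ihh, e$ihh)
  }
})

test_that("iHS: symmetry zero, per-bin standardization moments", {
  # ancestral and derived carrier sets with mirrored decay -> uns = 0
  hap <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L), c(0L, 1L, 0L))
  snp <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                    pos = c(100L, 200L, 300L), ref = "A", alt = "G",
                    ancestral = "A", polarized = TRUE, functional = FALSE)
  p <- haplotype_panel(hap, snp, paste0("s", 1:4), rep("P1", 4))
  ea <- ehh(p, "a", "ancestral", full_curve = TRUE)
  ed <- ehh(p, "a", "derived", full_curve = TRUE)
  expect_equal(ea$ihh, ed$ihh)

  set.seed(205)
  sim <- simulate_panel(sim_config(n_populations = 1L,
                                   samples_per_population = 40L,
                                   n_snps = 150L, drift_F = 0.1,
                                   region_length_bp = 300000L,
                                   rng_seed = 31L))
  tab <- ihs(sim$panel)
  ok <- !is.na(tab$ihs)
  for (b in unique(tab$bin[ok])) {
    v <- tab$ihs[ok & tab$bin == b]
    if (length(v) < 2) next
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(stats::sd(v) - 1), 1e-3)
  }
  mom <- ihs_bin_moments(tab)
  tab2 <- ihs(sim$panel, moments = mom)
  expect_equal(tab2$ihs, tab$ihs, tolerance = 1e-12)
})

test_that("CLR: nested-null exactness, non-negativity, sweep localization", {
  sim <- simulate_panel(sim_config(n_populations = 1L,
                                   samples_per_population = 30L,
                                   n_snps = 120L, drift_F = 0.1,
                                   region_length_bp = 400000L,
                                   rng_seed = 41L))
  p <- sim$panel
  # the null submodel (escape probability identically 1) gives CLR = 0
  null_scan <- clr_scan(p, grid = c(100000, 200000), alpha_grid = Inf)
  expect_equal(null_scan$clr, c(0, 0))
  sc <- clr_scan(p)
  expect_true(all(sc$clr >= 0))

  mid <- p$snp$pos[which.min(abs(p$snp$pos - 200000))]
  sw <- inject_sweep(p, mid, "POP1", final_derived_freq = 1,
                     homogenization_radius_bp = 80000L, seed = 42L)$panel
  scs <- clr_scan(sw)
  expect_gt(max(scs$clr), max(sc$clr))
  expect_lt(abs(attr(scs, "argmax") - mid), 80000L)

  unpol <- p; unpol$snp$polarized <- FALSE
  expect_error(clr_scan(unpol), "polarized|background")
})

test_that("forced total sweep gives EHH 1 across the homogenized radius", {
  sim <- simulate_panel(sim_config(n_populations = 1L,
                                   samples_per_population = 20L,
                                   n_snps = 60L, drift_F = 0.1,
                                   region_length_bp = 100000L,
                                   rng_seed = 43L))
  p <- sim$panel
  mid <- p$snp$pos[30]
  sw <- inject_sweep(p, mid, "POP1", final_derived_freq = 1,
                     homogenization_radius_bp = 200000L, seed = 44L)$panel
  sid <- sw$snp$snp_id[30]
  e <- ehh(sw, sid, "derived", full_curve = TRUE)
  expect_true(all(e$curve$ehh == 1))
})

test_that("genome percentile threshold: interpolation and oracle", {
  thr <- genome_percentile_threshold(1:100, 0.05)
  expect_gt(thr, 5); expect_lt(thr, 6)
  expect_equal(thr, oracle_quantile(1:100, 0.05))
  expect_equal(genome_percentile_threshold(rep(3.5, 25), 0.05), 3.5)
  set.seed(206)
  for (i in 1:30) {
    v <- rnorm(sample(20:200, 1))
    q <- runif(1)
    expect_equal(genome_percentile_threshold(v, q), oracle_quantile(v, q),
                 tolerance = 1e-12)
  }
  expect_error(genome_percentile_threshold(1:5, 0.05), ">= 20")
})
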