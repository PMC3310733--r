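# synthetic_data: generator invariants -- reproducibility, Balding-Nichols
# limits, sweep construction, planted sites, clines.

test_that("simulate_panel is a pure function of (config, seed)", {
  cfg <- sim_config(n_snps = 120L, rng_seed = 61L,
                    samples_per_population = 10L,
                    region_length_bp = 120000L)
  a <- simulate_panel(cfg); b <- simulate_panel(cfg)
  expect_identical(a$panel$haplotypes, b$panel$haplotypes)
  expect_identical(a$panel$snp, b$panel$snp)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$rng_seed <- 62L
  c2 <- simulate_panel(cfg2)
  expect_false(identical(a$panel$haplotypes, c2$panel$haplotypes))
  # global RNG stream untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulate_panel(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("drift_F -> 0 limit: population frequencies hug the ancestral one", {
  sim <- simulate_panel(sim_config(n_snps = 1500L, drift_F = 0.001,
                                   rng_seed = 63L,
                                   region_length_bp = 1500000L))
  tr <- sim$truth
  # Beta SD at F = 0.001 is ~0.016 at p = 0.5: the mean deviation collapses
  expect_lt(mean(abs(tr$p_POP1 - tr$p_anc)), 0.02)
  expect_lt(max(abs(tr$p_POP1 - tr$p_anc)), 0.10)
  f <- panel_fst(sim$panel)
  expect_lt(abs(fst_multilocus(f)), 0.02)
  expect_lt(mean(abs(f$fst), na.rm = TRUE), 0.02)
})

test_that("panel structure: 0/1 entries, ordered positions, no monomorphics", {
  sim <- simulate_panel(sim_config(n_snps = 200L, rng_seed = 64L,
                                   region_length_bp = 300000L))
  p <- sim$panel
  expect_true(all(p$haplotypes %in% c(0L, 1L)))
  expect_true(all(diff(p$snp$pos) > 0))
  cs <- colSums(p$haplotypes)
  expect_true(all(cs > 0 & cs < nrow(p$haplotypes)))
  expect_true(all(p$snp$ancestral %in% c(p$snp$ref, p$snp$alt)))
})

test_that("inject_sweep: radius 0 touches only the sweep column; freq guard", {
  sim <- simulate_panel(sim_config(n_populations = 1L, n_snps = 80L,
                                   samples_per_population = 20L,
                                   rng_seed = 65L,
                                   region_length_bp = 100000L))
  p <- sim$panel
  freq <- colMeans(p$haplotypes)
  j <- which(freq > 0.2 & freq < 0.5)[1]
  mid <- p$snp$pos[j]
  sw <- inject_sweep(p, mid, "POP1", final_derived_freq = 0.8,
                     homogenization_radius_bp = 0L, seed = 66L)
  expect_equal(mean(sw$panel$haplotypes[, j]), 0.8)
  expect_identical(sw$panel$haplotypes[, -j], p$haplotypes[, -j])
  expect_error(inject_sweep(p, mid, "POP1", final_derived_freq = 0.1,
                            homogenization_radius_bp = 0L),
               "below the current")
  expect_error(inject_sweep(p, mid + 1L, "POP1", 0.9, 0L),
               "exactly one SNP")
  # truth records the converted haplotypes
  expect_true(all(p$haplotypes[sw$truth$converted_rows, j] == 0L))
  expect_true(all(sw$panel$haplotypes[sw$truth$converted_rows, j] == 1L))
})

test_that("plant_utr_sites: by-construction recovery and option handling", {
  sim <- simulate_panel(sim_config(n_snps = 300L, rng_seed = 67L,
                                   samples_per_population = 10L,
                                   region_length_bp = 900000L))
  fams <- random_families(8, seed = 68L)
  pl <- plant_utr_sites(sim$panel, fams, n_sites = 12L,
                        n_background_snps = 10L, seed = 69L)
  expect_equal(nrow(pl$truth), 12L)
  # scan the emitted UTRs: exactly the planted calls come back
  fa <- tempfile(); write_utr_fasta(pl$utr_table, fa)
  utrs <- read_utrs(fa, pl$panel$snp)
  win <- do.call(rbind, lapply(utrs, build_windows))
  da <- stats::setNames(pl$panel$snp$ancestral == pl$panel$snp$ref,
                        pl$panel$snp$snp_id)
  calls <- scan_alleles(win, fams, derived_is_alt = da)
  poly <- calls[calls$verdict %in% c("disrupting", "creating"), ]
  key <- function(d) paste(d$snp_id, d$family_id, d$verdict)
  expect_setequal(key(poly), key(pl$truth))
  # all-disrupting mix
  pl2 <- plant_utr_sites(sim$panel, fams, n_sites = 8L,
                         fraction_allele_disrupting = 1,
                         n_background_snps = 0L, seed = 70L)
  expect_true(all(pl2$truth$verdict == "disrupting"))
  expect_true(all(pl2$truth$intact_allele == "ancestral"))
  # infeasible request errors
  expect_error(plant_utr_sites(sim$panel, fams, n_sites = 5000L,
                               seed = 71L), "cannot place")
  expect_error(plant_utr_sites(sim$panel, fams[0, ], n_sites = 2L),
               "non-empty")
})

test_that("plant_latitude_cline: exact cline at zero noise, centered null", {
  meta <- data.frame(population_id = sprintf("H%02d", 1:20),
                     n_samples = 20L,
                     absolute_latitude = seq(0, 57, 3),
                     excluded = FALSE, reason = ".",
                     stringsAsFactors = FALSE)
  cl <- plant_latitude_cline(meta, cline_slope = -0.01, n_cline_snps = 5L,
                             n_null_snps = 400L, noise_sd = 0,
                             seed = 72L)
  R <- apply(cl$freqs[1:5, ], 1, function(f)
    stats::cor(f, meta$absolute_latitude))
  expect_true(all(abs(R + 1) < 1e-12))
  Rnull <- apply(cl$freqs[-(1:5), ], 1, function(f)
    stats::cor(f, meta$absolute_latitude))
  expect_lt(abs(mean(Rnull)), 0.05)
  expect_error(plant_latitude_cline(meta[1:2, ]), "at least 3")
  # same seed, identical output
  cl2 <- plant_latitude_cline(meta, cline_slope = -0.01, n_cline_snps = 5L,
                              n_null_snps = 400L, noise_sd = 0, seed = 72L)
  expect_identical(cl$freqs, cl2$freqs)
})
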