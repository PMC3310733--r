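# Ground-truth-annotated input generator. The generator emulates the
# statistical structure the analysis assumes -- multi-population
# differentiation (Balding-Nichols Beta model with drift parameter F),
# distance-decaying LD, structurally injected selective sweeps,
# SNP-overlapping seed-match sites, and latitude clines -- at desk scale,
# with the truth emitted separately from the pipeline inputs.
#
# Haplotype LD comes from a Gaussian AR(1) copula: each haplotype carries an
# independent latent autoregressive process along the SNP sequence
# (step correlation exp(-rate * distance)) thresholded at the population
# allele frequency. Haplotypes are therefore mutually independent with exact
# Bernoulli(p_pop) marginals, which keeps the Weir-Cockerham F_ST
# calibration unbiased, while within-haplotype autocorrelation yields r^2
# decaying with distance.

#' Simulation configuration
#'
#' @param n_populations number of populations (default 2).
#' @param samples_per_population diploid samples per population (default 50).
#' @param n_snps SNP count before monomorphic-column dropping (default 1000).
#' @param drift_F Balding-Nichols differentiation parameter in (0,1)
#'   (default 0.1); per-population frequencies are Beta with mean p and
#'   variance F p (1-p).
#' @param recombination_rate_per_bp decay rate of the latent haplotype
#'   autocorrelation, exp(-rate * distance) (default 5e-5: r^2 halves over
#'   roughly 15 kb).
#' @param region_length_bp simulated region length (default 500,000).
#' @param rng_seed integer seed; identical seed, identical outputs.
#' @param anc_freq_range ancestral frequencies are uniform on this interval
#'   (default c(0.05, 0.95), avoiding mostly-monomorphic columns).
#' @param chrom chromosome label (default "1").
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_populations = 2L, samples_per_population = 50L,
                       n_snps = 1000L, drift_F = 0.1,
                       recombination_rate_per_bp = 5e-5,
                       region_length_bp = 500000L, rng_seed = 1L,
                       anc_freq_range = c(0.05, 0.95), chrom = "1") {
  stopifnot(drift_F > 0, drift_F < 1, n_populations >= 1,
            samples_per_population >= 1, n_snps >= 1,
            region_length_bp >= n_snps)
  structure(list(n_populations = as.integer(n_populations),
                 samples_per_population = as.integer(samples_per_population),
                 n_snps = as.integer(n_snps), drift_F = drift_F,
                 recombination_rate_per_bp = recombination_rate_per_bp,
                 region_length_bp = as.integer(region_length_bp),
                 rng_seed = as.integer(rng_seed),
                 anc_freq_range = anc_freq_range, chrom = chrom),
            class = "SimConfig")
}

#' Simulate a multi-population haplotype panel
#'
#' Ancestral frequencies are uniform on `anc_freq_range`; per-population
#' frequencies follow the Balding-Nichols Beta(p(1-F)/F, (1-p)(1-F)/F)
#' model; haplotypes are independent AR(1)-copula draws (see the module
#' header). Columns monomorphic across the whole panel are dropped and
#' counted (attribute `"n_monomorphic_dropped"`).
#'
#' @param config a `SimConfig`.
#' @return list: `panel` (a `HaplotypePanel`, coding 1 = derived) and
#'   `truth` (data.frame of true ancestral and per-population frequencies).
#' @export
simulate_panel <- function(config) {
  with_seed(config$rng_seed, {
    npop <- config$n_populations
    nh <- 2L * config$samples_per_population
    S <- config$n_snps
    pos <- sort(sample.int(config$region_length_bp, S))
    p_anc <- stats::runif(S, config$anc_freq_range[1], config$anc_freq_range[2])
    FF <- config$drift_F
    shape_scale <- (1 - FF) / FF
    p_pop <- matrix(0, nrow = npop, ncol = S)
    for (k in seq_len(npop))
      p_pop[k, ] <- stats::rbeta(S, p_anc * shape_scale,
                                 (1 - p_anc) * shape_scale)
    rho <- exp(-config$recombination_rate_per_bp * diff(pos))
    hap <- matrix(0L, nrow = npop * nh, ncol = S)
    for (k in seq_len(npop)) {
      z <- matrix(0, nrow = nh, ncol = S)
      z[, 1] <- stats::rnorm(nh)
      for (j in 2:S)
        z[, j] <- rho[j - 1] * z[, j - 1] +
          sqrt(1 - rho[j - 1]^2) * stats::rnorm(nh)
      thr <- stats::qnorm(p_pop[k, ])
      hap[(k - 1L) * nh + seq_len(nh), ] <-
        (z < matrix(thr, nrow = nh, ncol = S, byrow = TRUE)) + 0L
    }
    keep <- colSums(hap) > 0L & colSums(hap) < nrow(hap)
    n_drop <- sum(!keep)
    hap <- hap[, keep, drop = FALSE]
    pos <- pos[keep]; p_anc <- p_anc[keep]
    p_pop <- p_pop[, keep, drop = FALSE]
    S <- sum(keep)
    anc_base <- sample(DNA_BASES, S, replace = TRUE)
    der_base <- vapply(anc_base, function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    anc_is_ref <- stats::runif(S) < 0.5
    pops <- paste0("POP", seq_len(npop))
    snp <- data.frame(
      snp_id = sprintf("snp%05d", seq_len(S)),
      chrom = config$chrom, pos = pos,
      ref = ifelse(anc_is_ref, anc_base, der_base),
      alt = ifelse(anc_is_ref, der_base, anc_base),
      ancestral = anc_base, polarized = TRUE, functional = FALSE,
      stringsAsFactors = FALSE)
    samples <- paste0(rep(pops, each = config$samples_per_population), "_S",
                      rep(seq_len(config$samples_per_population), npop))
    panel <- haplotype_panel(
      hap, snp,
      hap_sample = rep(samples, each = 2L),
      hap_population = rep(pops, each = nh))
    truth <- data.frame(snp_id = snp$snp_id, pos = pos, p_anc = p_anc,
                        t(p_pop), stringsAsFactors = FALSE)
    names(truth)[-(1:3)] <- paste0("p_", pops)
    attr(panel, "n_monomorphic_dropped") <- n_drop
    list(panel = panel, truth = truth)
  })
}

#' Inject a selective sweep into a panel
#'
#' In the target population the derived allele at the sweep SNP is raised to
#' `final_derived_freq` by converting randomly chosen non-carriers; every
#' post-conversion carrier is homogenized onto a single donor haplotype
#' within `homogenization_radius_bp`, creating extended homozygosity and an
#' excess of high-frequency derived alleles around the sweep.
#'
#' @param panel a `HaplotypePanel`.
#' @param sweep_pos position (bp) of an existing SNP column.
#' @param target_population population id.
#' @param final_derived_freq target derived frequency in (0, 1].
#' @param homogenization_radius_bp bp radius homogenized around the sweep
#'   (0 = allele frequency changes only).
#' @param seed integer seed.
#' @return list: `panel` (modified) and `truth` (sweep snp_id, donor sample,
#'   converted haplotype row indices).
#' @export
inject_sweep <- function(panel, sweep_pos, target_population,
                         final_derived_freq = 0.9,
                         homogenization_radius_bp = 100000L, seed = 1L) {
  stopifnot(final_derived_freq > 0, final_derived_freq <= 1)
  j <- which(panel$snp$pos == sweep_pos &
               panel$snp$chrom == panel$snp$chrom[1])
  if (length(j) != 1L)
    stop("sweep position must match exactly one SNP column")
  rows <- panel_rows(panel, target_population)
  with_seed(seed, {
    carriers <- rows[panel$haplotypes[rows, j] == 1L]
    n_target <- max(1L, round(final_derived_freq * length(rows)))
    if (n_target < length(carriers))
      stop("final_derived_freq below the current derived frequency")
    if (length(carriers) == 0L) {
      donor <- sample(rows, 1L)
      panel$haplotypes[donor, j] <- 1L
      carriers <- donor
    }
    donor <- if (length(carriers) == 1L) carriers else sample(carriers, 1L)
    non <- setdiff(rows, carriers)
    converted <- if (n_target > length(carriers))
      sample(non, n_target - length(carriers)) else integer(0)
    panel$haplotypes[converted, j] <- 1L
    all_carriers <- c(carriers, converted)
    cols <- which(panel$snp$chrom == panel$snp$chrom[j] &
                    abs(panel$snp$pos - sweep_pos) <= homogenization_radius_bp)
    if (length(cols))
      panel$haplotypes[all_carriers, cols] <-
        matrix(panel$haplotypes[donor, cols], nrow = length(all_carriers),
               ncol = length(cols), byrow = TRUE)
    truth <- list(sweep_snp = panel$snp$snp_id[j], sweep_pos = sweep_pos,
                  population = target_population,
                  donor_row = donor, converted_rows = converted,
                  radius_bp = homogenization_radius_bp,
                  final_derived_freq = final_derived_freq)
    list(panel = panel, truth = truth)
  })
}

#' Random miRNA family table
#' @param n_families number of families (default 30).
#' @param seed integer seed.
#' @return data.frame usable wherever [read_mirna_families()] output is.
#' @export
random_families <- function(n_families = 30L, seed = 1L) {
  with_seed(seed, {
    seeds <- character(0)
    while (length(seeds) < n_families) {
      s <- paste(sample(c("A", "C", "G", "U"), 7L, replace = TRUE),
                 collapse = "")
      if (!s %in% seeds) seeds <- c(seeds, s)
    }
    data.frame(family_id = sprintf("fam%03d", seq_len(n_families)),
               seed = seeds,
               members = sprintf("mir-%03d-a,mir-%03d-b",
                                 seq_len(n_families), seq_len(n_families)),
               stringsAsFactors = FALSE)
  })
}

#' Force per-population derived frequencies at chosen SNPs
#'
#' Redraws the selected columns so each population's derived count is
#' exactly round(freq * n); used to plant high-F_ST loci. Local LD at the
#' redrawn columns is destroyed (acceptable for frequency-based tests).
#' @param panel a `HaplotypePanel`.
#' @param snp_ids SNPs to overwrite.
#' @param freqs matrix length(snp_ids) x populations of target derived
#'   frequencies.
#' @param seed integer seed.
#' @return the modified panel.
#' @export
force_differentiation <- function(panel, snp_ids, freqs, seed = 1L) {
  freqs <- matrix(freqs, nrow = length(snp_ids))
  with_seed(seed, {
    for (i in seq_along(snp_ids)) {
      j <- match(snp_ids[i], panel$snp$snp_id)
      if (is.na(j)) stop("unknown SNP: ", snp_ids[i])
      for (k in seq_along(panel$populations)) {
        rows <- panel_rows(panel, panel$populations[k])
        cnt <- round(freqs[i, k] * length(rows))
        v <- rep(0L, length(rows))
        if (cnt > 0L) v[sample(length(rows), cnt)] <- 1L
        panel$haplotypes[rows, j] <- v
      }
    }
    panel
  })
}

.sample_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# positions (1-based, within the site pattern) where a SNP breaks every
# accepted class: inside the hexamer shared by all classes
.core_positions <- function(site_type) {
  switch(site_type,
         "8mer" = 2:7, "7mer-m8" = 2:7,
         "7mer-A1" = 1:6, "6mer" = 1:6,
         stop("unknown site type: ", site_type))
}

#' Plant allele-dependent miRNA seed sites into synthetic 3'UTRs
#'
#' For each planted site one UTR is generated whose sequence carries, at the
#' chosen SNP's offset, one allele completing a seed match of the requested
#' type while the other allele breaks it. Flanks are rejection-sampled until
#' an allele-aware scan of the SNP's 15-nt window against *all* supplied
#' families yields exactly the planted call, so recovery is exact by
#' construction. Additional background UTR SNPs with no allele-dependent
#' site are generated the same way. Planted SNPs are chosen so no other
#' panel SNP falls inside any generated transcript.
#'
#' @param panel a `HaplotypePanel` (its snp table is updated in place:
#'   ref/alt/ancestral bases of planted SNPs are overwritten to realize the
#'   planted alleles; 0/1 haplotype coding is untouched).
#' @param families family table ([read_mirna_families()] layout).
#' @param n_sites planted allele-dependent sites (default 100).
#' @param site_type_mix named fractions over site types (must sum to 1;
#'   default 40/40/20 over 8mer / 7mer-m8 / 7mer-A1, no 6mers: the main
#'   scan does not accept them).
#' @param fraction_allele_disrupting fraction of planted sites where the
#'   derived allele disrupts an intact ancestral site (default 0.5; the
#'   rest are derived-allele-creating).
#' @param n_background_snps background UTR SNPs without allele-dependent
#'   sites (default 2 * n_sites).
#' @param gc background GC content (default 0.5).
#' @param utr_len_range UTR length range in bp (default 80..160).
#' @param minus_strand_frac fraction of minus-strand transcripts
#'   (default 0.1).
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempts per site (default 100).
#' @param exclude_region optional c(lo, hi) positions: SNPs inside are not
#'   used for UTRs (e.g. a sweep region whose frequencies will be
#'   manipulated afterwards).
#' @return list: `panel` (updated), `utr_table` (data.frame transcript_id,
#'   gene_id, chrom, strand, genomic_start, sequence -- plus-strand, ready
#'   for FASTA), `truth` (data.frame snp_id, family_id, site_type,
#'   intact_allele, verdict, transcript_id, gene_id), `background_snps`.
#' @export
plant_utr_sites <- function(panel, families, n_sites = 100L,
                            site_type_mix = c("8mer" = 0.4, "7mer-m8" = 0.4,
                                              "7mer-A1" = 0.2, "6mer" = 0),
                            fraction_allele_disrupting = 0.5,
                            n_background_snps = 2L * n_sites, gc = 0.5,
                            utr_len_range = c(80L, 160L),
                            minus_strand_frac = 0.1, seed = 1L,
                            max_tries = 100L, exclude_region = NULL) {
  if (nrow(families) == 0L) stop("families must be non-empty")
  if (abs(sum(site_type_mix) - 1) > 1e-9)
    stop("site_type_mix fractions must sum to 1")
  allow_6mer <- !is.na(site_type_mix["6mer"]) && site_type_mix["6mer"] > 0
  L_max <- utr_len_range[2]
  pos <- panel$snp$pos
  gaps_l <- c(Inf, diff(pos))
  gaps_r <- c(diff(pos), Inf)
  eligible <- which(gaps_l > L_max & gaps_r > L_max)
  if (!is.null(exclude_region))
    eligible <- eligible[pos[eligible] < exclude_region[1] |
                           pos[eligible] > exclude_region[2]]
  n_total <- n_sites + n_background_snps
  if (length(eligible) < n_total)
    stop(sprintf(paste0("cannot place %d sites without overlap: only %d ",
                        "sufficiently isolated SNPs"), n_total,
                 length(eligible)))
  with_seed(seed, {
    chosen <- sample(eligible, n_total)
    planted_idx <- chosen[seq_len(n_sites)]
    bg_idx <- chosen[-seq_len(n_sites)]
    types <- if (n_sites)
      sample(names(site_type_mix), n_sites, replace = TRUE,
             prob = site_type_mix) else character(0)
    fam_pick <- if (n_sites)
      sample(nrow(families), n_sites, replace = TRUE) else integer(0)
    disrupts <- stats::runif(n_sites) < fraction_allele_disrupting
    utr_rows <- list(); truth_rows <- list()
    make_one <- function(snp_j, fam_i, site_type, derived_disrupts) {
      planted <- !is.null(site_type)
      snp_pos <- panel$snp$pos[snp_j]
      for (try in seq_len(max_tries)) {
        L <- sample(utr_len_range[1]:utr_len_range[2], 1L)
        if (planted) {
          pat <- seed_site_patterns(families$seed[fam_i])[[site_type]]
          sl <- nchar(pat)
          cp <- sample(.core_positions(site_type), 1L)
          s0 <- sample(1L:(L - sl - 1L), 1L)     # 0-based site start, interior
          off <- s0 + cp - 1L                    # 0-based SNP offset
          seqc <- .sample_bases(L, gc)
          seqc[s0 + seq_len(sl)] <- strsplit(pat, "")[[1]]
          intact <- substr(pat, cp, cp)
          broken <- sample(setdiff(DNA_BASES, intact), 1L)
        } else {
          off <- sample(7L:(L - 8L), 1L)
          seqc <- .sample_bases(L, gc)
          intact <- seqc[off + 1L]
          broken <- sample(setdiff(DNA_BASES, intact), 1L)
          derived_disrupts <- stats::runif(1) < 0.5
        }
        sense <- paste(seqc, collapse = "")
        anc_base <- if (derived_disrupts) intact else broken
        der_base <- if (derived_disrupts) broken else intact
        anc_is_ref <- stats::runif(1) < 0.5
        ref_b <- if (anc_is_ref) anc_base else der_base
        alt_b <- if (anc_is_ref) der_base else anc_base
        sense_ref <- sense
        substr(sense_ref, off + 1L, off + 1L) <- ref_b
        id <- panel$snp$snp_id[snp_j]
        utr <- structure(list(
          transcript_id = paste0("tx_", id), gene_id = paste0("gene_", id),
          chrom = panel$snp$chrom[snp_j], strand = "+",
          genomic_start = snp_pos - off, length = L, sequence = sense_ref,
          snp_offsets = stats::setNames(off, id),
          snp_ref = stats::setNames(ref_b, id),
          snp_alt = stats::setNames(alt_b, id)), class = "UtrSequence")
        win <- build_windows(utr)
        calls <- scan_alleles(win, families, allow_6mer = allow_6mer,
                              derived_is_alt = stats::setNames(anc_is_ref, id))
        poly <- calls[calls$verdict %in% c("disrupting", "creating"), ,
                      drop = FALSE]
        ok <- if (planted) {
          nrow(poly) == 1L && poly$family_id == families$family_id[fam_i] &&
            poly$verdict == (if (derived_disrupts) "disrupting"
                             else "creating") &&
            (if (derived_disrupts) poly$site_type_anc
             else poly$site_type_der) == site_type
        } else nrow(poly) == 0L
        if (!ok) next
        return(list(utr = utr, anc_base = anc_base, ref_b = ref_b,
                    alt_b = alt_b, anc_is_ref = anc_is_ref,
                    verdict = if (!planted) NA_character_
                    else if (derived_disrupts) "disrupting" else "creating"))
      }
      stop("cannot place site after ", max_tries, " attempts (SNP ",
           panel$snp$snp_id[snp_j], ")")
    }
    all_idx <- c(planted_idx, bg_idx)
    for (q in seq_along(all_idx)) {
      snp_j <- all_idx[q]
      planted <- q <= n_sites
      res <- make_one(snp_j,
                      if (planted) fam_pick[q] else NA_integer_,
                      if (planted) types[q] else NULL,
                      if (planted) disrupts[q] else NA)
      u <- res$utr
      # a fraction of transcripts is emitted on the minus strand: the FASTA
      # stores the plus-strand sequence, and the SNP table's ref/alt/AA are
      # plus-strand bases, so complement and re-anchor genomic_start
      minus <- stats::runif(1) < minus_strand_frac
      comp1 <- function(b) chartr("ACGT", "TGCA", b)
      off <- unname(u$snp_offsets[1])
      if (minus) {
        panel$snp$ref[snp_j] <- comp1(res$ref_b)
        panel$snp$alt[snp_j] <- comp1(res$alt_b)
        panel$snp$ancestral[snp_j] <- comp1(res$anc_base)
        seq_plus <- revcomp_dna(u$sequence)
        g0 <- panel$snp$pos[snp_j] - (u$length - 1L - off)
      } else {
        panel$snp$ref[snp_j] <- res$ref_b
        panel$snp$alt[snp_j] <- res$alt_b
        panel$snp$ancestral[snp_j] <- res$anc_base
        seq_plus <- u$sequence
        g0 <- panel$snp$pos[snp_j] - off
      }
      panel$snp$polarized[snp_j] <- TRUE
      utr_rows[[q]] <- data.frame(
        transcript_id = u$transcript_id, gene_id = u$gene_id,
        chrom = u$chrom, strand = if (minus) "-" else "+",
        genomic_start = g0, sequence = seq_plus, stringsAsFactors = FALSE)
      if (planted)
        truth_rows[[q]] <- data.frame(
          snp_id = panel$snp$snp_id[snp_j],
          family_id = families$family_id[fam_pick[q]],
          site_type = types[q],
          intact_allele = if (disrupts[q]) "ancestral" else "derived",
          verdict = res$verdict,
          transcript_id = u$transcript_id, gene_id = u$gene_id,
          stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null, TRUE)])
    if (is.null(truth))
      truth <- data.frame(snp_id = character(0), family_id = character(0),
                          site_type = character(0),
                          intact_allele = character(0),
                          verdict = character(0),
                          transcript_id = character(0),
                          gene_id = character(0), stringsAsFactors = FALSE)
    list(panel = panel, utr_table = do.call(rbind, utr_rows), truth = truth,
         background_snps = panel$snp$snp_id[bg_idx])
  })
}

#' Plant a latitude cline in per-population allele frequencies
#'
#' Cline SNPs get derived frequency clamp01(intercept + slope * |lat| +
#' noise); null SNPs get latitude-independent frequencies drawn per
#' population around a SNP-specific base frequency.
#'
#' @param meta population metadata (>= 4 populations with distinct
#'   latitudes).
#' @param cline_slope frequency change per degree (default -0.01, the
#'   equator-high direction).
#' @param n_cline_snps planted cline SNPs (default 20).
#' @param n_null_snps latitude-independent SNPs (default 2000).
#' @param intercept frequency at the equator (default 0.9).
#' @param noise_sd Gaussian noise SD on cline SNPs (default 0.05).
#' @param null_sd per-population spread of null SNPs (default 0.15).
#' @param seed integer seed.
#' @return list: `freqs` (matrix SNPs x populations, rownames snp ids),
#'   `truth` (data.frame snp_id, is_cline).
#' @export
plant_latitude_cline <- function(meta, cline_slope = -0.01,
                                 n_cline_snps = 20L, n_null_snps = 2000L,
                                 intercept = 0.9, noise_sd = 0.05,
                                 null_sd = 0.15, seed = 1L) {
  if (nrow(meta) < 3L) stop("need at least 3 populations")
  if (nrow(meta) < 4L) warning("fewer than 4 populations: R is unstable")
  npop <- nrow(meta)
  lat <- meta$absolute_latitude
  with_seed(seed, {
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    cl <- matrix(clamp01(intercept + cline_slope * rep(lat, each = n_cline_snps) +
                           stats::rnorm(n_cline_snps * npop, 0, noise_sd)),
                 nrow = n_cline_snps, ncol = npop)
    base <- stats::runif(n_null_snps, 0.05, 0.95)
    nu <- matrix(clamp01(base + stats::rnorm(n_null_snps * npop, 0, null_sd)),
                 nrow = n_null_snps, ncol = npop)
    freqs <- rbind(cl, nu)
    rownames(freqs) <- c(sprintf("cline%04d", seq_len(n_cline_snps)),
                         sprintf("null%05d", seq_len(n_null_snps)))
    colnames(freqs) <- meta$population_id
    list(freqs = freqs,
         truth = data.frame(snp_id = rownames(freqs),
                            is_cline = rep(c(TRUE, FALSE),
                                           c(n_cline_snps, n_null_snps)),
                            stringsAsFactors = FALSE))
  })
}

#' Write a panel as a VCF (plus AA INFO tags)
#' @param panel a `HaplotypePanel`.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  samples <- unique(panel$hap_sample)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  # convert 0/1 (ancestral/derived) coding to REF/ALT codes per column
  hap <- panel$haplotypes
  flip <- !is.na(panel$snp$ancestral) & panel$snp$ancestral == panel$snp$alt
  hap[, flip] <- 1L - hap[, flip]
  h1 <- hap[seq(1L, nrow(hap), by = 2L), , drop = FALSE]
  h2 <- hap[seq(2L, nrow(hap), by = 2L), , drop = FALSE]
  info <- ifelse(is.na(panel$snp$ancestral), ".",
                 paste0("AA=", panel$snp$ancestral))
  for (j in seq_len(ncol(hap))) {
    gt <- paste0(h1[, j], "|", h2[, j])
    writeLines(paste(c(panel$snp$chrom[j], panel$snp$pos[j],
                       panel$snp$snp_id[j], panel$snp$ref[j],
                       panel$snp$alt[j], ".", "PASS", info[j], "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a UTR table as FASTA
#' @param utr_table data.frame from [plant_utr_sites()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utr_table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(utr_table))) {
    writeLines(c(sprintf(">%s|%s|%s|%s|%d", utr_table$transcript_id[i],
                         utr_table$gene_id[i], utr_table$chrom[i],
                         utr_table$strand[i], utr_table$genomic_start[i]),
                 utr_table$sequence[i]), con)
  }
  invisible(path)
}

#' Write population metadata
#' @param meta data.frame (population_id, n_samples, absolute_latitude,
#'   excluded, reason).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_meta <- function(meta, path) {
  out <- meta
  out$excluded <- as.integer(out$excluded)
  write_tsv(out, path)
}
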