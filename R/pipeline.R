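# End-to-end orchestration: simulate-or-load -> allele-aware scan -> F_ST +
# enrichment -> candidate and hitchhiking filters -> per-candidate selection
# statistics -> cline test -> report. Deterministic given (inputs, seed):
# one global seed fans out to per-stage child seeds.

#' Write a ground-truth-annotated synthetic dataset to disk
#'
#' Profiles: `null` (no planted signal beyond neutral target sites),
#' `enriched` (planted seed sites, a subset forced to high F_ST), `sweep`
#' (adds an injected sweep), `cline` (adds a latitude-cline frequency
#' table), `full` (all signal types; the end-to-end demo profile, including
#' one candidate excluded by the hitchhiking filter).
#'
#' @param profile one of "null", "enriched", "sweep", "cline", "full".
#' @param seed integer seed.
#' @param dir output directory; `inputs/` receives the pipeline inputs,
#'   `truth/` the ground-truth tables (never read by the pipeline).
#' @param scale size multiplier for the panel (default 1).
#' @return list: `paths` (named input paths), `truth` (list of truth
#'   objects).
#' @export
make_fixture <- function(profile, seed = 1L, dir = tempfile("fixture"),
                         scale = 1) {
  profiles <- c("null", "enriched", "sweep", "cline", "full")
  if (!profile %in% profiles)
    stop("unknown profile '", profile, "'; available: ",
         paste(profiles, collapse = ", "))
  ind <- file.path(dir, "inputs"); trd <- file.path(dir, "truth")
  dir.create(ind, recursive = TRUE, showWarnings = FALSE)
  dir.create(trd, recursive = TRUE, showWarnings = FALSE)
  small <- profile == "full"
  cfg <- sim_config(
    n_populations = 2L,
    samples_per_population = if (small) 40L else 50L,
    n_snps = round((if (small) 600L else 800L) * scale),
    drift_F = 0.1,
    region_length_bp = round((if (small) 1500000L else 2000000L) * scale),
    rng_seed = child_seed(seed, 1L))
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  truth <- list(panel = sim$truth)
  fams <- random_families(20L, seed = child_seed(seed, 2L))

  n_sites <- round((if (small) 40L else 100L) * min(1, scale))
  sweep_profile <- profile %in% c("sweep", "full")
  excl <- if (sweep_profile) {
    # the sweep elevates F_ST for everything inside its radius; keep UTR
    # SNPs out of it so the candidate truth stays constructional
    mid <- cfg$region_length_bp / 2
    c(mid - 150000, mid + 150000)
  } else NULL
  pl <- plant_utr_sites(panel, fams, n_sites = n_sites,
                        n_background_snps = 2L * n_sites,
                        seed = child_seed(seed, 3L), exclude_region = excl)
  panel <- pl$panel
  truth$sites <- pl$truth
  truth$background_snps <- data.frame(snp_id = pl$background_snps)

  forced <- character(0)
  if (profile %in% c("enriched", "full")) {
    n_force <- if (small) 5L else 20L
    forced <- with_seed(child_seed(seed, 4L),
                        sample(pl$truth$snp_id, n_force))
    panel <- force_differentiation(
      panel, forced,
      matrix(rep(c(0.97, 0.03), each = n_force), ncol = 2),
      seed = child_seed(seed, 5L))
    # so that "the candidates are exactly the planted ones" holds by
    # construction: planted target SNPs whose natural drift lands near the
    # candidate threshold are re-drawn with equalized frequencies
    nat <- setdiff(pl$truth$snp_id, forced)
    fnat <- panel_fst(panel)
    hot <- nat[nat %in% fnat$snp_id[!is.na(fnat$fst) & fnat$fst >= 0.4]]
    if (length(hot))
      panel <- force_differentiation(
        panel, hot, matrix(rep(c(0.5, 0.45), each = length(hot)), ncol = 2),
        seed = child_seed(seed, 9L))
  }
  truth$forced_high_fst <- data.frame(snp_id = forced)

  hitchhiked <- character(0)
  if (profile == "full" && length(forced)) {
    # plant a functional variant in perfect LD with one forced candidate:
    # the hitchhiking filter must exclude that candidate
    hitchhiked <- forced[1]
    k <- match(hitchhiked, panel$snp$snp_id)
    near <- which(panel$snp$chrom == panel$snp$chrom[k] &
                    abs(panel$snp$pos - panel$snp$pos[k]) <= 400000L &
                    !panel$snp$snp_id %in% c(pl$truth$snp_id,
                                             pl$background_snps))
    near <- setdiff(near, k)
    f <- near[1]
    panel$haplotypes[, f] <- panel$haplotypes[, k]
    panel$snp$functional[f] <- TRUE
    truth$hitchhiked <- data.frame(snp_id = hitchhiked,
                                   functional_snp = panel$snp$snp_id[f])
  }
  truth$expected_candidates <-
    data.frame(snp_id = setdiff(forced, hitchhiked))

  if (profile %in% c("sweep", "full")) {
    # sweep the modest-frequency SNP closest to the region center
    rows1 <- panel_rows(panel, "POP1")
    freq1 <- colMeans(panel$haplotypes[rows1, , drop = FALSE])
    cand <- which(freq1 <= 0.5)
    mid <- panel$snp$pos[cand[which.min(abs(panel$snp$pos[cand] -
                                              cfg$region_length_bp / 2))]]
    sw <- inject_sweep(panel, mid, "POP1", final_derived_freq = 0.9,
                       homogenization_radius_bp = 100000L,
                       seed = child_seed(seed, 6L))
    panel <- sw$panel
    truth$sweep <- as.data.frame(sw$truth[c("sweep_snp", "sweep_pos",
                                            "population", "radius_bp",
                                            "final_derived_freq")])
  }

  paths <- list(
    vcf = file.path(ind, "panel.vcf"),
    utrs = file.path(ind, "utrs.fasta"),
    families = file.path(ind, "families.tsv"),
    snps = file.path(ind, "snps.tsv"),
    populations = file.path(ind, "populations.tsv"))
  write_panel_vcf(panel, paths$vcf)
  write_utr_fasta(pl$utr_table, paths$utrs)
  write_tsv(fams, paths$families)
  write_snp_table(panel$snp, paths$snps)
  meta <- data.frame(population_id = panel$populations,
                     n_samples = cfg$samples_per_population,
                     absolute_latitude = c(10, 50)[seq_along(panel$populations)],
                     excluded = FALSE, reason = ".",
                     samples = vapply(panel$populations, function(pp)
                       paste(unique(panel$hap_sample[panel$hap_population ==
                                                       pp]), collapse = ","),
                       character(1)),
                     stringsAsFactors = FALSE)
  write_population_meta(meta, paths$populations)

  if (profile %in% c("cline", "full")) {
    n_hgdp <- 30L
    hmeta <- with_seed(child_seed(seed, 7L), data.frame(
      population_id = sprintf("HGDP%02d", seq_len(n_hgdp)),
      n_samples = 20L,
      absolute_latitude = round(stats::runif(n_hgdp, 0, 65), 1),
      excluded = rep(c(FALSE, TRUE), c(n_hgdp - 2L, 2L)),
      reason = rep(c(".", "recent-migration"), c(n_hgdp - 2L, 2L)),
      stringsAsFactors = FALSE))
    cl <- plant_latitude_cline(
      hmeta[!hmeta$excluded, ],
      n_cline_snps = max(1L, nrow(truth$expected_candidates)),
      n_null_snps = 1500L, seed = child_seed(seed, 8L))
    freqs <- cl$freqs
    # excluded populations get latitude-independent noise columns
    ex <- with_seed(child_seed(seed, 10L),
                    matrix(stats::runif(nrow(freqs) * 2L), ncol = 2L))
    colnames(ex) <- hmeta$population_id[hmeta$excluded]
    freqs <- cbind(freqs, ex)[, hmeta$population_id]
    if (nrow(truth$expected_candidates) > 0 && profile == "full")
      rownames(freqs)[seq_len(nrow(truth$expected_candidates))] <-
        truth$expected_candidates$snp_id
    ctab <- data.frame(snp_id = rownames(freqs), freqs, check.names = FALSE)
    paths$cline_freqs <- file.path(ind, "cline_freqs.tsv")
    paths$cline_populations <- file.path(ind, "cline_populations.tsv")
    write_tsv(ctab, paths$cline_freqs)
    write_population_meta(hmeta, paths$cline_populations)
    truth$cline <- cl$truth
  }

  for (nm in names(truth))
    if (is.data.frame(truth[[nm]]))
      write_tsv(truth[[nm]], file.path(trd, paste0(nm, ".tsv")))
  list(paths = paths, truth = truth)
}

#' Default pipeline configuration
#' @param ... overrides for any top-level field.
#' @return a config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    simulate = NULL,                    # list(profile=, ...) or NULL
    inputs = NULL,                      # named paths when not simulating
    scan = list(allow_6mer = FALSE, score_threshold = -0.2),
    enrichment = list(edges = default_fst_edges(), n_reps = 1000L,
                      with_replacement = FALSE),
    candidate = list(fst_threshold = 0.5),
    ld = list(window_bp = 500000L, r2_threshold = 0.5),
    stats = list(h_window_bp = 50000L, h_step_bp = 10000L,
                 ihs_bins = 20L, min_maf = 0.05,
                 clr_grid = 25L, ehh_cutoff = 0.05),
    cline = list(two_sided = TRUE, fst_threshold = 0.5))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: simulate-or-load inputs, allele-aware target scan, per-SNP F_ST,
#' F_ST-bin enrichment with bootstrap null and hypergeometric tail,
#' candidate filter (F_ST threshold), hitchhiking LD filter, per-candidate
#' selection statistics (windowed Fay-Wu H, iHS, regional CLR maximum),
#' optional latitude-cline test, and deterministic TSV reports. A resolved
#' copy of the configuration is written into the output directory, and the
#' filter log records input/retained/excluded counts at every stage.
#'
#' @param config list from [pipeline_config()] (or a YAML file path).
#' @return list: `report` (the candidate table), `enrichment`, `counts`
#'   (filter bookkeeping), `paths` (written files), `calls`, `fst`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- do.call(pipeline_config,
                                              yaml::read_yaml(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  counts <- list()
  note <- function(stage, n_in, n_kept)
    counts[[length(counts) + 1L]] <<-
    data.frame(stage = stage, n_in = n_in, n_retained = n_kept,
               n_excluded = n_in - n_kept)

  if (!is.null(config$simulate)) {
    fx <- do.call(make_fixture,
                  c(config$simulate,
                    list(seed = seed, dir = file.path(out_dir, "fixture"))))
    inputs <- fx$paths
  } else inputs <- config$inputs
  for (nm in c("vcf", "utrs", "families", "snps", "populations"))
    if (is.null(inputs[[nm]])) stop("missing input path: ", nm)

  snp_table <- read_snp_table(inputs$snps)
  meta <- read_population_meta(inputs$populations)
  pop_map <- if (!is.null(meta$samples)) {
    ids <- strsplit(meta$samples, ",", fixed = TRUE)
    stats::setNames(rep(meta$population_id, lengths(ids)), unlist(ids))
  } else stats::setNames(          # fall back to the <pop>_S<i> convention
    rep(meta$population_id, meta$n_samples),
    unlist(lapply(seq_len(nrow(meta)), function(i)
      paste0(meta$population_id[i], "_S", seq_len(meta$n_samples[i])))))
  panel <- read_vcf(inputs$vcf, pop_map)
  panel <- annotate_panel(panel, snp_table)
  fams <- read_mirna_families(inputs$families)
  utrs <- read_utrs(inputs$utrs, snp_table)
  note("vcf_records", ncol(panel$haplotypes) + attr(panel, "skipped"),
       ncol(panel$haplotypes))

  windows <- do.call(rbind, lapply(utrs, build_windows))
  derived_is_alt <- stats::setNames(
    !is.na(panel$snp$ancestral) & panel$snp$ancestral == panel$snp$ref,
    panel$snp$snp_id)
  calls <- scan_alleles(windows, fams,
                        allow_6mer = isTRUE(config$scan$allow_6mer),
                        score_threshold = config$scan$score_threshold,
                        derived_is_alt = derived_is_alt)
  fst <- panel_fst(panel)

  utr_snps <- unique(unlist(lapply(utrs, function(u) names(u$snp_offsets))))
  target_snps <- unique(calls$snp_id[calls$verdict %in%
                                       c("disrupting", "creating")])
  note("utr_snps", length(utr_snps), length(utr_snps))
  note("target_snps", length(utr_snps), length(target_snps))
  bg_fst <- fst$fst[fst$snp_id %in% utr_snps & !is.na(fst$fst)]
  tg_fst <- fst$fst[fst$snp_id %in% target_snps & !is.na(fst$fst)]
  edges <- config$enrichment$edges
  enr <- enrichment_scores(tg_fst, bg_fst, edges)
  boot <- bootstrap_null(bg_fst, n_draw = length(tg_fst),
                         n_reps = config$enrichment$n_reps, edges = edges,
                         seed = child_seed(seed, 101L),
                         replace = isTRUE(config$enrichment$with_replacement))
  top <- nrow(enr)
  n_top_bg <- enr$background_count[top]
  tail_p <- hypergeom_tail(N = length(bg_fst), K = length(tg_fst),
                           n = n_top_bg, k = enr$target_count[top])
  enr$null_mean <- boot$null_mean; enr$null_sd <- boot$null_sd
  enr$null_lo <- boot$null_lo; enr$null_hi <- boot$null_hi
  attr(enr, "top_bin_tail_p") <- tail_p

  cand <- candidate_filter(calls, fst, config$candidate$fst_threshold)
  note("candidate_fst_filter", length(target_snps), length(cand$snps))
  hh <- hitchhike_filter(cand$snps, panel,
                         window_bp = config$ld$window_bp,
                         r2_threshold = config$ld$r2_threshold)
  note("hitchhike_filter", length(cand$snps), length(hh$retained))

  report <- .candidate_report(hh$retained, panel, calls, fst, config)

  cline_tab <- NULL
  if (!is.null(inputs$cline_freqs) && length(hh$retained)) {
    cfreq <- utils::read.table(inputs$cline_freqs, header = TRUE, sep = "\t",
                               check.names = FALSE, stringsAsFactors = FALSE)
    rownames(cfreq) <- cfreq$snp_id
    cmeta <- read_population_meta(inputs$cline_populations)
    focal <- intersect(hh$retained, rownames(cfreq))
    if (length(focal)) {
      cline_tab <- cline_test(cfreq[, -1, drop = FALSE], cmeta,
                              focal_snps = focal,
                              two_sided = isTRUE(config$cline$two_sided))
      m <- match(report$snp_id, cline_tab$snp_id)
      report$cline_R <- cline_tab$pearson_R[m]
      report$cline_percentile <- cline_tab$percentile[m]
    }
  }

  counts <- do.call(rbind, counts)
  results <- list(calls = calls, fst = fst, enrichment = enr,
                  candidates = report, excluded = hh$excluded,
                  filter_counts = counts)
  if (!is.null(cline_tab)) results$cline <- cline_tab
  paths <- write_results_tables(results, out_dir)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], cfg_path)
  tp <- file.path(out_dir, "top_bin_tail_p.tsv")
  write_tsv(data.frame(top_bin_lo = edges[length(edges) - 1],
                       tail_p = tail_p), tp)
  list(report = report, enrichment = enr, counts = counts,
       paths = c(paths, cfg_path, tp), calls = calls, fst = fst)
}

# per-candidate selection statistics, the report table
.candidate_report <- function(snps, panel, calls, fst, config) {
  if (!length(snps))
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      families = character(0), verdict = character(0),
                      fst = numeric(0), stringsAsFactors = FALSE))
  st <- config$stats
  freqs <- panel_frequencies(panel)
  ihs_by_pop <- lapply(panel$populations, function(p)
    ihs(panel, population = p, n_bins = st$ihs_bins,
        min_maf = st$min_maf, cutoff = st$ehh_cutoff))
  names(ihs_by_pop) <- panel$populations
  clr_by_pop <- lapply(panel$populations, function(p)
    clr_scan(panel, population = p,
             grid = round(seq(min(panel$snp$pos), max(panel$snp$pos),
                              length.out = st$clr_grid))))
  names(clr_by_pop) <- panel$populations
  rows <- lapply(snps, function(id) {
    k <- match(id, panel$snp$snp_id)
    sub <- calls[calls$snp_id == id &
                   calls$verdict %in% c("disrupting", "creating"), ,
                 drop = FALSE]
    row <- data.frame(
      snp_id = id, gene_id = paste(unique(sub$gene_id), collapse = ","),
      families = paste(unique(sub$family_id), collapse = ","),
      verdict = paste(unique(sub$verdict), collapse = ","),
      fst = fst$fst[match(id, fst$snp_id)], stringsAsFactors = FALSE)
    for (p in panel$populations) {
      row[[paste0("freq_", p)]] <- unname(freqs[id, p])
      w <- c(panel$snp$pos[k] - st$h_window_bp / 2,
             panel$snp$pos[k] + st$h_window_bp / 2)
      row[[paste0("H_", p)]] <-
        fay_wu_h(unfolded_sfs(panel, w, population = p))$H
      is_tab <- ihs_by_pop[[p]]
      row[[paste0("ihs_", p)]] <-
        if (id %in% is_tab$snp_id) is_tab$ihs[match(id, is_tab$snp_id)]
      else NA_real_
      ct <- clr_by_pop[[p]]
      nearby <- abs(ct$pos - panel$snp$pos[k]) <= 150000
      row[[paste0("clr_max_", p)]] <-
        if (any(nearby)) max(ct$clr[nearby]) else NA_real_
    }
    row$ld_filter <- "pass"
    row
  })
  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' `mirsel simulate --profile <p> --seed <s> --out <dir>` writes a fixture;
#' `mirsel run --config <yaml> [--seed <s>] [--out <dir>]` runs the
#' pipeline. Exit codes: 0 ok, 1 data error, 2 config/usage error.
#' @param args character vector (default: command line).
#' @return exit status, invisibly.
#' @export
mirsel_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mirsel <simulate|run> [--profile p] [--config f] [--seed s] [--out dir]"
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- list(seed = 1L, out = "mirsel_out", profile = "full", config = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message(usage); return(invisible(2L))
    }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed)
  status <- tryCatch({
    if (cmd == "simulate") {
      make_fixture(opt$profile, seed = opt$seed, dir = opt$out)
      0L
    } else if (cmd == "run") {
      cfg <- if (!is.null(opt$config))
        do.call(pipeline_config, yaml::read_yaml(opt$config))
      else pipeline_config(simulate = list(profile = opt$profile))
      cfg$seed <- opt$seed
      if (is.null(cfg$out_dir)) cfg$out_dir <- opt$out
      run_pipeline(cfg)
      0L
    } else { message(usage); 2L }
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
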