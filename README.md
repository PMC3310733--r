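# mirsel

Detecting positively selected miRNA regulatory interactions at SNPs.

## What it does, and for whom

A 3'UTR SNP can create or destroy a canonical miRNA seed-match site, so one
allele is regulated by a miRNA and the other is not. If such an allele rose
to high frequency in some populations but not others, that regulatory
rewiring may have been a target of local positive selection. `mirsel` is an
R package for population geneticists who want to run (or stress-test) that
scan end to end:

1. **Allele-aware target scan** — 15-nt windows centered at each 3'UTR SNP,
   classified per allele against miRNA family seeds (8mer, 7mer-m8,
   7mer-A1, optionally 6mer; priority in that order, leftmost on ties);
   verdicts `disrupting` / `creating` / `both-intact`.
2. **Differentiation and enrichment** — per-SNP Weir–Cockerham F_ST
   (θ̂ = a/(a+b); multi-locus Σa/Σ(a+b)); bin-wise enrichment
   E_b = (t_b/T)/(g_b/G) of target-site SNPs over the 3'UTR background;
   a seeded bootstrap null (1,000 resamples by default) and the upper
   hypergeometric tail probability for the extreme bin (F_ST ≥ 0.5).
3. **Within-population selection statistics** — unfolded-SFS Fay–Wu
   H = θ_π − θ_H in sliding windows with an empirical 5% threshold; EHH
   curves and iHS = standardized ln(iHH_A/iHH_D); a composite likelihood
   ratio sweep scan against the genome-background SFS with per-lineage
   escape probability p_e = 1 − exp(−α·d).
4. **Hitchhiking control** — r²/D/D′/LOD by direct haplotype counting;
   candidates with r² ≥ 0.5 to an annotated functional variant within
   ±500 kb are excluded.
5. **Geographic clines** — Pearson correlation of derived allele frequency
   with absolute latitude across populations, ranked by its genome-wide
   empirical extremeness percentile (two-sided on |R|), with a
   high-F_ST-restricted variant.
6. **Synthetic data with ground truth** — Balding–Nichols differentiation
   with a drift parameter, AR(1)-copula LD, structurally injected sweeps,
   planted allele-dependent seed sites, planted latitude clines; truth
   tables are emitted separately from the pipeline inputs.

Formats: VCF 4.x (phased GT, optional AA ancestral-allele tag), FASTA
3'UTRs, TSV tables (SNP annotation, miRNA families, population metadata),
BED/TSV outputs, YAML pipeline configs. Internally 0-based half-open;
VCF stays 1-based at the boundary.

## Worked example

Simulate a two-population panel (50 diploids each, drift F = 0.1), plant 20
allele-dependent seed sites plus 40 site-free background UTR SNPs, force
three planted SNPs to extreme differentiation, then run the scan and the
enrichment test:

```r
library(mirsel)
sim <- simulate_panel(sim_config(n_populations = 2,
                                 samples_per_population = 50,
                                 n_snps = 800, drift_F = 0.1,
                                 region_length_bp = 2e6, rng_seed = 42))
fams <- random_families(10, seed = 43)
pl  <- plant_utr_sites(sim$panel, fams, n_sites = 20,
                       n_background_snps = 40, seed = 44)
p   <- force_differentiation(pl$panel, pl$truth$snp_id[1:3],
                             matrix(rep(c(0.97, 0.03), each = 3), ncol = 2),
                             seed = 45)

fa <- tempfile(); write_utr_fasta(pl$utr_table, fa)
utrs  <- read_utrs(fa, p$snp)
win   <- do.call(rbind, lapply(utrs, build_windows))
calls <- scan_alleles(win, fams,
                      derived_is_alt = setNames(p$snp$ancestral == p$snp$ref,
                                                p$snp$snp_id))
count_polymorphic_sites(calls)$n_snps_polymorphic
#> [1] 20

fst <- panel_fst(p)
tg  <- fst$fst[fst$snp_id %in% calls$snp_id[calls$verdict %in%
                                              c("disrupting", "creating")]]
bg  <- fst$fst[fst$snp_id %in% unlist(lapply(utrs, function(u)
                                             names(u$snp_offsets)))]
enr <- enrichment_scores(tg, bg)
round(enr$enrichment, 3)
#> [1] 0.771 1.071 1.200 3.000 0.000 2.250
hypergeom_tail(length(bg), length(tg),
               enr$background_count[6], enr$target_count[6])
#> [1] 0.1031399
candidate_filter(calls, fst)$snps
#> [1] "snp00126" "snp00577" "snp00689"
```

All 20 planted sites are recovered (recall and precision are exactly 1 by
construction — and independently verified against a brute-force classifier
in the tests). The top F_ST bin holds 3 of 20 target SNPs against 4 of 60
background SNPs: enrichment 2.25, but a tail probability of only 0.10 — a
60-SNP background is far too small for significance, which is the point of
the toy; the acceptance tests run the same machinery on a 20,000-SNP
background where a planted 3× top-bin enrichment yields P < 10⁻³. The
candidate filter returns exactly the three SNPs forced to F_ST ≥ 0.5.

The one-call version of all of the above is the pipeline:

```r
res <- run_pipeline(pipeline_config(seed = 5, out_dir = "out",
                                    simulate = list(profile = "full")))
res$report   # per-candidate gene, families, verdict, freqs, F_ST, H, iHS,
             # regional CLR maximum, LD-filter status, cline R + percentile
```

## Further reading

`vignettes/mirsel-methods.Rmd` documents the models and their assumptions,
every tunable parameter with its default and rationale, what the synthetic
world does and does not emulate, numerical choices, and known limitations.
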