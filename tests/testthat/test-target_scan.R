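# target_scan: seed-site classification, polymorphic windows, allele-aware
# calls. Expected values for the worked examples were computed with the
# exhaustive complementarity oracle in helper-oracles.R.

test_that("classify_site matches hand-checked seed-pairing cases", {
  # seed UAAUGCU -> heptamer AGCATTA on the mRNA
  r <- classify_site("CCAGCATTAACC", "UAAUGCU")
  expect_equal(r$type, "8mer")
  expect_equal(r$start, 2L)
  expect_equal(r$length, 8L)
  # RNA input sequences are fine too (U ~ T at the boundary)
  r_rna <- classify_site(chartr("T", "U", "CCAGCATTAACC"), "UAAUGCU")
  expect_equal(r_rna["type"], r["type"])

  r2 <- classify_site("CCAGCATTACC", "UAAUGCU")
  expect_equal(r2$type, "7mer-m8")
  expect_equal(classify_site("CCCCCCCCCCCCC", "UAAUGCU")$type, "none")
  # hexamer + A without the m8 base
  r3 <- classify_site("CCGCATTAACC", "UAAUGCU")
  expect_equal(r3$type, "7mer-A1")
  r4 <- classify_site("CCGCATTAGG", "UAAUGCU", allow_6mer = TRUE)
  expect_equal(r4$type, "6mer")
  expect_equal(classify_site("CCGCATTAGG", "UAAUGCU")$type, "none")
  expect_error(classify_site("ACGT", "UAAUGC"), "seed")
})

test_that("classify_site equals the exhaustive oracle on random windows", {
  set.seed(101)
  for (i in 1:300) {
    seed <- random_seed_rna()
    seq <- random_dna(sample(10:40, 1))
    a6 <- i %% 2 == 0
    got <- classify_site(seq, seed, allow_6mer = a6)
    want <- oracle_classify(seq, seed, allow_6mer = a6)
    expect_identical(got, want,
                     label = sprintf("seq=%s seed=%s", seq, seed))
  }
})

test_that("site class hierarchy: an 8mer window contains every lower class", {
  set.seed(102)
  found <- 0
  while (found < 25) {
    seed <- random_seed_rna()
    pats <- seed_site_patterns(seed)
    seq <- paste0(random_dna(5), pats[["8mer"]], random_dna(5))
    got <- oracle_classify(seq, seed, allow_6mer = TRUE)
    if (got$type != "8mer") next   # flanks may create an earlier 8mer
    found <- found + 1
    expect_true(grepl(pats[["7mer-m8"]], seq, fixed = TRUE))
    expect_true(grepl(pats[["7mer-A1"]], seq, fixed = TRUE))
    expect_true(grepl(pats[["6mer"]], seq, fixed = TRUE))
  }
})

make_utr <- function(seq, snp_off, ref, alt, id = "tx1") {
  structure(list(transcript_id = id, gene_id = paste0("g_", id),
                 chrom = "1", strand = "+", genomic_start = 1L,
                 length = nchar(seq), sequence = seq,
                 snp_offsets = stats::setNames(snp_off, "rs1"),
                 snp_ref = stats::setNames(ref, "rs1"),
                 snp_alt = stats::setNames(alt, "rs1")),
            class = "UtrSequence")
}

test_that("build_windows covers offsets -7..+7 with boundary truncation", {
  set.seed(103)
  seq <- random_dna(200)
  ref <- substr(seq, 51, 51)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  w <- build_windows(make_utr(seq, 50L, ref, alt))
  expect_equal(w$window_start, 43L)
  expect_equal(nchar(w$seq_ref), 15L)
  expect_equal(w$seq_ref, substr(seq, 44, 58))
  expect_false(w$truncated)

  ref3 <- substr(seq, 4, 4)
  w3 <- build_windows(make_utr(seq, 3L, ref3,
                               setdiff(c("A", "C", "G", "T"), ref3)[1]))
  expect_equal(nchar(w3$seq_ref), 11L)
  expect_true(w3$truncated)
  expect_equal(w3$center, 3L)

  bad <- make_utr(seq, 250L, "A", "C")
  expect_error(build_windows(bad), "outside")
})

test_that("ref and alt windows differ exactly at the center", {
  set.seed(104)
  for (i in 1:50) {
    seq <- random_dna(60)
    off <- sample(0:59, 1)
    ref <- substr(seq, off + 1, off + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    w <- build_windows(make_utr(seq, off, ref, alt))
    a <- strsplit(w$seq_ref, "")[[1]]
    b <- strsplit(w$seq_alt, "")[[1]]
    expect_equal(which(a != b), w$center + 1L)
  }
})

test_that("scan_alleles verdicts: disrupting, creating, both-intact, multi-family", {
  fam <- data.frame(family_id = c("famX", "famY"),
                    seed = c("UAAUGCU", "CUAAUGC"),
                    members = c("x", "y"), stringsAsFactors = FALSE)
  # famX heptamer AGCATTA; SNP in the core: ref intact, alt broken
  seq <- paste0("GGGGGG", "AGCATTA", "CGGGGG")     # 7mer-m8 at offset 6
  off <- 8L                                        # core base C at offset 8
  ref <- substr(seq, off + 1, off + 1)
  w <- build_windows(make_utr(seq, off, ref, "G"))
  calls <- scan_alleles(w, fam)
  calls <- calls[calls$family_id == "famX", ]
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$verdict, "disrupting")  # derived (= alt) loses the site
  expect_equal(calls$site_type_ref, "7mer-m8")
  expect_equal(calls$site_type_alt, "none")
  expect_equal(calls$site_start, 6L)

  # derived_is_alt = FALSE turns the same event into "creating"
  calls2 <- scan_alleles(w, fam[1, ],
                         derived_is_alt = c(rs1 = FALSE))
  expect_equal(calls2$verdict, "creating")

  # site inside the window but not overlapping the SNP: both alleles intact
  seq3 <- paste0("AGCATTA", "G", "CCCCCCC")        # site at offsets 0..6
  w3 <- build_windows(make_utr(seq3, 7L, "G", "C"))
  calls3 <- scan_alleles(w3, fam[1, ])
  expect_equal(calls3$verdict, "both-intact")

  # one SNP impacting two families with overlapping heptamers
  # famX heptamer AGCATTA (offsets 4..10), famY heptamer GCATTAG (5..11)
  seqm <- paste0("GGGG", "AGCATTAG", "GGG")
  offm <- 7L                                       # inside both cores
  wm <- build_windows(make_utr(seqm, offm, substr(seqm, 8, 8), "C"))
  callsm <- scan_alleles(wm, fam)
  poly <- callsm[callsm$verdict == "disrupting", ]
  expect_equal(sort(poly$family_id), c("famX", "famY"))
  cnt <- count_polymorphic_sites(callsm)
  expect_equal(cnt$n_snps_polymorphic, 1L)
  expect_equal(cnt$n_calls_polymorphic, 2L)
})

test_that("context scores drop low-confidence calls; absent scores pass", {
  fam <- data.frame(family_id = "famX", seed = "UAAUGCU", members = "x",
                    stringsAsFactors = FALSE)
  seq <- paste0("GGGGGG", "AGCATTA", "CGGGGG")
  w <- build_windows(make_utr(seq, 8L, "T", "G"))
  w$seq_ref <- paste0("GGGGGG", "AGCATTA", "CG")  # irrelevant; rebuild below
  w <- build_windows(make_utr(seq, 8L, substr(seq, 9, 9), "G"))
  base <- scan_alleles(w, fam)
  expect_equal(nrow(base), 1L)
  sc_pass <- data.frame(snp_id = "rs1", family_id = "famX", score = -0.9)
  sc_fail <- data.frame(snp_id = "rs1", family_id = "famX", score = -0.1)
  expect_equal(nrow(scan_alleles(w, fam, context_scores = sc_pass)), 1L)
  expect_equal(nrow(scan_alleles(w, fam, context_scores = sc_fail)), 0L)
  sc_other <- data.frame(snp_id = "rs9", family_id = "famX", score = -0.1)
  expect_equal(nrow(scan_alleles(w, fam, context_scores = sc_other)), 1L)
})

test_that("count_polymorphic_sites on empty calls is all zeros", {
  empty <- scan_alleles(
    data.frame(snp_id = character(0), transcript_id = character(0),
               gene_id = character(0), window_start = integer(0),
               center = integer(0), seq_ref = character(0),
               seq_alt = character(0), truncated = logical(0)),
    data.frame(family_id = "f", seed = "UAAUGCU", members = "m"))
  cnt <- count_polymorphic_sites(empty)
  expect_equal(cnt$n_snps_polymorphic, 0L)
  expect_equal(cnt$n_calls_polymorphic, 0L)
  expect_true(all(cnt$by_verdict == 0L))
})

test_that("strand invariance: minus-strand genomic input scans like the sense sequence", {
  set.seed(106)
  fam <- random_families(5, seed = 11)
  for (i in 1:10) {
    sense <- random_dna(60)
    off <- sample(10:49, 1)
    ref_s <- substr(sense, off + 1, off + 1)
    alt_s <- setdiff(c("A", "C", "G", "T"), ref_s)[1]
    direct <- scan_alleles(build_windows(make_utr(sense, off, ref_s, alt_s)),
                           fam)
    # same transcript presented as minus-strand genomic plus sequence
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">tx1|g_tx1|1|-|5000", revcomp_dna(sense)), fa)
    pos <- 5000L + 60L - 1L - off
    snp <- data.frame(snp_id = "rs1", chrom = "1", pos = pos,
                      ref = chartr("ACGT", "TGCA", ref_s),
                      alt = chartr("ACGT", "TGCA", alt_s),
                      stringsAsFactors = FALSE)
    u <- read_utrs(fa, snp)
    via_minus <- scan_alleles(build_windows(u[[1]]), fam)
    expect_equal(via_minus, direct)
  }
})
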