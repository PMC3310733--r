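---
title: "mirsel: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirsel: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsel)
```

## The problem

Most miRNA binding sites are strongly conserved, and variants that destroy
them are usually rare and deleterious. But gene-regulatory change is a major
substrate of recent human adaptation, and a 3'UTR SNP that creates or
destroys a seed match can rewire a miRNA interaction in one population but
not another. mirsel implements the computational side of a scan for such
events: find SNPs where one allele completes a canonical seed match and the
other breaks it, ask whether those SNPs are over-represented among loci with
extreme population differentiation, and then interrogate individual
candidates with within-population selection statistics, linkage
disequilibrium controls, and geographic allele-frequency clines.

The real analysis runs on phased cohort panels (millions of SNPs, dozens of
populations). Those inputs cannot ship with a package, so mirsel pairs every
analysis module with a synthetic-data generator that produces inputs with
known ground truth and the statistical structure the analysis assumes. Every
claim the test suite makes is a claim about recovering planted truth or
matching an independent brute-force oracle.

## Allele-aware seed-site calling

A miRNA recognizes its target through its seed, nucleotides 2-8 at the 5'
end. On the mRNA (sense strand), the canonical site classes are:

* **8mer** — reverse complement of seed positions 2-8, followed by A;
* **7mer-m8** — the heptamer alone;
* **7mer-A1** — reverse complement of seed positions 2-7, followed by A;
* **6mer** — the hexamer alone.

For every 3'UTR SNP we emit a 15-nt window centered at the SNP (clipped and
flagged at UTR edges), once per allele, and classify each allele for each
miRNA family with priority 8mer > 7mer-m8 > 7mer-A1 > 6mer, leftmost match
on ties (the TargetScan convention; the source pipeline does not state a
tie-break). A call is *disrupting* when the derived allele loses the only
accepted site, *creating* when it gains one, and *both-intact* when both
alleles carry a site — including the case of a site inside the window that
does not overlap the SNP. Only disrupting/creating calls enter the
polymorphic-site set. The main scan excludes bare 6mers; the fine-resolution
re-scan (`allow_6mer = TRUE`) accepts them. Optional context scores are
consumed, not computed: calls scoring above −0.2 (less negative = less
confident) are dropped when scores are supplied, and pass otherwise, because
the synthetic pipeline has no score source. Wobble pairs, centered sites and
3' compensatory pairing are out of scope: the pipeline is seed-match based.

Sequences are stored as DNA in mRNA sense orientation (minus-strand
transcripts are reverse-complemented at load); seeds are RNA; the comparison
layer maps U to T. When several transcripts share a gene the longest is
kept, and SNPs whose reference base contradicts the sequence are dropped and
counted.

## Differentiation and enrichment

Per-SNP differentiation is the Weir–Cockerham (1984) variance-component
estimator θ̂ in its haploid form (inputs are phased chromosomes), with the
Hudson two-population estimator as an alternative, since absolute bin
membership depends on the estimator and the source analysis consumed
precomputed values. Small negative estimates are kept, not floored; SNPs
monomorphic everywhere are flagged undefined rather than set to 0. For
multi-locus summaries `fst_multilocus()` uses the ratio of summed components
Σa/Σ(a+b) — the 1984 multi-locus definition. The distinction matters: the
mean of per-SNP ratios is biased low (≈0.21 at a true drift of 0.3 in our
calibration) while the ratio of sums recovers the Balding–Nichols drift
parameter to within the ±0.03 acceptance band.

The enrichment test bins F_ST values into (0, .1, .2, .3, .4, .5, 1.0) —
half-open bins, top bin closed at 1, chosen so the top bin matches the
F_ST ≥ 0.5 extreme-differentiation criterion; edges are configurable because
they are not dictated by the method. Per bin, the enrichment score is
E_b = (t_b/T)/(g_b/G), target fraction over background fraction. The null is
1,000 seeded draws of T SNPs from the background (without replacement by
default — the described resampling draws datasets of distinct SNPs; with
replacement is a flag), summarized by mean, SD and a percentile interval.
The extreme bin additionally gets an upper hypergeometric tail probability,
computed in log space from `lchoose` sums; the background population
includes the target SNPs (targets are a subset of all 3'UTR SNPs), with the
exclusive convention available since the source is silent on it. No
multiple-testing layer is added: the analysis reports one raw tail
probability for the single extreme-bin test and empirical percentiles
elsewhere, and the pipeline mirrors that.

## Within-population selection statistics

**Fay–Wu's H** is reported unnormalized, H = θ_π − θ_H, from the unfolded
SFS of polarized SNPs; strongly negative H flags an excess of
high-frequency derived alleles. Windows default to 50 kb sliding by 10 kb
(the source consumed precomputed genome-wide values; window sizes there are
not restated, so ours are declared, not inferred). Significance lines use
the empirical 5% quantile of the panel-wide distribution (type-7 linear
interpolation).

**EHH and iHS.** EHH at a distance is the probability that two random
haplotypes carrying the core allele are identical from the core to that
distance, computed by exact haplotype grouping; iHH is the trapezoidal
integral over physical distance (no genetic map is available), truncated
when EHH drops below 0.05 or at the distance bound. The unstandardized
score is ln(iHH_ancestral/iHH_derived), standardized to mean 0 / SD 1
within 20 equal-width derived-frequency bins. Minimum MAF is 0.05 and
|iHS| > 2 is the conventional signal threshold; all of these follow the
standard iHS literature and are configurable. One numerically consequential
choice: when the analyzed region is itself a sweep locus (as in our
injected-sweep simulations), the sweep floods its own frequency bins and
within-panel standardization absorbs the signal; real analyses standardize
genome-wide, where sweeps are negligible. `ihs()` therefore accepts
reference bin moments (`ihs_bin_moments()` on a sweep-free panel), and the
calibration tests use the pre-sweep panel as the genome-wide reference.

**CLR sweep scan.** At each grid position, the composite likelihood of the
observed per-SNP derived counts is evaluated under a sweep model: with
pre-sweep sample count b₀ drawn from the background SFS, each of the n
lineages independently *escapes* the sweep with probability
p_e = 1 − exp(−α·d) at distance d, keeping its original state, while all
non-escaped lineages carry the swept haplotype's state. Marginally

P(b | b₀) = (1 − b₀/n)·Binom(b; b₀, p_e) + (b₀/n)·Binom(n−b; n−b₀, p_e),

which collapses to a point mass at b₀ when p_e = 1. The background SFS is
estimated from all panel SNPs in the population (counts 0..n, Laplace
pseudocount 0.5 so no observable count has probability zero — the
smoothing cancels in the nested limit). α is maximized over a log-spaced
grid that always includes the p_e ≡ 1 point, so CLR ≥ 0 holds exactly as a
nested-model property. Note the direction: escape probability *grows* with
α·d, so the no-sweep submodel is the α → ∞ (equivalently p_e ≡ 1) limit and
small α means a wide sweep footprint. A grid maximizer rather than a
continuous optimizer keeps the scan deterministic.

## Hitchhiking control and clines

A candidate (allele-dependent site call with F_ST ≥ 0.5) is excluded when
any annotated functional variant within ±500 kb has r² ≥ 0.5 with it. LD is
computed by direct haplotype counting (the panel is phased; an EM fallback
for unphased data is out of scope): D, D′ (normalized by the
allele-frequency bound), r², and a base-10 multinomial likelihood-ratio LOD,
the standard pairwise definition, since the source reports LOD without
defining it. r² is evaluated within each population separately — pooling
haplotypes across differentiated populations manufactures r² between any
two high-F_ST loci through structure alone, which would void the filter.

The cline test is the unweighted Pearson correlation of derived allele
frequency with absolute latitude across non-excluded populations.
Populations are excluded by metadata flags (with reasons), not hard-coded
names. Because population frequencies are not independent (shared ancestry),
no parametric p-value is attached; inference is the empirical extremeness
percentile of the correlation against the genome-wide distribution,
two-sided on |R| by default (the source says "most extreme" without
specifying sidedness; one-sided is a flag), self-inclusive (the most extreme
SNP in a set of N gets 1/N), with a restricted variant over SNPs with
F_ST ≥ 0.5.

## The synthetic world

The generator's defaults state the simulated world once:

* **Differentiation**: ancestral frequencies uniform on [0.05, 0.95]
  (avoiding near-monomorphic columns; panel-wide monomorphic columns are
  dropped and counted), per-population frequencies Balding–Nichols Beta with
  mean p and variance F·p(1−p). Default panels: 2 populations × 50 diploids,
  drift F = 0.1 for fixtures, F = 0.3 for calibration, matching common-SNP
  differentiation scales in human multi-population panels.
* **LD**: each haplotype is an independent draw from a Gaussian AR(1) copula
  — a latent autoregressive process along the SNP sequence with step
  correlation exp(−rate·distance), thresholded at the population frequency.
  The stated design was a Li–Stephens-style copying chain; a copying chain
  correlates the sampled haplotypes with each other, inflating the
  between-population variance component and biasing the very F_ST
  calibration the acceptance criteria demand, so the copula (independent
  haplotypes, exact marginals, r² decaying with distance at rate 5e-5/bp,
  halving over roughly 15 kb) was adopted instead.
* **Sweeps** are injected structurally, not forward-simulated: carriers of
  the sweep allele are raised to the target frequency and every
  post-conversion carrier copies one donor haplotype within the
  homogenization radius (default 100 kb, final frequency 0.9). This
  produces the tested signatures — extended homozygosity, high-frequency
  derived excess, locally distorted SFS — by construction, at the price of
  an unrealistically sharp sweep edge.
* **Planted sites**: one synthetic UTR per chosen SNP (lengths 80-160 bp,
  GC 0.5, 10% minus-strand), with one allele completing a site of the
  requested type (default mix 40/40/20 over 8mer/7mer-m8/7mer-A1; no 6mers
  since the main scan rejects them) and the other breaking it; flanks are
  rejection-sampled until scanning the window against *all* families returns
  exactly the planted call, so recovery is exact by construction and the
  scanner itself is validated separately against an exhaustive
  complementarity oracle. Background UTR SNPs with no allele-dependent call
  are generated the same way. Planted SNPs are chosen isolated enough that
  no other panel SNP falls inside any transcript.
* **Clines**: planted SNPs get frequency clamp(0.9 − 0.01·|latitude| +
  N(0, 0.05)) across populations (latitudes spread over 0-65°), null SNPs
  get latitude-independent per-population noise around a random base. The
  slope/noise choice puts planted |R| near 0.95 against a null |R| spread of
  ≈0.2 with 25-30 populations — a strong cline, deliberately clearly
  separated, in the spirit of the strongest observed examples.

What a green test does *not* establish: the generator has no demography
(growth, migration, admixture), no mutation model, no forward-in-time
selection, no genetic map, and sweep edges are sharp. Power numbers measured
here are for this stated world, not for any real cohort.

## Determinism and numerics

Every generator is a pure function of (config, seed): seeds are set inside
`with_seed()`, which restores the caller's RNG state, and the pipeline fans
one global seed into logged per-stage child seeds (all below 2^31). Pipeline
reruns with the same seed produce byte-identical tables. Degenerate inputs
are flagged rather than silently coerced: monomorphic SNPs give NA LD and
F_ST, fewer than 2 core-allele carriers give undefined EHH, iHH_derived = 0
gives an undefined iHS, constant frequency gives an undefined cline
correlation. Filter-count bookkeeping (input = retained + excluded) is
emitted at every pipeline stage.

## Known limitations

The CLR model is a deliberately reduced form of the full sweep-likelihood
machinery (single swept state, binomial escape, no recombination-rate
input); it is used for localization, not parameter estimation. The
hypergeometric enrichment test treats SNPs as exchangeable, ignoring LD
between background SNPs, exactly as the source analysis does. iHS within
small simulated regions depends on reference-moment standardization as
described above. Multiallelic VCF records are skipped, not decomposed; and
ancestral-allele conflicts between multiple outgroups are not adjudicated —
one ancestral call per SNP is accepted, and SNPs without one are retained
but excluded from polarization-dependent statistics.
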