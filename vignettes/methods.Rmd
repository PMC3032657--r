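---
title: "Methods: candidate-gene diversity and LD analysis in popgenld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene diversity and LD analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popgenld)
```

# The data model

`popgenld` analyses surveys in which heterozygous plants from open-pollinated
populations are crossed to a homozygous tester line (gamete capture), so that
subtracting the tester allele yields one fully **phased haploid gene
fragment per line**. Every analysis in the package leans on this: linkage
disequilibrium is computed from directly counted haplotype frequencies (no EM
phasing step exists or is needed), haplotype inventories are exact, and AMOVA
has two levels only (among populations, among individuals within them) —
there is no within-individual level in haploid data.

A study consists of per-gene gapped FASTA alignments with BED-like region
annotations (5'UTR / exon / intron / 3'UTR plus the reading-frame offset of
the first exonic base), an SSR table of single-allele calls per line, and a
population assignment table. Fragments are stored in coding orientation by
convention; there is no strand handling.

# Site calling and classification

A SNP is an alignment column with at least two unambiguous nucleotides and at
least two distinct ones; gaps never count as alleles. An insertion–deletion
polymorphism is treated as **one binary polymorphic site**: a maximal run of
`-` shared (identical start and end) by its carriers, anchored at its first
column. Carriers whose gap extent differs form distinct indel sites — this
preserves single-site atomicity without guessing at event homology. Missing
data are handled by per-site deletion throughout.

The minor allele frequency of a site is the frequency of its second most
common allele, which keeps MAF in [0, 0.5] also for triallelic SNPs (these
are supported and flagged, not silently merged). The LD stage removes sites
with MAF < 0.05 (a site at exactly 0.05 is kept); rare variants make r²
estimates unstable.

Exonic SNPs are classified by translating both alleles' codons, with the
per-column majority base as the codon background; a codon truncated by the
fragment edge yields `NA` rather than a guess. Non-synonymous changes are
additionally scored for polarity change using three residue classes
(nonpolar: A V L I P F W M G C; polar uncharged: S T Y N Q; charged:
D E K R H). Exonic indels with length divisible by three are
`frameshift-free-indel`; others are flagged and not classified.

# Diversity statistics

Nucleotide diversity π is the mean over unordered sequence pairs of
differences per comparable site, where "comparable" means both rows carry an
unambiguous nucleotide — alignment gaps are excluded from numerator *and*
denominator, so indels never inflate or deflate π. Consequently indel sites
contribute to haplotypes and LD but never to π or to the segregating-site
count S. Exact concordance with tools that handle gaps differently is
therefore not promised; the convention is documented rather than hidden.

Haplotype diversity uses the sample-size-corrected Hd = n/(n−1)(1 − Σpᵢ²)
with Nei's (1987) heterozygosity variance for the standard deviation.

Tajima's D uses the 1989 constants, with π entering as the *total* mean
pairwise difference count and S counting SNP sites only. Significance comes
from Tajima's beta approximation on [D_min, D_max]; the p-value is
two-sided. A gene with S = 0 returns a flagged `NA` — D is undefined there,
and the package does not emulate tools that report a value anyway.

# dN/dS and the neutrality test

ω is estimated by Nei–Gojobori (1986) counting: fractional
synonymous/non-synonymous site counts per codon (changes to stop codons count
as non-synonymous; observed stop codons are a data-integrity error by
default, maskable in pipeline mode), equal-weight averaging over mutational
pathways for multi-hit codons (pathways through stop codons are excluded when
a stop-free pathway exists), Jukes–Cantor correction, and gene-level
aggregation as the **ratio of pairwise means** (more stable than the mean of
ratios when many pairs have dS = 0). For degenerate toy inputs where a
substitution proportion reaches the Jukes–Cantor bound of 3/4, the capped
uncorrected proportion is used so that quantities like ω = 0 remain defined;
realistic within-species data never get near the bound.

A maximum-likelihood codon model with a likelihood-ratio test is a larger
estimator with its own assumptions; within-species divergences here are tiny,
where counting methods and ML agree in sign and magnitude class. The shipped
significance method is a codon bootstrap: resample codons with replacement,
recompute dN − dS, and report the two-sided normal tail of the observed
difference over the bootstrap standard deviation. With fewer than 10
polymorphic codons the p-value is flagged unreliable. No claim is made of
reproducing published ω values estimated with other machinery.

# SSR statistics

PIC follows Botstein et al.; its bootstrap uses multinomial resampling of the
locus' non-missing calls, exactly equivalent in distribution to resampling
lines at a single locus but vectorisable to the default 10,000 replicates.
Both a percentile confidence interval and a bootstrap SD are emitted, since
summary tables in this literature print sometimes one, sometimes the other.

Allelic richness uses the rarefaction formula
Rs = Σᵢ [1 − C(N−Nᵢ, n)/C(N, n)] via log-gamma binomials; the rarefaction
size defaults per locus to the smallest per-population count of non-missing
calls (the Fstat convention) and is configurable. A private allele is one
observed in exactly one population; the percentage denominator is that
population's total count of distinct observed alleles summed over loci (this
convention reproduces the arithmetic of published tables of this shape; see
the acceptance tests).

# Linkage disequilibrium and its decay

With phase known, D = p_AB − p_A·p_B is counted directly. One composite
formula r² = ΣᵢⱼDᵢⱼ²/[(1−Σpᵢ²)(1−Σqⱼ²)] serves all site types — it reduces
algebraically to D²/(p_A p_a p_B p_b) in the biallelic case and handles
multiallelic SSR pairs. Note a property of this composite that surprises at
first sight: for k equifrequent alleles in perfect association it equals
1/(k−1)·(k−1)/k·…, e.g. 0.5 for k = 3, not 1 — it is a variance-weighted
summary, not a normalised association measure. Fisher's exact test is
reported for biallelic pairs only; multiallelic pairs carry `NA` (a
documented limitation rather than a silently different test).

The decay model is the Hill–Weir drift–recombination expectation with sample
size adjustment, parameterised per bp (C = Γ·d). Γ is fitted by nonlinear
least squares with three fixed starts plus a deterministic log-grid/golden
section fallback; the best SSE wins, so the fit is reproducible bit-for-bit.
A fit whose curve has already decayed below 0.05 before the first observed
distance is flagged as boundary (`gamma` is then only bounded below by the
data).

The significance threshold takes all C(L, 2) pairwise r² values among the
unlinked SSR loci, square-root transforms them (closer to normality), takes
the 95th percentile with type-7 linear interpolation (fixed for
reproducibility), and squares back. The **extent of LD** is the bisection
root of E[r² | Γ̂d, n] = threshold, with sentinels: `zero` when the curve
starts below the threshold, `beyond_range` when it is still above at the
longest analysed fragment (default d_max = 1371 bp, configurable). The
pipeline pools all genes' within-gene pairs into one scatter (per-gene or
per-population fits are available by subsetting); `n` is the rounded mean
line count across genes.

# Population structure

DICE similarity 2a/(2a+b+c) is computed on binary presence/absence profiles —
one feature per SSR allele or per gene haplotype; a line missing from a gene
simply has that gene's features absent. PCoA is the classical Gower
double-centering of −D²/2 with eigen-decomposition; coordinates are
eigenvectors scaled by √λ, and percent variance uses positive eigenvalues
only (DICE distances are not Euclidean, so negative eigenvalues occur and are
excluded from the denominator rather than truncated silently).

AMOVA uses squared distances equal to allele mismatch counts across loci
(scaled up proportionally when calls are missing), the two-level
sums-of-squares decomposition with the unequal-sample coefficient n₀, and
Φ_ST = σ²_among/(σ²_among+σ²_within). Significance permutes whole individuals
among populations, with p = (1 + #{Φ_perm ≥ Φ_obs})/(n_perm + 1) so p is
never zero. (Some published tables describe this significance informally as
an exact test; the permutation test is what is actually computed here.)

# The synthetic-data generator

The generator is a forward-time **haploid** Wright–Fisher model: each deme of
`census_n` gametes reproduces with multinomial resampling; offspring
recombine two parental gametes at `rec_per_bp` per bp per meiosis (mosaic
gametes — this is what makes intra-genic decay testable), mutate under
infinite sites at `mu` per site per generation, and occasionally acquire
atomic indels (lengths drawn from {1, 2, 3, 200}, mirroring the observed
range in surveys of this shape, stored as presence/absence at an anchor and
never overlapping). Migration replaces a parent with one from another deme at
`migration_rate`. The final generation is sampled without replacement to the
configured sample sizes; each gene independently drops ~10% of lines to
emulate amplification failure. Reference coding sequence is generated
stop-free, and exonic mutations that would create a nonsense codon on the
reference background are rejected — the emulated genes are functional genes
under trivial purifying selection against nonsense alleles; rare stop codons
can still arise from recombination between intra-codon variants, which the
pipeline masks with a warning.

Because gametes are haploid, θ = 2Nμ and Γ = 2Nc per bp (the factor-4
diploid-census formulas halve). The recorded ground-truth
`gamma_per_bp = 2 × (n_pops × census_n) × rec_per_bp`.

SSR loci are simulated *unlinked by construction*: per locus, a global
allele-frequency vector (Dirichlet) is perturbed per population with
concentration (1−F_ST)/F_ST and one allele is drawn per line. They therefore
test the null behaviour of r² and the AMOVA partition but carry no linkage
signal at all.

## Stated-world defaults and calibration

Defaults emulate the survey design the package targets: 5 populations
sampled at 33/44/15/41/68 (201 lines), 11 fragments of the survey's lengths,
37 SSR loci with 2–18 alleles, among-population variance near 13%
(`ssr_fst = 0.13`, `migration_rate = 0.016` giving Nm ≈ 1.6), SNP density
near one per ~50 bp (`mu = 3.4e-6` at the default horizon), roughly 0–2
indels per gene (`indel_mu = 1e-4`), and intra-genic LD decaying within
hundreds of bp (`rec_per_bp = 6e-5`, i.e. Γ ≈ 0.06/bp for the pooled
metapopulation).

Two generator choices deserve explicit justification:

* **`census_n = 100` per deme.** The sampled breeding populations are larger
  than the samples but not huge; 100 haploid gametes per deme keeps the
  forward simulation fast while leaving every sample size (max 68) drawable
  without replacement. The configuration type carries this as an explicit
  field because "sample size" and "population size" must be distinct for the
  sampling contract to be checkable.
* **`n_generations = 1250`** follows the rule G ≈ 2.5 × total haploid census.
  An earlier default of 400 generations was a mistake worth recording: the
  within-deme genealogy equilibrates quickly (deme size 100), but the pooled
  metapopulation coalesces on the scale of its total size (≈570 with the
  structure correction), and at G = 400 the young genealogies depressed
  short-range r², inflating fitted Γ by ~1.7× relative to the generating
  value. A panmictic equilibrium control showed the fitting machinery itself
  to be unbiased, and the 5-deme study refit at G = 1200 recovered Γ within
  noise. Since the emulated populations are long-established and the
  Hill–Weir curve being fitted *assumes* drift–recombination equilibrium, the
  horizon was corrected to the equilibrium rule (and μ rescaled to keep the
  stated SNP density). The lesson is general: a generator meant to validate
  an equilibrium estimator must itself be run to equilibrium.

## What a green test does and does not establish

The generator emulates: phased haploid fragments with realistic density and
length; atomic indels; intra-genic recombination with a known Γ; moderate
population structure; unlinked multiallelic markers; per-gene missingness.
It does **not** emulate: selection (beyond nonsense purging), demographic
history (bottlenecks, admixture, growth), mutation-rate heterogeneity or
CpG effects, genotyping error, allele-size homoplasy in SSRs, or linkage
among SSR loci. Green acceptance tests therefore establish that the
*estimators* recover the truth of a neutral equilibrium island model at
study scale — not that any particular biological dataset meets those
assumptions.

# Numerical choices

* Percentiles: type-7 linear interpolation, fixed for reproducibility.
* Decay fit: SSE tolerance 1e-10, multi-start {1e-4, 1e-2, 1} per bp plus a
  log-grid fallback; extent bisection tolerance 0.5 bp.
* Permutation p-values use the +1 correction; bootstrap seeds derive from the
  single pipeline seed, so reruns are byte-identical.
* Degenerate inputs: monomorphic genes yield one haplotype (Hd = 0) and
  flagged Tajima results; genes with fewer than two MAF-filtered sites report
  mean r² as `NA` ("n.a." in CSV); ω is `NA` whenever dS = 0 or no exonic
  polymorphism exists.
* All stochastic stages (simulation, bootstraps, permutations) flow from one
  integer seed through a single RNG-restoring helper.

# Known limitations

* The multiallelic composite r² is one of several conventions in circulation;
  comparisons across tools should check which is in use.
* The Tajima beta approximation is known to be rough in the extreme tails.
* The AMOVA distance scales missing-data mismatch counts linearly, which is
  unbiased only if missingness is random across loci.
* Per-population decay fits (smaller n, population-specific thresholds) are
  supported by the building blocks but not orchestrated by `run_pipeline()`,
  which implements the pooled analysis.
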