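---
title: "Compression-based genetic relatedness: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression-based genetic relatedness: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comprel)
```

## The idea

Standard marker-based relatedness (the VanRaden genomic relationship matrix,
GRM) correlates genotypes one SNP at a time. Two individuals can also be
compared as *strings*: if the byte sequence of one genome helps a lossless
compressor describe the other, the two carry shared patterns — in genetic
data, shared haplotypes. `comprel` implements this compression view of
relatedness alongside the pedigree NRM and the GRM, a REML/BLUP engine that
accepts any mixture of these matrices as covariance kernels, and a
sliding-window scan that contrasts two populations for selection signatures.

The quantities, for a genotype string $x$ with compressed size $Z(x)$:

* **Compression efficiency** $CE = (S_B - S_A)/S_B$, the fractional size
  reduction of the encoded genotypes (sizes before/after compression).
* **CEh** $= CE / Het$: CE expressed against genome-wide heterozygosity.
  Runs of homozygosity make a string trivially compressible; dividing by
  heterozygosity separates haplotype-driven regularity from plain
  homozygosity.
* **Normalized compression distance**
  $NCD(x,y) = \dfrac{Z(xy) - \min\{Z(x), Z(y)\}}{\max\{Z(x), Z(y)\}}$,
  a computable proxy for the (uncomputable) normalized information
  distance. $Z(xy)$ compresses the concatenation.
* **CRM1** $s_{ij} = 2.5\,e^{-5 d_{ij}}$ — Shepard's distance-to-similarity
  law applied to the NCD matrix. Simple, but its diagonal is unscaled.
* **CRM2** — a linear rescaling: diagonal $\bar d_{\mathrm{diag}}/d_{ii}$
  (so self–self values average exactly 1) and off-diagonal
  $1.75\,[1 - (d_{ij}-\min d)/(\max d - \min d)]$, grounding the matrix in
  the expectations of meiosis (1 self, 0.5 full sibs, 0.25 half sibs).
* **CRM3** — each animal's profile of per-window CE values, correlated
  between animals.

## The mixed model

`reml_fit()` fits $y = X\beta + \sum_r Z_r u_r + e$ with
$u_r \sim N(0, C_r\sigma^2_{u_r})$ for any set of relationship matrices
$C_r$, by direct maximization of the restricted log-likelihood over
log-variances (Nelder–Mead with a restart polish; convergence when a
restart improves the objective by less than $10^{-8}$ and moves parameters
by less than $10^{-6}$). Single-kernel models use an eigendecomposition of
the kernel, making each likelihood evaluation $O(n)$ after one $O(n^3)$
factorization — cross-validation refits rely on this path. Kernels that are
not positive semi-definite (possible for CRM1/CRM2, which are not built as
cross-products) are bent by flooring eigenvalues at $10^{-6}$, with a
warning. BLUP breeding values are
$\hat u_r = \sigma^2_{u_r} C_r Z_r' V^{-1}(y - X\hat\beta)$, so animals
without records receive EBVs through their relatives.

Fitting a pedigree kernel and a marker kernel together decomposes the
additive variance; the **missing heritability**
$C_{miss} = 1 - \sigma^2_u / (\sigma^2_a + \sigma^2_u)$ is the fraction of
the pedigree-defined variance the marker matrix fails to capture.
Cross-validation accuracy repeatedly holds out 20 % of phenotypes, refits,
and correlates predicted EBVs of the held-out animals with their
phenotypes adjusted by the *training* fixed-effect estimates — the
conventional reading of "adjusted phenotypes", adopted here because the
adjusted values must not borrow information from the held-out records.

## The worked toy example

A five-animal, 30-SNP toy (in `toy_fixture()`) anchors the arithmetic:

```{r toy}
toy <- toy_fixture()
G <- grm(toy$genotypes)
round(unclass(G), 2)
```

Animals 1–2 (parent–offspring in the accompanying pedigree) score 0.35,
animals 3–4 score 0.67, and animal 2 against animals 3–4 scores −0.67 —
the centering by twice the sample allele frequency is what makes negative
values (less similar than an average pair) possible, and is the only
construction that reproduces these anchors.

## Compressor configuration: two hard-won constraints

The compressor is DEFLATE (the algorithm behind gzip), driven directly
through zlib with a pinned header so sizes are bit-reproducible. Two
properties of DEFLATE shape the defaults and the honest scope of the
method:

1. **Search depth.** Genotype strings use a three-symbol alphabet, so the
   hash chains DEFLATE consults for back-references are saturated by short
   nearby matches. At the gzip default level 6 the bounded chain search
   gives up long before reaching a matching segment thousands of bytes
   back: the self-distance $NCD(x,x)$, which should be near 0, collapses
   towards 1 already for 10-kb strings. At level 9 the chain search is deep
   enough to recover long-range similarity. **The package default is
   therefore level 9**; level 6 remains available
   (`compressor_config(level = 6)`) to mirror the gzip tool.
2. **Window size.** DEFLATE can only reference the previous 32 KB. Beyond
   ~32 000 loci encoded at one byte per genotype, two concatenated genomes
   cannot "see" each other and every NCD saturates regardless of level.
   Whole-chip analyses should therefore compress per window or per
   chromosome chunk (as the CRM3 and scan components do by construction),
   or operate on subsets of up to ~30 k SNPs.

`compressed_size()` also reports sizes net of the container overhead
(the size of compressing an empty input, ~20 bytes for a gzip stream).
Window-level CE uses net sizes — at 50-SNP scale the container would
otherwise dominate — while NCD uses raw sizes, matching its defining
formula. $Z(xy)$ is computed with the lower-indexed animal first and the
matrix is symmetrized by averaging the two orders, since DEFLATE is
order-sensitive in practice though the distance is symmetric in intent.

## The synthetic-data generator

Every statistical claim in the test suite is exercised on data from
`simulate_pedigree_population()`, `simulate_two_populations()` and
`simulate_phenotype()`:

* **Pedigrees** are gene-dropped: founders drawn in Hardy–Weinberg
  proportions from a uniform allele-frequency spectrum on [0.05, 0.95],
  offspring built from one recombinant gamete per parent. The
  recombination fraction between adjacent loci defaults to 0.5 (unlinked —
  minimum Monte Carlo variance for the 0.5/0.25 relatedness expectations);
  setting it small (e.g. 0.002) produces the long shared haplotype blocks
  that real chips show and that compression-based relatedness depends on.
* **Two-population mode** draws each population's frequencies
  Balding–Nichols style around a common ancestral spectrum at a target
  $F_{ST}$ (0.2 by default, the regime of strongly diverged cattle
  populations), and can overlay a hard sweep: within a chosen region,
  population A's frequencies are pushed to 0.95 fixation of the
  ancestrally major allele, collapsing local heterozygosity without
  touching population B.
* **Phenotypes** are $y = X\beta + u + e$ on a yearling-weight-like scale
  (mean 300, phenotypic variance 350 trait-units², intercept plus a
  3-level contemporary group with effects 0/+15/−10), with $u$ drawn from
  a supplied relationship matrix or from random causal loci.

What the generator does **not** emulate: realistic linkage-disequilibrium
maps and recombination hotspots, genotyping error and imputation
artifacts, selection within the pedigree, and the MAF spectra of real
chips. Passing tests therefore demonstrate internal consistency of the
estimators under clean Mendelian data, not field performance.

## Numerical and design choices

* Missing genotype calls are the integer −9 internally and the character
  `'3'` in encoded strings, keeping byte length fixed and the alphabet
  unambiguous. Missing calls are centered to zero in the GRM (no
  information) and excluded from frequency and heterozygosity counts.
* Monomorphic loci contribute zero to both the GRM numerator and
  denominator and are retained, matching the formula verbatim.
* CRM2's min/max range is taken over *all* pairs including the diagonal by
  default — the only reading under which off-diagonal values are bounded
  by $1.75\,(1 - (d_{\min\mathrm{off}} - d_{\min})/(d_{\max}-d_{\min}))
  \approx 0.75$ on data whose self–self distances are smallest; the
  off-diagonal-only scope (under which the bound is 1.75) is available as
  an option.
* CRM3 windows default to 50 consecutive SNPs; the final partial window is
  retained; the correlation is Pearson (Spearman optional). Window
  partitioning always yields $\lceil L / w \rceil$ windows.
* Per-SNP $F_{ST}$ is the two-population Weir–Cockerham ANOVA estimator in
  its allele-frequency form (only frequencies and allele counts enter);
  negative estimates are retained; loci fixed for the same allele in both
  populations are defined as 0 and flagged. Window $F_{ST}$ is the
  arithmetic mean of per-SNP values; genome-wide summaries should use
  `fst_overall()` (ratio of summed variance components), because averaging
  per-SNP ratios is noticeably downward biased (≈0.15 realized under a
  generative $F_{ST}$ of 0.2, versus ≈0.20 for the ratio-of-sums form).
* Windows with zero heterozygosity have undefined CEh and are flagged and
  excluded from ranking rather than assigned infinite values.
* The NRM uses the tabular method with founders treated as non-inbred;
  ancestry can be truncated at a given number of generations counted back
  from the youngest generation (a study choice, not part of the method —
  unlimited by default).

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at deliberately reduced
scale: pedigree simulations of 40–160 families at 2 000–5 000 unlinked
loci (≥ 200 half-sib and ≥ 200 full-sib pairs, n = 800 phenotyped animals
for variance-component recovery over 20 replicates), two-population scans
of 40–100 animals per population at 1 000–5 000 loci, and NCD matrices of
up to ~50 animals at 5 000 loci. These sizes give Monte Carlo error well
inside the asserted bands while keeping a full run in minutes.

## Known limitations

* **Half-sib resolution of CRM2.** Full sibs share IBD2 segments, which
  appear as exact byte matches and separate cleanly. Half sibs share only
  IBD1 segments, where the second haplotype differs; the resulting CRM2
  contrast between half-sib and unrelated pairs on simulated data
  (~0.002) sits at the compressor's resolution floor, so the class
  ordering full-sib > half-sib > unrelated holds on average but not in
  every replicate. This is a genuine property of DEFLATE-based NCD on
  clean simulated data, not a tuning artifact.
* **Chip-scale NCD** requires chunking (the 32 KB window, above).
* The toy example's published per-animal CE percentages and NCD values
  depend on the exact byte layout of the original genotype files, which
  is not public; the package reproduces their *ordering relations*
  (animals 1 and 5 most compressible, 3 and 4 least) and the GRM anchors
  exactly, but not those compressor-dialect-specific constants.
* Variance-component standard errors are not computed (no information
  matrix); inference on components should use likelihood-ratio
  comparisons or replicate simulations.

## A small end-to-end run

```{r pipeline}
sim <- simulate_pedigree_population(n_families = 40, family_size = 5,
                                    n_loci = 2000, seed = 7)
G <- grm(sim$genotypes)
ph <- simulate_phenotype(G, h2 = 0.4, seed = 7)
fit <- reml_fit(y ~ cg, data = ph, random = list(grm = G))
summary(fit)
cv <- cv_accuracy(fit, n_splits = 5, seed = 3)
c(mean = cv$mean, sd = cv$sd)
```

(A note on scale: with only a hundred or so genotyped animals at modest
locus counts, the bulk eigenvalues of a GRM are close enough to 1 that
$\sigma^2_u G + \sigma^2_e I$ is weakly identified and REML can drift to a
boundary; variance-component fits here use several hundred animals.)
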