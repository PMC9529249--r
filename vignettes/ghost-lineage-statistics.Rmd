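---
title: "Ghost-lineage introgression statistics: models, choices and limits"
author: "ghostDex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghost-lineage introgression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

Everything starts from a `SiteMatrix`: biallelic sites by samples, one
pseudo-haploid call per cell (0/1/missing), with per-site annotation
(alleles, ancestral state, transversion and CpG flags) carried as row
metadata of a `RangedSummarizedExperiment`. A pseudo-haploid call is a
single allele sampled per site and individual — the standard reduction for
low-coverage ancient genomes, which avoids genotype-likelihood modelling at
the price of extra sampling noise. Two consequences drive many choices
below: each sample contributes exactly one allele to any frequency, and a
panel "fixed ancestral in the sample" is *not* fixed in the population.

Polarization recodes every retained site so that code 0 matches the
outgroup-derived ancestral track; sites whose ancestral base is unknown or
matches neither allele are dropped (counted and reported). The minor-allele
frequency used by `filterSites()` is computed from the non-missing haploid
calls; filters apply in a fixed order (whitelist, CpG, transversion,
minimum call count, MAF) so that logged per-filter drop counts are
well-defined. Transversion-only analysis is the usual guard against
post-mortem deamination (C→T/G→A) artefacts: a site whose allele pair is
A/G or C/T is a transition and is excluded.

## D and D_ex

For panels H1, H2, H3 with per-site derived-allele frequencies
$p_1, p_2, p_3$ among non-missing calls, each site contributes
$(1-p_1)p_2p_3$ to nABBA and $p_1(1-p_2)p_3$ to nBABA, and

$$D = \frac{\sum nABBA - \sum nBABA}{\sum nABBA + \sum nBABA}.$$

Single genomes are the degenerate 0/1 frequency case, where these weights
reduce to literal ABBA/BABA pattern counts. We chose frequency weighting
for groups (rather than integer "counts of observations") because it is
insensitive to uneven coverage across group members and reduces exactly to
the single-genome definition.

The extended statistic first ascertains lineage-specific variation.
A site enters the D_ex site set iff:

1. H3 carries the derived allele (a group H3 must be *fixed* derived among
   its non-missing calls by default — the conservative reading; an
   any-derived toggle exists);
2. every conditioning panel and the root-fixed panel has at least one
   non-missing call ("covered at least once");
3. strict mode: the derived frequency is 0 in every conditioning panel and
   in the root-fixed panel; window mode: 0 in the root-fixed panel and
   within $(l, h]$ (default $(0, 0.10]$) in at least one conditioning
   panel.

Window mode's "at least one panel" reading is the default because the
alternative ("all panels at most $h$") changes the question from "where
does rare sharing occur" to "nowhere is it common"; the stricter variant is
available via `constrainAllGroups = TRUE`. Over retained sites, nBABA_ex
and nABBA_ex accrue $p_1$ and $p_2$, and D_ex is normalized identically to
D. Swapping H1 and H2 negates both statistics bit-exactly, which the test
suite asserts.

Disentangling restricts window-ascertained sites to those where the target
genome carries the derived allele and asks, per outgroup individual, how
often that individual shares it. Two denominators are defensible —
shared-variant *sites*, or total sharing *observations* summed over
individuals — and both are reported; the per-site proportion is the
default because it keeps rows comparable across individuals with different
coverage. The measure remains coverage-sensitive (a deeper individual is
non-missing at more shared sites), which is why the per-individual
informative-site counts are part of the output.

## Resampling errors

Linkage makes per-site resampling anticonservative, so errors come from
contiguous genomic blocks (default 5 Mb; block id is
`floor((pos-1)/blockSize)` within a chromosome). Blocks with zero
informative mass are excluded rather than resampled as zeros — resampling
empty blocks would deflate the variance of the *informative* mass that the
statistic actually uses. Two estimators are provided:

- a weighted delete-one-block jackknife (Busing et al. 1999), with block
  weights equal to the block's informative pattern mass — the default for
  classic D, matching common ABBA-BABA practice;
- a block bootstrap (resample all blocks with replacement, default 1000
  replicates), the default for D_ex. Replicate $b$ draws from
  `seed + b`, so runs are reproducible and trivially parallelizable.

Z = D/se; se = 0 (a degenerate resampling distribution) yields Z = NA with
a warning rather than an infinite score. An exhaustive-enumeration oracle
(all $3^3$ resamples of three blocks) pins the bootstrap's large-replicate
limit in the tests.

## Phylogenomics

IBS distance is the mismatch proportion over co-called sites, with
per-pair deletion of missing data; pairs with no co-called sites are NA
and block tree building with an explicit error. Neighbour joining uses the
canonical Saitou–Nei agglomeration via `ape::nj()` (the field-standard
implementation); negative branch lengths, a known NJ artefact on
non-additive inputs, are clamped to zero with a warning. Node support is a
*pseudo-bootstrap over genomic regions*: each replicate samples 50 blocks
of 5 Mb without replacement, recomputes IBS and NJ, and supports are the
percentage of replicates containing each internal bipartition of the base
tree. Supports are computed on unrooted bipartitions, so the rooting
choice cannot alter them. Classical (Torgerson) MDS uses
`stats::cmdscale`; axis signs are made deterministic (largest-magnitude
loading positive), and negative eigenvalues among the retained axes draw a
warning. Distance-to-outgroup QC flags samples more than 3 sd from the
mean of their leave-one-out group peers in either direction — error
inflates the distance, while duplicate-like samples sit anomalously low.

## mtDNA summaries

Pairwise differences between aligned consensus sequences exclude positions
where either sequence is `N`; alignment gaps are treated as missing by
default (toggleable), since consensus callers emit `N` for uncovered sites
and gaps usually represent indel uncertainty rather than substitutions.
Group summaries are means of *raw counts*, not per-site rates, matching
how such matriline diversities are usually quoted; exclusions (e.g. a
low-stringency consensus) are applied before pairing.

## The synthetic generator

`simulateScenario()` draws a root derived-allele frequency per site from
Uniform(0.05, 0.95), evolves it down a population tree by per-branch
Balding–Nichols pulls
$p' \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$,
optionally mixes a ghost leaf's frequency into a target population
($(1-\alpha)p + \alpha p_{ghost}$, genome-wide or within one block), and
then draws pseudo-haploid calls with per-sample call rate and per-call
symmetric error (folded into the Bernoulli probability). Transition vs
transversion allele pairs and CpG flags are drawn at stated fractions
(defaults 2/3 and 5%). All randomness flows from one scenario seed;
identical seeds give byte-identical output.

Drift parameters are *drift intensities*, not divergence times. The
`tur_like_ghost` preset uses F = 0.5 for the deep outgroup branch, 0.03–0.10
within the ingroup clades, and F = 0.85 for the ghost branch with four
sampled ghost genomes. The high ghost drift encodes a severely
bottlenecked, long-isolated refugial lineage; it makes ghost-derived
alleles essentially private and internally fixed, which is the regime in
which conditioning on the ghost's own lineage-mates empties the ascertained
site set — the specificity behaviour the statistic is designed to have. The
admixture proportion is $\alpha = 0.1$ genome-wide
(`introgressed_block` instead plants a locally fixed haplotype,
$\alpha = 0.9$, in a single 5 Mb block). The null preset is panmictic below
the ingroup ancestor with the same diverged outgroup.

What the generator does *not* model: linkage within blocks (sites are
exchangeable given frequencies), new mutations on internal branches (all
variation is standing at the root, so "privacy" arises from drift, not
mutation), reference bias, damage patterns, and read-level error structure.
Passing the calibration suite therefore shows the statistics behave
correctly under drift + pseudo-haploid sampling + symmetric error; it does
not certify robustness to damage or mapping artefacts, which is exactly why
transversion-only filtering and the error-QC table exist on the real-data
path.

The mtDNA simulator evolves sequences by exact Jukes–Cantor transition
probabilities along a supplied tree ($P(\mathrm{diff}) =
\tfrac{3}{4}(1-e^{-4d/3})$, multiple hits included) and masks each leaf
position to `N` at a stated rate.

## Calibration experiments and problem sizes

`dexNullReplicate()`/`dexGhostReplicate()` fix the canonical experiment:
500,000 sites on 20 chromosomes of 50 Mb (200 blocks of 5 Mb), call rate
0.9, error 0.002, 1000-replicate bootstrap, 50 seeded replicates per
calibration. These sizes keep a full calibration within minutes on a single
core while leaving ~2,500 sites per block, enough that the block bootstrap
operates in its intended regime. Under the null the |Z| ≥ 3 rate is
expected at the Gaussian ~0.3%, so observing it in fewer than 2% of 50
replicates is the pass condition; at α = 0.1 the open test is expected to
detect (D_ex > 0, Z ≥ 3) in ≥ 90% of replicates while the ghost-conditioned
control returns to null-like rates.

## Numerical and degenerate-input policy

Zero informative sites is an explicit error for D and D_ex (never a silent
0). Fewer than two informative blocks is an error for any standard error.
Identical H1/H2 panels are permitted (D_ex ≡ 0, a useful self-check) but
partially overlapping panels are rejected, as is any overlap of H1/H2 with
H3 or the conditioning set. Multi-allelic tped sites are rejected at read
time with a logged warning (the caller's handling upstream is unknowable
from its output, so the reader takes the conservative path); discordant
haploid token pairs are a hard error naming site and sample. Missing-call
encodings `0 0` and `N N` are treated identically. Coordinates are 1-based
and fully closed throughout; chromosome names are opaque strings.
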