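---
title: "Detecting and characterizing polymorphic inversion landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing polymorphic inversion landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscape)
```

## The problem

Polymorphic chromosomal inversions segregate as two orientations of a
chromosomal segment. Recombination is suppressed in heterokaryotypes, so
the two arrangements diverge like partially isolated populations while the
whole segment is inherited as one locus. In SNP data from many individuals
this produces local population structure that is decoupled from geography,
long-range linkage disequilibrium (LD), and a characteristic three-cluster
genotype geometry. `invscape` turns those signatures into a reproducible
pipeline: detect candidate regions, genotype samples into karyotypes,
characterize each inversion (frequencies, age, Hardy–Weinberg behaviour,
clines), and test maintenance hypotheses (mutation load, gene enrichment,
genotype–environment association). This vignette documents the models, the
parameter choices, and the design decisions behind each stage.

## The synthetic cohort generator

Real inversion landscapes come from hundreds of resequenced genomes; the
package instead ships a parametric generator whose defaults mirror a
range-wide European sampling design: 18 populations in two weakly
differentiated geographic groups (7 southern, 8 northern) bridged by three
admixed populations, 240 diploid individuals (six populations of 14,
twelve of 13), and an optional X-like contig on which males are
hemizygous.

The model is Balding–Nichols throughout. Each site draws an ancestral
frequency from a density proportional to 1/p truncated to [0.01, 0.99] —
a neutral-spectrum-like excess of rare alleles, which matters for the
MAF-matched permutation tests. Collinear sites then draw one frequency per
geographic group from `Beta(p(1−F)/F, (1−p)(1−F)/F)` with `F = group_fst`
(default 0.021); admixed populations mix the two group frequencies by
their ancestry fraction. Sites inside an inversion draw one frequency per
*arrangement* with `F = arr_fst` (default 0.4, inside the moderate-to-high
range typical of Mb-scale inversions), and a fraction `fixed_frac` of
inversion sites is fully fixed between arrangements — this is the dial
that controls absolute divergence `d_xy` and therefore apparent age. Every
haplotype carries one arrangement label per inversion, Bernoulli with the
population's cline-adjusted frequency; the cline is logistic in latitude,
`freq = logistic(logit(base_freq) + slope·(lat − 50°))`, which keeps
frequencies in [0, 1] for any slope. Genotypes are sums of two
conditionally independent haplotypes. Overlapping inversions are two
specs with overlapping intervals; sites in the geometric intersection are
controlled by the first-listed inversion, so the second inversion's signal
comes from its exclusive segment — which is exactly how it surfaces on a
later PC axis in genotyping. A double crossover is modelled as a third
haplotype class R derived from B that carries A-arrangement alleles inside
a nested subinterval. Mutation-load asymmetry (`load_excess_minor = L`)
shrinks nonsynonymous minor-arrangement frequencies toward 0.5 by the
factor `s` solving `0.5 − s²(0.5 − E[h]) = L·E[h]`, so the minor
arrangement's expected nonsynonymous heterozygosity is exactly `L` times
baseline (valid while `L·E[h] < 0.5`; clamped otherwise). Missingness is
uniform at random (2% default); per-site depth is Normal(23, 6) truncated
at 1, matching a medium-coverage resequencing design, and male per-sample
depth on the X-like contig is halved.

What the generator deliberately does **not** emulate: within-arrangement
LD (sites are conditionally independent given arrangement and group, so
all LD is arrangement-induced), indels, read-level error, and
non-uniform missingness. Two consequences for interpreting green tests.
First, the LD-block criterion ("median pairwise r² > 0.4") only fires for
strongly diverged arrangements (a large `fixed_frac`); at `arr_fst = 0.4`
with no fixed differences the median pairwise r² is around 0.02, so
detection on such simulations rests on the local-PCA/MDS route. Real
inversions carry additional within-arrangement LD that the block detector
would also exploit. Second, all diversity statistics are per *variant
site*; real per-bp values are diluted by monomorphic positions, so
simulated `d_xy` (≈ 0.2 per SNP) and the ages derived from it are on a
different scale than per-bp field values — the estimators are identical.

## Detection

`local_pca()` re-implements the windowed-PCA scan concretely: windows are
runs of `window_snps` consecutive SNPs (default 100 for stability at low
density; bp windows are available), each summarized by the rank-k
(default k = 2) reconstruction of its sample×sample covariance,
trace-normalized; the distance between windows is the Frobenius norm
between these reconstructions. This distance is deterministic,
rotation-invariant, and insensitive to window SNP counts. Classical MDS
embeds the distance matrix, and every MDS axis is oriented so its
largest-magnitude entry is positive — removing the sign indeterminacy
that otherwise makes one-sided rules meaningless.

`mds_outlier_regions()` flags windows beyond `sd_mult` (default 2) SDs of
the mean MDS score and merges flagged windows separated by at most
`max_gap` (default 20) unflagged windows. The default is two-sided, with
a one-sided option. The pipeline wrapper `scan_contig()` uses the
one-sided rule (under the deterministic orientation the inversion side is
positive), discards regions supported by fewer than two outlier windows,
uses 50-SNP windows for boundary resolution, and adds LD blocks from a
10-kb-thinned, MAF > 5% SNP set. These wrapper defaults were chosen on
null false-positive grounds: with single-window regions admitted, random
fluctuations in inversion-free data produce of the order of one spurious
region per 10 Mb; requiring two flagged windows with the one-sided rule
drives that well below one while leaving multi-window inversion signals
untouched. `kmeans_mds_segmentation()` (deterministic quantile-seeded 1-D
k-means on MDS1) is the complementary route for contigs where an
inversion spans most of the sequence and the "outlier" logic inverts.

`ld_block_detect()` grows blocks greedily from the leftmost adjacent pair
with r² above the threshold, extending while the median of all pairwise
r² inside stays above it ("most SNPs in high LD" read as the median), and
closes the block at the last SNP whose own median LD with the block was
high, tolerating up to `max_weak = 5` consecutive weak columns. The
backtracking stops a strong block from swallowing unlinked flanking SNPs
on the strength of its internal median alone.

## Karyotype genotyping

`genotype_inversion()` runs PCA on the region's SNPs (missing dosages
mean-imputed per site), clusters PC1 with deterministic quantile-seeded
k-means (k = 3), and assigns the middle cluster as heterokaryotypes. The
call is confirmed only if (i) the middle cluster is significantly more
heterozygous than both outer clusters — one-sided Welch tests at p < 0.05
— and (ii) the middle centroid lies within 35–65% of the span between the
outer centroids. The centroid window is the numerical analogue of the
"heterozygotes have ≈50/50 mixed ancestry" criterion used when
karyotyping is done by admixture proportions; both thresholds are
package decisions where practice is usually visual. The more frequent
homokaryote cluster is labelled AA, so A/B labels are frequency-based and
arbitrary up to a swap — comparisons against truth in the tests allow the
swap. Contigs with fewer than 10,000 SNPs are refused (an explicit
`override` exists for small simulations) because sparse contigs give
ambiguous three-cluster fits.

Overlapping inversions (`overlap_genotyping()`) walk PC1→PC2→PC3 and
accept the first axis that passes the three-cluster confirmation and is
not collinear (dosage r² < 0.5) with the already-called karyotype.
Cosegregating duplicate calls — the same physical inversion split across
two assembly contigs — are recognized by `inversion_ld()`: dosage r² ≥
0.9 plus genotype concordance ≥ 0.95 recommends a merge.
`double_crossover_scan()` computes windowed Weir–Cockerham F_ST between
the called homokaryote classes and flags runs of ≥ 2 consecutive 100-kb
windows below 25% of the region median — the local homogenization left
by a historical double crossover. The 25%/2-window rule is the package's
operationalization of "significantly reduced".

## Population-genetic statistics

All estimators work from hard genotype calls (the generator simulates
high, clean coverage; with real low-coverage data a genotype-likelihood
route would be preferable — out of scope here). Per-site π uses the
unbiased `2·n_ref·n_alt/(n(n−1))`; `d_xy = p_A(1−p_B)+p_B(1−p_A)`;
Weir–Cockerham F_ST uses the full two-level variance components including
the heterozygosity term, and windowed F_ST is a ratio of sums (stable in
sparse windows, unlike a mean of ratios). Tajima's D uses the standard
constants with the chromosome count taken as the floored mean of
non-missing chromosomes over segregating sites. Sites where a group is
entirely missing are dropped from dxy/F_ST denominators. Windows come
from `make_windows()` — half-open, trailing partial retained; the
conventional schemes are 100-kb windows at 20-kb steps (F_ST scans) and
nonoverlapping 100-kb (diversity) or 200-kb (mutation load) windows.

## Characterization

Arrangement frequencies are allele counts from assigned karyotypes, with
unassigned samples excluded and hemizygous males counted once. Age is
`T = d_xy/2μ` generations with `μ = 2.9×10⁻⁹` per site per generation as
the headline rate and one generation per year for Myr conversion
(configurable); these are rough ages by construction — gene flux and
selection are ignored. Hardy–Weinberg tests are exact
(Levene–Haldane conditional on allele counts, two-sided by probability
ordering, with one-sided heterozygote excess/deficit variants); X-linked
loci use the joint conditional distribution over male allele counts and
female genotypes; karyotypes with more than two haplotype classes (a
recombinant R) fall back to an allele-shuffling permutation test with
`p = (1+#extreme)/(1+B)`.

Cline tests are Pearson correlations of per-population arrangement
frequency with latitude. Their reference distribution comes from
`maf_matched_permutation()`: 1,000 SNPs outside all inversions whose
global MAF is within ±0.05 of the inversion's minor-arrangement
frequency, each contributing its own frequency–latitude r²; the empirical
p is the plain fraction of null r² at or above the observed one,
matching the count-ratio convention of permutation tests in this
literature (an add-one option exists). "1,000" is read as one set of
1,000 SNPs per inversion. If too few SNPs match, the window widens in
0.05 steps with a warning. Across inversions, Hommel correction
(`p.adjust`) is the intended multiple-testing adjustment.

## Mutation load and haplotype structuring

`pin_pis_windows()` computes π at nonsynonymous and synonymous sites per
200-kb window and their ratio (a ratio of mean site-π values, not a mean
of ratios, to avoid exploding near-zero denominators). Thresholds follow
the lenient published pair: a karyotype group enters the analysis only
with more than 4 individuals and at least 4 usable windows, and windows
need more than 5 genes; both stricter alternatives are selectable.
"Strict" collinear filtering removes every collinear window on a contig
that carries any confirmed inversion, because suppressed recombination
leaks beyond inversion boundaries. `load_contrasts()` reports both Welch
t and Wilcoxon p for inversions-vs-collinear (two-sided) and
minor-vs-major (one-sided, minor greater) — the literature uses both
test families, so both are emitted — plus the correlation of per-group
median ratio with arrangement frequency. `nj_structuring()` builds
neighbor-joining trees (via `ape`) from normalized Hamming distances
between phased haplotypes (MAF ≥ 0.1 within the class) and flags
structuring when some internal bipartition separates two clades of ≥ 3
tips whose mean between-clade distance exceeds twice the pooled
within-clade mean — a numerical stand-in for what is usually a visual
topology call.

## Association tests

`or_enrichment()` keeps gene positions fixed and relocates each inversion
independently per permutation: a contig drawn with probability
proportional to length among contigs the interval fits on, then a uniform
start. Permuted intervals may overlap; the statistic is the number of
gene midpoints inside the union, and p is the count-ratio over 10,000
permutations. A gene is "inside" an inversion iff its midpoint is. The
count statistic is discrete, so raw p-values are lumpy; the calibration
test in the suite therefore checks exact uniformity of the randomized
(tie-broken) p and validity of the reported p at nominal levels.
`or_divergence_scan()` reports per-gene nonsynonymous d_xy between
homokaryotes with a 0.9 "fixed or nearly fixed" flag; `or_dnds_mk()` is
a counting-method dN/dS over supplied effective site counts with
Fisher's exact test on the McDonald–Kreitman 2×2 table;
`or_coverage_contrast()` flags candidate hemizygous deletions when the
between-class depth ratio leaves [0.6, 1.67] at Wilcoxon p < 0.01.

`lfmm_ridge()` is a closed-form latent-factor association model: regress
loci on environmental covariates, extract k latent factors (default
k = 5) from the SVD of the residuals, re-estimate per-locus effects
jointly with the factors by OLS, calibrate z-scores per covariate with a
genomic-inflation factor (median z²/0.456), and attach
Benjamini–Hochberg q-values. With k = 0 it reduces exactly to per-locus
regression, which the tests exploit as a degenerate-case oracle. The
standard pre-filters (locus missingness ≤ 20%, MAF ≥ 0.1, sample
missingness < 30%, per-locus mean imputation) live in `run_gea()`, which
can also drop SNPs inside inversions and append each inversion as a
single 0/1/2 pseudo-locus. Environmental covariates come from
`env_pca()` on z-scored per-population variables.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open internally and 1-based only in VCF
text. PCA/MDS axes follow one deterministic sign rule (largest-magnitude
loading positive). k-means is always 1-D and quantile-seeded, so there
is no restart stochasticity; genotyping and scanning are invariant to
sample order and PC sign flips. Monomorphic contigs, empty regions,
zero-variance frequencies, zero-length inversions and degenerate
contingency tables raise errors rather than returning silently. The
depth filter's cutoff (mean + 1 SD) is data-derived; re-applying the
filter to its own output re-estimates a lower cutoff, so exact
idempotence holds when the reported cutoff is passed back explicitly.
The heterozygote-excess site filter (one-sided exact test, p < 0.01) and
the X-like-contig rule (male:female median relative coverage < 0.75 with
female coverage ≈ 1) are package decisions where the practice they
formalize reports observations, not rules. Site thinning keeps the first
eligible SNP and enforces a true minimum spacing.

## Problem sizes in the test-suite and acceptance runs

The suite exercises study-scale structure at desk scale: cohorts of 240
individuals on 2–10 Mb contigs with SNP densities of 0.5–2 per kb
(5,000–20,000 variants), 20-seed replicate batteries for detection,
karyotyping and load recovery, a 100,000-variant simulation for age
recovery, and 200-replicate nulls for the permutation and latent-factor
calibrations. These sizes were chosen so each property is measured with
comfortable statistical margin while the whole suite stays interactive.

## Known limitations

Breakpoint-resolution detection is out of reach of this class of method;
boundaries are window-resolution. Genotype-likelihood estimation,
statistical phasing, recombination-rate (ρ) inference and admixture-model
population assignment are not implemented — the simulator emits phased
truth and hard genotypes, and geographic groups are taken from metadata.
Ages inherit all caveats of `T = d_xy/2μ`. The per-contig outlier scan
assumes inversions occupy a minority of the contig; whole-contig
inversions should be approached with `kmeans_mds_segmentation()` or
per-genome window sets.
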