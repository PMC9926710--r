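---
title: "Methods: pseudo-testcross mapping of an XY sex locus"
author: "PTXmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-testcross mapping of an XY sex locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

PTXmap infers an XX/XY sex-determination system from one outbred F1
family. This vignette documents the statistical model behind each stage,
the parameters that matter, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

# The inference chain

## Variant filtering

Two filters run in sequence, both consuming a `GenotypeTable` (a
`SummarizedExperiment` of genotype codes and allele read counts).

The **read-support filter** keeps a variant only if (1) no sample is
missing; (2) each homozygous-reference sample has ≤ 2 alternate reads and
\> 10 reference reads; (3) the mirror-image rule for homozygous-alternate
samples; and (4) each heterozygote's alternate allele fraction lies
strictly in (0.3, 0.7). All bounds are deliberately strict: a fraction of
exactly 0.3 fails. The heterozygote band is the binding rule — at 47×
coverage a single heterozygous sample falls outside it with probability
≈ 0.9%, so with ~46 heterozygous samples per testcross variant roughly a
third of true variants are sacrificed for call quality. At 20× the same
rule removes almost everything, which is why the family should be
sequenced to several tens of fold coverage before this filter is
meaningful.

The **hard site filter** applies the conventional annotation thresholds:
SNPs fail on QD \< 2, FS \> 60, MQ \< 40, MQRankSum \< −12.5,
ReadPosRankSum \< −8 or DP \< 10; indels on QD \< 2, FS \> 200 or
ReadPosRankSum \< −20. The two rank-sum thresholds are negative — the
conventional signs — since positive cut-offs of 12.5 and 8 would discard
essentially every site. Missing annotations pass and are counted, since a
missing value is evidence of nothing.

## Pseudo-testcross extraction and error screening

Offspring at maternal (0/0 × 0/1) and paternal (0/1 × 0/0, 0/1 × 1/1)
variants are recoded A/B/U. The U class drives two screens with distinct
signatures:

* sporadic U calls at a rate of a fraction of a percent per offspring are
  individual genotyping errors;
* U in about a quarter of offspring at a variant means both parents were
  truly heterozygous and one was miscalled homozygous — the offspring
  segregate 1:2:1 and the off-pattern homozygote class has expectation
  exactly 0.25.

All U codes are masked to missing, and variants with more than 10%
missing offspring (strictly) are removed, which eliminates essentially
all het × het contamination. Remaining variants are tested against 1:1
segregation (χ²₁, no continuity correction; removal at p \< 10⁻⁵),
thinned to ≥ 5 kb spacing by a greedy per-contig scan that always keeps
the first variant, and binned: variants with exactly identical code
vectors (missing pattern included — a conservative choice, since
co-binning across different missing patterns would have to invent calls)
become one marker. A second segregation test at the Bonferroni-corrected
0.05 level runs per marker after binning. The filter order follows the
narrative order of the underlying protocol: support → hard → extraction →
masking → segregation → thinning → binning → distortion.

## Two-point linkage and grouping

For markers with N pairwise-complete offspring and R mismatches, phase is
chosen so the recombinant count R′ = min(R, N−R), r̂ = R′/N, and
LOD = R′ log₁₀ r̂ + (N−R′) log₁₀(1−r̂) + N log₁₀ 2 with the convention
0·log 0 = 0 (so two identical markers give LOD = N log₁₀ 2, and no
infinite LOD can arise because the first term vanishes exactly when
r̂ = 0). Groups are connected components of the graph with edges at
rf ≤ 0.4 and LOD ≥ `suggestLod(n)`, the Bonferroni threshold
χ²₁(1 − 0.05/C(n,2)) / (2 ln 10).

## Ordering and map curation

Ordering minimises the sum of adjacent recombination fractions (SARF): an
exhaustive search over the five most informative markers (ties broken by
marker order, mirror orders skipped) seeds the map, and the remaining
markers are inserted greedily in descending order of their best pairwise
LOD. SARF was chosen over a multipoint likelihood because it is exactly
reproducible, fast, and equivalent on two-class testcross data at these
marker densities. Insertion ties below 10⁻⁶ in the criterion are treated
as equivalent placements when they are explained by a zero-rf neighbour
(the marker is placed at the leftmost tying slot); genuinely ambiguous
markers are set aside as unplaceable.

Ordered groups are then **curated**. The local expansion a marker x adds
beyond rf additivity, rf(a,x) + rf(x,b) − rf(a,b), equals 2k/N where k
counts offspring in which x disagrees with both flanking markers. Genuine
double crossovers produce k ~ Poisson(N·(rf(a,b)/2)²); a marker exceeding
the upper predictive bound λ + 3.5√λ (with a floor of one offspring) is
removed as not confidently placeable. This is the programmatic equivalent
of the recombination-fraction-plot inspection step customary in testcross
mapping, and it matters: with a 1.2% genotyping-error rate, roughly a
third of markers carry at least one undetected A↔B flip, and each such
marker would otherwise inflate the map by ~2 spurious recombinants
(≈ 2 cM at 90 offspring) — enough to visibly compress the
maternal:paternal length ratio. A companion terminal rule removes bins of
≤ 2 variants sitting within 2.5 recombinant-equivalents outside a
terminal bin of ≥ 5 variants, the characteristic signature of an
error-bearing copy of a large cosegregating block (such as the
non-recombining region). Phase-complementary markers co-located within
10⁻⁴ cM on a shared contig are redundant (the same variants called
against opposite alleles); the smaller bin is dropped.

Adjacent rf values are converted to centimorgans with the Kosambi
function d = 25 ln((1+2r)/(1−2r)) and accumulated from 0; groups are
numbered by decreasing genetic length.

## Sex-QTL scan

`calcGenoProb()` runs a two-state forward–backward chain per offspring
with transition probabilities equal to the Kosambi inverse of the cM gap
and emission 1 − e for the observed class (e = 10⁻⁴ by default, the
conventional genotyping-error prior; missing markers emit uniformly).
Posteriors match brute-force path enumeration to 10⁻⁹ (tested up to six
markers). `scanBinary()` fits, per marker, intercept-only versus
intercept + P(B) logistic models by IRLS (50-iteration cap, fitted
probabilities clamped to [10⁻¹⁰, 1−10⁻¹⁰]) and reports
LOD = Δlog-likelihood / ln 10. The cap-and-clamp scheme makes perfect
separation well defined: the full model saturates and the LOD equals the
analytic bound −[n₁ ln(n₁/n) + n₀ ln(n₀/n)]/ln 10. Permutation
thresholds shuffle the phenotype with a caller-supplied seed (restored on
exit) and take the type-7 quantile of the per-permutation maximum LOD;
the 10⁻⁵-level line customary in sex-QTL figures cannot be estimated from
1000 permutations and is deliberately not reported.

Concordance at the peak is assessed on the *inferred* genotype (posterior
class from the linkage phase), not the raw code: raw codes still carry
the genotyping errors that the hidden chain corrects, and the biological
claim — every animal's sex matches its inherited haplotype across the
NRR — is about the haplotype.

## Region delineation

On the paternal map, the sex-associated group's peak position defines the
non-recombining region: contigs all of whose paternal variants sit at
that position (tolerance 10⁻⁶ cM) are NRR; contigs with recombining
paternal markers are pseudoautosomal; contigs present in only one
parent's sex group are listed separately, since they may have diverged or
simply lack heterozygous variants in the other parent. Exact recovery of
the simulated NRR holds when error injection is disabled; at a 1.2% error
rate surviving error markers can displace individual contigs, so the
pipeline reports the delineation as best-effort evidence rather than a
guarantee.

## Depth of coverage and expression

Per-sample scales are the mean raw depth over the five longest contigs;
contigs ≥ 2500 bp enter a length-weighted PCA of the normalized
sample × contig matrix (samples as observations), and a two-component
Gaussian mixture on PC1 (model-based hierarchical initialisation, hence
deterministic) splits homogametic from heterogametic samples. If no
contig shows a between-group mean difference above 0.25 — half the
hemizygous dosage step, far above depth noise — the verdict is "no sex
signal" rather than an arbitrary labelling. Contig flags use an
unequal-variance t statistic with Benjamini–Hochberg correction across
contigs (q \< 0.05); the original bootstrap machinery of
depth-of-coverage sexing is not reproducible from its description, and
the t/BH combination tests the same null with a controlled FDR. The
[0.4, 0.6] window on the homogametic-minus-heterogametic difference
defines X-linked; other significant contigs are "sex-linked/abnormal"
(Y-linked contigs land at ≈ −0.5). "Coverage" of a gene means breadth —
the fraction of bases covered by ≥ 1 read — and the Y screen requires
\< 50% breadth in one sex with \> 90% in the other, both rules strict.

Expression classification calls a gene sex-specific at threshold t when
its own gonozooid class exceeds t and the other two tissue means are at
most t; the screen applies t = 1, then reclassifies the remainder at
t = 5, and reports the union. "Expressed" is strictly greater than t:
this convention classifies every row of the packaged candidate tables
correctly.

# The synthetic family

`simulateCross()` emulates the study design the analysis assumes: two
diploid parents, 90 F1 offspring, 15 chromosomes, female map twice the
male map, one sex chromosome whose proximal 38% never recombines in male
meiosis, ~5% of testcross-candidate sites truly het × het with one parent
miscalled homozygous, and a 1.2% per-call genotyping error rate applied
as a uniform redraw over the three diploid genotypes (so a third of
errors surface as the unexpected homozygote class, matching the observed
U rate of e/3).

Three design choices deserve emphasis:

* **Kosambi-consistent meiosis.** Gametes are Markov chains along the
  variant sites with switch probability equal to the Kosambi inverse of
  the adjacent genetic gap. A Poisson crossover process would make
  recombinant fractions Haldane-distributed and the mapper — which
  converts rf to cM through Kosambi — would never exactly recover the
  configured lengths; the Markov construction keeps simulator and mapper
  self-consistent, and realised switch counts still approximate Poisson
  crossover counts with mean equal to the map length in Morgans for
  densely spaced sites.
* **Read counts follow the call, not the truth.** Allele depths are
  drawn conditional on the reported genotype (total depth Poisson; alt
  count binomial at 0.5 for heterozygotes, at the 0.002 error floor for
  homozygotes). Drawing them from the true genotype would let the
  support filter detect and delete every injected miscall, which real
  read-level artifacts (allelic dropout, mismapping) do not permit.
* **Physical scale.** Chromosome physical sizes are free parameters; the
  desk-scale default of 1.2 Mb per chromosome with 360 sites gives a
  realistic *relative* geometry — after 5 kb thinning the maternal and
  paternal variant sets interleave densely enough that markers of the
  two maps pair within the 5 kb window — while keeping a full run of the
  pipeline around a quarter of a minute. Absolute bp-per-cM is therefore
  not realistic, and bp-denominated outputs (NRR extent) are interpreted
  relative to the simulated genome.

The generator does **not** emulate read-level data (no FASTQ, alignment
or caller artifacts beyond the error floor), population structure beyond
a single full-sib family, interference-consistent crossover placement
across non-adjacent intervals, sexual chimerism, or chromosome-scale
variation in marker density. Passing tests demonstrate that the
implementation recovers what the model plants; they do not show
robustness to violations the generator cannot produce.

# Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `nOffspring` | 90 | animals | typical F1 family size for this design |
| `chromLengthCM` | 55…30 | cM (male) | paternal map totals ≈ 0.6 Morgans/chromosome |
| `femaleMapFactor` | 2.0 | — | observed heterochiasmy in the target system |
| `nrrFraction` | 0.38 | — | NRR ≈ 6.46 of ≈ 17 Mbp on the real Y |
| `meanDepth` | 20 (47 for filter-bearing runs) | × | desk default; the support filter presumes ≈ 47× |
| `genotypeErrorRate` | 0.012 | per call | observed per-offspring error scale |
| `abxabRate` | 0.05 | per candidate site | observed het × het contamination |
| `maxRf` / `minLod` | 0.4 / `suggestLod(n)` | — | grouping thresholds of the protocol |
| `maxMissing` | 0.10 | — | strict "more than 10% missing" removal |
| `thin minBp` | 5000 | bp | physical thinning window |
| `errorProb` | 10⁻⁴ | per call | conventional prior in genotype-probability chains |

Problem sizes used in the shipped tests and acceptance script — a
15-chromosome, 90-offspring family at 47× with ~5400 sites; 10,000
replicate het × het variants; 10,000-meiosis crossover checks; brute-force
oracles at ≤ 6 markers and ≤ 10 Wilcoxon pairs — were chosen so the whole
suite completes in a few minutes on one core while keeping every
stochastic band at 3–4σ.

# Numerical conventions and degenerate inputs

* χ² segregation tests use the survival function of χ²₁ without
  continuity correction.
* `twoPoint` on fewer than two complete pairs returns an invalid-flagged
  result; grouping treats such pairs as unlinked.
* `orderGroup` of a single marker is a passthrough at 0 cM; all-zero-rf
  chains order arbitrarily but deterministically and span 0 cM.
* Map positions are non-decreasing and start at 0 by class validity.
* The Wilcoxon test drops zero differences, is exact (signrank
  distribution) for n ≤ 25 without ties, enumerates all 2ⁿ sign patterns
  exactly for tied ranks at n ≤ 15, and otherwise uses the normal
  approximation with tie correction; all differences zero gives p = 1.
* Depth normalization flags zero-scale samples unusable; contigs with
  zero variance in both groups get p = 1 (identical means) or 0.
* The permutation seed is an explicit argument (default 2023) and the
  caller's RNG state is restored on exit.

# Known limitations

* Ordering is SARF-greedy, not multipoint maximum likelihood; at very
  low marker densities or extreme missingness it can transpose nearby
  markers (distances are unaffected in expectation).
* Map curation trades a small number of genuine double recombinants
  (bounded by the Poisson guard) for the removal of error markers;
  curated maps are mildly conservative in total length.
* The NRR/PAR boundary is delineated at contig resolution and, under
  genotyping error, is best-effort (see above).
* Only the two testcross configurations are supported; fully informative
  ab × cd markers are out of scope.
* FPKM tables are consumed, never estimated; replicate-level expression
  variance is not modelled.
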