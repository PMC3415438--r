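---
title: "Models and methods behind melanomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind melanomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

melanomics reimplements a tumor/normal melanoma whole-genome analysis as a
self-contained, seedable package. This vignette is the package's own
account of the science: the models, the parameter choices and why they
were made, what the synthetic generator does and does not emulate, and the
numerical conventions that matter when reading results.

## The genotype model and its score scale

Evidence at a site is a stack of reads, each contributing an observed base
`b` with Phred base quality `Q` (error probability `e = 10^(-Q/10)`).
Only reads with mapping quality ≥ 30 and bases ≥ Q20 enter scoring; `N`
bases are dropped. The likelihood of a diploid genotype `{a1, a2}` is the
product over reads of `0.5·P(b|a1) + 0.5·P(b|a2)` with
`P(b|a) = 1 − e` when `b = a` and `e/3` otherwise — sequencing errors are
spread uniformly over the three non-template bases, the simplest model
consistent with the Phred contract. The prior over the 10 genotypes is
flat; whether the original caller used a reference-biased prior is not
documented, so we use flat and say so.

Two scores summarise the posterior. **MPG** is the posterior odds of the
best genotype over the second best — confidence in the genotype itself.
**MPV** is the odds of the aggregate non-reference posterior against
homozygous reference — confidence that the sample differs from the
reference. Both are clamped to ±255 when a posterior mass underflows, and
ties (possible only with pathological evidence, e.g. one read of each
base) break lexicographically with score 0, hence uncallable.

The scores are kept in **natural-log units**. This is a deliberate choice
forced by the calling thresholds themselves: a concordant high-quality
read moves the hom-ref MPG score by `ln 2 ≈ 0.69`, so the joint
callability criterion — score ≥ 10 *and* score/Q20-depth ≥ 0.5 — is
satisfiable at reference sites (score/depth → 0.69, score ≥ 10 from
roughly 15 concordant reads). Had the score been log10, the per-read
contribution would cap at `log10 2 ≈ 0.30` and no reference site could
ever reach a coverage ratio of 0.5; the quoted thresholds would exclude
essentially the whole genome (we measured ~0.1% callable territory under
that reading). With natural-log scores the same thresholds reproduce the
expected 80–95% callable genome at 30–48× coverage. MPV keeps the same
units with threshold 10 and no ratio criterion.

At genome scale the site likelihood is an exact linear function of the
per-site counts of reads grouped by (base, quality tier), so all sites of
a chromosome are scored with one matrix product (`score_sites()`). The
test suite asserts bit-level agreement between this path and the
read-stack path, and equality of posteriors with a brute-force
enumeration oracle to 1e-9 on a thousand random stacks.

## Somatic calling and the validation filters

A site is a somatic SSNV candidate when the tumor is MPV-callable, the
normal is MPG-callable, and the tumor's best variant genotype carries an
allele absent from the normal genotype. Sites whose tumor alleles are a
subset of the normal alleles (loss of heterozygosity) contribute no novel
allele and are dropped; we do not additionally drop tumor genotype
changes that share both alleles with the normal, the narrower of the two
possible readings. Known (dbSNP-style) positions are subtracted, as are
positions within 10 bases — inclusive, measured to the nearest indel
position — of a tumor indel call.

The three validation filters mirror the Sanger-driven error analysis:

1. **normal lookup** — any normal-sample read of mapQ ≥ 1 carrying the
   somatic allele;
2. **indel proximity** — an indel called from mapQ ≥ 1 reads with
   MPV ≥ 10 within 10 bp;
3. **strand bias** — every somatic-allele read on a single strand. A
   single read trivially satisfies "one strand", so the filter requires
   at least two somatic-allele reads before it may trigger.

Flagged calls leave the pass set but are retained with their flags (they
appear in the VCF FILTER column). `make_validation_fixture()` builds
deterministic 73-call (tissue) and 78-call (cell-culture) candidate sets
whose evidence encodes the published validation outcomes — 29 of 30
discordant tissue calls carry filter-triggering evidence spread over the
three filters, one discordant call is clean, and no concordant call
triggers anything — so the cascade's bookkeeping (97.7% and 98.7%
post-filter concordance) is reproduced by computation, not assertion.

## Copy number

Depth is summarised in non-overlapping 5 kb tiles; a tile is callable
when ≥ 80% of its bases are uniquely mappable and normal depth is
positive. The tumor/normal ratio is divided by its genome-wide median
(library-size correction) before log2. GC-content correction is omitted —
the synthetic reads have no GC bias — and is listed as a limitation for
real data. The segment caller classifies tiles at ±0.25 log2 by default;
the thresholds are configurable because the original pipeline's
segmentation parameters are not recoverable (the parameter table is an
unreadable figure in the source), and ±0.25 corresponds to roughly a
single-copy change at ~60% purity. Runs of ≥ 2 genomically consecutive
same-direction tiles merge into segments; an uncallable tile breaks a
run. Copy number is purity-adjusted by inverting the mixture expectation
`2^log2r = p·CN/2 + (1 − p)` and clipping at zero.

Cross-sample specificity is deliberately conservative: a segment called
in one sample is sample-specific only if *every* overlapped tile of the
other sample with a defined ratio lies strictly inside (−0.1, +0.1);
tiles at or beyond ±0.1 mark it shared even though never called. Tiles
with undefined ratios are excluded from the quantifier, so a segment
overlapping only unmappable territory in the other sample stays
sample-specific. The complementary strict window defines the copy-neutral
mask that restricts somatic indel calling and the purity analysis.

## Purity

At a heterozygous somatic site in diploid territory of a homogeneous
tumor, half the reads carry the somatic allele; admixed normal cells
dilute this. We take one fraction per passing somatic site from mapQ ≥ 30
reads, exclude CNV territory and sites under 10 reads (fraction
granularity), and locate the mode by Gaussian-kernel smoothing (bandwidth
0.02 on the fraction scale, evaluated on a 1001-point grid over
[0, 0.5]). The estimate is `(0.5 − mode)·2·100` percent normal cells,
floored at zero; fewer than 100 sites is an explicit error. The kernel
choice makes the estimator deterministic and robust to histogram binning;
the expected-mode comparison pools depths rather than conditioning on
them. Parameter-recovery tests plant purities 1.0/0.7/0.58 at 100× over
2000 sites and require the estimate within 3 points; a round-trip test
bounds the bias through the full simulator.

## Spectrum and strand bias

Substitutions collapse into six classes keyed by the pyrimidine of the
mutated pair; a purine-reference substitution counts in its class's
complement slot. For transcribed-strand analysis only intronic variants
inside single-strand gene territory are oriented (variants under genes on
both strands are excluded — the source is silent on this case);
minus-strand substitutions are reverse-complemented so key/complement
slots align with the coding/template strands. Each class with data gets a
two-sided exact binomial test of the key count against 50%; sidedness is
not stated in the source, and two-sided is the conservative choice.

## Enrichment null

The published block-sampling framework conditions on genome structure we
do not reconstruct; the package replaces it with a documented, seedable
simplification: per chromosome, all variant positions are mapped into the
concatenated callable territory, rotated by one uniform circular offset,
and mapped back. Inter-variant spacing — hence local clustering — is
preserved exactly; territory boundaries are respected by construction.
Enrichment is `log2(observed / mean(null))` over 10000 samplings by
default (overridable; the bundled smoke profile uses 1000), with ±1 null
SD as the error scale and suppression below 10 observed overlaps. The
common-SNP control accepts any position list; a helper filters a variant
table at ≥ 5% minor allele frequency, and the pipeline thins the control
to 2000 positions for tractability.

## Landscape partitioning and DHS analysis

The genic-landmark partition claims bases in fixed priority order:
coding, 5' UTR, 3' UTR, intron (gene minus exons), intergenic
TSS-proximal (within 5000 bp of any TSS, inclusive), intergenic
TSS-distal. Whole intervals (e.g. DHSs) are assigned to the
highest-priority category they overlap by ≥ 1 bp — priority-first rather
than majority-vote, matching single-category assignment of whole
elements. Non-genic constraint tiles mask everything within 10 kb of any
part of a gene or TSS, carve 50 kb tiles from the remainder, drop tiles
with zero constrained overlap, sort by constrained fraction and split
into ten equal bins, the remainder joining the last bin (the source
states "ten equal-sized bins" without a remainder rule).

DHS clustering links intervals across cell types at ≥ 1 bp overlap
(book-ended intervals do not link); connected components span the union
interval and carry the contributing cell types. The signature tree
clusters each type's binary cluster-membership vector under Euclidean
distance with average linkage — the source names only the metric, so the
linkage is our fixed, documented choice — with rows in lexicographic
label order for deterministic tie-breaking, then re-roots on the GM
outgroup clade (falling back, with a warning, to the first outgroup tip
if the outgroup is not monophyletic). Trees serialise to Newick with
branch lengths from merge heights. A DHS cluster is transcribed when any
mapQ ≥ 30 RNA read overlaps it; two cluster sets are compared by
two-sided Fisher exact test on the 2×2 of membership × transcribed.

## The synthetic generator

The generator reproduces the statistical structure the pipeline assumes,
at study conditions fixed once: 42 somatic SSNVs per Mb per tumor sample;
75% of somatic substitutions drawn as C>T/G>A (the UV signature dominates
the published spectra; the exact fraction is not printed, and 0.75 is our
one-time choice); two tumor samples sharing 96% of their somatic load
(the published shared fraction over common callable territory), with
purities 1.0 (culture) and 0.58 (tissue, i.e. 42% normal cells); normal
48×, tumors 30×; base qualities Q40/Q30/Q20 at 0.7/0.2/0.1; 5% of reads
at low mapping quality (Q10) — the two-point mapQ mixture suffices
because the analysis only ever thresholds at Q30 and Q1; germline
heterozygosity 1/1500 bp with 90% of germline variants in the
known-variant list. Tumor reads mix tumor-cell and normal-cell alleles
by purity; copy number scales both depth and allele sampling weights
inside planted CNV segments (the mutated allele sits on one copy;
germline hets inside CNVs are treated as balanced). Evidence is generated
per site — pileup columns, not aligned reads — in two interchangeable
forms: full per-read stacks and per-site (base × quality-tier) count
matrices for genome scale.

What it does **not** emulate, and what passing tests therefore do not
show about real data: alignment and duplicate artifacts, context- or
cycle-dependent error profiles, GC-coverage bias, subclonal population
structure (a single tumor clone plus normal admixture only), indel read
evidence (indel calls are carried as scored records), and FASTQ/BAM
emission.

## Numerical conventions and problem sizes

Intervals are GRanges (1-based, closed) internally; BED and GFF3 files
cross the 0-based half-open boundary through rtracklayer, VCF positions
are 1-based, and the pileup TSV dialect uses 1-based positions. All
randomness flows from explicit seeds: the simulator derives per-stage,
per-chromosome, per-sample seeds from its one configured seed, and the
pipeline's own draws (null rotations, control thinning, strand splits at
error-driven sites) use fixed offsets of the pipeline seed, so a rerun of
the same configuration is byte-identical file for file.

The bundled smoke profile (`smoke_config()`) runs the whole pipeline on
five 2 Mb chromosomes — 10 Mb of genome, three samples at full depth —
with 1000 enrichment samplings and a 2000-position control; this is the
problem size used by the end-to-end tests and keeps a complete run in the
minutes range on one CPU. Unit and property tests use 0.1–5 Mb genomes;
the genotyper oracle suite enumerates all 10 genotypes on stacks of up to
50 reads. Purity recovery uses 2000 sites at 100×; enrichment calibration
uses a 10 Mb genome at 1000 samplings.

## Known limitations

No GC correction and no segmentation p-values in the CNV caller; the
enrichment null is a circular-rotation stand-in for the published
structure-aware bootstrap; the purity model ignores CNV-aware allele
fractions beyond masking CNV territory; multi-allelic sites beyond the
10 diploid genotypes are out of scope; and the validation fixtures encode
the published Sanger outcomes rather than re-deriving them from raw
traces, which is exactly what they are for — regression-testing the
filter cascade's bookkeeping.
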