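---
title: "Methods: pooled-segregant QTL mapping, aneuploidy and dosage analysis"
author: "bsaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-segregant QTL mapping, aneuploidy and dosage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The mapping problem

A diploid wine yeast that is heterozygous at thousands of sites is
sporulated; each haploid monosporic clone receives one random mosaic
of the two parental haplotypes.  If a trait (here, growth on a toxic
molybdate medium) is controlled by segregating loci, pools of
phenotypically extreme clones will show skewed allele frequencies near
those loci and 50/50 frequencies elsewhere.  `bsaqtl` implements that
whole chain: marker discovery from a multi-sample VCF, the pool-pair
association scan, QTL interval calling, read-depth aneuploidy
detection, de-novo variant subtraction, and a chromosome-dosage
summary of expression counts — plus a cross simulator that generates
every input, so each stage is testable without raw sequencing data.

## The association statistic

For a marker with reference/alternate read counts $(r_1, a_1)$ in one
pool and $(r_2, a_2)$ in another, the score is the absolute log odds
ratio

$$\mathrm{LOD} = \left|\log_{10}
  \frac{(a_1 + \tfrac12)/(r_1 + \tfrac12)}
       {(a_2 + \tfrac12)/(r_2 + \tfrac12)}\right|.$$

Two choices are deliberate.  The Haldane–Anscombe $\tfrac12$
correction keeps every site finite: a fully selected locus sequenced
at 40x in both pools scores $\log_{10} 6561 \approx 3.82$ rather than
infinity, and the statistic stays symmetric under swapping pools or
swapping ref/alt in both pools at once.  Second, the score is computed
from read counts, not from rounded frequencies, so deeper sites carry
more information.  Zero-depth sites in either pool are skipped and
counted rather than scored.

Peaks are local maxima with LOD above a cutoff of 3; each peak's
support interval runs outward to the first flanking marker whose LOD
has fallen one unit below the peak (the chromosome end if that never
happens).  Endpoints sit on marker positions — the data's actual
resolution.  When two peaks' intervals overlap on a chromosome they
are merged and the higher peak kept; an exact tie between adjacent
maxima resolves to the leftmost, so output is deterministic.  The
common region of two comparisons is the pairwise intersection of their
intervals, which is how two overlapping single-comparison intervals
such as 512–560 kb and 527–572 kb reduce to a shared 527–560 kb
candidate region.

No smoothing is applied by default, matching a per-variant scan; a
rolling-median option (`smooth_window`, in markers) exists for
low-depth data.  Permutation significance is out of scope by design:
the fixed LOD-3 rule is the procedure being reproduced.

## Marker filtering and de-novo variants

Heterozygous markers are called from the parent sample of a VCF with
an inclusive allele-frequency band and a depth floor: keep a site when
$0.25 \le a/(r+a) \le 0.75$ and $r + a \ge 20$.  Both bounds are
closed so the printed limits are attainable — AD of (15,45) at depth
60 (AF exactly 0.75) is retained.  Multiallelic records are skipped
and counted; the filter is idempotent and monotone in its parameters.

De-novo variants of the evolved strain are the set difference keyed on
(chromosome, position, ref, alt): a variant survives only if the
identical alternate allele is absent from the parent's calls and from
the parent's heterozygous set.  Matching on position alone would
conflate different substitutions at one site, so the stricter key is
used.

## Aneuploidy from read depth

Coverage is averaged in non-overlapping 1000-bp tiling windows (a
partial terminal window is normalized by its true length).  Each
chromosome's median window depth is divided by the genome-wide median;
medians rather than means keep both numerator and denominator robust
to local amplifications.  A chromosome is flagged when its ratio falls
within 0.15 of a grid point $k/2$, $k \ne 2$: a trisomic chromosome in
a diploid sits at $3/2 = 1.5$, a monosomy at $0.5$.  Tiling windows
were chosen over sliding ones so windows are independent; ratios are
invariant under global depth scaling.  A labelled extension,
`segmental_cnv()`, reports runs of ten or more consecutive aberrant
windows as within-chromosome candidates.

## Expression dosage

Counts are normalized with median-of-ratios size factors (the median,
over genes detected in every sample, of count over gene-wise geometric
mean).  Per-gene log2 fold changes use strain means plus a 0.5
pseudocount, chosen so a gene absent from both strains scores exactly
zero and low-count genes stay stable.  The dosage summary contrasts
each chromosome's mean log2 FC with the mean of all other chromosomes
together; a 1.5x dosage is expected near $\log_2 1.5 \approx 0.585$
over a background near zero.  Because it is not stated whether such
summaries are taken over all genes or significant genes only, both
variants are reported when significance flags are supplied.
Differential-expression testing itself (dispersion estimation, Wald
tests) is deliberately not reimplemented; the module accepts external
FDR flags and otherwise stays descriptive.  Two-fold binning is
inclusive: $|\log_2 \mathrm{FC}| \ge 1$.

## What the simulator emulates

The generator reproduces the statistical structure the analysis
assumes, under fixed default study conditions:

* 16 chromosomes with S288c-like lengths; 18,047 markers placed
  uniformly at random, proportional to chromosome length (the
  filtered-marker density of a deeply sequenced heterozygous diploid).
* Meiosis: each segregant chromosome starts from either haplotype with
  probability 1/2; crossovers are Poisson with mean equal to the
  genetic length under a uniform 0.35 cM/kb map (the yeast genome
  average) with no interference, so two-point recombination follows
  Haldane's function $c = (1 - e^{-2d})/2$.
* Phenotype: a deterministic two-locus epistatic rule — major locus
  (chrXII analog) sensitive/resistant, modifier (chrIV analog)
  splitting the resistant class — plus an Intermediate noise class
  drawn with probability 0.4 from resistant genotypes.  With 69
  segregants this realizes cluster configurations near the observed
  37/9/9/14 split; intermediates are never pooled.
* Reads: per-site depth Poisson around 80x for pools and 133x for the
  parent (a negative-binomial dispersion knob exists), alternate reads
  binomial with a 0.002 per-read error; counts are written as a
  VCF 4.2 with per-sample AD/DP so the analysis consumes real files.
* Coverage: window depths Poisson-scaled by chromosome copy number at
  100x; expression: log-uniform baselines in 10–1000, negative
  binomial with dispersion 0.05, 3 parent vs 1 evolved replicates,
  dosage folds applied per chromosome.

What it does not emulate: gene conversion and spore-viability effects,
GC-content and mappability bias in coverage, base-level read errors
correlated along reads, linkage disequilibrium from shared library
preparation, or real expression covariance between neighbouring genes.
Passing tests therefore demonstrate that the statistics recover
planted structure under the stated sampling models — not that every
artifact of real short-read data is handled.

## Numerical and degenerate-input choices

Interval arithmetic is 1-based closed internally (VCF convention);
BED output converts to 0-based half-open.  Zero-depth sites are
skipped, not errored, during scans but are an error in `lod_score()`
called directly.  A cross with an empty phenotype pool refuses to
generate reads for it.  Window widths below 100 bp or wider than the
smallest chromosome are rejected.  Stage seeds are fanned out from one
global seed through a fixed affine scheme so each pipeline stage is
independently reproducible; all generators are bit-reproducible given
the same seed.

## Problem sizes and observed behaviour

The replicate studies in the test suite use desk-scale versions of the
study design chosen to keep the whole suite fast while leaving the
per-replicate statistics at the study's own depths: 2,000 markers
(about one per 6 kb) instead of 18,047, 50 replicates for QTL
recovery, and 100 for trisomy recovery.  At those conditions the
planted major QTL lies inside the called 1-LOD interval in ~94% of
replicates and the sensitive-vs-resistant scans call no intervals on
the 14 chromosomes without planted loci.  The 9-vs-9
resistant-vs-resistant comparison does occasionally (~8% of
replicates) exceed LOD 3 on a null chromosome: with only nine clones a
pool's local haplotype frequency drifts far from 0.5, and the scan
honestly reports that drift.  That is a property of tiny pools at a
fixed LOD-3 rule, worth remembering when interpreting
resistant-vs-resistant intervals from real crosses of this size.

A worked end-to-end example with printed output is in the README;
`run_bsa_pipeline(default_config(seed))` reproduces it.

## Known limitations

The LOD statistic has no explicit null model, so the LOD-3 rule's
false-positive rate depends on pool size and depth (see above).
Support intervals are marker-resolution and can only be as tight as
the local marker spacing.  Aneuploidy calls assume most of the genome
sits at baseline ploidy; a genome where half the chromosomes are
aberrant would shift the median baseline.  The dosage summary is
descriptive and inherits whatever biases the supplied significance
flags carry.
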