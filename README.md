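# bsaqtl

Bulk segregant analysis (BSA) for yeast crosses: map a trait by
sequencing pools of phenotypically extreme haploid segregants and
scanning for allele-frequency divergence between pools, with
companion modules for read-depth aneuploidy detection, de-novo
variant identification, and chromosome-dosage expression summaries.

The package targets the analyst who has a heterozygous diploid strain
(e.g. a wine yeast selected for a resistance phenotype), sporulates
it, phenotypes the monosporic clones, and pool-sequences the
phenotype classes — and who wants the whole chain from multi-sample
VCF to called QTL intervals as reproducible, tested functions.  A
built-in cross simulator generates every input (marker maps, meiotic
genotypes, pooled read counts, coverage tracks with planted
copy-number changes, dosage-affected expression counts), so the
entire pipeline runs and is verifiable without any raw sequencing
data.

## The statistic

Markers are sites heterozygous in the parent, kept when the parent's
alternate-allele frequency lies in [0.25, 0.75] at depth ≥ 20.  For a
marker with ref/alt read counts (r₁, a₁) and (r₂, a₂) in two pools,
association is scored as the absolute log odds ratio with a
Haldane–Anscombe continuity correction:

    LOD = | log10( ((a₁+½)/(r₁+½)) / ((a₂+½)/(r₂+½)) ) |

QTL peaks are local maxima with LOD > 3; each peak's support interval
extends to the first flanking markers where the LOD has dropped one
unit below the peak, and intervals from two comparisons intersect
into a common candidate region.  Aneuploidy is called from 1000-bp
coverage windows as the chromosome-median / genome-median depth ratio
snapped to the copy-number grid (3:2 = trisomy in a diploid).
Expression dosage is summarized as each chromosome's mean log2 fold
change (median-of-ratios normalized) against all other chromosomes.

## Worked example

```r
library(bsaqtl)
run <- run_bsa_pipeline(default_config(seed = 1), out_dir = "readme_run")
print(run)
```

```
<bsa_run> seed 1 -> readme_run
  13 artifacts: cross.vcf, het_sites.tsv, lod_SvRP.tsv, lod_SvRE.tsv, lod_RPvRE.tsv
<cluster_report> 69 segregants
          phenotype  n percent
1         Sensitive 42      61
2 ResistantParental  9      13
3  ResistantEvolved 10      14
4      Intermediate  8      12
  common QTL region: chrXII 530681-530681
  common QTL region: chrXII 537607-552338
  aneuploidy: chrI ratio 1.50 (copy 3)
```

Reading it: the simulated cross of 69 monosporic clones split into a
sensitive majority, two small resistant classes, and an intermediate
class (the three non-intermediate classes are what gets pooled and
sequenced).  Both sensitive-vs-resistant LOD scans peaked on chrXII —
where the major resistance locus was planted at 543.5 kb — and their
1-LOD support intervals intersect in a common region containing it
(at 80× pooled depth the noisy per-marker LOD can split the peak, so
a degenerate one-marker intersection can appear next to the main
region, as here).  The coverage stage recovers the planted chrI
trisomy as a 1.50 depth ratio.  All stage outputs (VCF, LOD TSVs,
interval BEDs, bedGraph coverage, count and summary TSVs, truth and
manifest JSON) are in `readme_run/`; rerunning with the same config
is bit-identical, and `plot(run$results$comparison)` draws the
three-panel genome-wide LOD figure.

Individual stages are plain functions if you bring your own files:

```r
vcf <- read_vcf("pools.vcf")
het <- call_het_sites(vcf, parent_sample = "parent")   # 0.25-0.75, depth >= 20
tr  <- bsa_scan(het, pool_counts(vcf, "sensitive"), pool_counts(vcf, "resistant"))
call_qtl(tr, threshold = 3, drop = 1)
```

```r
lod_score(40, 0, 0, 40)
#> [1] 3.81697      # complete selection at 40x clears the LOD-3 cutoff
```

## Layout

* `R/` — simulators (`simulate_*`), variant IO (`read_vcf`,
  `call_het_sites`, `subtract_parental_variants`), the scan
  (`lod_score`, `bsa_scan`, `call_qtl`, `common_region`,
  `compare_all_pools`), CNV (`window_depth`, `chromosome_ratios`,
  `call_aneuploidy`), expression (`size_factors`,
  `log2_fold_change`, `chromosome_dosage_summary`,
  `bin_fold_changes`), and the orchestrator (`run_bsa_pipeline`,
  `cluster_report`).
* `vignettes/bsa-qtl-mapping.Rmd` — the methods vignette: model
  assumptions, parameter choices, what the simulator does and does
  not emulate, numerical decisions, limitations.
* `inst/scripts/run_pipeline.R` — shell entry point over
  `run_bsa_pipeline()` for YAML-config runs.
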